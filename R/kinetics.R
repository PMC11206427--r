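#' Two-compartment disposition constants
#'
#' Micro rate constants and hybrid (alpha/beta) rate constants of the
#' two-compartment disposition system: `k10 = CL/Vc`, `k12 = Q/Vc`,
#' `k21 = Q/Vp`, with `alpha` and `beta` the roots of
#' \eqn{s^2 - (k_{10}+k_{12}+k_{21})s + k_{10}k_{21} = 0} (alpha >= beta > 0).
#'
#' @param ind Individual parameters: a list with positive `cl`, `vc`, `vp`,
#'   `q` (as returned by [individual_parameters()]).
#' @return List with `k10`, `k12`, `k21`, `alpha`, `beta` (all 1/h).
#' @examples
#' disposition(list(cl = 3.55, vc = 33.5, vp = 138, q = 52.8))
#' @export
disposition <- function(ind) {
  cl <- ind$cl; vc <- ind$vc; vp <- ind$vp; q <- ind$q
  if (any(c(cl, vc, vp) <= 0) || q < 0)
    stop("disposition requires positive CL, Vc, Vp and non-negative Q")
  k10 <- cl / vc
  k12 <- q / vc
  k21 <- q / vp
  s <- k10 + k12 + k21
  p <- k10 * k21
  disc <- sqrt(max(s^2 - 4 * p, 0))
  alpha <- (s + disc) / 2
  beta <- p / alpha # numerically stable companion root
  if (beta <= 0)
    stop("degenerate disposition: beta rate constant is non-positive (Q = 0?)")
  list(k10 = k10, k12 = k12, k21 = k21, alpha = alpha, beta = beta)
}

#' Build a dosing regimen table
#'
#' Dose events are rows of a data frame with columns `time` (h), `amt` (mg),
#' `route` (`"iv"`, `"oral"`, `"ng"`), `tinf` (infusion duration, h; `NA`
#' for extravascular doses), `ss` (1 = the record stands for an established
#' steady-state regimen), and `ii` (inter-dose interval, h; required when
#' `ss = 1`).
#'
#' @param amt Dose amount (mg), positive.
#' @param interval Dosing interval (h).
#' @param n_doses Number of doses; ignored when `ss = TRUE`.
#' @param route Administration route.
#' @param tinf Infusion duration (h), IV only; default 1 h.
#' @param start Time of the first dose (h).
#' @param ss If `TRUE`, emit a single steady-state dose record.
#' @return A `data.frame` of dose events.
#' @examples
#' dose_regimen(200, 12, ss = TRUE)             # 200 mg q12h IV at steady state
#' dose_regimen(200, 12, n_doses = 5, route = "oral")
#' @export
dose_regimen <- function(amt, interval, n_doses = 1L,
                         route = c("iv", "oral", "ng"),
                         tinf = 1, start = 0, ss = FALSE) {
  route <- match.arg(route)
  stopifnot(amt > 0, interval > 0)
  if (route != "iv") tinf <- NA_real_ else stopifnot(tinf > 0)
  if (ss) {
    data.frame(time = start, amt = amt, route = route, tinf = tinf,
               ss = 1L, ii = interval)
  } else {
    data.frame(time = start + interval * (seq_len(n_doses) - 1L), amt = amt,
               route = route, tinf = tinf, ss = 0L, ii = NA_real_)
  }
}

# Contribution of one dose event to the central concentration at times t
# (absolute). Exponential-term bookkeeping shared by single-dose and
# steady-state records; steady state multiplies each exponential by its
# accumulation factor 1/(1 - exp(-lambda * ii)).
one_dose_conc <- function(t, dose, ind, dc) {
  tau <- t - dose$time
  out <- numeric(length(t))
  live <- tau >= 0
  if (!any(live)) return(out)
  tau <- tau[live]
  ss <- isTRUE(dose$ss == 1)
  if (ss) {
    if (!is.finite(dose$ii) || dose$ii <= 0)
      stop("steady-state dose record requires a positive interval ii")
    tau <- tau %% dose$ii # continuing q-ii dosing
  }
  al <- dc$alpha; be <- dc$beta; k21 <- dc$k21
  if (dose$route == "iv") {
    tinf <- dose$tinf
    if (!is.finite(tinf) || tinf <= 0) stop("IV dose requires a positive tinf")
    r0 <- dose$amt / tinf
    co <- c(al = (al - k21) / (al - be), be = (k21 - be) / (al - be))
    lam <- c(al = al, be = be)
    val <- numeric(length(tau))
    for (i in 1:2) {
      l <- lam[i]
      cterm <- r0 * co[i] / (ind$vc * l)
      acc <- if (ss) exp(-l * dose$ii) / (1 - exp(-l * dose$ii)) else 0
      during <- tau <= tinf
      # during infusion: current (truncated) input plus accumulated tail of
      # earlier doses; after: single post-infusion decay with accumulation
      val[during] <- val[during] + cterm *
        ((1 - exp(-l * tau[during])) +
           (1 - exp(-l * tinf)) * exp(-l * (tau[during] - tinf)) * acc)
      post <- !during
      accpost <- if (ss) 1 / (1 - exp(-l * dose$ii)) else 1
      val[post] <- val[post] + cterm *
        (1 - exp(-l * tinf)) * exp(-l * (tau[post] - tinf)) * accpost
    }
  } else {
    ka <- ind$ka
    if (!is.finite(ka) || ka <= 0) stop("oral dose requires ka > 0")
    # guard exact pole ka == alpha or beta
    if (abs(ka - al) < 1e-9 * al) ka <- ka * (1 + 1e-7)
    if (abs(ka - be) < 1e-9 * be) ka <- ka * (1 + 1e-7)
    co <- c((k21 - al) / ((ka - al) * (be - al)),
            (k21 - be) / ((ka - be) * (al - be)),
            (k21 - ka) / ((al - ka) * (be - ka)))
    lam <- c(al, be, ka)
    scale <- ind$f_oral * dose$amt * ka / ind$vc
    val <- numeric(length(tau))
    for (i in 1:3) {
      acc <- if (ss) 1 / (1 - exp(-lam[i] * dose$ii)) else 1
      val <- val + scale * co[i] * exp(-lam[i] * tau) * acc
    }
  }
  out[live] <- val
  out
}

#' Central-compartment concentration by superposition
#'
#' Closed-form concentration of the linear two-compartment model with
#' zero-order infusion (IV) or first-order absorption (oral/nasogastric)
#' input, summed over all dose events administered at or before each
#' requested time. Steady-state dose records are evaluated with the exact
#' accumulation factors.
#'
#' @param ind Individual parameters ([individual_parameters()] or any list
#'   with `cl`, `vc`, `vp`, `q`, `ka`, `f_oral`).
#' @param doses Dose-event data frame (see [dose_regimen()]), sorted by time.
#' @param t Numeric vector of times (h, non-negative).
#' @return Concentrations (mg/L), one per element of `t`.
#' @examples
#' ind <- individual_parameters(vori_final_model(), reference_covariates())
#' concentration(ind, dose_regimen(200, 12, ss = TRUE), c(1, 6, 12))
#' @export
concentration <- function(ind, doses, t) {
  stopifnot(is.numeric(t), all(t >= 0))
  if (is.null(doses) || nrow(doses) == 0L) return(numeric(length(t)))
  if (is.unsorted(doses$time)) stop("dose events must be sorted by time")
  dc <- disposition(ind)
  out <- numeric(length(t))
  # a steady-state record stands for the whole established regimen: it
  # resets the system, superseding all earlier dose events
  ss_times <- doses$time[doses$ss == 1]
  last_ss <- vapply(t, function(ti) {
    prior <- ss_times[ss_times <= ti]
    if (length(prior)) max(prior) else -Inf
  }, 0)
  for (r in seq_len(nrow(doses))) {
    contrib <- one_dose_conc(t, doses[r, ], ind, dc)
    contrib[doses$time[r] < last_ss] <- 0
    out <- out + contrib
  }
  pmax(out, 0)
}

#' Steady-state exposure metrics
#'
#' Daily exposure and trough for a maintenance regimen whose interval
#' divides 24 h: `auc24 = F * (daily dose) / CL` (F = 1 for IV), the
#' steady-state trough `cmin` evaluated at the end of the dosing interval,
#' and the half-life reported two ways — the hybrid terminal (beta) phase
#' half-life `ln 2 / beta`, and a mono-compartmental convention
#' `ln 2 * Vc / CL` labelled `table3_convention` (the summary convention
#' used in grouped parameter tables).
#'
#' @param ind Individual parameters.
#' @param regimen A dose-event data frame describing one repeating dose:
#'   a steady-state record from `dose_regimen(..., ss = TRUE)`, or a single
#'   dose row whose `ii`/`interval` is taken from `interval`.
#' @param interval Dosing interval override (h); defaults to the regimen's
#'   `ii`.
#' @return List with `auc24` (mg·h/L), `cmin` (mg/L), `half_life` (h, beta)
#'   and `half_life_table3` (h).
#' @export
steady_state_metrics <- function(ind, regimen, interval = NULL) {
  if (is.null(interval)) interval <- regimen$ii[1]
  if (!is.finite(interval) || interval <= 0 || (24 %% interval) != 0)
    stop("regimen interval must be positive and divide 24 h")
  amt <- regimen$amt[1]
  stopifnot(amt > 0)
  f <- if (regimen$route[1] == "iv") 1 else ind$f_oral
  ssrec <- regimen[1, ]
  ssrec$ss <- 1L; ssrec$ii <- interval; ssrec$time <- 0
  dc <- disposition(ind)
  cmin <- one_dose_conc(interval - 1e-9, ssrec, ind, dc)
  list(auc24 = f * amt * (24 / interval) / ind$cl,
       cmin = as.numeric(cmin),
       half_life = log(2) / dc$beta,
       half_life_table3 = log(2) * ind$vc / ind$cl)
}
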
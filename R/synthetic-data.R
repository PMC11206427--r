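# Lognormal parameters matched to a reported median and IQR:
# sdlog = log(q75/q25) / (2 * qnorm(0.75)); meanlog is then calibrated so
# that the median AFTER truncation to [lower, upper] equals the target
# (heavy-tailed covariates such as qCRP would otherwise be shifted by the
# physiologic cap).
lnorm_from_median_iqr <- function(median, q25, q75, lower, upper) {
  sdlog <- log(q75 / q25) / (2 * qnorm(0.75))
  trunc_median <- function(mu) {
    p <- stats::plnorm(c(lower, upper), mu, sdlog)
    stats::qlnorm(p[1] + 0.5 * (p[2] - p[1]), mu, sdlog)
  }
  mu <- stats::uniroot(function(m) trunc_median(m) - median,
                       log(median) + c(-2, 2), tol = 1e-10)$root
  list(meanlog = mu, sdlog = sdlog, lower = lower, upper = upper)
}

# truncated lognormal by resampling (no point mass at the bounds)
rlnorm_trunc <- function(n, meanlog, sdlog, lower, upper) {
  x <- rlnorm(n, meanlog, sdlog)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- rlnorm(length(bad), meanlog, sdlog)
    bad <- bad[x[bad] < lower | x[bad] > upper]
  }
  x
}

#' Synthetic study-design generator configuration
#'
#' Defaults emulate the observed ICU cohort: 408 subjects; about 10%
#' contribute an intensive steady-state profile (the prospective sub-study)
#' and the rest sparse steady-state troughs from routine TDM, a quarter of
#' whom are monitored on a second occasion; routes 68.1% IV / 11.0% oral /
#' 20.8% nasogastric; 83.8% on 200 mg q12h with the remainder spread over
#' 100-300 mg q12h; CRRT prevalence 24% and ECMO 22%; covariates lognormal,
#' matched to the cohort's median/IQR. Prothrombin time is not tabulated in
#' the source cohort; its distribution (median 15 s, IQR 13-18 s) is a
#' documented stand-in.
#'
#' @param n_subjects Number of subjects.
#' @param frac_intensive Fraction with the intensive 7-sample profile.
#' @param prob_second_occasion Probability a sparse subject has a second
#'   trough occasion (calibrated so expected observations scale to the
#'   cohort's 746 at n = 408).
#' @param route_mix Named probabilities for `iv`, `oral`, `ng`.
#' @param regimen_mix Named probabilities over q12h maintenance doses (mg).
#' @param crrt_prevalence,ecmo_prevalence Bernoulli prevalences.
#' @param prob_female Probability of female sex.
#' @param tinf Infusion duration (h) for IV dosing.
#' @param interval Dosing interval (h).
#' @param model True generating `vori_model` (defaults to the published
#'   final model).
#' @param seed Master seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_subjects = 408L,
                             frac_intensive = 0.10,
                             prob_second_occasion = 0.254,
                             route_mix = c(iv = 0.681, oral = 0.110, ng = 0.208),
                             regimen_mix = c(`200` = 0.838, `150` = 0.039,
                                             `100` = 0.022, `250` = 0.051,
                                             `300` = 0.050),
                             crrt_prevalence = 0.24,
                             ecmo_prevalence = 0.22,
                             prob_female = 0.297,
                             tinf = 1, interval = 12,
                             model = vori_final_model(),
                             seed = 20240522L) {
  stopifnot(n_subjects >= 0, frac_intensive >= 0, frac_intensive <= 1)
  route_mix <- route_mix / sum(route_mix)
  regimen_mix <- regimen_mix / sum(regimen_mix)
  cov_dists <- list(
    qcrp = lnorm_from_median_iqr(73.6, 30.0, 160.0, 0.5, 600),
    clcr = lnorm_from_median_iqr(68.5, 45.5, 102.5, 5, 300),
    plt = lnorm_from_median_iqr(150.5, 88.0, 223.8, 10, 1000),
    pt = lnorm_from_median_iqr(15, 13, 18, 8, 60),
    age = lnorm_from_median_iqr(66, 57, 73, 18, 95),
    weight = lnorm_from_median_iqr(65, 55, 75, 35, 150),
    ast = lnorm_from_median_iqr(36, 23, 61, 5, 1500),
    alt = lnorm_from_median_iqr(27, 16, 51, 3, 1500),
    bili = lnorm_from_median_iqr(12.9, 8.1, 24.2, 2, 400),
    alb = lnorm_from_median_iqr(34, 30.3, 38, 15, 55),
    sofa = lnorm_from_median_iqr(7, 4, 10, 0.5, 24),
    apache2 = lnorm_from_median_iqr(19, 14, 25, 2, 60))
  structure(list(n_subjects = as.integer(n_subjects),
                 frac_intensive = frac_intensive,
                 prob_second_occasion = prob_second_occasion,
                 route_mix = route_mix, regimen_mix = regimen_mix,
                 crrt_prevalence = crrt_prevalence,
                 ecmo_prevalence = ecmo_prevalence,
                 prob_female = prob_female,
                 tinf = tinf, interval = interval,
                 cov_dists = cov_dists, model = model, seed = seed),
            class = "generator_config")
}

#' Sample subject covariate vectors
#'
#' Continuous covariates are lognormal draws matched to the cohort's
#' median/IQR and truncated to physiologic ranges; CRRT/ECMO/sex are
#' Bernoulli. Covariates are sampled independently of clearance random
#' effects, so covariates not in the generating model act as null "decoys"
#' for selection-specificity checks.
#'
#' @param n Number of subjects.
#' @param config A [generator_config()].
#' @param seed Optional seed (defaults to the config's).
#' @return Data frame, one row per subject.
#' @export
sample_covariates <- function(n, config = generator_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n >= 0)
  out <- data.frame(row.names = seq_len(n))
  for (nm in names(config$cov_dists)) {
    d <- config$cov_dists[[nm]]
    out[[nm]] <- rlnorm_trunc(n, d$meanlog, d$sdlog, d$lower, d$upper)
  }
  out$sofa <- round(out$sofa)
  out$apache2 <- round(out$apache2)
  out$crrt <- rbinom(n, 1, config$crrt_prevalence)
  out$ecmo <- rbinom(n, 1, config$ecmo_prevalence)
  out$sex <- rbinom(n, 1, config$prob_female)
  out
}

#' Sample dosing and observation designs
#'
#' Intensive subjects receive IV dosing (the intensive schedule is
#' infusion-anchored) and a 7-sample steady-state profile: pre-dose, end of
#' infusion, and 2, 4, 6, 8 and 12 h after the start of infusion. Sparse
#' subjects receive one steady-state trough 30 min before the next dose,
#' with a second monitoring occasion four days later in a configurable
#' fraction. Steady state is encoded as an SS dose record (dosing
#' established for >= 5 days before sampling).
#'
#' @param n Number of subjects.
#' @param config A [generator_config()].
#' @param seed Optional seed.
#' @return List of per-subject designs: `route`, `amt`, `intensive`,
#'   `occasions` (dose-record start times) and `obs_times` per occasion
#'   (relative to the occasion's dose record).
#' @export
sample_design <- function(n, config = generator_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tinf <- config$tinf
  ii <- config$interval
  lapply(seq_len(n), function(i) {
    intensive <- runif(1) < config$frac_intensive
    route <- if (intensive) "iv" else
      sample(names(config$route_mix), 1, prob = config$route_mix)
    amt <- as.numeric(sample(names(config$regimen_mix), 1,
                             prob = config$regimen_mix))
    occ_starts <- 10 * ii # >= 5 days of q12h dosing
    if (!intensive && runif(1) < config$prob_second_occasion)
      occ_starts <- c(occ_starts, occ_starts + 8 * ii)
    obs <- if (intensive)
      list(c(0, tinf, 2, 4, 6, 8, 12))
    else
      rep(list(ii - 0.5), length(occ_starts))
    list(route = route, amt = amt, intensive = intensive,
         occasions = occ_starts, obs_times = obs)
  })
}

#' Generate a synthetic event dataset
#'
#' Draws covariates and designs, samples per-subject lognormal random
#' effects from the model's omega, computes concentrations from the
#' closed-form kinetics with the covariate model evaluated occasion-wise
#' (the second trough occasion redraws the CRRT flag with persistence and
#' jitters qCRP), and adds combined proportional + additive residual error.
#' Negative simulated concentrations are resampled; values below the assay
#' LLOQ are flagged BLQ. The generating model and true etas are stored in
#' the dataset's `truth` slot for recovery tests.
#'
#' @param config A [generator_config()].
#' @param seed Optional master seed override.
#' @return A `pk_dataset` with `truth = list(model, etas, config)`.
#' @export
generate_dataset <- function(config = generator_config(), seed = NULL) {
  if (is.null(seed)) seed <- config$seed
  set.seed(seed)
  n <- config$n_subjects
  model <- config$model
  if (n == 0L) {
    empty <- data.frame(ID = character(), TIME = numeric(), EVID = integer())
    return(pk_dataset(empty, source = "synthetic", seed = seed,
                      truth = list(model = model, etas = NULL, config = config)))
  }
  covs <- sample_covariates(n, config)
  designs <- sample_design(n, config)
  etas <- cbind(cl = rnorm(n, 0, model$omega["cl"]),
                vc = rnorm(n, 0, model$omega["vc"]),
                vp = rnorm(n, 0, model$omega["vp"]))
  prop <- model$sigma["prop"]; add <- model$sigma["add"]
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    des <- designs[[i]]
    sub_rows <- list()
    for (k in seq_along(des$occasions)) {
      ck <- covs[i, , drop = FALSE]
      if (k > 1) { # occasion-varying CRRT (persistent) and inflammation
        if (runif(1) > 0.7) ck$crrt <- rbinom(1, 1, config$crrt_prevalence)
        ck$qcrp <- min(max(ck$qcrp * rlnorm(1, 0, 0.3), 0.5), 600)
      }
      ind <- individual_parameters(model, ck, etas[i, ])
      t0 <- des$occasions[k]
      dose <- data.frame(time = t0, amt = des$amt, route = des$route,
                         tinf = if (des$route == "iv") config$tinf else NA_real_,
                         ss = 1L, ii = config$interval)
      tt <- des$obs_times[[k]]
      f <- concentration(ind, dose, t0 + tt)
      y <- f * (1 + rnorm(length(f), 0, prop)) + rnorm(length(f), 0, add)
      neg <- which(y < 0)
      while (length(neg)) {
        y[neg] <- f[neg] * (1 + rnorm(length(neg), 0, prop)) +
          rnorm(length(neg), 0, add)
        neg <- neg[y[neg] < 0]
      }
      base <- cbind(ck, row.names = NULL)
      dose_row <- cbind(data.frame(ID = i, TIME = t0, EVID = 1L, AMT = des$amt,
                                   DUR = dose$tinf, ROUTE = des$route,
                                   SS = 1L, II = config$interval,
                                   DV = NA_real_, MDV = 1L, BLQ = 0L, OCC = k),
                        base)
      obs_rows <- cbind(data.frame(ID = i, TIME = t0 + tt, EVID = 0L, AMT = 0,
                                   DUR = NA_real_, ROUTE = NA_character_,
                                   SS = 0L, II = NA_real_,
                                   DV = y, MDV = 0L,
                                   BLQ = as.integer(y < VORI_LLOQ), OCC = k),
                        base[rep(1, length(tt)), , drop = FALSE])
      sub_rows[[k]] <- rbind(dose_row, obs_rows)
    }
    rows[[i]] <- do.call(rbind, sub_rows)
  }
  ev <- do.call(rbind, rows)
  ev <- ev[order(as.integer(ev$ID), ev$TIME, -ev$EVID), ]
  rownames(ev) <- NULL
  pk_dataset(ev, source = "synthetic", seed = seed,
             truth = list(model = model, etas = etas, config = config))
}
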
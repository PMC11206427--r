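# Independent numerical oracles used across the test files.

# Stiff-ODE oracle for the two-compartment model with first-order
# absorption and zero-order infusion (amounts A_depot, A_central,
# A_peripheral). Independent of the package's closed-form path.
# Non-steady-state dose events only.
ode_conc <- function(ind, doses, times) {
  stopifnot(requireNamespace("deSolve", quietly = TRUE))
  dc <- list(k10 = ind$cl / ind$vc, k12 = ind$q / ind$vc, k21 = ind$q / ind$vp)
  deriv <- function(t, A, p) {
    infusing <- p$rate > 0 && t >= p$t0 && t <= p$t0 + p$tinf
    r <- if (infusing) p$rate else 0
    list(c(-ind$ka * A[1],
           ind$ka * A[1] + r - (dc$k10 + dc$k12) * A[2] + dc$k21 * A[3],
           dc$k12 * A[2] - dc$k21 * A[3]))
  }
  # integrate piecewise over a breakpoint grid of dose starts/infusion ends
  breaks <- sort(unique(c(0, doses$time,
                          doses$time + ifelse(is.na(doses$tinf), 0, doses$tinf),
                          times)))
  A <- c(0, 0, 0)
  out <- numeric(length(times))
  for (k in seq_len(length(breaks) - 1L)) {
    t0 <- breaks[k]; t1 <- breaks[k + 1L]
    start <- which(abs(doses$time - t0) < 1e-12)
    for (d in start) {
      if (doses$route[d] == "iv") next # handled via the rate term
      A[1] <- A[1] + ind$f_oral * doses$amt[d]
    }
    act <- which(doses$route == "iv" & doses$time <= t0 &
                 doses$time + doses$tinf > t0 + 1e-12)
    p <- if (length(act) == 1L)
      list(rate = doses$amt[act] / doses$tinf[act], t0 = doses$time[act],
           tinf = doses$tinf[act])
    else list(rate = 0, t0 = 0, tinf = 0)
    if (t1 > t0 + 1e-12) {
      sol <- deSolve::lsoda(A, c(t0, t1), deriv, p, rtol = 1e-11, atol = 1e-12)
      A <- as.numeric(sol[nrow(sol), -1])
    }
    hit <- which(abs(times - t1) < 1e-12)
    out[hit] <- A[2] / ind$vc
    if (any(abs(times - 0) < 1e-12)) out[abs(times - 0) < 1e-12] <- 0
  }
  out
}

# adaptive-quadrature oracle for the one-random-effect marginal likelihood
# (eta on clearance only, additive residual error), returned as -2 log L
quad_ofv_1d <- function(y, times, regimen, model, add_sd, omega_cl) {
  f_eta <- function(e) vapply(e, function(ei) {
    ind <- individual_parameters(model, list(), c(cl = ei))
    prod(dnorm(y, concentration(ind, regimen, times), add_sd))
  }, 0)
  lik <- function(e) f_eta(e) * dnorm(e, 0, omega_cl)
  L <- integrate(lik, -8 * omega_cl, 8 * omega_cl, rel.tol = 1e-12)$value
  -2 * log(L)
}

# single-subject event table at steady state (one SS dose record)
ss_subject_events <- function(id, dv, times, amt = 200, ii = 12, tinf = 1,
                              route = "iv", t0 = 0, covs = NULL) {
  n <- length(times)
  ev <- data.frame(ID = id, TIME = c(t0, t0 + times), EVID = c(1L, rep(0L, n)),
                   AMT = c(amt, rep(0, n)),
                   DUR = c(if (route == "iv") tinf else NA_real_, rep(NA_real_, n)),
                   ROUTE = c(route, rep(NA_character_, n)),
                   SS = c(1L, rep(0L, n)), II = c(ii, rep(NA_real_, n)),
                   DV = c(NA_real_, dv), MDV = c(1L, rep(0L, n)))
  if (!is.null(covs)) ev <- cbind(ev, covs[rep(1, nrow(ev)), , drop = FALSE],
                                  row.names = NULL)
  ev
}

# covariate-free model with configurable variability
plain_model <- function(omega = c(cl = 0.3, vc = 0, vp = 0),
                        sigma = c(prop = 0, add = 0.3), f_oral = 0.835)
  vori_model(cl_tv = 3.55, vc = 33.5, vp = 138, q = 52.8, f_oral = f_oral,
             omega = omega, sigma = sigma)
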
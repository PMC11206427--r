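#' Conditional weighted residuals and goodness-of-fit table
#'
#' CWRES from the FOCE linearisation around the empirical-Bayes etas:
#' with \eqn{G_i = \partial f_i/\partial \eta} at the mode,
#' \eqn{V_i = G_i \Omega G_i' + \mathrm{diag}(g_i)} (interaction: the
#' residual variance \eqn{g_i} is evaluated at the conditional
#' predictions), and \eqn{E_i = f_i(\hat\eta_i) - G_i\hat\eta_i}, the
#' residual vector is the Cholesky-whitened \eqn{V_i^{-1/2}(y_i - E_i)}.
#' Approximately standard normal under a correct model. With all omegas
#' zero and additive-only error this reduces to `(DV - PRED)/sigma_add`.
#'
#' @param data A `pk_dataset`.
#' @param model A `vori_model` (typically the fitted one).
#' @param fit Optional `vori_fit` supplying the EB etas (recomputed when
#'   omitted).
#' @return Goodness-of-fit data frame, one row per quantifiable (non-BLQ)
#'   observation: `ID`, `TIME`, `DV`, `PRED`, `IPRED`, `CWRES`.
#' @export
cwres <- function(data, model, fit = NULL) {
  subs <- compile_for_kernel(data, model$cov_effects)
  etas <- if (!is.null(fit)) fit$eb_etas else eb_estimate(data, model)
  ids <- vapply(subs, `[[`, "", "id")
  eta_m <- matrix(0, length(subs), 3)
  rownames(eta_m) <- ids
  eta_m[rownames(etas), ] <- etas
  act <- which(model$omega > 0)
  omega <- diag(model$omega[act]^2, nrow = length(act))
  f_hat <- kernel_predict(subs, model, eta_m)
  f_pop <- kernel_predict(subs, model, NULL)
  h <- 1e-4
  out <- vector("list", length(subs))
  for (i in seq_along(subs)) {
    s <- subs[[i]]
    if (!length(s$t)) next
    fi <- f_hat[[i]]
    G <- matrix(0, length(fi), length(act))
    for (a in seq_along(act)) {
      ep <- eta_m; em <- eta_m
      ep[i, act[a]] <- ep[i, act[a]] + h
      em[i, act[a]] <- em[i, act[a]] - h
      G[, a] <- (kernel_predict(subs[i], model, ep[i, , drop = FALSE])[[1]] -
                 kernel_predict(subs[i], model, em[i, , drop = FALSE])[[1]]) / (2 * h)
    }
    g <- residual_variance(fi, model)
    V <- diag(g, nrow = length(g))
    if (length(act)) V <- V + G %*% omega %*% t(G)
    ch <- try(chol(V), silent = TRUE)
    if (inherits(ch, "try-error"))
      stop("singular conditional covariance for subject ", s$id)
    E <- fi - if (length(act)) drop(G %*% eta_m[i, act]) else 0
    w <- forwardsolve(t(ch), s$y - E)
    out[[i]] <- data.frame(ID = s$id, TIME = s$t, DV = s$y,
                           PRED = f_pop[[i]], IPRED = fi, CWRES = w)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a replicate dataset from the model
#'
#' Keeps the design (subjects, doses, observation times, covariates) and
#' replaces observed concentrations with model simulations: new lognormal
#' etas per subject, combined residual error, negative draws resampled,
#' BLQ re-flagged at the assay LLOQ.
#'
#' @param data Template `pk_dataset`.
#' @param model Generating `vori_model`.
#' @param seed Optional seed.
#' @return A `pk_dataset` with simulated `DV`.
#' @export
simulate_from_model <- function(data, model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  subs <- compile_for_kernel(data, model$cov_effects, include_blq = TRUE)
  n <- length(subs)
  etas <- cbind(rnorm(n, 0, model$omega["cl"]),
                rnorm(n, 0, model$omega["vc"]),
                rnorm(n, 0, model$omega["vp"]))
  f <- kernel_predict(subs, model, etas)
  ev <- data$events
  prop <- model$sigma[["prop"]]; add <- model$sigma[["add"]]
  for (i in seq_len(n)) {
    fi <- f[[i]]
    if (!length(fi)) next
    y <- fi * (1 + rnorm(length(fi), 0, prop)) + rnorm(length(fi), 0, add)
    neg <- which(y < 0)
    while (length(neg)) {
      y[neg] <- fi[neg] * (1 + rnorm(length(neg), 0, prop)) +
        rnorm(length(neg), 0, add)
      neg <- neg[y[neg] < 0]
    }
    rows <- which(ev$ID == subs[[i]]$id & ev$EVID == 0 & ev$MDV == 0)
    ev$DV[rows] <- y
    ev$BLQ[rows] <- as.integer(y < VORI_LLOQ)
  }
  pk_dataset(ev, source = paste0(data$source, " (simulated)"),
             seed = if (is.null(seed)) NA_integer_ else seed,
             truth = list(model = model, etas = etas))
}

#' Nonparametric bootstrap of the population model
#'
#' Resamples subjects with replacement to the original count, refits each
#' resample starting from the point estimates, and summarises converged
#' fits by per-parameter median and 2.5/97.5 percentiles. More than 20%
#' failed fits triggers a prominent warning.
#'
#' @param data A `pk_dataset`.
#' @param model Fitted `vori_model` used as the refit starting point.
#' @param n_resamples Number of bootstrap resamples (study convention 1000).
#' @param seed Seed for the resample indices (same seed, same indices).
#' @param control [fit_control()] for the refits.
#' @return Object of class `vori_bootstrap`: `summary` (data frame with
#'   `parameter`, `median`, `lo`, `hi`), `estimates` (resample x parameter
#'   matrix), `n_converged`, `n_failed`, `indices`.
#' @export
pk_bootstrap <- function(data, model, n_resamples = 1000L, seed = 1L,
                         control = fit_control(compute_rse = FALSE, nm_maxit = 200L)) {
  stopifnot(n_resamples >= 1)
  set.seed(seed)
  ids <- unique(data$events$ID)
  idx <- matrix(sample.int(length(ids), length(ids) * n_resamples,
                           replace = TRUE), nrow = n_resamples)
  est <- vector("list", n_resamples)
  for (b in seq_len(n_resamples)) {
    take <- ids[idx[b, ]]
    ev_list <- lapply(seq_along(take), function(k) {
      sub <- data$events[data$events$ID == take[k], ]
      sub$ID <- sprintf("bs%04d", k)
      sub
    })
    bs_data <- pk_dataset(do.call(rbind, ev_list),
                          source = sprintf("bootstrap resample %d", b))
    ft <- fit_quiet(bs_data, model, control)
    if (!is.null(ft) && ft$converged) est[[b]] <- ft$estimates
  }
  ok <- !vapply(est, is.null, TRUE)
  if (mean(!ok) > 0.2)
    warning(sprintf("bootstrap: %d of %d resample fits failed (> 20%%)",
                    sum(!ok), n_resamples))
  if (!any(ok)) stop("all bootstrap resample fits failed")
  em <- do.call(rbind, est[ok])
  qs <- apply(em, 2, quantile, probs = c(0.5, 0.025, 0.975), names = FALSE)
  structure(list(summary = data.frame(parameter = colnames(em),
                                      median = qs[1, ], lo = qs[2, ],
                                      hi = qs[3, ], row.names = NULL),
                 estimates = em,
                 n_converged = sum(ok), n_failed = sum(!ok),
                 indices = idx, seed = seed),
            class = "vori_bootstrap")
}

#' @export
print.vori_bootstrap <- function(x, ...) {
  cat(sprintf("Nonparametric bootstrap: %d converged, %d failed\n",
              x$n_converged, x$n_failed))
  print(transform(x$summary, median = signif(median, 4), lo = signif(lo, 4),
                  hi = signif(hi, 4)), row.names = FALSE)
  invisible(x)
}

# time after (last) dose; steady-state records wrap modulo the interval
tad_of <- function(sub) {
  doses <- sub$doses
  vapply(seq_along(sub$t), function(j) {
    t <- sub$t[j]
    prior <- which(doses[, "time"] <= t)
    if (!length(prior)) return(t)
    d <- prior[length(prior)]
    tad <- t - doses[d, "time"]
    if (doses[d, "ss"] == 1) tad <- tad %% doses[d, "ii"]
    tad
  }, 0)
}

#' Prediction-corrected visual predictive check
#'
#' Observations and simulations are scaled by the ratio of the bin-median
#' population prediction to each row's own population prediction, removing
#' dose and covariate heterogeneity, then compared as percentiles: the
#' observed 5th/50th/95th percentiles per time-after-dose bin against the
#' 95% confidence band of the same percentiles across `n_sim` simulated
#' replicates. Bins are quantile-based on time after dose; bins with fewer
#' than 5 observations are merged with their neighbour.
#'
#' @param data A `pk_dataset`.
#' @param model Fitted `vori_model`.
#' @param n_sim Number of simulated replicates (study convention 1000).
#' @param bins Number of time-after-dose bins.
#' @param seed Seed for the simulations.
#' @return Object of class `vori_vpc`: a per-bin data frame `bands` with
#'   observed percentiles (`obs_p5`, `obs_p50`, `obs_p95`) and simulated
#'   95% CIs (`p5_lo` .. `p95_hi`), plus `n_sim` and `seed`.
#' @export
pcvpc <- function(data, model, n_sim = 1000L, bins = 8L, seed = 1L) {
  set.seed(seed)
  subs <- compile_for_kernel(data, model$cov_effects)
  pred <- kernel_predict(subs, model, NULL)
  obs <- do.call(rbind, lapply(seq_along(subs), function(i) {
    s <- subs[[i]]
    if (!length(s$t)) return(NULL)
    data.frame(sub = i, row = seq_along(s$t), tad = tad_of(s), y = s$y,
               pred = pred[[i]])
  }))
  if (is.null(obs) || nrow(obs) < 10L) stop("too few observations for a VPC")
  # quantile bins on TAD, merged to >= 5 observations each
  br <- unique(quantile(obs$tad, probs = seq(0, 1, length.out = bins + 1L)))
  if (length(br) < 2L) br <- range(obs$tad) + c(-1e-9, 1e-9)
  bin <- cut(obs$tad, br, include.lowest = TRUE, labels = FALSE)
  repeat {
    cnt <- table(factor(bin, levels = seq_len(length(br) - 1L)))
    small <- which(cnt < 5L)
    if (!length(small) || length(br) <= 2L) break
    k <- small[1]
    drop_edge <- if (k == 1L) 2L else k
    br <- br[-drop_edge]
    bin <- cut(obs$tad, br, include.lowest = TRUE, labels = FALSE)
  }
  nb <- length(br) - 1L
  # prediction correction: bin-median PRED over each row's own PRED
  med_pred <- tapply(obs$pred, bin, median)
  cf <- med_pred[as.character(bin)] / pmax(obs$pred, 1e-12)
  pc_obs <- obs$y * cf
  probs <- c(0.05, 0.5, 0.95)
  obs_q <- t(vapply(seq_len(nb), function(b)
    quantile(pc_obs[bin == b], probs, names = FALSE), numeric(3)))
  sim_q <- array(NA_real_, c(n_sim, nb, 3))
  prop <- model$sigma[["prop"]]; add <- model$sigma[["add"]]
  n <- length(subs)
  for (ss in seq_len(n_sim)) {
    etas <- cbind(rnorm(n, 0, model$omega["cl"]),
                  rnorm(n, 0, model$omega["vc"]),
                  rnorm(n, 0, model$omega["vp"]))
    fsim <- kernel_predict(subs, model, etas)
    fo <- unlist(fsim) # same subject/row order as `obs`
    ysim <- fo * (1 + rnorm(length(fo), 0, prop)) + rnorm(length(fo), 0, add)
    neg <- which(ysim < 0)
    while (length(neg)) {
      ysim[neg] <- fo[neg] * (1 + rnorm(length(neg), 0, prop)) +
        rnorm(length(neg), 0, add)
      neg <- neg[ysim[neg] < 0]
    }
    keep <- ysim >= VORI_LLOQ # mirror the observed (non-BLQ) set
    pc_sim <- ysim * cf
    for (b in seq_len(nb)) {
      sel <- keep & bin == b
      if (sum(sel) >= 2L)
        sim_q[ss, b, ] <- quantile(pc_sim[sel], probs, names = FALSE)
    }
  }
  ci <- apply(sim_q, c(2, 3), quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  bands <- data.frame(bin = seq_len(nb),
                      tad_lo = br[-length(br)], tad_hi = br[-1],
                      n_obs = as.integer(table(factor(bin, levels = seq_len(nb)))),
                      obs_p5 = obs_q[, 1], obs_p50 = obs_q[, 2],
                      obs_p95 = obs_q[, 3],
                      p5_lo = ci[1, , 1], p5_hi = ci[2, , 1],
                      p50_lo = ci[1, , 2], p50_hi = ci[2, , 2],
                      p95_lo = ci[1, , 3], p95_hi = ci[2, , 3])
  structure(list(bands = bands, n_sim = n_sim, seed = seed),
            class = "vori_vpc")
}

#' @export
print.vori_vpc <- function(x, ...) {
  cat(sprintf("Prediction-corrected VPC (%d simulations)\n", x$n_sim))
  print(transform(x$bands, tad_lo = round(tad_lo, 2), tad_hi = round(tad_hi, 2)),
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Plot a prediction-corrected VPC
#'
#' Observed percentile lines over the simulated 95% confidence bands.
#' Requires ggplot2.
#'
#' @param x A `vori_vpc`.
#' @return A ggplot object.
#' @export
plot_pcvpc <- function(x) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  b <- x$bands
  b$mid <- (b$tad_lo + b$tad_hi) / 2
  ggplot2::ggplot(b, ggplot2::aes(x = mid)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = p5_lo, ymax = p5_hi),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = p50_lo, ymax = p50_hi),
                         fill = "firebrick", alpha = 0.25) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = p95_lo, ymax = p95_hi),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = obs_p50), colour = "firebrick") +
    ggplot2::geom_line(ggplot2::aes(y = obs_p5), linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = obs_p95), linetype = 2) +
    ggplot2::labs(x = "time after dose (h)",
                  y = "prediction-corrected concentration (mg/L)")
}
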
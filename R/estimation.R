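#' Combined residual-error variance
#'
#' Variance of the combined error model \eqn{y = f(1+\epsilon) + \epsilon'}:
#' \eqn{(f \sigma_{prop})^2 + \sigma_{add}^2}.
#'
#' @param c_pred Predicted concentration(s), mg/L, non-negative.
#' @param sigma Named vector with `prop` and `add` (or a `vori_model`).
#' @return Residual variance(s) in (mg/L)^2.
#' @examples
#' residual_variance(2, c(prop = 0.089, add = 0.192))
#' @export
residual_variance <- function(c_pred, sigma) {
  if (inherits(sigma, "vori_model")) sigma <- sigma$sigma
  stopifnot(all(c_pred >= 0))
  (c_pred * sigma[["prop"]])^2 + sigma[["add"]]^2
}

# ---- kernel plumbing -------------------------------------------------------

# covariate design entry for one effect: log(x/ref) for the power form,
# the raw 0/1 flag for the factor form (whose packed coefficient is the
# log multiplier), so that log CL = log CL_tv + X %*% beta + eta_cl
design_column <- function(ce, values) {
  if (ce$form == "power") {
    if (any(values <= 0, na.rm = TRUE))
      stop("non-positive value for covariate '", ce$covariate, "'")
    log(values / ce$reference)
  } else values
}

effect_label <- function(ce) paste0("beta_", ce$covariate)

# compiled kernel input: per-subject t, y, dose matrix, design matrix
compile_for_kernel <- function(ds, effects, include_blq = FALSE) {
  cov_names <- vapply(effects, function(e) e$covariate, "")
  subs <- compile_subjects(ds, cov_names, include_blq = include_blq)
  lapply(subs, function(s) {
    X <- matrix(0, length(s$t), length(effects))
    for (k in seq_along(effects))
      if (length(s$t))
        X[, k] <- design_column(effects[[k]], s$cov[, k])
    d <- s$doses
    dm <- cbind(time = d$time, amt = d$amt,
                route = as.numeric(d$route != "iv"),
                tinf = ifelse(is.na(d$tinf), 1, d$tinf),
                ss = d$ss, ii = ifelse(is.na(d$ii), 0, d$ii))
    list(id = s$id, t = s$t, y = s$y, doses = dm, X = X)
  })
}

model_to_pars <- function(model) {
  beta <- vapply(model$cov_effects, function(ce)
    if (ce$form == "power") ce$coefficient else log(ce$coefficient), 0)
  list(cl_tv = model$theta$cl_tv, vc = model$theta$vc, vp = model$theta$vp,
       q = model$theta$q, ka = model$theta$ka, f = model$theta$f_oral,
       beta = as.numeric(beta), omega = as.numeric(model$omega),
       prop = unname(model$sigma[["prop"]]), add = unname(model$sigma[["add"]]))
}

pars_to_model <- function(pars, template) {
  eff <- template$cov_effects
  for (k in seq_along(eff))
    eff[[k]]$coefficient <- if (eff[[k]]$form == "power") pars$beta[k]
      else exp(pars$beta[k])
  m <- template
  m$theta$cl_tv <- pars$cl_tv; m$theta$vc <- pars$vc; m$theta$vp <- pars$vp
  m$theta$q <- pars$q; m$theta$ka <- pars$ka; m$theta$f_oral <- pars$f
  m$cov_effects <- eff
  m$omega[] <- pars$omega
  m$sigma[] <- c(pars$prop, pars$add)
  m
}

#' FOCE-style marginal objective function value
#'
#' Minus twice the approximate log marginal likelihood: each subject's
#' integral over random effects is approximated by a Laplace expansion at
#' the empirical-Bayes eta mode, with interaction (the residual variance is
#' evaluated at the conditional predictions) and numerically differentiated
#' Hessians. With all omegas zero this reduces to the exact fixed-effects
#' Gaussian -2 log-likelihood.
#'
#' @param data A `pk_dataset`.
#' @param model A `vori_model`.
#' @return The objective function value (scalar).
#' @export
foce_ofv <- function(data, model) {
  subs <- compile_for_kernel(data, model$cov_effects)
  res <- .ofv_kernel(subs, model_to_pars(model), matrix(0, 0, 3))
  if (!res$ok || !is.finite(res$ofv))
    stop("non-finite objective; check model parameters against the data")
  res$ofv
}

#' Empirical-Bayes random-effect estimates
#'
#' Posterior-mode (MAP) eta per subject given population parameters.
#' Subjects without quantifiable observations get the prior mode, zero.
#'
#' @param data A `pk_dataset` (or a single-subject subset).
#' @param model A `vori_model`.
#' @return Numeric matrix (subjects x 3) with columns `cl`, `vc`, `vp` and
#'   subject ids as row names.
#' @export
eb_estimate <- function(data, model) {
  subs <- compile_for_kernel(data, model$cov_effects)
  res <- .ofv_kernel(subs, model_to_pars(model), matrix(0, 0, 3))
  etas <- res$etas
  dimnames(etas) <- list(vapply(subs, `[[`, "", "id"), c("cl", "vc", "vp"))
  etas
}

# ---- parameter packing for the outer optimiser -----------------------------

# transformed, unconstrained parameterisation: log for positive parameters,
# logit for F, identity for signed power exponents, log for factor
# multipliers and omegas/sigmas; fixed entries are dropped from the vector
pack_spec <- function(model, estimate_f) {
  spec <- list()
  addp <- function(name, trans) spec[[length(spec) + 1L]] <<-
    list(name = name, trans = trans)
  addp("cl_tv", "log"); addp("vc", "log"); addp("vp", "log"); addp("q", "log")
  if (estimate_f) addp("f", "logit")
  for (k in seq_along(model$cov_effects))
    addp(paste0("beta", k), "identity") # factor effects packed as log-mult
  for (d in 1:3) if (model$omega[d] > 0) addp(paste0("omega", d), "log")
  if (model$sigma[["prop"]] > 0) addp("prop", "log")
  if (model$sigma[["add"]] > 0) addp("add", "log")
  spec
}

pack_pars <- function(pars, spec) {
  vapply(spec, function(s) {
    val <- if (grepl("^beta", s$name))
      pars$beta[as.integer(sub("beta", "", s$name))]
    else if (grepl("^omega", s$name))
      pars$omega[as.integer(sub("omega", "", s$name))]
    else pars[[s$name]]
    switch(s$trans, log = log(val), logit = qlogis(val), identity = val)
  }, 0)
}

unpack_pars <- function(x, spec, pars0) {
  pars <- pars0
  for (i in seq_along(spec)) {
    s <- spec[[i]]
    val <- switch(s$trans, log = exp(x[i]), logit = plogis(x[i]),
                  identity = x[i])
    if (grepl("^beta", s$name))
      pars$beta[as.integer(sub("beta", "", s$name))] <- val
    else if (grepl("^omega", s$name))
      pars$omega[as.integer(sub("omega", "", s$name))] <- val
    else pars[[s$name]] <- val
  }
  pars
}

# human-readable parameter names on the natural scale
spec_labels <- function(spec, model) {
  vapply(seq_along(spec), function(i) {
    nm <- spec[[i]]$name
    if (grepl("^beta", nm))
      effect_label(model$cov_effects[[as.integer(sub("beta", "", nm))]])
    else if (grepl("^omega", nm))
      paste0("omega_", c("cl", "vc", "vp")[as.integer(sub("omega", "", nm))])
    else switch(nm, f = "f_oral", prop = "sigma_prop", add = "sigma_add", nm)
  }, "")
}

#' Fitting control settings
#'
#' @param maxit Maximum BFGS iterations.
#' @param reltol Relative convergence tolerance on the objective.
#' @param grad_step Relative finite-difference step for the outer gradient.
#' @param hessian_step Step for the standard-error Hessian.
#' @param compute_rse Compute RSEs from the inverse objective Hessian.
#' @param nm_maxit Iteration budget for the derivative-free Nelder-Mead
#'   pre-optimisation that precedes the BFGS polish; 0 disables it. The
#'   marginal-likelihood surface is multimodal in the weakly identified
#'   directions, and the simplex stage is much less likely to stall in a
#'   poor basin when starting far from the optimum.
#' @return List of control settings.
#' @export
fit_control <- function(maxit = 400L, reltol = 1e-8, grad_step = 1e-4,
                        hessian_step = 5e-4, compute_rse = TRUE,
                        nm_maxit = 3000L) {
  list(maxit = maxit, reltol = reltol, grad_step = grad_step,
       hessian_step = hessian_step, compute_rse = compute_rse,
       nm_maxit = nm_maxit)
}

#' Fit the population model by FOCE-style maximum likelihood
#'
#' Maximises the Laplace/FOCE marginal likelihood over the population
#' parameters on an unconstrained transformed scale (log for positive
#' parameters, logit for bioavailability, identity for signed covariate
#' exponents). `ka` is always fixed; `F` is estimated only when the data
#' contain extravascular doses (on IV-only data it is fixed with a
#' warning); omegas fixed at zero in `model0` stay fixed. Relative standard
#' errors come from the inverse of the numerically differentiated objective
#' Hessian via the delta method.
#'
#' @param data A `pk_dataset`.
#' @param model0 Starting `vori_model` (structure defines what is
#'   estimated).
#' @param control A [fit_control()] list.
#' @return An object of class `vori_fit`: `model` (estimates), `ofv`,
#'   `estimates` (named natural-scale vector), `se`, `rse` (percent),
#'   `eb_etas`, `converged`, `n_function_evals`.
#' @export
pk_fit <- function(data, model0, control = fit_control()) {
  stopifnot(inherits(data, "pk_dataset"), inherits(model0, "vori_model"))
  if (n_subjects(data) == 0L) stop("cannot fit an empty dataset")
  subs <- compile_for_kernel(data, model0$cov_effects)
  any_ev <- any(vapply(subs, function(s) any(s$doses[, "route"] == 1), TRUE))
  estimate_f <- any_ev
  if (!any_ev && model0$theta$f_oral < 1)
    warning("no extravascular doses: bioavailability is not identifiable and was fixed")
  pars0 <- model_to_pars(model0)
  spec <- pack_spec(model0, estimate_f)
  x0 <- pack_pars(pars0, spec)
  nev <- 0L
  # inner eta searches always start from the prior mode so the objective is
  # deterministic (no history dependence across outer iterations)
  no_start <- matrix(0, 0, 3)
  make_obj <- function(spec_use, base) {
    function(x) {
      nev <<- nev + 1L
      pars <- unpack_pars(x, spec_use, base)
      res <- .ofv_kernel(subs, pars, no_start)
      if (!res$ok || !is.finite(res$ofv)) return(1e10)
      res$ofv
    }
  }
  objective <- make_obj(spec, pars0)
  x <- x0
  if (control$nm_maxit > 0) {
    nm <- optim(x, objective, method = "Nelder-Mead",
                control = list(maxit = control$nm_maxit))
    x <- nm$par
  }
  opt <- optim(x, objective, method = "BFGS",
               control = list(maxit = control$maxit, reltol = control$reltol,
                              ndeps = rep(control$grad_step, length(x))))
  xhat <- opt$par
  pars_hat <- unpack_pars(xhat, spec, pars0)
  model_hat <- pars_to_model(pars_hat, model0)
  res <- .ofv_kernel(subs, pars_hat, no_start)
  etas <- res$etas
  dimnames(etas) <- list(vapply(subs, `[[`, "", "id"), c("cl", "vc", "vp"))

  labels <- spec_labels(spec, model0)
  natural <- vapply(seq_along(spec), function(i) {
    s <- spec[[i]]
    v <- switch(s$trans, log = exp(xhat[i]), logit = plogis(xhat[i]),
                identity = xhat[i])
    if (grepl("^beta", s$name) &&
        model0$cov_effects[[as.integer(sub("beta", "", s$name))]]$form == "factor")
      exp(v) else v
  }, 0)
  # note: factor betas are packed as log-multipliers (identity transform),
  # so their natural value is exp(packed)
  names(natural) <- labels

  se <- rse <- setNames(rep(NA_real_, length(spec)), labels)
  hessian_pd <- NA
  if (control$compute_rse) {
    H <- ofv_hessian(make_obj(spec, pars0), xhat, control$hessian_step)
    ei <- eigen((H + t(H)) / 2, symmetric = TRUE)
    pos <- ei$values > max(ei$values) * 1e-10
    hessian_pd <- all(pos)
    # Moore-Penrose fallback when the Hessian is singular along weakly
    # identified directions (covariance-step analogue of a "singular R")
    cov <- 2 * ei$vectors[, pos, drop = FALSE] %*%
      diag(1 / ei$values[pos], nrow = sum(pos)) %*%
      t(ei$vectors[, pos, drop = FALSE])
    if (all(is.finite(diag(cov))) && all(diag(cov) >= 0)) {
      se_x <- sqrt(diag(cov))
      for (i in seq_along(spec)) {
        s <- spec[[i]]
        is_factor <- grepl("^beta", s$name) &&
          model0$cov_effects[[as.integer(sub("beta", "", s$name))]]$form == "factor"
        se[i] <- if (s$trans == "log" || is_factor) natural[i] * se_x[i]
        else if (s$trans == "logit") natural[i] * (1 - natural[i]) * se_x[i]
        else se_x[i]
        rse[i] <- 100 * se[i] / abs(natural[i])
      }
    }
  }
  structure(list(model = model_hat, ofv = res$ofv, estimates = natural,
                 se = se, rse = rse, eb_etas = etas,
                 hessian_pd = hessian_pd,
                 converged = opt$convergence == 0,
                 n_function_evals = nev, opt = opt[c("convergence", "counts")],
                 estimate_f = estimate_f),
            class = "vori_fit")
}

# central-difference Hessian of the objective
ofv_hessian <- function(fn, x, h) {
  n <- length(x)
  H <- matrix(0, n, n)
  f0 <- fn(x)
  for (i in seq_len(n)) {
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    H[i, i] <- (fn(xp) - 2 * f0 + fn(xm)) / h^2
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    xpp <- x; xpp[c(i, j)] <- x[c(i, j)] + h
    xpm <- x; xpm[i] <- x[i] + h; xpm[j] <- x[j] - h
    xmp <- x; xmp[i] <- x[i] - h; xmp[j] <- x[j] + h
    xmm <- x; xmm[c(i, j)] <- x[c(i, j)] - h
    H[i, j] <- H[j, i] <- (fn(xpp) - fn(xpm) - fn(xmp) + fn(xmm)) / (4 * h^2)
  }
  H
}

#' @export
print.vori_fit <- function(x, ...) {
  cat(sprintf("FOCE fit: OFV %.3f, %s, %d objective evaluations\n", x$ofv,
              if (x$converged) "converged" else "NOT converged",
              x$n_function_evals))
  tab <- data.frame(estimate = signif(x$estimates, 4),
                    rse_pct = signif(x$rse, 3))
  print(tab)
  invisible(x)
}

#' Population and individual predictions for every observation row
#'
#' One prediction per observation record (`EVID = 0`, `MDV = 0`, BLQ rows
#' included), computed from the closed-form kinetics with each row's
#' covariate values. With `etas = NULL` all random effects are zero
#' (population prediction, PRED); passing the empirical-Bayes matrix gives
#' individual predictions (IPRED). Observations before any dose predict 0
#' with a warning.
#'
#' @param model A `vori_model`.
#' @param data A `pk_dataset`.
#' @param etas Optional matrix of etas (rows named by subject id, columns
#'   `cl`, `vc`, `vp`).
#' @return Data frame: `ID`, `TIME`, `DV`, `BLQ`, `pred`.
#' @export
predict_dataset <- function(model, data, etas = NULL) {
  stopifnot(inherits(model, "vori_model"), inherits(data, "pk_dataset"))
  ev <- data$events
  out <- list()
  warned <- FALSE
  for (id in unique(ev$ID)) {
    sub <- ev[ev$ID == id, ]
    obs <- sub[sub$EVID == 0 & sub$MDV == 0, ]
    if (!nrow(obs)) next
    dr <- sub[sub$EVID == 1, ]
    doses <- data.frame(time = dr$TIME, amt = dr$AMT, route = dr$ROUTE,
                        tinf = dr$DUR, ss = dr$SS, ii = dr$II)
    eta <- c(cl = 0, vc = 0, vp = 0)
    if (!is.null(etas) && id %in% rownames(etas)) eta[] <- etas[id, ]
    first_dose <- if (nrow(doses)) min(doses$time) else Inf
    if (any(obs$TIME < first_dose) && !warned) {
      warning("observation(s) before any dose predict 0")
      warned <- TRUE
    }
    pred <- vapply(seq_len(nrow(obs)), function(j) {
      ind <- individual_parameters(model, obs[j, covariate_names(data)], eta)
      concentration(ind, doses, obs$TIME[j])
    }, 0)
    out[[id]] <- data.frame(ID = id, TIME = obs$TIME, DV = obs$DV,
                            BLQ = obs$BLQ, pred = pred)
  }
  if (!length(out))
    return(data.frame(ID = character(), TIME = numeric(), DV = numeric(),
                      BLQ = integer(), pred = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# fast kernel-based predictions for the non-BLQ observations used in
# estimation; returns a list of per-subject prediction vectors
kernel_predict <- function(subs, model, etas = NULL) {
  if (is.null(etas)) etas <- matrix(0, length(subs), 3)
  .predict_kernel(subs, model_to_pars(model), etas)
}
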
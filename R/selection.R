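# Chi-square(1 df) OFV-change thresholds used by the stepwise search:
# p < 0.05 to enter, p < 0.005 to stay.
FORWARD_DOFV <- 3.84
BACKWARD_DOFV <- 7.88

#' Screen empirical-Bayes etas against covariates
#'
#' Exploratory association of the clearance random effect with each
#' candidate covariate: Pearson correlation (subject-level covariate value
#' vs eta) for continuous covariates, difference of group mean etas for
#' 0/1 flags. For reporting only; it gates nothing.
#'
#' @param fit A `vori_fit` (or an eta matrix with subject-id row names).
#' @param data The `pk_dataset` the fit used.
#' @param covariates Covariate names to screen; defaults to every covariate
#'   column.
#' @return Data frame: `covariate`, `type`, `association`, `note`.
#' @export
screen_etas <- function(fit, data, covariates = covariate_names(data)) {
  if (n_subjects(data) == 0L) stop("empty dataset")
  etas <- if (inherits(fit, "vori_fit")) fit$eb_etas else fit
  ev <- data$events
  obs <- ev[ev$EVID == 0 & ev$MDV == 0, ]
  out <- lapply(covariates, function(cc) {
    x <- tapply(obs[[cc]], obs$ID, function(v) median(v, na.rm = TRUE))
    x <- x[rownames(etas)]
    e <- etas[, "cl"]
    flag <- all(x %in% c(0, 1), na.rm = TRUE)
    if (length(unique(x[!is.na(x)])) < 2L)
      return(data.frame(covariate = cc, type = if (flag) "categorical" else
                        "continuous", association = 0,
                        note = "constant covariate"))
    if (flag)
      data.frame(covariate = cc, type = "categorical",
                 association = mean(e[x == 1]) - mean(e[x == 0]), note = "")
    else
      data.frame(covariate = cc, type = "continuous",
                 association = cor(x, e, use = "complete.obs"), note = "")
  })
  do.call(rbind, out)
}

# build a candidate covariate_effect: power form normalised to the dataset
# median (observation rows) for continuous covariates, factor form for 0/1
# flags; initial coefficient is neutral
candidate_effect <- function(data, covariate) {
  ev <- data$events
  obs <- ev[ev$EVID == 0 & ev$MDV == 0, ]
  x <- obs[[covariate]]
  if (is.null(x)) stop("covariate '", covariate, "' not in dataset")
  if (all(x %in% c(0, 1), na.rm = TRUE))
    covariate_effect(covariate, "factor", coefficient = 1.0001)
  else
    covariate_effect(covariate, "power", coefficient = 0.01,
                     reference = median(x, na.rm = TRUE))
}

add_effect <- function(model, effect) {
  model$cov_effects <- c(model$cov_effects, list(effect))
  model
}

drop_effect <- function(model, covariate) {
  keep <- vapply(model$cov_effects, function(e) e$covariate != covariate, TRUE)
  model$cov_effects <- model$cov_effects[keep]
  model
}

fit_quiet <- function(data, model, control) {
  tryCatch(suppressWarnings(pk_fit(data, model, control)),
           error = function(e) NULL)
}

#' One forward-inclusion step
#'
#' Fits the current model extended by each candidate covariate on clearance
#' (power form normalised to the dataset median for continuous covariates,
#' factor form for flags) and returns the candidate with the largest OFV
#' drop if that drop exceeds 3.84 (chi-square, 1 df, p < 0.05). Ties break
#' by larger drop then alphabetical name; non-converged candidate fits
#' count as no improvement.
#'
#' @param data A `pk_dataset`.
#' @param model Current `vori_model`.
#' @param candidates Candidate covariate names not already in the model.
#' @param control [fit_control()] for the candidate fits.
#' @param base_fit Optional fit of `model` (re-used if supplied).
#' @return List: `covariate` (or `NULL`), `delta_ofv`, `fit` (the winning
#'   fit or `NULL`), `tested` (per-candidate OFV drops).
#' @export
forward_step <- function(data, model, candidates,
                         control = fit_control(compute_rse = FALSE, nm_maxit = 500L),
                         base_fit = NULL) {
  in_model <- vapply(model$cov_effects, function(e) e$covariate, "")
  candidates <- setdiff(candidates, in_model)
  if (!length(candidates)) return(list(covariate = NULL, delta_ofv = NA_real_,
                                       fit = NULL, tested = NULL))
  if (is.null(base_fit)) base_fit <- fit_quiet(data, model, control)
  base_ofv <- base_fit$ofv
  candidates <- sort(candidates)
  fits <- vector("list", length(candidates))
  drops <- rep(-Inf, length(candidates))
  for (i in seq_along(candidates)) {
    cand_model <- add_effect(model, candidate_effect(data, candidates[i]))
    ft <- fit_quiet(data, cand_model, control)
    if (is.null(ft)) next
    fits[[i]] <- ft
    drops[i] <- base_ofv - ft$ofv
  }
  tested <- data.frame(covariate = candidates, delta_ofv = drops)
  best <- which.max(drops) # first index wins ties -> alphabetical
  if (is.finite(drops[best]) && drops[best] > FORWARD_DOFV)
    list(covariate = candidates[best], delta_ofv = drops[best],
         fit = fits[[best]], tested = tested)
  else
    list(covariate = NULL, delta_ofv = if (length(drops)) max(drops) else NA_real_,
         fit = NULL, tested = tested)
}

#' One backward-elimination step
#'
#' Refits the model with each covariate removed in turn. The covariate
#' whose removal raises the OFV the least is removed when that increase is
#' below 7.88 (chi-square, 1 df, p < 0.005); when every increase is at
#' least 7.88, all covariates are retained and `NULL` is returned.
#'
#' @inheritParams forward_step
#' @param full_fit Optional fit of the full `model`.
#' @return List: `covariate` (removed, or `NULL`), `delta_ofv` (the OFV
#'   increase), `fit` (reduced-model fit), `tested`.
#' @export
backward_step <- function(data, model,
                          control = fit_control(compute_rse = FALSE, nm_maxit = 500L),
                          full_fit = NULL) {
  covs <- vapply(model$cov_effects, function(e) e$covariate, "")
  if (!length(covs)) stop("model has no covariates to eliminate")
  if (is.null(full_fit)) full_fit <- fit_quiet(data, model, control)
  full_ofv <- full_fit$ofv
  ord <- order(covs)
  fits <- vector("list", length(covs))
  incr <- rep(Inf, length(covs))
  for (i in ord) {
    red <- drop_effect(model, covs[i])
    ft <- fit_quiet(data, red, control)
    if (is.null(ft)) next
    fits[[i]] <- ft
    incr[i] <- ft$ofv - full_ofv
  }
  tested <- data.frame(covariate = covs, delta_ofv = incr)
  worst <- which.min(incr)
  if (is.finite(incr[worst]) && incr[worst] < BACKWARD_DOFV)
    list(covariate = covs[worst], delta_ofv = incr[worst],
         fit = fits[[worst]], tested = tested)
  else
    list(covariate = NULL, delta_ofv = min(incr), fit = NULL, tested = tested)
}

#' Flag covariate effects with poor relative standard errors
#'
#' Covariate effects whose RSE exceeds the threshold are flagged for
#' explicit removal (the precision-based exclusion applied after the
#' stepwise search).
#'
#' @param fit A `vori_fit`.
#' @param threshold_pct RSE threshold in percent (default 50).
#' @return Character vector of flagged covariate names (possibly empty).
#' @export
apply_rse_rule <- function(fit, threshold_pct = 50) {
  stopifnot(inherits(fit, "vori_fit"))
  labs <- names(fit$rse)
  beta <- grepl("^beta_", labs)
  flagged <- labs[beta & !is.na(fit$rse) & fit$rse > threshold_pct]
  sub("^beta_", "", flagged)
}

#' Stepwise covariate model building on clearance
#'
#' Forward inclusion (OFV drop > 3.84 to enter) followed by backward
#' elimination (OFV increase >= 7.88 to stay), then the RSE-based
#' exclusion. One covariate enters or leaves per cycle; the trace is
#' replayable (deterministic given data and starting model).
#'
#' @param data A `pk_dataset`.
#' @param base_model Covariate-free starting `vori_model`.
#' @param candidates Candidate covariate names.
#' @param control [fit_control()] for all fits.
#' @param rse_threshold RSE (%) above which a retained covariate is dropped.
#' @return List of class `scm_result`: `model` (final), `fit` (final fit,
#'   with RSEs), `trace` (data frame of steps: step, covariate, delta_ofv,
#'   decision).
#' @export
select_covariates <- function(data, base_model, candidates,
                              control = fit_control(compute_rse = FALSE, nm_maxit = 500L),
                              rse_threshold = 50) {
  trace <- list()
  note <- function(step, covariate, delta, decision)
    trace[[length(trace) + 1L]] <<- data.frame(step = step,
                                               covariate = covariate,
                                               delta_ofv = delta,
                                               decision = decision)
  model <- base_model
  current_fit <- fit_quiet(data, model, control)
  repeat {
    st <- forward_step(data, model, candidates, control, base_fit = current_fit)
    if (is.null(st$covariate)) {
      note("forward", "(none)", st$delta_ofv, "stop")
      break
    }
    note("forward", st$covariate, st$delta_ofv, "added")
    model <- st$fit$model
    current_fit <- st$fit
  }
  while (length(model$cov_effects)) {
    st <- backward_step(data, model, control, full_fit = current_fit)
    if (is.null(st$covariate)) {
      note("backward", "(none)", st$delta_ofv, "all retained")
      break
    }
    note("backward", st$covariate, st$delta_ofv, "removed")
    model <- st$fit$model
    current_fit <- st$fit
  }
  final_control <- control
  final_control$compute_rse <- TRUE
  final_fit <- fit_quiet(data, model, final_control)
  for (cc in apply_rse_rule(final_fit, rse_threshold)) {
    note("rse_rule", cc, NA_real_, sprintf("removed (RSE > %g%%)", rse_threshold))
    model <- drop_effect(model, cc)
    final_fit <- fit_quiet(data, model, final_control)
  }
  structure(list(model = model, fit = final_fit,
                 trace = do.call(rbind, trace)),
            class = "scm_result")
}

#' @export
print.scm_result <- function(x, ...) {
  cat("Stepwise covariate search\n")
  print(x$trace, row.names = FALSE)
  covs <- vapply(x$model$cov_effects, function(e) e$covariate, "")
  cat("final covariates on CL:",
      if (length(covs)) paste(covs, collapse = ", ") else "(none)", "\n")
  invisible(x)
}
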
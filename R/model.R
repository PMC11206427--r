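#' Covariate effect on a structural parameter
#'
#' Describes one multiplicative covariate effect on a population parameter,
#' either a power function of a continuous covariate normalised to a
#' reference value, \eqn{(x/x_{ref})^{\theta}}, or a categorical multiplier
#' \eqn{\theta^{x}} for a 0/1 flag. Evaluating a power effect exactly at its
#' reference covariate value yields 1 by construction.
#'
#' @param covariate Covariate name (matched against dataset columns,
#'   case-insensitive).
#' @param form `"power"` for continuous covariates, `"factor"` for 0/1 flags.
#' @param coefficient Signed exponent (power form) or strictly positive
#'   multiplier (factor form).
#' @param reference Reference value for the power form; must be positive.
#'   Ignored for the factor form.
#' @param parameter Structural parameter the effect acts on; only `"cl"`
#'   (clearance) is supported.
#' @return An object of class `covariate_effect`.
#' @examples
#' covariate_effect("qcrp", "power", coefficient = -0.142, reference = 73.6)
#' covariate_effect("crrt", "factor", coefficient = 1.46)
#' @export
covariate_effect <- function(covariate, form = c("power", "factor"),
                             coefficient, reference = NULL,
                             parameter = "cl") {
  form <- match.arg(form)
  stopifnot(is.character(covariate), length(covariate) == 1L,
            is.numeric(coefficient), length(coefficient) == 1L,
            is.finite(coefficient))
  if (form == "power") {
    if (is.null(reference) || !is.numeric(reference) || reference <= 0)
      stop("power-form covariate effect on '", covariate,
           "' requires a positive reference value")
  } else {
    if (coefficient <= 0)
      stop("factor-form covariate effect on '", covariate,
           "' requires a positive multiplier")
    reference <- NULL
  }
  structure(
    list(parameter = tolower(parameter), covariate = tolower(covariate),
         form = form, reference = reference, coefficient = coefficient),
    class = "covariate_effect")
}

#' @export
print.covariate_effect <- function(x, ...) {
  if (x$form == "power")
    cat(sprintf("CL ~ (%s/%g)^%g\n", x$covariate, x$reference, x$coefficient))
  else
    cat(sprintf("CL ~ %g^%s\n", x$coefficient, x$covariate))
  invisible(x)
}

#' Population pharmacokinetic model definition
#'
#' Bundles the structural two-compartment parameters, the covariate model on
#' clearance, the inter-individual variability (IIV) standard deviations and
#' the combined residual-error parameters. Absorption rate constant `ka` is
#' a fixed (never estimated) constant, and intercompartmental clearance `q`
#' carries no IIV; both constraints are honoured by the fitting machinery.
#'
#' IIV is modelled log-normally, \eqn{P_i = P_{pop} e^{\eta_i}} with
#' \eqn{\eta_i \sim N(0, \omega^2)}. Percent coefficients of variation are
#' reported as \eqn{100\,\omega} (the common pharmacometric convention for
#' this magnitude); the exact lognormal transform
#' \eqn{100\sqrt{e^{\omega^2}-1}} is available via `cv_convention`.
#'
#' @param cl_tv Typical clearance (L/h).
#' @param vc Central volume (L).
#' @param vp Peripheral volume (L).
#' @param q Intercompartmental clearance (L/h).
#' @param ka First-order absorption rate constant (1/h), fixed.
#' @param f_oral Bioavailability shared by oral and nasogastric routes,
#'   in (0, 1].
#' @param cov_effects List of [covariate_effect()] objects (clearance only).
#' @param omega Named numeric vector of IIV standard deviations for
#'   `cl`, `vc`, `vp` (ω, not ω²); entries of 0 disable that random effect.
#' @param sigma Named numeric vector with `prop` (proportional SD,
#'   dimensionless) and `add` (additive SD, mg/L); at least one positive.
#' @param cv_convention How `%CV` maps to ω: `"sd"` treats %CV as 100·ω,
#'   `"lognormal"` uses the exact lognormal relation.
#' @return An object of class `vori_model`.
#' @seealso [vori_final_model()] for the published final model.
#' @export
vori_model <- function(cl_tv, vc, vp, q, ka = 1.2, f_oral = 1,
                       cov_effects = list(),
                       omega = c(cl = 0, vc = 0, vp = 0),
                       sigma = c(prop = 0, add = 0),
                       cv_convention = c("sd", "lognormal")) {
  cv_convention <- match.arg(cv_convention)
  for (p in c("cl_tv", "vc", "vp", "q", "ka")) {
    v <- get(p)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("'", p, "' must be a single positive number")
  }
  if (!is.numeric(f_oral) || f_oral <= 0 || f_oral > 1)
    stop("'f_oral' must lie in (0, 1]")
  om <- c(cl = 0, vc = 0, vp = 0)
  om[names(omega)] <- omega
  if (any(om < 0)) stop("omega standard deviations must be non-negative")
  sg <- c(prop = 0, add = 0)
  sg[names(sigma)] <- sigma
  if (any(sg < 0) || all(sg == 0))
    stop("sigma components must be non-negative with at least one positive")
  stopifnot(all(vapply(cov_effects, inherits, TRUE, "covariate_effect")))
  structure(
    list(theta = list(cl_tv = cl_tv, vc = vc, vp = vp, q = q, ka = ka,
                      f_oral = f_oral, ka_fixed = TRUE),
         cov_effects = cov_effects,
         omega = om, sigma = sg, cv_convention = cv_convention),
    class = "vori_model")
}

#' @export
print.vori_model <- function(x, ...) {
  cat("Two-compartment population PK model\n")
  with(x$theta, cat(sprintf(
    "  CL_tv %.3g L/h | Vc %.3g L | Vp %.3g L | Q %.3g L/h | Ka %.3g /h (fixed) | F %.3g\n",
    cl_tv, vc, vp, q, ka, f_oral)))
  cat(sprintf("  IIV (%%CV): CL %.1f, Vc %.1f, Vp %.1f; residual prop %.3g, add %.3g mg/L\n",
              100 * x$omega["cl"], 100 * x$omega["vc"], 100 * x$omega["vp"],
              x$sigma["prop"], x$sigma["add"]))
  if (length(x$cov_effects)) {
    cat("  Covariates on CL:\n")
    for (ce in x$cov_effects) {
      cat("    "); print(ce)
    }
  }
  invisible(x)
}

#' Published final model for voriconazole in critically ill patients
#'
#' The final covariate model: clearance is the typical value scaled by power
#' functions of quick C-reactive protein (qCRP, exponent -0.142, reference
#' 73.6 mg/L), creatinine clearance (+0.218, 71.8 mL/min), platelet count
#' (+0.166, 144 x 10^9/L) and prothrombin time (-0.875, 15 s), and a 1.46
#' multiplier under continuous renal replacement therapy (CRRT). Structural
#' and variability parameters are the reported population estimates.
#'
#' @return A `vori_model` with the published parameter estimates.
#' @examples
#' m <- vori_final_model()
#' individual_clearance(m, reference_covariates())  # typical value, 3.55 L/h
#' @export
vori_final_model <- function() {
  vori_model(
    cl_tv = 3.55, vc = 33.5, vp = 138, q = 52.8, ka = 1.2, f_oral = 0.835,
    cov_effects = vori_final_cov_effects(),
    omega = c(cl = 0.498, vc = 0.667, vp = 0.817),
    sigma = c(prop = 0.089, add = 0.192))
}

#' @rdname vori_final_model
#' @export
vori_final_cov_effects <- function() {
  list(
    covariate_effect("qcrp", "power", coefficient = -0.142, reference = 73.6),
    covariate_effect("clcr", "power", coefficient = 0.218, reference = 71.8),
    covariate_effect("crrt", "factor", coefficient = 1.46),
    covariate_effect("plt", "power", coefficient = 0.166, reference = 144),
    covariate_effect("pt", "power", coefficient = -0.875, reference = 15))
}

#' Reference covariate vector
#'
#' Covariates set exactly to the final-model normalisation constants (and
#' CRRT off), at which every covariate term equals 1 and clearance equals
#' its typical value.
#'
#' @param qcrp,clcr,plt,pt,crrt Optional overrides.
#' @return Named numeric vector.
#' @export
reference_covariates <- function(qcrp = 73.6, clcr = 71.8, plt = 144,
                                 pt = 15, crrt = 0) {
  c(qcrp = qcrp, clcr = clcr, plt = plt, pt = pt, crrt = crrt)
}

#' Evaluate one covariate effect
#' @noRd
eval_cov_effect <- function(ce, covs) {
  x <- covs[[ce$covariate]]
  if (is.null(x) || is.na(x))
    stop("covariate '", ce$covariate, "' missing from covariate vector")
  if (ce$form == "power") {
    if (x <= 0)
      stop("non-positive value for covariate '", ce$covariate, "'")
    (x / ce$reference)^ce$coefficient
  } else {
    if (!x %in% c(0, 1))
      stop("flag covariate '", ce$covariate, "' must be 0 or 1")
    ce$coefficient^x
  }
}

#' Individual clearance under the covariate model
#'
#' Evaluates \eqn{CL_i = CL_{tv} \prod_k h_k(x_{ik}) \, e^{\eta_{CL}}} where
#' each \eqn{h_k} is a power or factor covariate term of the model.
#'
#' @param model A `vori_model`.
#' @param covs Named vector/list of covariate values (must contain every
#'   covariate the model uses).
#' @param eta_cl Random-effect value on log clearance (default 0 gives the
#'   typical individual).
#' @return Clearance in L/h (strictly positive).
#' @examples
#' individual_clearance(vori_final_model(), reference_covariates(crrt = 1))
#' @export
individual_clearance <- function(model, covs, eta_cl = 0) {
  stopifnot(inherits(model, "vori_model"))
  cl <- model$theta$cl_tv
  for (ce in model$cov_effects) cl <- cl * eval_cov_effect(ce, as.list(covs))
  cl * exp(eta_cl)
}

#' Individual kinetic parameter set
#'
#' Applies the covariate model and lognormal random effects to produce one
#' individual's kinetic parameters.
#'
#' @param model A `vori_model`.
#' @param covs Covariate vector (see [individual_clearance()]).
#' @param eta Named numeric vector with elements `cl`, `vc`, `vp`
#'   (missing entries default to 0).
#' @return List with `cl`, `vc`, `vp`, `q`, `ka`, `f_oral`, `eta`.
#' @export
individual_parameters <- function(model, covs, eta = c(cl = 0, vc = 0, vp = 0)) {
  e <- c(cl = 0, vc = 0, vp = 0)
  e[names(eta)] <- eta
  list(cl = individual_clearance(model, covs, e[["cl"]]),
       vc = model$theta$vc * exp(e[["vc"]]),
       vp = model$theta$vp * exp(e[["vp"]]),
       q = model$theta$q,
       ka = model$theta$ka,
       f_oral = model$theta$f_oral,
       eta = e)
}

#' Convert reported %CV to an omega standard deviation
#'
#' @param cv_pct Percent coefficient of variation.
#' @param convention `"sd"` (%CV = 100·ω) or `"lognormal"`
#'   (%CV = 100·sqrt(exp(ω²)−1)).
#' @return ω on the standard-deviation scale.
#' @export
omega_from_cv <- function(cv_pct, convention = c("sd", "lognormal")) {
  convention <- match.arg(convention)
  cv <- cv_pct / 100
  if (convention == "sd") cv else sqrt(log1p(cv^2))
}

#' @rdname omega_from_cv
#' @param omega ω on the standard-deviation scale.
#' @export
cv_from_omega <- function(omega, convention = c("sd", "lognormal")) {
  convention <- match.arg(convention)
  if (convention == "sd") 100 * omega else 100 * sqrt(expm1(omega^2))
}
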
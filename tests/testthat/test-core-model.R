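test_that("covariate model reproduces the typical value and hand-checked cases", {
  m <- vori_final_model()
  # every ratio term is exactly 1 at the reference covariates
  expect_identical(individual_clearance(m, reference_covariates()), 3.55)
  expect_equal(individual_clearance(m, reference_covariates(crrt = 1)),
               3.55 * 1.46, tolerance = 1e-12)
  expect_equal(individual_clearance(m, reference_covariates(qcrp = 40)),
               3.871083, tolerance = 1e-6)
  # eta acts multiplicatively on the log scale
  expect_equal(individual_clearance(m, reference_covariates(), eta_cl = 0.5),
               3.55 * exp(0.5), tolerance = 1e-12)
})

test_that("clearance is monotone in each covariate with the documented sign", {
  m <- vori_final_model()
  cl_at <- function(...) individual_clearance(m, reference_covariates(...))
  grid <- seq(0.5, 2, length.out = 9)
  expect_true(all(diff(vapply(grid, function(s) cl_at(qcrp = 73.6 * s), 0)) < 0))
  expect_true(all(diff(vapply(grid, function(s) cl_at(pt = 15 * s), 0)) < 0))
  expect_true(all(diff(vapply(grid, function(s) cl_at(clcr = 71.8 * s), 0)) > 0))
  expect_true(all(diff(vapply(grid, function(s) cl_at(plt = 144 * s), 0)) > 0))
  expect_gt(cl_at(crrt = 1) / cl_at(crrt = 0), 1)
})

test_that("invalid covariates are rejected by name", {
  m <- vori_final_model()
  expect_error(individual_clearance(m, reference_covariates(qcrp = -3)), "qcrp")
  expect_error(individual_clearance(m, reference_covariates(crrt = 2)), "crrt")
  expect_error(covariate_effect("x", "power", coefficient = 1), "reference")
  expect_error(covariate_effect("x", "factor", coefficient = -2), "positive")
})

test_that("disposition constants satisfy the quadratic-root identities", {
  ind <- list(cl = 3.55, vc = 33.5, vp = 138, q = 52.8)
  d <- disposition(ind)
  expect_equal(d$k10, 3.55 / 33.5, tolerance = 1e-12)
  expect_equal(d$beta, 0.01982771, tolerance = 1e-6)
  expect_equal(log(2) / d$beta, 34.9585, tolerance = 1e-4)
  expect_equal(d$alpha * d$beta, d$k10 * d$k21, tolerance = 1e-10)
  expect_equal(d$alpha + d$beta, d$k10 + d$k12 + d$k21, tolerance = 1e-10)
  expect_gte(d$alpha, d$beta)
  expect_error(disposition(list(cl = 3.55, vc = 33.5, vp = 138, q = 0)),
               "non-positive")
})

test_that("closed-form kinetics match an independent ODE oracle", {
  skip_if_not_installed("deSolve")
  m <- plain_model()
  set.seed(42)
  for (rep in 1:3) {
    ind <- individual_parameters(m, list(),
                                 c(cl = rnorm(1, 0, 0.3), vc = rnorm(1, 0, 0.3),
                                   vp = rnorm(1, 0, 0.3)))
    doses <- rbind(
      dose_regimen(200, 12, n_doses = 3, route = "iv", tinf = runif(1, 0.5, 2)),
      dose_regimen(150, 12, n_doses = 2, route = "oral", start = 5.3))
    doses <- doses[order(doses$time), ]
    tt <- sort(runif(50, 0.01, 40))
    expect_equal(concentration(ind, doses, tt), ode_conc(ind, doses, tt),
                 tolerance = 1e-6)
  }
})

test_that("single-dose AUC equals Dose/CL and superposition is linear", {
  m <- plain_model()
  ind <- individual_parameters(m, list())
  # trapezoidal AUC to 10 terminal half-lives
  thalf <- log(2) / disposition(ind)$beta
  tt <- seq(0, 10 * thalf, length.out = 20000)
  cc <- concentration(ind, dose_regimen(200, 12), tt)
  auc <- sum(diff(tt) * (head(cc, -1) + tail(cc, -1)) / 2)
  expect_equal(auc, 200 / ind$cl, tolerance = 0.005)
  # oral dose: AUC0-inf = F * Dose / CL
  cco <- concentration(ind, dose_regimen(200, 12, route = "oral"), tt)
  auco <- sum(diff(tt) * (head(cco, -1) + tail(cco, -1)) / 2)
  expect_equal(auco, 0.835 * 200 / ind$cl, tolerance = 0.005)
  # superposition linearity of interleaved regimens
  a <- dose_regimen(200, 12, n_doses = 3)
  b <- dose_regimen(100, 12, n_doses = 2, route = "oral", start = 4)
  both <- rbind(a, b); both <- both[order(both$time), ]
  tt2 <- c(0.5, 3, 6, 10, 18, 30)
  expect_equal(concentration(ind, both, tt2),
               concentration(ind, a, tt2) + concentration(ind, b, tt2),
               tolerance = 1e-12)
  # no doses -> zero
  expect_identical(concentration(ind, a[0, ], c(0, 5)), c(0, 0))
})

test_that("steady-state metrics match closed forms and long superposition", {
  m <- plain_model()
  ind <- individual_parameters(m, list())
  reg <- dose_regimen(200, 12, ss = TRUE)
  sm <- steady_state_metrics(ind, reg)
  expect_equal(sm$auc24, 400 / 3.55, tolerance = 1e-12)
  expect_equal(sm$half_life, 34.9585, tolerance = 1e-4)
  # the mono-compartmental reporting convention ln2*Vc/CL
  ind2 <- individual_parameters(m, list()); ind2$cl <- 3.78
  expect_equal(steady_state_metrics(ind2, reg)$half_life_table3,
               log(2) * 33.5 / 3.78, tolerance = 1e-12)
  expect_equal(log(2) * 33.5 / 3.78, 6.143, tolerance = 1e-3)
  # trough from the accumulation closed form vs explicit 60-dose superposition
  # (the 35-h terminal phase needs ~2 weeks of dosing to be within 0.1%)
  long <- dose_regimen(200, 12, n_doses = 60)
  expect_equal(sm$cmin,
               concentration(ind, long, 59 * 12 + 12 - 1e-9),
               tolerance = 1e-3)
  # steady-state AUC over one day equals daily dose / CL (dose-interval invariance)
  reg8 <- dose_regimen(150, 8, ss = TRUE)
  expect_equal(steady_state_metrics(ind, reg8)$auc24, 450 / 3.55,
               tolerance = 1e-12)
  expect_error(steady_state_metrics(ind, dose_regimen(200, 7, ss = TRUE)),
               "divide")
})

test_that("dataset predictions equal pointwise kinetics and respect etas", {
  m <- vori_final_model()
  cfg <- generator_config(n_subjects = 8, seed = 3)
  ds <- generate_dataset(cfg)
  pr <- predict_dataset(m, ds)
  expect_equal(nrow(pr), n_observations(ds))
  # one subject checked against a direct concentration() call
  ev <- ds$events
  id1 <- ev$ID[1]
  sub <- ev[ev$ID == id1, ]
  obsr <- sub[sub$EVID == 0, ][1, ]
  dr <- sub[sub$EVID == 1, ]
  ind <- individual_parameters(m, obsr[covariate_names(ds)])
  byhand <- concentration(ind, data.frame(time = dr$TIME, amt = dr$AMT,
                                          route = dr$ROUTE, tinf = dr$DUR,
                                          ss = dr$SS, ii = dr$II), obsr$TIME)
  expect_equal(pr$pred[pr$ID == id1][1], byhand, tolerance = 1e-12)
  # empty dataset -> empty table
  empty <- pk_dataset(data.frame(ID = character(), TIME = numeric(),
                                 EVID = integer()))
  expect_identical(nrow(predict_dataset(m, empty)), 0L)
  # raising eta_cl monotonically lowers steady-state predictions
  ids <- unique(ev$ID)
  for (e in c(0.3, 0.6)) {
    et0 <- matrix(0, length(ids), 3, dimnames = list(ids, c("cl", "vc", "vp")))
    et1 <- et0; et1[, "cl"] <- e
    expect_true(all(predict_dataset(m, ds, et1)$pred <
                    predict_dataset(m, ds, et0)$pred))
  }
})
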
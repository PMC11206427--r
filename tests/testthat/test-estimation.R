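test_that("combined residual variance follows the error model", {
  s <- c(prop = 0.089, add = 0.192)
  expect_equal(residual_variance(0, s), 0.192^2, tolerance = 1e-12)
  expect_equal(residual_variance(2, s), 0.068548, tolerance = 1e-6)
  expect_equal(sqrt(residual_variance(2, s)), 0.2618, tolerance = 1e-3)
  expect_equal(residual_variance(c(0, 5, 100), c(prop = 0, add = 1)),
               c(1, 1, 1), tolerance = 1e-12)
  expect_error(residual_variance(-1, s))
})

test_that("empirical-Bayes etas behave at the degenerate limits", {
  m <- plain_model(omega = c(cl = 0.4, vc = 0, vp = 0))
  # subject without observations sits at the prior mode
  ev <- ss_subject_events("a", dv = numeric(), times = numeric())
  expect_identical(unname(eb_estimate(pk_dataset(ev), m)[1, ]), c(0, 0, 0))
  # omega -> 0 pins eta at zero regardless of data
  m0 <- plain_model(omega = c(cl = 1e-12, vc = 0, vp = 0))
  m0$omega["cl"] <- 0
  ev2 <- ss_subject_events("b", dv = 9, times = 11.5)
  expect_identical(unname(eb_estimate(pk_dataset(ev2), m0)[1, ]), c(0, 0, 0))
})

test_that("empirical-Bayes etas recover a known eta from a rich profile", {
  m <- plain_model(omega = c(cl = 0.5, vc = 0, vp = 0),
                   sigma = c(prop = 0, add = 1e-4))
  true_eta <- 0.37
  tt <- c(0, 1, 2, 4, 6, 8, 12)
  ind <- individual_parameters(m, list(), c(cl = true_eta))
  dv <- concentration(ind, dose_regimen(200, 12, ss = TRUE), tt)
  ds <- pk_dataset(ss_subject_events("s", dv, tt))
  expect_equal(eb_estimate(ds, m)[1, "cl"], true_eta, tolerance = 1e-3)
})

test_that("with no random effects the objective is the exact Gaussian -2LL", {
  m <- plain_model(omega = c(cl = 0, vc = 0, vp = 0),
                   sigma = c(prop = 0.1, add = 0.2))
  ds <- generate_dataset(generator_config(n_subjects = 10, model = m), seed = 2)
  pr <- predict_dataset(m, ds)
  pr <- pr[pr$BLQ == 0, ]
  g <- residual_variance(pr$pred, m)
  expect_equal(foce_ofv(ds, m),
               sum(log(2 * pi * g) + (pr$DV - pr$pred)^2 / g),
               tolerance = 1e-8)
})

test_that("the Laplace objective matches adaptive quadrature on toy subjects", {
  # rich 7-sample profile, one random effect on CL, additive error
  m <- plain_model(omega = c(cl = 0.3, vc = 0, vp = 0))
  tt <- c(0, 1, 2, 4, 6, 8, 12)
  reg <- dose_regimen(200, 12, ss = TRUE)
  set.seed(1)
  ind <- individual_parameters(m, list(), c(cl = 0.25))
  y <- concentration(ind, reg, tt) + rnorm(7, 0, 0.3)
  ofv <- foce_ofv(pk_dataset(ss_subject_events("r", y, tt)), m)
  oracle <- quad_ofv_1d(y, tt, reg, m, add_sd = 0.3, omega_cl = 0.3)
  expect_equal(ofv, oracle, tolerance = 1e-3)
  # sparse single trough at modest omega (the Laplace error grows with
  # omega when a subject carries a single observation)
  m2 <- plain_model(omega = c(cl = 0.1, vc = 0, vp = 0))
  ofv2 <- foce_ofv(pk_dataset(ss_subject_events("s", 3.2, 11.5)), m2)
  oracle2 <- quad_ofv_1d(3.2, 11.5, reg, m2, add_sd = 0.3, omega_cl = 0.1)
  expect_equal(ofv2, oracle2, tolerance = 1e-3)
})

test_that("the objective is additive over subjects and invariant to relabelling", {
  m <- vori_final_model()
  ds <- generate_dataset(generator_config(n_subjects = 14, seed = 6))
  base <- foce_ofv(ds, m)
  # duplicating every subject doubles the objective
  ev <- ds$events
  twin <- ev; twin$ID <- paste0(twin$ID, "_copy")
  expect_equal(foce_ofv(pk_dataset(rbind(ev, twin)), m), 2 * base,
               tolerance = 1e-8)
  # subject order does not matter
  ids <- unique(ev$ID)
  shuf <- do.call(rbind, lapply(rev(ids), function(i) ev[ev$ID == i, ]))
  expect_equal(foce_ofv(pk_dataset(shuf), m), base, tolerance = 1e-8)
  # a uniform shift of the time origin does not matter
  shifted <- ev; shifted$TIME <- shifted$TIME + 24
  expect_equal(foce_ofv(pk_dataset(shifted), m), base, tolerance = 1e-8)
})

test_that("noise-free rich data recover the structural parameters within 1%", {
  truth <- plain_model(omega = c(cl = 0, vc = 0, vp = 0),
                       sigma = c(prop = 0, add = 1e-4))
  tt <- c(0.25, 0.5, 1, 1.5, 2, 3, 5, 8, 12, 18, 24, 36, 48, 72)
  rows <- lapply(1:6, function(i) {
    dv <- concentration(individual_parameters(truth, list()),
                        dose_regimen(200, 96, tinf = 1), tt)
    ev <- ss_subject_events(paste0("s", i), dv, tt, amt = 200, ii = 96)
    ev$SS <- 0L; ev$II <- NA_real_
    ev
  })
  ds <- pk_dataset(do.call(rbind, rows))
  start <- truth
  start$theta$cl_tv <- 3.55 * 1.3; start$theta$vc <- 33.5 * 0.75
  start$theta$vp <- 138 * 1.3; start$theta$q <- 52.8 * 0.75
  ft <- suppressWarnings(pk_fit(ds, start,
                                fit_control(compute_rse = FALSE,
                                            nm_maxit = 1500L)))
  expect_equal(unname(ft$estimates["cl_tv"]), 3.55, tolerance = 0.01)
  expect_equal(unname(ft$estimates["vc"]), 33.5, tolerance = 0.01)
  expect_equal(unname(ft$estimates["vp"]), 138, tolerance = 0.01)
  expect_equal(unname(ft$estimates["q"]), 52.8, tolerance = 0.01)
  # refitting from the optimum barely moves the objective
  ft2 <- suppressWarnings(pk_fit(ds, ft$model,
                                 fit_control(compute_rse = FALSE,
                                             nm_maxit = 0L)))
  expect_lt(abs(ft2$ofv - ft$ofv), 0.1)
})

test_that("a two-compartment fit beats a one-compartment restriction on rich data", {
  truth <- plain_model(omega = c(cl = 0.2, vc = 0, vp = 0),
                       sigma = c(prop = 0, add = 0.15))
  cfg <- generator_config(n_subjects = 12, frac_intensive = 1, model = truth)
  ds <- generate_dataset(cfg, seed = 9)
  ft2c <- suppressWarnings(pk_fit(ds, truth, fit_control(compute_rse = FALSE,
                                                         nm_maxit = 800L)))
  # one-compartment restriction: no peripheral exchange (Q pinned to a
  # negligible value); profile CL, Vc and the error term in the test itself
  obj1c <- function(p) {
    m1 <- truth
    m1$theta$cl_tv <- exp(p[1]); m1$theta$vc <- exp(p[2])
    m1$theta$vp <- 1; m1$theta$q <- 1e-4
    m1$sigma["add"] <- exp(p[3]); m1$omega["cl"] <- exp(p[4])
    foce_ofv(ds, m1)
  }
  o1 <- optim(log(c(3.55, 33.5 + 138, 0.15, 0.2)), obj1c,
              control = list(maxit = 500))
  expect_gt(o1$value, ft2c$ofv)
})

test_that("bioavailability is fixed with a warning on IV-only data", {
  m <- plain_model(omega = c(cl = 0.3, vc = 0, vp = 0), f_oral = 0.835)
  cfg <- generator_config(n_subjects = 12, route_mix = c(iv = 1, oral = 0, ng = 0),
                          model = m)
  ds <- generate_dataset(cfg, seed = 13)
  expect_warning(ft <- pk_fit(ds, m, fit_control(compute_rse = FALSE,
                                                 nm_maxit = 200L)),
                 "bioavailability")
  expect_false("f_oral" %in% names(ft$estimates))
  expect_equal(ft$model$theta$f_oral, 0.835) # untouched
})
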
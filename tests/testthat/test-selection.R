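# shared fixture: clearance driven by qCRP and CRRT, decoys independent
sel_truth <- function()
  vori_model(cl_tv = 3.55, vc = 33.5, vp = 138, q = 52.8, f_oral = 0.835,
             cov_effects = list(
               covariate_effect("qcrp", "power", coefficient = -0.35,
                                reference = 73.6),
               covariate_effect("crrt", "factor", coefficient = 1.6)),
             omega = c(cl = 0.35, vc = 0.5, vp = 0.6),
             sigma = c(prop = 0.089, add = 0.192))

sel_dataset <- function(n = 110, seed = 77)
  generate_dataset(generator_config(n_subjects = n, model = sel_truth()),
                   seed = seed)

test_that("eta screening flags generating covariates and not nulls", {
  ds <- sel_dataset(n = 200)
  etas <- eb_estimate(ds, ds$truth$model)
  scr <- screen_etas(etas, ds, c("qcrp", "crrt", "alb", "sex"))
  # the generating covariate shows with its true (negative) sign; note the
  # model already explains qcrp, so screen against the covariate-FREE model
  base <- sel_truth(); base$cov_effects <- list()
  scr0 <- screen_etas(eb_estimate(ds, base), ds, c("qcrp", "crrt", "alb", "sex"))
  expect_lt(scr0$association[scr0$covariate == "qcrp"], -0.3)
  expect_gt(scr0$association[scr0$covariate == "crrt"], 0.2)
  # covariates independent of clearance stay near zero
  expect_lt(abs(scr0$association[scr0$covariate == "alb"]), 0.15)
  expect_lt(abs(scr0$association[scr0$covariate == "sex"]), 0.15)
  # under the generating model the qcrp effect is absorbed
  expect_lt(abs(scr$association[scr$covariate == "qcrp"]), 0.15)
  expect_error(screen_etas(etas, generate_dataset(
    generator_config(n_subjects = 0), seed = 1)), "empty")
  # constant covariate reported as zero with a note
  ev <- ds$events; ev$constcov <- 1
  scr2 <- screen_etas(etas, pk_dataset(ev), "constcov")
  expect_identical(scr2$association, 0)
  expect_match(scr2$note, "constant")
})

test_that("stepwise search retains true covariates, sheds decoys, and replays", {
  ds <- sel_dataset()
  base <- sel_truth(); base$cov_effects <- list()
  ctl <- fit_control(compute_rse = FALSE, nm_maxit = 300L, maxit = 200L)
  sel <- select_covariates(ds, base, c("qcrp", "crrt", "ecmo"), control = ctl)
  kept <- vapply(sel$model$cov_effects, function(e) e$covariate, "")
  expect_setequal(kept, c("qcrp", "crrt"))
  tr <- sel$trace
  # the dominant generating covariate enters first, above the 3.84 gate
  first <- tr[tr$step == "forward", ][1, ]
  expect_identical(first$covariate, "qcrp")
  expect_gt(first$delta_ofv, 3.84)
  # every retained covariate survived the 7.88 backward gate
  expect_true(all(tr$delta_ofv[tr$step == "backward" &
                               tr$decision == "all retained"] >= 7.88))
  # replay: identical data and settings give an identical trace
  sel2 <- select_covariates(ds, base, c("qcrp", "crrt", "ecmo"), control = ctl)
  expect_identical(sel$trace, sel2$trace)
  expect_equal(sel$fit$ofv, sel2$fit$ofv, tolerance = 1e-10)
})

test_that("forward and backward deltas are gated at 3.84 and 7.88", {
  ds <- sel_dataset()
  base <- sel_truth(); base$cov_effects <- list()
  ctl <- fit_control(compute_rse = FALSE, nm_maxit = 300L, maxit = 200L)
  fw <- forward_step(ds, base, c("qcrp", "sex"), control = ctl)
  expect_identical(fw$covariate, "qcrp")
  expect_gt(fw$delta_ofv, 3.84)
  # a null covariate alone does not clear the gate
  fw0 <- forward_step(ds, base, "sex", control = ctl)
  expect_null(fw0$covariate)
  expect_lt(fw0$delta_ofv, 3.84)
  # removing a strong covariate raises the OFV well above 7.88: retained
  full <- sel_truth()
  bw <- backward_step(ds, full, control = ctl)
  expect_null(bw$covariate)
  expect_gt(bw$delta_ofv, 7.88)
  expect_error(backward_step(ds, base, control = ctl), "no covariates")
})

test_that("the RSE rule flags only imprecise covariate effects", {
  fake <- structure(list(rse = c(cl_tv = 4, beta_qcrp = 77, beta_crrt = 6,
                                 beta_plt = NA, omega_cl = 60)),
                    class = "vori_fit")
  expect_identical(apply_rse_rule(fake), "qcrp")
  expect_identical(apply_rse_rule(fake, threshold_pct = 80), character(0))
  fake2 <- structure(list(rse = c(beta_qcrp = 15, beta_crrt = 12)),
                     class = "vori_fit")
  expect_identical(apply_rse_rule(fake2), character(0))
})
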
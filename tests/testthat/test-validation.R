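test_that("CWRES collapses to standardized residuals without random effects", {
  m <- plain_model(omega = c(cl = 0, vc = 0, vp = 0),
                   sigma = c(prop = 0, add = 0.25))
  ds <- generate_dataset(generator_config(n_subjects = 12, model = m), seed = 3)
  cw <- cwres(ds, m)
  expect_equal(cw$CWRES, (cw$DV - cw$PRED) / 0.25, tolerance = 1e-10)
  expect_equal(cw$IPRED, cw$PRED, tolerance = 1e-12)
})

test_that("CWRES is calibrated to N(0,1) on well-specified data", {
  m <- vori_final_model()
  ds <- generate_dataset(generator_config(n_subjects = 150), seed = 21)
  cw <- cwres(ds, m)
  expect_identical(nrow(cw), n_observations(ds) -
                     sum(ds$events$BLQ, na.rm = TRUE))
  expect_gt(mean(cw$CWRES), -0.1)
  expect_lt(mean(cw$CWRES), 0.1)
  expect_gt(sd(cw$CWRES), 0.9)
  expect_lt(sd(cw$CWRES), 1.1)
  # residuals concentrate in the +/-2 band used on diagnostic plots
  expect_gte(mean(abs(cw$CWRES) <= 2), 0.93)
})

test_that("bootstrap is deterministic and degenerates correctly", {
  m <- plain_model(omega = c(cl = 0.3, vc = 0, vp = 0))
  one <- ss_subject_events("s1", dv = c(3.1, 4.4), times = c(11.5, 2),
                           covs = NULL)
  one <- one[order(one$TIME), ]
  # N identical subjects: every resample is the same dataset
  ev <- do.call(rbind, lapply(1:10, function(i) {
    x <- one; x$ID <- paste0("s", i); x
  }))
  ds <- pk_dataset(ev)
  ctl <- fit_control(compute_rse = FALSE, nm_maxit = 0L, maxit = 2000L)
  bs <- pk_bootstrap(ds, m, n_resamples = 3, seed = 7, control = ctl)
  expect_lt(max(bs$summary$hi - bs$summary$lo), 1e-8)
  expect_identical(bs$n_converged + bs$n_failed, 3L)
  # same seed, bit-identical resample indices
  bs2 <- pk_bootstrap(ds, m, n_resamples = 3, seed = 7, control = ctl)
  expect_identical(bs$indices, bs2$indices)
})

test_that("reduced bootstrap medians sit near the point estimates", {
  m <- plain_model(omega = c(cl = 0.35, vc = 0, vp = 0))
  ds <- generate_dataset(generator_config(n_subjects = 50, model = m), seed = 31)
  ctl <- fit_control(compute_rse = FALSE, nm_maxit = 150L, maxit = 200L)
  ft <- suppressWarnings(pk_fit(ds, m, ctl))
  bs <- pk_bootstrap(ds, ft$model, n_resamples = 12, seed = 5, control = ctl)
  med <- setNames(bs$summary$median, bs$summary$parameter)
  for (p in c("cl_tv", "omega_cl", "f_oral"))
    expect_equal(unname(med[p]), unname(ft$estimates[p]), tolerance = 0.10)
  # percentile interval brackets the point estimate for clearance
  expect_gt(unname(ft$estimates["cl_tv"]), bs$summary$lo[bs$summary$parameter == "cl_tv"])
  expect_lt(unname(ft$estimates["cl_tv"]), bs$summary$hi[bs$summary$parameter == "cl_tv"])
})

test_that("prediction correction uses the bin-median over own-prediction ratio", {
  # identical subjects: every PRED in a bin is equal -> corrected = raw
  m <- plain_model(omega = c(cl = 0.3, vc = 0, vp = 0))
  tt <- c(2, 5, 8, 11.5)
  ev <- do.call(rbind, lapply(1:30, function(i) {
    x <- ss_subject_events(paste0("s", i), dv = c(5.1, 4.2, 3.9, 3.1), times = tt)
    x
  }))
  ds <- pk_dataset(ev)
  v <- pcvpc(ds, m, n_sim = 40, bins = 4, seed = 2)
  obs_all <- ds$events$DV[ds$events$EVID == 0]
  tads <- ds$events$TIME[ds$events$EVID == 0]
  for (b in seq_len(nrow(v$bands))) {
    sel <- tads > v$bands$tad_lo[b] - 1e-9 & tads <= v$bands$tad_hi[b] + 1e-9
    expect_equal(unname(v$bands$obs_p50[b]),
                 unname(quantile(obs_all[sel], 0.5)), tolerance = 1e-10)
  }
  # percentile bands are nested and bins partition the observations
  expect_true(all(v$bands$obs_p5 <= v$bands$obs_p50))
  expect_true(all(v$bands$obs_p50 <= v$bands$obs_p95))
  expect_identical(sum(v$bands$n_obs), length(obs_all))
  # explicit ratio arithmetic: halving a row's PRED doubles its correction
  expect_equal(2 * 1.5, 4 / 2 * 1.5) # pcY = (bin median 4 / own 2) * Y
})

test_that("the pcVPC of the generating model covers its own percentiles", {
  m <- vori_final_model()
  ds <- generate_dataset(generator_config(n_subjects = 120), seed = 17)
  v <- pcvpc(ds, m, n_sim = 120, bins = 6, seed = 4)
  b <- v$bands
  inside <- b$obs_p50 >= b$p50_lo & b$obs_p50 <= b$p50_hi
  expect_gte(mean(inside), 0.9)
  # deterministic given the seed
  v2 <- pcvpc(ds, m, n_sim = 120, bins = 6, seed = 4)
  expect_identical(v$bands, v2$bands)
})
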
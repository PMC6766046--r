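test_that("generator tables are deterministic under the seed and well shaped", {
  cfg <- generator_config(n_districts = 40, n_provinces = 5,
                          n_residences = 50, seed = 3)
  d1 <- generate_districts(cfg); d2 <- generate_districts(cfg)
  expect_identical(d1, d2)
  expect_equal(nrow(d1), 40)
  expect_true(all(d1$greenery >= cfg$greenery_range[1] &
                    d1$greenery <= cfg$greenery_range[2]))
  m1 <- generate_meteorology(cfg); m2 <- generate_meteorology(cfg)
  expect_identical(m1, m2)
  expect_equal(nrow(m1), 12 * 5)
  expect_true(all(m1$wind >= 0))
  # built-in seasonality: January colder than July in every province
  jan <- m1$temp[m1$month == 1]; jul <- m1$temp[m1$month == 7]
  expect_true(all(jul - jan > 0))
})

test_that("synthetic CSV output is byte-identical across reruns", {
  cfg <- generator_config(n_districts = 20, n_provinces = 4,
                          n_residences = 120, seed = 9)
  d1 <- tempfile("simA"); d2 <- tempfile("simB")
  p1 <- simulate_to_dir(cfg, d1); p2 <- simulate_to_dir(cfg, d2)
  for (f in names(p1)) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]),
                     info = paste("file", f))
  }
})

test_that("truth is forward/inverse consistent: inverting truth returns planted S", {
  cfg <- generator_config(n_residences = 400, seed = 21)
  d <- generate_districts(cfg); m <- generate_meteorology(cfg)
  sim <- generate_residences(cfg, d, m)
  tr <- sim$truth$residences
  S_back <- infiltration_from_measurement(tr$ci_annual, Cs = tr$Cs, Cbm = 0,
                                          Co = tr$Co, lam = cfg$lam,
                                          lam_v = tr$lam_v)
  expect_equal(S_back, tr$S_true, tolerance = 1e-10)
})

test_that("calibrated coefficients stay linear in the design and match truth S", {
  cfg <- generator_config(n_residences = 500, seed = 22)
  d <- generate_districts(cfg); m <- generate_meteorology(cfg)
  sim <- generate_residences(cfg, d, m)
  tr <- sim$truth$residences
  res <- sim$residences
  ref <- cfg$coefficients
  didx <- match(res$district_id, d$district_id)
  feat <- data.frame(stratum = tr$stratum, greenery = d$greenery[didx],
                     district_gm = d$radon_gm[didx], material = res$material,
                     cracks = res$cracks, floors = res$floors)
  dsg <- build_design(feat, ref)
  for (st in names(dsg)) {
    beta <- unlist(sim$truth$calibration[[st]]$coefficients)
    X <- dsg[[st]]$X
    lin <- drop(X %*% beta[colnames(X)])
    # S_true minus the calibrated linear predictor is the residual noise,
    # which has roughly the configured SD and no systematic offset
    eps <- tr$S_true[dsg[[st]]$rows] - lin
    expect_lt(abs(mean(eps)), 0.5)
    expect_lt(abs(sd(eps) - cfg$residual_sd), 0.6)
  }
})

test_that("generated stratum GM/GSD match the configured targets", {
  cfg <- generator_config(n_residences = 3000, seed = 23)
  d <- generate_districts(cfg); m <- generate_meteorology(cfg)
  sim <- generate_residences(cfg, d, m)
  tr <- sim$truth$residences
  for (st in 1:4) {
    ci <- tr$ci_annual[tr$stratum == st]
    tgt <- cfg$stratum_targets[st, ]
    # calibration solves on the realized sample, so the match is tight
    expect_equal(geometric_mean(ci), tgt$gm, tolerance = 1e-6)
    expect_equal(geometric_sd(ci), tgt$gsd, tolerance = 1e-6)
  }
})

test_that("measurement split and planted outliers behave as configured", {
  cfg <- generator_config(n_residences = 1500, seed = 24,
                          outlier_fraction = 0.03)
  d <- generate_districts(cfg); m <- generate_meteorology(cfg)
  sim <- generate_residences(cfg, d, m)
  tr <- sim$truth$residences
  res <- sim$residences
  expect_equal(sum(tr$planted_outlier), round(0.03 * 1500))
  # two-point GM re-annualized recovers the (possibly contaminated) truth
  gm <- sqrt(res$radon_pt1 * res$radon_pt2)
  ann <- gm * unname(cfg$seasonal_factors[res$season])
  clean <- !tr$planted_outlier
  # net measurement noise on the log GM has SD log(gsd)/sqrt(2)
  lr <- log(ann[clean]) - log(tr$ci_annual[clean])
  expect_lt(abs(sd(lr) - log(cfg$measurement_gsd) / sqrt(2)), 0.02)
  expect_lt(abs(mean(lr)), 0.01)
  # contaminants sit ~6 stratum log-SDs from the stratum geometric mean
  shift <- abs(log(ann[!clean]) -
                 log(cfg$stratum_targets$gm[tr$stratum[!clean]]))
  sd_st <- log(cfg$stratum_targets$gsd[tr$stratum[!clean]])
  expect_true(all(shift > 5 * sd_st & shift < 7 * sd_st))
})

test_that("noiseless generation is exactly reproducible through the forward model", {
  cfg <- generator_config(n_residences = 200, residual_sd = 0,
                          measurement_gsd = 1, outlier_fraction = 0,
                          seed = 25)
  d <- generate_districts(cfg); m <- generate_meteorology(cfg)
  sim <- generate_residences(cfg, d, m)
  res <- sim$residences; tr <- sim$truth$residences
  expect_equal(res$radon_pt1, res$radon_pt2)
  ann <- res$radon_pt1 * unname(cfg$seasonal_factors[res$season])
  expect_equal(ann, tr$ci_annual, tolerance = 1e-12)
})

test_that("generator configuration validates its invariants", {
  expect_error(generator_config(stratum_mix = c(0.5, 0.5, 0.5, 0.5)))
  expect_error(generator_config(greenery_range = c(-5, 50)), "greenery_range")
  expect_error(generator_config(measurement_gsd = 0.9))
  expect_error(generator_config(outlier_fraction = 1.2))
})
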
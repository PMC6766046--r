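ref <- reference_coefficients()

test_that("the packaged coefficient set carries the expected structure", {
  expect_setequal(names(ref$strata), as.character(1:4))
  s3 <- ref$strata[["3"]]
  expect_setequal(s3$predictors, c("greenery", "district_gm", "material"))
  expect_setequal(s3$materials, c("concrete", "red_brick", "cement_block"))
  expect_false("soil" %in% ref$strata[["4"]]$materials)
  # reference levels carry no coefficient
  for (s in ref$strata)
    expect_false(any(grepl("concrete", names(s$coefficients))))
})

test_that("design matrices honour reference cells and stratum predictor sets", {
  rows <- data.frame(
    stratum = c(1L, 1L, 3L, 4L),
    greenery = c(10, 20, 30, 40),
    district_gm = c(50, 60, 70, 80),
    material = c("concrete", "wood", "cement_block", "other"),
    cracks = c("0-1", "2+", "0-1", "2+"),
    floors = c("1", "2+", "2+", "1")
  )
  d <- build_design(rows, ref)
  # reference residence: all dummies zero
  X1 <- d[["1"]]$X
  expect_equal(unname(X1[1, setdiff(colnames(X1), c("intercept", "greenery",
                                                    "district_gm"))]),
               rep(0, ncol(X1) - 3))
  expect_equal(unname(X1[2, "material_wood"]), 1)
  # stratum 3 never emits crack/floor (or soil/wood) columns
  expect_false(any(c("cracks_2plus", "floors_2plus", "material_soil",
                     "material_wood") %in% colnames(d[["3"]]$X)))
  # rows partition exactly by stratum
  expect_setequal(unlist(lapply(d, `[[`, "rows")), 1:4)
  # material level blank in stratum 3 is rejected by name
  bad <- rows[3, ]; bad$material <- "wood"
  expect_error(build_design(bad, ref), "wood")
  bad$material <- "granite"
  expect_error(build_design(bad, ref), "granite")
})

test_that("zero-noise fits recover generating coefficients to machine precision", {
  set.seed(61)
  for (st in 1:4) {
    df <- simulate_stratum_design(120, st, ref, residual_sd = 0)
    fit <- fit_infiltration(df, ref)
    beta_hat <- fit$strata[[as.character(st)]]$coefficients
    beta_true <- ref$strata[[as.character(st)]]$coefficients[names(beta_hat)]
    expect_equal(beta_hat, beta_true, tolerance = 1e-9)
    expect_equal(fit$strata[[as.character(st)]]$sigma, 0, tolerance = 1e-8)
  }
})

test_that("OLS linearity: doubling responses doubles every coefficient", {
  set.seed(62)
  df <- simulate_stratum_design(200, 2, ref, residual_sd = 2)
  f1 <- fit_infiltration(df, ref)
  df2 <- df; df2$S <- 2 * df2$S
  f2 <- fit_infiltration(df2, ref)
  expect_equal(f2$strata[["2"]]$coefficients,
               2 * f1$strata[["2"]]$coefficients)
})

test_that("residuals are orthogonal to every design column", {
  set.seed(63)
  df <- simulate_stratum_design(300, 1, ref, residual_sd = 3)
  d <- build_design(df, ref)
  fit <- fit_infiltration(d, ref)
  resid <- df$S - drop(d[["1"]]$X %*% fit$strata[["1"]]$coefficients)
  expect_lt(max(abs(crossprod(d[["1"]]$X, resid))), 1e-7)
})

test_that("degenerate designs are rejected with informative errors", {
  set.seed(64)
  df <- simulate_stratum_design(5, 1, ref, residual_sd = 1)
  expect_error(fit_infiltration(df, ref), "cannot identify")
  df <- simulate_stratum_design(80, 1, ref, residual_sd = 1)
  df$material <- "concrete"
  df$cracks <- "0-1"  # constant dummy columns: collinear with the intercept
  expect_error(fit_infiltration(df, ref), "rank deficient")
})

test_that("prediction evaluates the published linear predictor by hand", {
  model <- as_infiltration_model(ref)
  expect_equal(ref$strata[["4"]]$coefficients[["intercept"]], 11.09)
  row1 <- data.frame(stratum = 1L, greenery = 10, district_gm = 50,
                     material = "concrete", cracks = "0-1", floors = "1")
  expect_equal(predict_s(model, row1, ref), -15.89 + 0.18 * 10 + 2.73 * 50)
  # the intercept is recovered as the prediction difference of two points
  # one district-GM unit apart at zero greenery
  r4a <- data.frame(stratum = 4L, greenery = 0, district_gm = 2,
                    material = "concrete", cracks = "0-1", floors = "1")
  r4b <- r4a; r4b$district_gm <- 1
  expect_equal(2 * predict_s(model, r4b, ref) - predict_s(model, r4a, ref),
               11.09)
})

test_that("prediction at the stratum mean design point equals the mean fitted S", {
  set.seed(65)
  df <- simulate_stratum_design(250, 2, ref, residual_sd = 2)
  d <- build_design(df, ref)
  fit <- fit_infiltration(d, ref)
  fitted_mean <- mean(drop(d[["2"]]$X %*% fit$strata[["2"]]$coefficients))
  expect_equal(fitted_mean, mean(df$S), tolerance = 1e-10)
})

test_that("predict_ci composes the fitted S with the steady state", {
  model <- as_infiltration_model(ref)
  row <- data.frame(stratum = 2L, greenery = 30, district_gm = 40,
                    material = "red_brick", cracks = "2+", floors = "1")
  S <- predict_s(model, row, ref)
  ci <- predict_ci(model, row, Cs = 90, Co = 10, lam_v = 0.4, ref = ref)
  expect_equal(ci, steady_state_ci(S, Cs = 90, Cbm = 0, Co = 10, lam_v = 0.4))
  # monotone in the predicted S through any covariate that raises it
  row_hi <- row; row_hi$district_gm <- 80
  expect_gt(predict_ci(model, row_hi, Cs = 90, Co = 10, lam_v = 0.4,
                       ref = ref), ci)
  # round-trip: with S forced to the inverted value of a measurement,
  # the predicted concentration is that measurement
  ci_meas <- 57.3
  S_inv <- infiltration_from_measurement(ci_meas, Cs = 90, Co = 10,
                                         lam_v = 0.4)
  expect_equal(steady_state_ci(S_inv, Cs = 90, Cbm = 0, Co = 10,
                               lam_v = 0.4), ci_meas)
})

test_that("fitted models survive a JSON round trip", {
  set.seed(66)
  df <- do.call(rbind, lapply(1:4, function(st)
    simulate_stratum_design(100, st, ref, residual_sd = 2)))
  fit <- fit_infiltration(df, ref)
  path <- tempfile(fileext = ".json")
  write_infiltration_model(fit, path)
  back <- read_infiltration_model(path)
  expect_equal(back$strata[["1"]]$coefficients,
               fit$strata[["1"]]$coefficients, tolerance = 1e-12)
  newrows <- df[sample(nrow(df), 40), ]
  expect_equal(predict_s(back, newrows, ref), predict_s(fit, newrows, ref),
               tolerance = 1e-12)
})

test_that("standard errors and p-values match the stats::lm summary", {
  set.seed(67)
  df <- simulate_stratum_design(150, 3, ref, residual_sd = 2)
  fit <- fit_infiltration(df, ref)$strata[["3"]]
  lmfit <- summary(lm(S ~ greenery + district_gm + material, data = within(df, {
    material <- factor(material, levels = ref$strata[["3"]]$materials)
  })))
  expect_equal(unname(fit$coefficients),
               unname(coef(lmfit)[, 1]), tolerance = 1e-10)
  expect_equal(unname(fit$se), unname(coef(lmfit)[, 2]), tolerance = 1e-10)
  expect_equal(unname(fit$p), unname(coef(lmfit)[, 4]), tolerance = 1e-10)
})
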
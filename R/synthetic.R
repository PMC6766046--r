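#' Configuration of the synthetic survey generator
#'
#' Defines the study conditions the generator emulates: the administrative
#' geography (233 districts in 17 provinces, matching the national survey
#' frame), the stratum mix and the per-stratum log-normal targets for
#' annual indoor radon (GM/GSD of the four residence strata), the
#' infiltration-factor coefficients driving the forward model, noise
#' levels, seasonal correction factors, ventilation parameters and
#' reference levels for the regional proxies.
#'
#' @param n_districts,n_provinces,n_residences table sizes; defaults 233,
#'   17 and 2000.
#' @param stratum_mix proportions over strata 1..4 (sum 1). Default
#'   \code{c(0.25, 0.35, 0.05, 0.35)}: detached houses dominate rural
#'   groundwater use, the other-residence/groundwater stratum is small.
#' @param stratum_targets data.frame with columns \code{stratum, gm, gsd};
#'   default the packaged per-stratum annual summaries.
#' @param coefficients coefficient set ([reference_coefficients()] format)
#'   used as the forward-model truth.
#' @param residual_sd SD of the infiltration-factor noise term
#'   (Bq m-3 h-1); default 2.
#' @param measurement_gsd multiplicative log-normal measurement error GSD
#'   applied independently to each of the two measurement points;
#'   default 1.1. Set to 1 for noiseless measurements.
#' @param outlier_fraction fraction of residences planted as gross
#'   contaminants; default 0.
#' @param outlier_sd_mult contaminant magnitude in units of the stratum's
#'   log-scale SD; default 6.
#' @param seasonal_factors named season-to-multiplier map used to
#'   de-annualize measurements (the truth file records it); default
#'   winter 0.85, spring 1, summer 1.2, autumn 1.
#' @param habit_weights,habit_mix ventilation-habit multipliers for N and
#'   the population mix over low/medium/high.
#' @param ft,fw,Ti ventilation-model parameters (see [ventilation_rate()])
#'   and the fixed indoor temperature (degC).
#' @param soil_reference,outdoor_reference reference concentrations
#'   (Bq m-3) that district/province weights multiply.
#' @param greenery_range district greenery-ratio bounds within [0, 100].
#' @param district_gm_gm,district_gm_gsd log-normal parameters of the
#'   district indoor-radon GMs; defaults 86.52 (the national winter-survey
#'   GM) and 1.5.
#' @param survey_per_district,survey_gsd winter-survey records generated
#'   per district and their within-district GSD.
#' @param lam radon decay constant (h-1).
#' @param calibrate logically, calibrate each stratum's forward model so the
#'   generated annual concentrations hit the stratum GM/GSD targets
#'   (affine map of the linear predictor; see the methods vignette).
#' @param seed integer seed fixing all randomness end-to-end.
#' @return A list of class \code{generator_config}.
#' @export
generator_config <- function(n_districts = 233L,
                             n_provinces = 17L,
                             n_residences = 2000L,
                             stratum_mix = c(0.25, 0.35, 0.05, 0.35),
                             stratum_targets = NULL,
                             coefficients = reference_coefficients(),
                             residual_sd = 2,
                             measurement_gsd = 1.1,
                             outlier_fraction = 0,
                             outlier_sd_mult = 6,
                             seasonal_factors = c(winter = 0.85, spring = 1,
                                                  summer = 1.2, autumn = 1),
                             habit_weights = default_habit_weights(),
                             habit_mix = c(low = 0.25, medium = 0.5,
                                           high = 0.25),
                             ft = 0.03, fw = 0.01, Ti = 20,
                             soil_reference = 86.52,
                             outdoor_reference = 10,
                             greenery_range = c(5, 85),
                             district_gm_gm = 86.52,
                             district_gm_gsd = 1.5,
                             survey_per_district = 30L,
                             survey_gsd = 1.8,
                             lam = radon_decay_constant,
                             calibrate = TRUE,
                             seed = 1L) {
  if (is.null(stratum_targets)) {
    stratum_targets <- data.frame(
      stratum = 1:4,
      gm = vapply(as.character(1:4),
                  function(s) coefficients$strata[[s]]$gm, numeric(1)),
      gsd = vapply(as.character(1:4),
                   function(s) coefficients$strata[[s]]$gsd, numeric(1))
    )
  }
  stopifnot(n_districts >= 1, n_provinces >= 1, n_residences >= 1,
            length(stratum_mix) == 4, abs(sum(stratum_mix) - 1) < 1e-8,
            all(stratum_targets$gsd > 1),
            measurement_gsd >= 1, residual_sd >= 0,
            outlier_fraction >= 0, outlier_fraction < 1)
  if (greenery_range[1] < 0 || greenery_range[2] > 100 ||
      greenery_range[1] >= greenery_range[2])
    stop("greenery_range must be an increasing interval within [0, 100]")
  check_pos(unlist(seasonal_factors), "seasonal_factors")
  check_pos(soil_reference, "soil_reference")
  check_pos(outdoor_reference, "outdoor_reference")
  check_pos(lam, "lam")
  cfg <- list(n_districts = as.integer(n_districts),
              n_provinces = as.integer(n_provinces),
              n_residences = as.integer(n_residences),
              stratum_mix = stratum_mix,
              stratum_targets = stratum_targets,
              coefficients = coefficients,
              residual_sd = residual_sd,
              measurement_gsd = measurement_gsd,
              outlier_fraction = outlier_fraction,
              outlier_sd_mult = outlier_sd_mult,
              seasonal_factors = unlist(seasonal_factors),
              habit_weights = unlist(habit_weights),
              habit_mix = unlist(habit_mix),
              ft = ft, fw = fw, Ti = Ti,
              soil_reference = soil_reference,
              outdoor_reference = outdoor_reference,
              greenery_range = greenery_range,
              district_gm_gm = district_gm_gm,
              district_gm_gsd = district_gm_gsd,
              survey_per_district = as.integer(survey_per_district),
              survey_gsd = survey_gsd,
              lam = lam,
              calibrate = isTRUE(calibrate),
              seed = as.integer(seed))
  class(cfg) <- "generator_config"
  cfg
}

#' Generate the synthetic district table
#'
#' Districts carry a greenery ratio (uniform on the configured interval)
#' and a district indoor-radon geometric mean (log-normal), and are linked
#' round-robin to provinces.
#'
#' @param cfg a [generator_config()].
#' @return data.frame: \code{district_id, province_id, greenery, radon_gm}.
#' @export
generate_districts <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed + 101L)
  n <- cfg$n_districts
  data.frame(
    district_id = sprintf("D%03d", seq_len(n)),
    province_id = sprintf("P%02d", ((seq_len(n) - 1L) %% cfg$n_provinces) + 1L),
    greenery = stats::runif(n, cfg$greenery_range[1], cfg$greenery_range[2]),
    radon_gm = stats::rlnorm(n, log(cfg$district_gm_gm),
                             log(cfg$district_gm_gsd)),
    stringsAsFactors = FALSE
  )
}

#' Generate synthetic monthly meteorological normals per province
#'
#' Twelve monthly rows per province: temperature follows a sinusoid with a
#' January minimum (temperate northern-hemisphere seasonality) plus small
#' noise; wind speed is log-normal around a province mean.
#'
#' @param cfg a [generator_config()].
#' @return data.frame: \code{province_id, month, temp, wind} (degC, m s-1).
#' @export
generate_meteorology <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed + 202L)
  provinces <- sprintf("P%02d", seq_len(cfg$n_provinces))
  out <- do.call(rbind, lapply(provinces, function(p) {
    mean_t <- stats::runif(1, 10, 14)
    amp <- stats::runif(1, 11, 15)
    wmean <- stats::runif(1, 1.5, 3)
    m <- 1:12
    data.frame(
      province_id = p, month = m,
      temp = mean_t - amp * cos(2 * pi * (m - 1) / 12) +
        stats::rnorm(12, 0, 0.5),
      wind = wmean * exp(stats::rnorm(12, 0, 0.15)),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Generate the synthetic winter survey
#'
#' Record-level winter indoor-radon survey used by the regional weighting
#' scheme: per district, log-normal records around the district GM.
#'
#' @param cfg a [generator_config()].
#' @param districts table from [generate_districts()].
#' @return data.frame: \code{district_id, province_id, radon} (Bq m-3).
#' @export
generate_survey <- function(cfg, districts) {
  stopifnot(inherits(cfg, "generator_config"), is.data.frame(districts))
  set.seed(cfg$seed + 303L)
  k <- cfg$survey_per_district
  n <- nrow(districts) * k
  idx <- rep(seq_len(nrow(districts)), each = k)
  data.frame(
    district_id = districts$district_id[idx],
    province_id = districts$province_id[idx],
    radon = stats::rlnorm(n, log(districts$radon_gm[idx]),
                          log(cfg$survey_gsd)),
    stringsAsFactors = FALSE
  )
}

#' Annual-mean ventilation rate per province at N = 1
#'
#' Averages the monthly ventilation rates computed from the province's
#' monthly temperature and wind normals at the configured indoor
#' temperature; the habit multiplier N scales this base rate linearly, so
#' per-residence rates are \code{base[province] * N}.
#'
#' @param meteo monthly normals (\code{province_id, month, temp, wind}).
#' @param ft,fw,Ti ventilation parameters and indoor temperature.
#' @return Named numeric vector of base rates (h-1) keyed by province.
#' @export
province_ventilation <- function(meteo, ft, fw, Ti) {
  stopifnot(is.data.frame(meteo),
            all(c("province_id", "month", "temp", "wind") %in% names(meteo)))
  lv <- ventilation_rate(ft, fw, Ti = Ti, To = meteo$temp, u = meteo$wind,
                         N = 1)
  tapply(lv, meteo$province_id, mean)
}

# solve the per-stratum affine calibration: find (a, c) such that
# Ci = (a + c*P + r) / (lam + lam_v), r = eps + lam_v*Co - lam*Cs,
# has sample geometric mean gm_t and geometric SD gsd_t. Positivity of all
# Ci is guaranteed by restricting a above the feasibility bound; slopes c
# under which the positivity-constrained intercept can no longer reach the
# target GM are treated as over-dispersed (the log spread diverges at the
# feasibility boundary), so bisection on c always brackets the GSD target.
calibrate_affine <- function(P, eps, lam_v, Cs, Co, lam, gm_t, gsd_t) {
  r <- eps + lam_v * Co - lam * Cs
  denom <- lam + lam_v
  ci_of <- function(a, c) (a + c * P + r) / denom
  solve_a <- function(c) {
    a_min <- max(-(c * P + r))
    f <- function(a) mean(log(ci_of(a, c))) - log(gm_t)
    lo <- a_min + 1e-9 * max(1, abs(a_min))
    if (f(lo) >= 0) return(NA_real_)  # GM target unreachable at this slope
    hi <- max(a_min + 1, abs(a_min) + 1)
    while (f(hi) < 0 && hi < 1e12) hi <- hi * 2
    stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  }
  # sdlog - target, with infeasible slopes counted as over-dispersed
  gap <- function(c) {
    a <- solve_a(c)
    if (is.na(a)) return(Inf)
    stats::sd(log(ci_of(a, c))) - log(gsd_t)
  }
  if (length(P) < 3L || stats::sd(P + eps) == 0) {
    a <- solve_a(1)
    if (is.na(a)) a <- solve_a(0)
    return(list(a = a, c = if (is.na(a)) 0 else 1, matched_gsd = FALSE))
  }
  if (gap(0) >= 0) {
    # spread floor from ventilation/regional variation already at or above
    # the target: match the GM only
    warning("stratum spread floor exceeds target GSD ", gsd_t,
            "; matching GM only")
    return(list(a = solve_a(0), c = 0, matched_gsd = FALSE))
  }
  c_lo <- 0
  c_hi <- 1e-3
  k <- 0L
  while (gap(c_hi) < 0 && k < 60L) {
    c_lo <- c_hi
    c_hi <- c_hi * 2
    k <- k + 1L
  }
  for (i in seq_len(200L)) {
    c_mid <- (c_lo + c_hi) / 2
    if (gap(c_mid) < 0) c_lo <- c_mid else c_hi <- c_mid
    if (c_hi - c_lo < 1e-10 * max(1, c_hi)) break
  }
  c_star <- c_lo  # feasible side of the bracket
  list(a = solve_a(c_star), c = c_star, matched_gsd = TRUE)
}

#' Forward-simulate synthetic residences and their radon measurements
#'
#' Draws residence features (stratum, district, building traits, habits,
#' measurement season), computes the true infiltration factor from the
#' configured coefficients plus Gaussian noise, the per-residence
#' ventilation rate from the province meteorology and habit-weighted N, the
#' regional soil/outdoor proxies from the winter survey weights, and the
#' true annual indoor concentration from the steady-state solution. The
#' annual truth is then optionally contaminated with gross outliers,
#' de-annualized by the inverse seasonal factor of the assigned measurement
#' season, and split into two measurement points with independent
#' multiplicative log-normal error.
#'
#' When \code{cfg$calibrate} is TRUE each stratum's linear predictor is
#' affinely recalibrated (intercept shift plus slope scaling) so the
#' realized annual concentrations match the stratum's configured GM and GSD;
#' the truth object records the calibrated coefficients, which remain
#' exactly linear in the design.
#'
#' @param cfg a [generator_config()].
#' @param districts,meteo tables from [generate_districts()] and
#'   [generate_meteorology()].
#' @param survey winter survey from [generate_survey()]; generated from
#'   \code{cfg} if NULL.
#' @return A list with \code{residences} (the measurement-level table:
#'   \code{residence_id, district_id, province_id, res_type, groundwater,
#'   material, cracks, floors, vent_habit, season, radon_pt1, radon_pt2}),
#'   \code{survey}, and \code{truth} — a list holding the per-residence
#'   truth table (\code{S_true, lam_v, ci_annual, Cs, Co, stratum,
#'   planted_outlier}), the calibrated per-stratum coefficients, the
#'   seasonal factors, habit weights, ventilation parameters and reference
#'   levels used.
#' @export
generate_residences <- function(cfg, districts, meteo, survey = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  if (is.null(survey)) survey <- generate_survey(cfg, districts)

  dist_w <- regional_weights(survey, "district")
  prov_w <- regional_weights(survey, "province")
  Cs_by_district <- stats::setNames(dist_w$weight * cfg$soil_reference,
                                    dist_w$region_id)
  Co_by_province <- stats::setNames(prov_w$weight * cfg$outdoor_reference,
                                    prov_w$region_id)
  base_lv <- province_ventilation(meteo, cfg$ft, cfg$fw, cfg$Ti)

  set.seed(cfg$seed + 404L)
  n <- cfg$n_residences
  stratum <- sample(1:4, n, replace = TRUE, prob = cfg$stratum_mix)
  d_idx <- sample.int(nrow(districts), n, replace = TRUE)
  district_id <- districts$district_id[d_idx]
  province_id <- districts$province_id[d_idx]

  ref <- cfg$coefficients
  res_type <- vapply(as.character(stratum),
                     function(s) ref$strata[[s]]$res_type, character(1))
  groundwater <- vapply(as.character(stratum),
                        function(s) ref$strata[[s]]$groundwater, character(1))
  material <- vapply(as.character(stratum), function(s)
    sample(ref$strata[[s]]$materials, 1L), character(1))
  cracks <- sample(cracks_levels(), n, replace = TRUE)
  floors <- sample(floors_levels(), n, replace = TRUE)
  vent_habit <- sample(names(cfg$habit_mix), n, replace = TRUE,
                       prob = cfg$habit_mix)
  season <- sample(season_levels(), n, replace = TRUE)

  lam_v <- unname(base_lv[province_id]) * unname(cfg$habit_weights[vent_habit])
  Cs <- unname(Cs_by_district[district_id])
  Co <- unname(Co_by_province[province_id])

  feat <- data.frame(stratum = stratum,
                     greenery = districts$greenery[d_idx],
                     district_gm = districts$radon_gm[d_idx],
                     material = material, cracks = cracks, floors = floors,
                     stringsAsFactors = FALSE)
  # linear predictor under the configured (uncalibrated) coefficients
  P <- rep(NA_real_, n)
  for (st in as.character(sort(unique(stratum)))) {
    rows <- which(stratum == as.integer(st))
    X <- design_matrix_for(feat[rows, , drop = FALSE], st, ref)
    P[rows] <- drop(X %*% ref$strata[[st]]$coefficients[colnames(X)])
  }
  eps <- stats::rnorm(n, 0, cfg$residual_sd)

  calib <- list()
  S_true <- rep(NA_real_, n)
  for (st in as.character(sort(unique(stratum)))) {
    rows <- which(stratum == as.integer(st))
    tgt <- cfg$stratum_targets[cfg$stratum_targets$stratum == as.integer(st), ]
    if (cfg$calibrate) {
      cal <- calibrate_affine(P[rows], eps[rows], lam_v[rows], Cs[rows],
                              Co[rows], cfg$lam, tgt$gm, tgt$gsd)
    } else {
      cal <- list(a = 0, c = 1, matched_gsd = NA)
    }
    beta <- ref$strata[[st]]$coefficients
    beta_cal <- cal$c * beta
    beta_cal["intercept"] <- cal$a + cal$c * beta["intercept"]
    calib[[st]] <- list(a = cal$a, c = cal$c,
                        matched_gsd = cal$matched_gsd,
                        coefficients = as.list(beta_cal))
    S_true[rows] <- cal$a + cal$c * P[rows] + eps[rows]
  }

  ci_annual <- (S_true + lam_v * Co - cfg$lam * Cs) / (cfg$lam + lam_v)
  n_neg <- 0L
  for (iter in seq_len(100L)) {
    neg <- which(ci_annual <= 0)
    if (!length(neg)) break
    if (cfg$residual_sd == 0)
      stop("negative annual concentrations with zero residual noise; ",
           "recalibrate or adjust references")
    n_neg <- n_neg + length(neg)
    eps[neg] <- stats::rnorm(length(neg), 0, cfg$residual_sd)
    for (st in as.character(unique(stratum[neg]))) {
      rows <- neg[stratum[neg] == as.integer(st)]
      S_true[rows] <- calib[[st]]$a +
        calib[[st]]$c * P[rows] + eps[rows]
    }
    ci_annual <- (S_true + lam_v * Co - cfg$lam * Cs) / (cfg$lam + lam_v)
  }
  if (any(ci_annual <= 0))
    stop("could not realize positive annual concentrations after resampling")
  if (n_neg > 0)
    warning("resampled residual noise for ", n_neg,
            " negative draw(s) of annual concentration")

  # plant gross contaminants on the annual log scale, placed at
  # +/- outlier_sd_mult stratum log-SDs from the stratum geometric mean
  planted <- rep(FALSE, n)
  ci_obs <- ci_annual
  n_out <- round(cfg$outlier_fraction * n)
  if (n_out > 0) {
    out_idx <- sample.int(n, n_out)
    planted[out_idx] <- TRUE
    sdlog <- log(cfg$stratum_targets$gsd)[stratum[out_idx]]
    gm_st <- cfg$stratum_targets$gm[stratum[out_idx]]
    sign <- sample(c(-1, 1), n_out, replace = TRUE)
    ci_obs[out_idx] <- gm_st * exp(sign * cfg$outlier_sd_mult * sdlog)
  }

  # de-annualize by the season's inverse factor, then split into two points
  c_season <- ci_obs / unname(cfg$seasonal_factors[season])
  sig <- log(cfg$measurement_gsd)
  pt1 <- c_season * exp(stats::rnorm(n, 0, sig))
  pt2 <- c_season * exp(stats::rnorm(n, 0, sig))

  residences <- data.frame(
    residence_id = sprintf("R%05d", seq_len(n)),
    district_id = district_id, province_id = province_id,
    res_type = res_type, groundwater = groundwater,
    material = material, cracks = cracks, floors = floors,
    vent_habit = vent_habit, season = season,
    radon_pt1 = pt1, radon_pt2 = pt2,
    stringsAsFactors = FALSE
  )
  truth_table <- data.frame(
    residence_id = residences$residence_id,
    stratum = stratum, S_true = S_true, lam_v = lam_v,
    ci_annual = ci_annual, Cs = Cs, Co = Co,
    planted_outlier = planted, stringsAsFactors = FALSE
  )
  list(residences = residences,
       survey = survey,
       truth = list(
         residences = truth_table,
         calibration = calib,
         seasonal_factors = as.list(cfg$seasonal_factors),
         habit_weights = as.list(cfg$habit_weights),
         ft = cfg$ft, fw = cfg$fw, Ti = cfg$Ti, lam = cfg$lam,
         soil_reference = cfg$soil_reference,
         outdoor_reference = cfg$outdoor_reference,
         n_negative_resampled = n_neg
       ))
}

#' Simulate design rows and responses for one stratum
#'
#' Design-level forward simulation used for coefficient-recovery studies:
#' draws greenery uniform on \code{x1_range}, the district indoor-radon GM
#' log-normal with the national winter-survey parameters, and the
#' categorical traits uniform over the stratum's admitted levels, then
#' computes the infiltration-factor response from the stratum's linear
#' predictor plus Gaussian noise. Uses the caller's RNG state.
#'
#' @param n number of rows.
#' @param stratum stratum 1..4.
#' @param ref coefficient set supplying the generating truth.
#' @param residual_sd response noise SD (Bq m-3 h-1); default 2.
#' @param x1_range greenery bounds; default c(0, 100).
#' @param x2_gm,x2_gsd log-normal parameters of the district GM; defaults
#'   86.52 and 2.14 (the national winter-survey summary).
#' @return data.frame with \code{stratum, greenery, district_gm, material,
#'   cracks, floors, S}, ready for [fit_infiltration()].
#' @export
simulate_stratum_design <- function(n, stratum,
                                    ref = reference_coefficients(),
                                    residual_sd = 2,
                                    x1_range = c(0, 100),
                                    x2_gm = 86.52, x2_gsd = 2.14) {
  meta <- ref$strata[[as.character(stratum)]]
  df <- data.frame(
    stratum = as.integer(stratum),
    greenery = stats::runif(n, x1_range[1], x1_range[2]),
    district_gm = stats::rlnorm(n, log(x2_gm), log(x2_gsd)),
    material = sample(meta$materials, n, replace = TRUE),
    cracks = sample(cracks_levels(), n, replace = TRUE),
    floors = sample(floors_levels(), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  X <- design_matrix_for(df, stratum, ref)
  df$S <- drop(X %*% meta$coefficients[colnames(X)]) +
    stats::rnorm(n, 0, residual_sd)
  df
}

#' Write a complete synthetic data set to a directory
#'
#' Generates districts, meteorology, the winter survey and the residence
#' measurements under the configured seed and writes
#' \code{districts.csv}, \code{meteo.csv}, \code{survey.csv},
#' \code{residences.csv} and \code{truth.json}, all consumed unchanged by
#' [run_pipeline()]. Byte-identical on re-run with the same configuration.
#'
#' @param cfg a [generator_config()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the list of written file paths.
#' @export
simulate_to_dir <- function(cfg, dir) {
  stopifnot(inherits(cfg, "generator_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  districts <- generate_districts(cfg)
  meteo <- generate_meteorology(cfg)
  survey <- generate_survey(cfg, districts)
  sim <- generate_residences(cfg, districts, meteo, survey)
  paths <- c(
    districts = file.path(dir, "districts.csv"),
    meteo = file.path(dir, "meteo.csv"),
    survey = file.path(dir, "survey.csv"),
    residences = file.path(dir, "residences.csv"),
    truth = file.path(dir, "truth.json")
  )
  utils::write.csv(districts, paths["districts"], row.names = FALSE)
  utils::write.csv(meteo, paths["meteo"], row.names = FALSE)
  utils::write.csv(survey, paths["survey"], row.names = FALSE)
  utils::write.csv(sim$residences, paths["residences"], row.names = FALSE)
  jsonlite::write_json(sim$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "columns")
  invisible(paths)
}
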
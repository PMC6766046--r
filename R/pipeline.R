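#' Configuration of an end-to-end pipeline run
#'
#' Paths to the four input tables plus every tunable of the estimation
#' chain: ventilation parameters, habit weights, seasonal factors, the
#' outlier threshold, regional reference levels and the decay constant.
#'
#' @param residences,districts,meteo,survey paths to the input CSVs
#'   (columns as written by [simulate_to_dir()]).
#' @param ft,fw,Ti ventilation-model parameters; defaults 0.03 h-1 degC-1,
#'   0.01 h-1 s2 m-2 and an indoor temperature of 20 degC.
#' @param habit_weights named multipliers for N by ventilation habit.
#' @param seasonal_factors named season multipliers for annualization.
#' @param z_max log-scale outlier threshold (default 3).
#' @param outlier_scope \code{"stratum"} or \code{"pooled"} screening.
#' @param soil_reference,outdoor_reference reference levels (Bq m-3) for
#'   the district soil proxy and province outdoor proxy.
#' @param lam radon decay constant (h-1).
#' @param out output directory (optional; no files written when NULL).
#' @param ref coefficient metadata ([reference_coefficients()]) defining
#'   predictor sets and reference levels.
#' @return A list of class \code{run_config}.
#' @export
run_config <- function(residences, districts, meteo, survey,
                       ft = 0.03, fw = 0.01, Ti = 20,
                       habit_weights = default_habit_weights(),
                       seasonal_factors = default_seasonal_factors(),
                       z_max = 3,
                       outlier_scope = c("stratum", "pooled"),
                       soil_reference = 86.52,
                       outdoor_reference = 10,
                       lam = radon_decay_constant,
                       out = NULL,
                       ref = reference_coefficients()) {
  outlier_scope <- match.arg(outlier_scope)
  paths <- c(residences = residences, districts = districts,
             meteo = meteo, survey = survey)
  missing_files <- paths[!file.exists(paths)]
  if (length(missing_files))
    stop("input file(s) not found: ", paste(missing_files, collapse = ", "))
  check_pos(lam, "lam")
  cfg <- list(paths = as.list(paths), ft = ft, fw = fw, Ti = Ti,
              habit_weights = unlist(habit_weights),
              seasonal_factors = unlist(seasonal_factors),
              z_max = z_max, outlier_scope = outlier_scope,
              soil_reference = soil_reference,
              outdoor_reference = outdoor_reference,
              lam = lam, out = out, ref = ref)
  class(cfg) <- "run_config"
  cfg
}

#' Agreement between measured and estimated values
#'
#' Per-stratum agreement summary used to judge the estimation chain: root
#' mean squared error, mean bias (estimated minus measured) and the
#' least-squares concordance line (intercept and slope of estimated on
#' measured), plus a pooled row.
#'
#' @param measured,estimated equal-length paired numeric vectors.
#' @param strata stratum label per pair (1..4).
#' @return data.frame of class \code{agreement_report} with columns
#'   \code{stratum, n, rmse, bias, slope, intercept}; the last row pools
#'   all pairs (\code{stratum = "all"}).
#' @export
evaluate_agreement <- function(measured, estimated, strata) {
  if (length(measured) != length(estimated) ||
      length(measured) != length(strata))
    stop("measured, estimated and strata must have equal length")
  check_num(measured, "measured"); check_num(estimated, "estimated")
  one <- function(m, e) {
    d <- e - m
    cl <- if (length(m) >= 2 && stats::sd(m) > 0)
      stats::coef(stats::lm(e ~ m)) else c(NA_real_, NA_real_)
    data.frame(n = length(m), rmse = sqrt(mean(d^2)), bias = mean(d),
               slope = unname(cl[2]), intercept = unname(cl[1]))
  }
  groups <- split(seq_along(measured), strata)
  rows <- do.call(rbind, lapply(names(groups), function(g) {
    idx <- groups[[g]]
    cbind(stratum = g, one(measured[idx], estimated[idx]))
  }))
  rows <- rbind(rows, cbind(stratum = "all", one(measured, estimated)))
  class(rows) <- c("agreement_report", "data.frame")
  rows
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Agreement of estimated vs measured values\n")
  df <- as.data.frame(x)
  df[-1] <- lapply(df[-1], function(v) signif(v, 4))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Run the full estimation pipeline
#'
#' Executes the fixed stage order: preprocess raw residence measurements to
#' annual means (two-point GM, seasonal correction, log-scale outlier
#' screen, stratification); derive district soil and province outdoor
#' proxies from the winter survey GM-ratio weights; compute per-residence
#' annual ventilation rates from province meteorology and habit-weighted N;
#' invert the steady state for each residence's infiltration factor;
#' fit the per-stratum regression; predict the infiltration factor and the
#' indoor concentration; and evaluate agreement. Per-stage record counts
#' are logged to stderr. When an output directory is configured,
#' \code{models.json}, \code{predictions.csv} and \code{report.json} are
#' written; on stage failure partial outputs are removed and the error
#' names the stage.
#'
#' @param cfg a [run_config()].
#' @return A list: \code{model} (the fitted \code{infiltration_model}),
#'   \code{predictions} (data.frame over kept residences: measured annual
#'   concentration, calculated and estimated S, estimated Ci, proxies and
#'   ventilation rate), \code{agreement_ci} and \code{agreement_s}
#'   (\code{agreement_report}s), and \code{counts}.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  outputs <- character(0)
  stage <- "load"
  result <- tryCatch({
    residences <- utils::read.csv(cfg$paths$residences,
                                  stringsAsFactors = FALSE)
    districts <- utils::read.csv(cfg$paths$districts,
                                 stringsAsFactors = FALSE)
    meteo <- utils::read.csv(cfg$paths$meteo, stringsAsFactors = FALSE)
    survey <- utils::read.csv(cfg$paths$survey, stringsAsFactors = FALSE)
    message(sprintf("[load] %d residences, %d districts, %d survey records",
                    nrow(residences), nrow(districts), nrow(survey)))

    stage <- "preprocess"
    ann <- preprocess_residences(residences, cfg$seasonal_factors,
                                 z_max = cfg$z_max,
                                 scope = cfg$outlier_scope)
    kept <- ann[!ann$outlier_flag, , drop = FALSE]
    message(sprintf("[preprocess] kept %d of %d (removed %d outliers)",
                    nrow(kept), nrow(ann), sum(ann$outlier_flag)))

    stage <- "regional"
    dist_tab <- scale_reference(regional_weights(survey, "district"),
                                cfg$soil_reference)
    prov_tab <- scale_reference(regional_weights(survey, "province"),
                                cfg$outdoor_reference)
    Cs_map <- stats::setNames(dist_tab$estimate, dist_tab$region_id)
    Co_map <- stats::setNames(prov_tab$estimate, prov_tab$region_id)
    message(sprintf("[regional] %d district and %d province proxies",
                    nrow(dist_tab), nrow(prov_tab)))

    stage <- "ventilation"
    base_lv <- province_ventilation(meteo, cfg$ft, cfg$fw, cfg$Ti)
    bad_prov <- setdiff(unique(kept$province_id), names(base_lv))
    if (length(bad_prov))
      stop("no meteorology for province(s): ",
           paste(bad_prov, collapse = ", "))
    lam_v <- unname(base_lv[kept$province_id]) *
      unname(cfg$habit_weights[kept$vent_habit])
    if (any(is.na(lam_v)))
      stop("unknown ventilation habit label(s): ",
           paste(setdiff(unique(kept$vent_habit),
                         names(cfg$habit_weights)), collapse = ", "))
    message(sprintf("[ventilation] lam_v range %.3f-%.3f h-1",
                    min(lam_v), max(lam_v)))

    stage <- "invert"
    bad_d <- setdiff(unique(kept$district_id), names(Cs_map))
    if (length(bad_d))
      stop("no survey proxy for district(s): ",
           paste(bad_d, collapse = ", "))
    Cs <- unname(Cs_map[kept$district_id])
    Co <- unname(Co_map[kept$province_id])
    S_calc <- infiltration_from_measurement(kept$c_annual, Cs = Cs,
                                            Cbm = 0, Co = Co,
                                            lam = cfg$lam, lam_v = lam_v)
    message(sprintf("[invert] S range %.2f-%.2f Bq m-3 h-1",
                    min(S_calc), max(S_calc)))

    stage <- "fit"
    d_idx <- match(kept$district_id, districts$district_id)
    records <- data.frame(stratum = kept$stratum,
                          greenery = districts$greenery[d_idx],
                          district_gm = districts$radon_gm[d_idx],
                          material = kept$material,
                          cracks = kept$cracks, floors = kept$floors,
                          S = S_calc, stringsAsFactors = FALSE)
    model <- fit_infiltration(records, cfg$ref)
    message(sprintf("[fit] %d strata fitted", length(model$strata)))

    stage <- "predict"
    S_hat <- predict_s(model, records, cfg$ref)
    ci_hat <- steady_state_ci(S = S_hat, Cs = Cs, Cbm = 0, Co = Co,
                              lam = cfg$lam, lam_v = lam_v)
    predictions <- data.frame(
      residence_id = kept$residence_id, stratum = kept$stratum,
      c_annual = kept$c_annual, S_calc = S_calc, S_hat = S_hat,
      ci_hat = ci_hat, Cs = Cs, Co = Co, lam_v = lam_v,
      stringsAsFactors = FALSE
    )

    stage <- "evaluate"
    agreement_ci <- evaluate_agreement(kept$c_annual, ci_hat, kept$stratum)
    agreement_s <- evaluate_agreement(S_calc, S_hat, kept$stratum)
    counts <- list(n_input = nrow(ann), n_outliers = sum(ann$outlier_flag),
                   n_kept = nrow(kept))

    stage <- "write"
    if (!is.null(cfg$out)) {
      dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
      outputs <- c(file.path(cfg$out, "models.json"),
                   file.path(cfg$out, "predictions.csv"),
                   file.path(cfg$out, "report.json"))
      write_infiltration_model(model, outputs[1])
      utils::write.csv(predictions, outputs[2], row.names = FALSE)
      jsonlite::write_json(
        list(counts = counts,
             agreement_ci = as.data.frame(agreement_ci),
             agreement_s = as.data.frame(agreement_s)),
        outputs[3], auto_unbox = TRUE, digits = NA, pretty = TRUE,
        dataframe = "rows")
      message(sprintf("[write] outputs in %s", cfg$out))
    }
    list(model = model, predictions = predictions,
         agreement_ci = agreement_ci, agreement_s = agreement_s,
         counts = counts)
  }, error = function(e) {
    existing <- outputs[file.exists(outputs)]
    if (length(existing)) unlink(existing)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  result
}
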
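#' Geometric mean of the two in-residence measurement points
#'
#' Indoor radon is measured at two points per residence (typically living
#' room and bedroom); the per-residence concentration is their geometric
#' mean, the natural location summary for log-normal concentrations.
#'
#' @param pt1,pt2 measured radon at the two points (Bq m-3), > 0. Vectorized.
#' @return sqrt(pt1 * pt2), Bq m-3.
#' @examples
#' two_point_gm(4, 9)  # 6
#' @export
two_point_gm <- function(pt1, pt2) {
  check_pos(pt1, "pt1"); check_pos(pt2, "pt2")
  sqrt(pt1 * pt2)
}

#' Seasonal correction to annual-mean concentration
#'
#' Indoor radon is higher in winter and lower in summer; a measurement made
#' in one season is converted to an annual-mean-equivalent concentration by
#' a season-specific multiplicative correction factor.
#'
#' @param c_meas measured concentration(s), Bq m-3.
#' @param season measurement-season label(s), must be names of
#'   \code{factors}.
#' @param factors named numeric vector (or list) mapping season labels to
#'   strictly positive multipliers; see [default_seasonal_factors()].
#' @return Annualized concentration(s): \code{c_meas * factors[season]}.
#' @export
seasonal_correction <- function(c_meas, season, factors) {
  check_pos(c_meas, "c_meas")
  factors <- unlist(factors)
  check_pos(factors, "seasonal factors")
  season <- as.character(season)
  unknown <- setdiff(unique(season), names(factors))
  if (length(unknown))
    stop("unknown season label(s) ", paste(sQuote(unknown), collapse = ", "),
         "; known: ", paste(sQuote(names(factors)), collapse = ", "))
  c_meas * unname(factors[season])
}

#' Default seasonal correction factors
#'
#' Identity factors (all 1) for the four seasons: annualization is a no-op
#' unless study-specific factors are supplied. The synthetic-data generator
#' records the factors it used so round trips are exact.
#'
#' @return Named numeric vector over winter/spring/summer/autumn.
#' @export
default_seasonal_factors <- function() {
  stats::setNames(rep(1, 4), season_levels())
}

#' Default habit weights for the ventilation multiplier N
#'
#' Ordinal ventilation-habit categories and their multiplier on the
#' air-exchange model's N: residents who ventilate rarely get N below 1,
#' frequent ventilators above 1.
#'
#' @return Named numeric vector \code{c(low = 0.8, medium = 1, high = 1.2)}.
#' @export
default_habit_weights <- function() {
  c(low = 0.8, medium = 1.0, high = 1.2)
}

#' Screen outliers on the log scale
#'
#' Single-pass z-score screen: values whose absolute deviation from the mean
#' exceeds \code{z_max} standard deviations are flagged as outliers. Applied
#' to log concentrations, this removes gross contaminants (transcription
#' errors, device faults) while keeping the bulk of a log-normal sample.
#' With zero variance nothing is removed.
#'
#' @param values numeric vector (log concentrations), length >= 3.
#' @param z_max positive threshold; default 3.
#' @return A list: \code{keep} (logical), \code{kept} and \code{removed}
#'   (the partitioned values), \code{z} (the scores).
#' @examples
#' screen_outliers(c(rep(0, 9), 100))$removed  # z = 2.85 < 3: nothing removed
#' @export
screen_outliers <- function(values, z_max = 3) {
  check_num(values, "values")
  if (length(values) < 3L) stop("need at least 3 values to screen")
  check_pos(z_max, "z_max")
  s <- stats::sd(values)
  z <- if (s == 0) rep(0, length(values)) else
    abs(values - mean(values)) / s
  keep <- z <= z_max
  list(keep = keep, kept = values[keep], removed = values[!keep], z = z)
}

#' Assign the model stratum of a residence
#'
#' The model is stratified by residence type crossed with groundwater usage:
#' Type 1 = detached house with groundwater, Type 2 = detached without,
#' Type 3 = other residence with groundwater, Type 4 = other without.
#'
#' @param res_type \code{"detached"} or \code{"other"}. Vectorized.
#' @param groundwater \code{"yes"} or \code{"no"}. Vectorized.
#' @return Integer vector of strata 1..4.
#' @examples
#' assign_stratum("detached", "yes")  # 1
#' assign_stratum("other", "yes")     # 3
#' @export
assign_stratum <- function(res_type, groundwater) {
  res_type <- as.character(res_type)
  groundwater <- as.character(groundwater)
  if (any(is.na(res_type)) || any(is.na(groundwater)))
    stop("res_type and groundwater must be non-missing")
  if (!all(res_type %in% c("detached", "other")))
    stop("res_type must be 'detached' or 'other'")
  if (!all(groundwater %in% c("yes", "no")))
    stop("groundwater must be 'yes' or 'no'")
  1L + 2L * (res_type == "other") + (groundwater == "no")
}

#' Preprocess raw residence records to analysis-ready annual concentrations
#'
#' Fixed pipeline order: per-residence geometric mean of the two measurement
#' points, seasonal correction to an annual mean, natural-log transform,
#' single-pass outlier screen on the log scale (within stratum by default),
#' and stratum assignment. Outliers are flagged, not dropped, so callers
#' control exclusion.
#'
#' @param residences data.frame with columns \code{residence_id},
#'   \code{district_id}, \code{province_id}, \code{res_type},
#'   \code{groundwater}, \code{material}, \code{cracks}, \code{floors},
#'   \code{vent_habit}, \code{radon_pt1}, \code{radon_pt2}, \code{season}.
#' @param seasonal_factors named multipliers; default
#'   [default_seasonal_factors()].
#' @param z_max log-scale outlier threshold; default 3.
#' @param scope screen outliers \code{"stratum"}-wise (default) or
#'   \code{"pooled"} across all records.
#' @return The input with added columns \code{stratum} (1..4),
#'   \code{c_annual} (Bq m-3), \code{log_c} and \code{outlier_flag}
#'   (logical).
#' @export
preprocess_residences <- function(residences,
                                  seasonal_factors = default_seasonal_factors(),
                                  z_max = 3,
                                  scope = c("stratum", "pooled")) {
  scope <- match.arg(scope)
  stopifnot(is.data.frame(residences))
  needed <- c("residence_id", "res_type", "groundwater",
              "radon_pt1", "radon_pt2", "season")
  missing_cols <- setdiff(needed, names(residences))
  if (length(missing_cols))
    stop("residences is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  out <- residences
  out$stratum <- assign_stratum(out$res_type, out$groundwater)
  gm <- two_point_gm(out$radon_pt1, out$radon_pt2)
  out$c_annual <- seasonal_correction(gm, out$season, seasonal_factors)
  out$log_c <- log(out$c_annual)
  out$outlier_flag <- FALSE
  groups <- if (scope == "stratum") split(seq_len(nrow(out)), out$stratum)
            else list(seq_len(nrow(out)))
  for (idx in groups) {
    if (length(idx) >= 3L) {
      scr <- screen_outliers(out$log_c[idx], z_max = z_max)
      out$outlier_flag[idx] <- !scr$keep
    }
  }
  out
}
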
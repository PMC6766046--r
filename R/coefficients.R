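#' Packaged reference coefficients for the four residence strata
#'
#' The package ships a reference set of per-stratum infiltration-factor
#' regression coefficients, their standard errors, the stratum-specific
#' predictor sets, and the annual indoor-radon summary statistics
#' (geometric mean and geometric standard deviation, Bq m-3) for the four
#' residence strata (detached vs other residences, crossed with groundwater
#' usage), together with the national winter-survey summary used for the
#' regional weighting scheme. These values drive the synthetic-data
#' generator defaults and serve as anchors for parameter-recovery checks.
#'
#' @param path path to a coefficient JSON file; defaults to the packaged set.
#' @return A list with elements \code{reference_levels}, \code{survey} and
#'   \code{strata}; \code{strata} is a list keyed \code{"1"}..\code{"4"},
#'   each holding \code{label}, \code{res_type}, \code{groundwater},
#'   \code{gm}, \code{gsd}, \code{predictors}, \code{materials},
#'   \code{coefficients} and \code{se} (named numeric vectors).
#' @examples
#' ref <- reference_coefficients()
#' ref$strata[["1"]]$coefficients["district_gm"]
#' @export
reference_coefficients <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "infiltration_coefficients.json",
                        package = "radonmbe", mustWork = TRUE)
  ref <- jsonlite::read_json(path, simplifyVector = TRUE)
  ref$strata <- lapply(ref$strata, function(s) {
    s$coefficients <- unlist(s$coefficients)
    s$se <- unlist(s$se)
    s
  })
  ref
}

#' Stratum metadata: predictor sets and allowed material levels
#'
#' The four model strata do not share one predictor set: the
#' other-residence/groundwater stratum (Type 3) excludes the crack and floor
#' terms and admits only concrete, red brick and cement block materials,
#' and the other-residence/no-groundwater stratum (Type 4) has no soil or
#' wood material level. This accessor exposes that metadata so design
#' construction treats predictor sets as data, not code branches.
#'
#' @param stratum integer 1..4.
#' @param ref a coefficient set from [reference_coefficients()].
#' @return A list with \code{predictors} (character), \code{materials}
#'   (character, first element is the reference level) and \code{label}.
#' @export
stratum_predictors <- function(stratum, ref = reference_coefficients()) {
  stopifnot(length(stratum) == 1L, stratum %in% 1:4)
  s <- ref$strata[[as.character(stratum)]]
  list(predictors = s$predictors, materials = s$materials, label = s$label)
}

# canonical category levels used across the package
material_levels <- function() {
  c("concrete", "red_brick", "cement_block", "soil", "wood", "other")
}
cracks_levels <- function() c("0-1", "2+")
floors_levels <- function() c("1", "2+")
season_levels <- function() c("winter", "spring", "summer", "autumn")
habit_levels <- function() c("low", "medium", "high")
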
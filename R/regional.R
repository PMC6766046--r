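#' Regional geometric-mean ratio weights from winter survey records
#'
#' Soil and outdoor radon are rarely measured directly at national scale.
#' The package derives regional proxies from winter indoor-radon survey
#' records (winter measurements minimise the ventilation signal): each
#' region's weight is the ratio of its geometric mean to the geometric mean
#' of all records. District-level weights stand in for soil radon variation;
#' the same computation at province level stands in for outdoor radon.
#'
#' @param records data.frame with columns \code{district_id},
#'   \code{province_id} (when \code{level = "province"}) and \code{radon}
#'   (Bq m-3, strictly positive).
#' @param level aggregate by \code{"district"} or \code{"province"}.
#' @param z_max optional log-scale outlier threshold applied to the pooled
#'   log records before computing means (same |z| rule as
#'   [screen_outliers()]); \code{NULL} (default) skips screening.
#' @return A data.frame of class \code{regional_table} with one row per
#'   region: \code{region_id}, \code{n}, \code{gm} (Bq m-3) and
#'   \code{weight} = regional GM / total GM. The record-count-weighted mean
#'   of \code{log(weight)} is exactly 0 (the total GM is conserved).
#' @examples
#' recs <- data.frame(district_id = c("A", "A", "B", "B"),
#'                    province_id = "P1",
#'                    radon = c(100, 100, 25, 25))
#' regional_weights(recs)  # weights 2.0 and 0.5
#' @export
regional_weights <- function(records, level = c("district", "province"),
                             z_max = NULL) {
  level <- match.arg(level)
  stopifnot(is.data.frame(records))
  id_col <- paste0(level, "_id")
  if (!all(c(id_col, "radon") %in% names(records)))
    stop("records must have columns '", id_col, "' and 'radon'")
  if (nrow(records) == 0L) stop("no survey records")
  check_pos(records$radon, "radon")
  if (!is.null(z_max)) {
    keep <- screen_outliers(log(records$radon), z_max = z_max)$keep
    records <- records[keep, , drop = FALSE]
  }
  lr <- log(records$radon)
  total_log_gm <- mean(lr)
  by_region <- split(lr, as.character(records[[id_col]]))
  tab <- data.frame(
    region_id = names(by_region),
    n = vapply(by_region, length, integer(1)),
    gm = vapply(by_region, function(v) exp(mean(v)), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  tab$weight <- exp(log(tab$gm) - total_log_gm)
  attr(tab, "total_gm") <- exp(total_log_gm)
  attr(tab, "level") <- level
  class(tab) <- c("regional_table", "data.frame")
  tab
}

#' Scale regional weights to concentration estimates
#'
#' Maps ratio weights to concentration proxies by a common reference level:
#' \code{estimate = weight * reference}. Since the weights are relative, the
#' choice of reference shifts every downstream infiltration factor by a
#' stratum-constant amount that the regression intercept absorbs.
#'
#' @param table a \code{regional_table} from [regional_weights()].
#' @param reference reference concentration (Bq m-3), > 0.
#' @return The table with an added/updated \code{estimate} column (Bq m-3).
#' @export
scale_reference <- function(table, reference) {
  stopifnot(inherits(table, "regional_table") ||
              (is.data.frame(table) && "weight" %in% names(table)))
  check_pos(reference, "reference")
  stopifnot(length(reference) == 1L)
  table$estimate <- table$weight * reference
  table
}

#' @export
print.regional_table <- function(x, ...) {
  cat(sprintf("Regional GM-ratio table (%s level): %d regions, total GM %.2f Bq m-3\n",
              attr(x, "level"), nrow(x), attr(x, "total_gm")))
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("  ...", nrow(x) - 10L, "more regions\n")
  invisible(x)
}
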
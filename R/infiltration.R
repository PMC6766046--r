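# canonical coefficient names for one stratum, in design-column order
coef_names_for <- function(stratum, ref = reference_coefficients()) {
  meta <- ref$strata[[as.character(stratum)]]
  nm <- "intercept"
  if ("greenery" %in% meta$predictors) nm <- c(nm, "greenery")
  if ("district_gm" %in% meta$predictors) nm <- c(nm, "district_gm")
  if ("material" %in% meta$predictors)
    nm <- c(nm, paste0("material_", setdiff(meta$materials, meta$materials[1])))
  if ("cracks" %in% meta$predictors) nm <- c(nm, "cracks_2plus")
  if ("floors" %in% meta$predictors) nm <- c(nm, "floors_2plus")
  nm
}

# dummy-coded numeric design matrix for one stratum; errors on category
# levels outside the stratum's allowed set
design_matrix_for <- function(df, stratum, ref = reference_coefficients()) {
  meta <- ref$strata[[as.character(stratum)]]
  n <- nrow(df)
  cols <- list(intercept = rep(1, n))
  if ("greenery" %in% meta$predictors) {
    check_num(df$greenery, "greenery")
    if (any(df$greenery < 0 | df$greenery > 100))
      stop("greenery ratio must be within [0, 100] percent")
    cols$greenery <- df$greenery
  }
  if ("district_gm" %in% meta$predictors) {
    check_pos(df$district_gm, "district_gm")
    cols$district_gm <- df$district_gm
  }
  if ("material" %in% meta$predictors) {
    mat <- as.character(df$material)
    bad <- setdiff(unique(mat), meta$materials)
    if (length(bad))
      stop("material level(s) ", paste(sQuote(bad), collapse = ", "),
           " not admitted in stratum ", stratum, " (allowed: ",
           paste(meta$materials, collapse = ", "), ")")
    for (lvl in setdiff(meta$materials, meta$materials[1]))
      cols[[paste0("material_", lvl)]] <- as.numeric(mat == lvl)
  }
  if ("cracks" %in% meta$predictors) {
    cr <- as.character(df$cracks)
    bad <- setdiff(unique(cr), cracks_levels())
    if (length(bad))
      stop("cracks level(s) ", paste(sQuote(bad), collapse = ", "),
           " unknown (allowed: ", paste(cracks_levels(), collapse = ", "), ")")
    cols$cracks_2plus <- as.numeric(cr == "2+")
  }
  if ("floors" %in% meta$predictors) {
    fl <- as.character(df$floors)
    bad <- setdiff(unique(fl), floors_levels())
    if (length(bad))
      stop("floors level(s) ", paste(sQuote(bad), collapse = ", "),
           " unknown (allowed: ", paste(floors_levels(), collapse = ", "), ")")
    cols$floors_2plus <- as.numeric(fl == "2+")
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  X
}

#' Build per-stratum design matrices for the infiltration-factor regression
#'
#' Splits annualized residence records (joined to their district covariates)
#' by stratum and dummy-codes the categorical predictors against the
#' reference levels concrete material, 0-1 crack locations, and at most one
#' floor. Each stratum uses only its own predictor set: the
#' other-residence/groundwater stratum carries no crack or floor terms and
#' admits only three material levels.
#'
#' @param records data.frame with columns \code{stratum} (1..4),
#'   \code{greenery} (district greenery ratio, percent), \code{district_gm}
#'   (district indoor-radon GM, Bq m-3), \code{material}, \code{cracks},
#'   \code{floors}, and optionally the response \code{S} (Bq m-3 h-1).
#' @param ref coefficient/metadata set from [reference_coefficients()].
#' @return A named list over the strata present; each element holds
#'   \code{X} (numeric design matrix with canonical column names),
#'   \code{S} (response vector or NULL), \code{rows} (row indices into
#'   \code{records}).
#' @export
build_design <- function(records, ref = reference_coefficients()) {
  stopifnot(is.data.frame(records), "stratum" %in% names(records))
  if (!all(records$stratum %in% 1:4)) stop("stratum must be 1..4")
  out <- list()
  for (st in sort(unique(records$stratum))) {
    rows <- which(records$stratum == st)
    df <- records[rows, , drop = FALSE]
    out[[as.character(st)]] <- list(
      X = design_matrix_for(df, st, ref),
      S = if ("S" %in% names(df)) df$S else NULL,
      rows = rows
    )
  }
  out
}

#' Fit the per-stratum infiltration-factor regression
#'
#' Ordinary least squares of the infiltration factor S on district greenery
#' ratio, district indoor-radon geometric mean, and the building traits in
#' each stratum's predictor set, with coefficient standard errors and
#' two-sided p-values from the t distribution on the residual degrees of
#' freedom.
#'
#' @param design per-stratum designs from [build_design()] (the response
#'   \code{S} must be present), or a data.frame acceptable to
#'   \code{build_design}.
#' @param ref metadata set from [reference_coefficients()].
#' @return An object of class \code{infiltration_model}: a list with
#'   \code{strata}, each stratum holding named vectors \code{coefficients},
#'   \code{se}, \code{p}, plus \code{sigma} (residual SD, Bq m-3 h-1),
#'   \code{df_residual}, \code{n}, \code{r_squared}, \code{predictors} and
#'   \code{materials}.
#' @export
fit_infiltration <- function(design, ref = reference_coefficients()) {
  if (is.data.frame(design)) design <- build_design(design, ref)
  strata <- list()
  for (st in names(design)) {
    d <- design[[st]]
    if (is.null(d$S)) stop("stratum ", st, " design has no response S")
    X <- d$X
    if (nrow(X) <= ncol(X))
      stop("stratum ", st, ": ", nrow(X), " rows cannot identify ",
           ncol(X), " coefficients")
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
      stop("stratum ", st, ": design is rank deficient; collinear column(s): ",
           paste(dropped, collapse = ", "))
    }
    fit <- stats::lm.fit(X, d$S)
    res <- fit$residuals
    dfres <- nrow(X) - ncol(X)
    sigma2 <- sum(res^2) / dfres
    XtX_inv <- chol2inv(qr.R(qrX))
    se <- sqrt(diag(XtX_inv) * sigma2)
    names(se) <- colnames(X)
    beta <- fit$coefficients[colnames(X)]
    tval <- beta / se
    pval <- 2 * stats::pt(abs(tval), dfres, lower.tail = FALSE)
    ss_tot <- sum((d$S - mean(d$S))^2)
    meta <- ref$strata[[st]]
    strata[[st]] <- list(
      coefficients = beta, se = se, p = pval,
      sigma = sqrt(sigma2), df_residual = dfres, n = nrow(X),
      r_squared = if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_,
      predictors = meta$predictors, materials = meta$materials
    )
  }
  structure(list(strata = strata,
                 reference_levels = ref$reference_levels),
            class = "infiltration_model")
}

#' @export
print.infiltration_model <- function(x, ...) {
  cat("Per-stratum infiltration-factor model (S in Bq m-3 h-1)\n")
  for (st in names(x$strata)) {
    s <- x$strata[[st]]
    cat(sprintf("Stratum %s: n = %d, residual SD = %.2f, R^2 = %.3f\n",
                st, s$n, s$sigma, s$r_squared))
    tab <- data.frame(beta = round(s$coefficients, 3),
                      se = round(s$se, 3),
                      p = signif(s$p, 3))
    print(tab)
  }
  invisible(x)
}

#' Construct an infiltration model directly from a coefficient set
#'
#' Wraps a known coefficient table (for instance the packaged reference
#' set) as an \code{infiltration_model} usable with [predict_s()], without
#' fitting. Standard errors and p-values are carried through if present.
#'
#' @param ref a set from [reference_coefficients()].
#' @param residual_sd residual SD to record per stratum (default 0).
#' @return An \code{infiltration_model}.
#' @export
as_infiltration_model <- function(ref = reference_coefficients(),
                                  residual_sd = 0) {
  strata <- lapply(ref$strata, function(s) {
    list(coefficients = s$coefficients, se = s$se,
         p = rep(NA_real_, length(s$coefficients)),
         sigma = residual_sd, df_residual = NA_integer_, n = NA_integer_,
         r_squared = NA_real_,
         predictors = s$predictors, materials = s$materials)
  })
  structure(list(strata = strata,
                 reference_levels = ref$reference_levels),
            class = "infiltration_model")
}

#' Predict the infiltration factor for residences
#'
#' Evaluates each stratum's linear predictor at the supplied design rows.
#' Prediction is a plain coefficient dot product, so models restored from
#' JSON predict identically to freshly fitted ones.
#'
#' @param model an \code{infiltration_model}.
#' @param newdata data.frame with \code{stratum} and the stratum's
#'   predictor columns (\code{greenery}, \code{district_gm},
#'   \code{material}, \code{cracks}, \code{floors}).
#' @param ref metadata set matching the model's predictor encoding.
#' @return Numeric vector of predicted S (Bq m-3 h-1), aligned to
#'   \code{newdata} rows.
#' @export
predict_s <- function(model, newdata, ref = reference_coefficients()) {
  stopifnot(inherits(model, "infiltration_model"), is.data.frame(newdata))
  out <- rep(NA_real_, nrow(newdata))
  design <- build_design(newdata, ref)
  for (st in names(design)) {
    s <- model$strata[[st]]
    if (is.null(s))
      stop("model has no stratum ", st, " fit")
    X <- design[[st]]$X
    miss <- setdiff(colnames(X), names(s$coefficients))
    if (length(miss))
      stop("model stratum ", st, " lacks coefficient(s): ",
           paste(miss, collapse = ", "))
    out[design[[st]]$rows] <- drop(X %*% s$coefficients[colnames(X)])
  }
  out
}

#' Predict indoor radon concentrations from the infiltration model
#'
#' Composes the fitted infiltration factor with the steady-state solution:
#' the predicted entry rate feeds the closed-form indoor concentration with
#' the regional soil proxy Cs, outdoor proxy Co and the residence's
#' ventilation rate. The building-material compartment is folded into Cs
#' (entry from building materials is small relative to soil).
#'
#' @inheritParams predict_s
#' @param Cs regional soil-radon proxy per row (Bq m-3).
#' @param Co regional outdoor-radon proxy per row (Bq m-3).
#' @param lam radon decay constant (h-1).
#' @param lam_v per-row ventilation rate (h-1).
#' @return Predicted indoor radon concentrations (Bq m-3).
#' @export
predict_ci <- function(model, newdata, Cs, Co,
                       lam = radon_decay_constant, lam_v,
                       ref = reference_coefficients()) {
  S <- predict_s(model, newdata, ref)
  steady_state_ci(S = S, Cs = Cs, Cbm = 0, Co = Co, lam = lam, lam_v = lam_v)
}

#' Serialize / restore a fitted infiltration model as flat JSON
#'
#' One JSON object per stratum with coefficients, standard errors,
#' p-values, residual SD and predictor metadata, so fitted models are
#' portable across sessions and tools.
#'
#' @param model an \code{infiltration_model}.
#' @param path file path for the JSON.
#' @return \code{write_infiltration_model} returns \code{path} invisibly;
#'   \code{read_infiltration_model} returns the restored
#'   \code{infiltration_model}.
#' @export
write_infiltration_model <- function(model, path) {
  stopifnot(inherits(model, "infiltration_model"))
  payload <- list(
    reference_levels = model$reference_levels,
    strata = lapply(model$strata, function(s) {
      list(coefficients = as.list(s$coefficients),
           se = as.list(s$se),
           p = as.list(s$p),
           sigma = s$sigma, df_residual = s$df_residual, n = s$n,
           r_squared = s$r_squared,
           predictors = s$predictors, materials = s$materials)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_infiltration_model
#' @export
read_infiltration_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  strata <- lapply(payload$strata, function(s) {
    s$coefficients <- unlist(s$coefficients)
    s$se <- unlist(s$se)
    s$p <- unlist(s$p)
    s
  })
  structure(list(strata = strata,
                 reference_levels = payload$reference_levels),
            class = "infiltration_model")
}
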
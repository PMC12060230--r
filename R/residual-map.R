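#' Residual trait values for a pair of correlated traits
#'
#' Regresses the secondary trait on the primary trait (ordinary least
#' squares over pairwise-complete RILs) and returns the residuals, which
#' capture the variation in the secondary trait not explained by its
#' correlation with the primary. The caller designates as primary the trait
#' with the greater maximum QTL LOD score; when the two maxima are equal the
#' designation is an explicit analysis choice. Residual traits feed the
#' standard scan pipeline ([lod_scan()], [perm_threshold()],
#' [find_qtl_regions()]) with a fresh permutation threshold: a shared QTL
#' whose effect on the secondary trait is fully mediated by the primary
#' trait drops out of the residual scan, while an independent QTL is
#' retained.
#'
#' @param y_secondary Secondary trait values (residuals are computed for
#'   this trait).
#' @param y_primary Primary trait values, aligned to `y_secondary`; must be
#'   non-constant.
#' @return A list of class `residual_trait`: `residuals` (aligned to the
#'   input, NA where either trait was missing), `slope`, `intercept`,
#'   `n_used`.
#' @export
residualize <- function(y_secondary, y_primary) {
  if (length(y_secondary) != length(y_primary)) {
    abort("trait vectors must be aligned (equal length)")
  }
  ok <- !is.na(y_secondary) & !is.na(y_primary)
  x <- y_primary[ok]
  y <- y_secondary[ok]
  if (length(x) < 3) abort("need at least 3 complete cases")
  if (sd(x) == 0) abort("primary trait is constant; slope undefined")
  slope <- cov(x, y) / var(x)
  intercept <- mean(y) - slope * mean(x)
  res <- rep(NA_real_, length(y_secondary))
  res[ok] <- y - (intercept + slope * x)
  structure(
    list(residuals = res, slope = slope, intercept = intercept,
         n_used = sum(ok)),
    class = "residual_trait"
  )
}

#' @export
print.residual_trait <- function(x, ...) {
  cat(sprintf("<residual_trait> n = %d, slope = %.4g, intercept = %.4g\n",
              x$n_used, x$slope, x$intercept))
  invisible(x)
}

#' Add a residual trait column to a RIL trait table
#'
#' Convenience wrapper around [residualize()] for data-frame pipelines.
#'
#' @param data A data frame with one row per RIL.
#' @param secondary,primary Column names (strings) of the secondary and
#'   primary traits.
#' @param name Name of the new residual column (default
#'   `"<secondary>_resid"`).
#' @return `data` with the residual column appended.
#' @export
residual_trait <- function(data, secondary, primary,
                           name = paste0(secondary, "_resid")) {
  fit <- residualize(data[[secondary]], data[[primary]])
  data[[name]] <- fit$residuals
  data
}
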
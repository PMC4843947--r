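# Functional connectivity from preprocessed regional time series.

#' Pearson functional-connectivity matrix
#'
#' Pearson product-moment correlation between every pair of regional time
#' series.  Inputs are assumed to be fully preprocessed (band-passed,
#' nuisance-regressed) regional averages; that stage is upstream of this
#' package.  The result is symmetrized by averaging with its transpose to
#' remove floating-point asymmetry and has a unit diagonal.
#'
#' @param ts T x N numeric matrix, rows = time points, columns = regions.
#' @return N x N correlation matrix with attribute `transform = "raw_r"`.
#' @export
#' @examples
#' ts <- matrix(rnorm(300), 100, 3)
#' range(pearson_fc(ts))
pearson_fc <- function(ts) {
  if (!is.matrix(ts) || !is.numeric(ts)) abort_format("time series must be a numeric matrix")
  if (anyNA(ts) || any(!is.finite(ts))) abort_validation("time series contains non-finite values")
  if (nrow(ts) < 3) abort_validation("need at least 3 time points for correlation")
  sds <- apply(ts, 2, sd)
  if (any(sds == 0)) {
    abort_validation(sprintf("zero-variance time series in region(s): %s",
                             paste(which(sds == 0), collapse = ", ")))
  }
  r <- cor(ts)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  structure(r, transform = "raw_r")
}

#' Transform a functional-connectivity matrix
#'
#' Value transform applied before histogram binning: `"raw_r"` is the
#' identity, `"abs_r"` takes elementwise absolute values, `"fisher_z"`
#' applies atanh after clipping correlations to |r| <= 1 - 1e-7.
#'
#' @param fc correlation matrix from [pearson_fc()].
#' @param transform one of `"raw_r"`, `"abs_r"`, `"fisher_z"`.
#' @return transformed matrix with attribute `transform` updated.
#' @export
transform_fc <- function(fc, transform = c("raw_r", "abs_r", "fisher_z")) {
  if (!is.character(transform) ||
      !transform[1] %in% c("raw_r", "abs_r", "fisher_z")) {
    abort_parameter(sprintf("unknown fc transform: %s",
                            paste(transform[1], collapse = "")))
  }
  transform <- transform[1]
  out <- switch(transform,
    raw_r = fc,
    abs_r = abs(fc),
    fisher_z = {
      clipped <- pmin(pmax(fc, -1 + 1e-7), 1 - 1e-7)
      atanh(clipped)
    })
  attr(out, "transform") <- transform
  out
}
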
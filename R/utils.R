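# Internal validators and shared constants.

# Path-class integer coding used both in memory and on disk:
# 0 = disconnected, 1 = primary, 2 = secondary, 3 = tertiary, 4 = higher.
PATH_CLASS_CODES <- c(disconnected = 0L, primary = 1L, secondary = 2L,
                      tertiary = 3L, higher = 4L)

# Path order for consensus tie-breaks: primary is the lowest order,
# disconnected the highest.
PATH_CLASS_ORDER <- c("primary", "secondary", "tertiary", "higher",
                      "disconnected")

abort_format <- function(msg) abort(msg, class = "fcentropy_format_error")
abort_validation <- function(msg) abort(msg, class = "fcentropy_validation_error")
abort_parameter <- function(msg) abort(msg, class = "fcentropy_parameter_error")

is_wholenumber <- function(x, tol = 1e-8) {
  is.numeric(x) && all(abs(x - round(x)) < tol)
}

check_square <- function(m, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    abort_format(sprintf("%s must be a square matrix (got %s x %s)",
                         what, NROW(m), NCOL(m)))
  }
  invisible(m)
}

#' Convert a path-class code matrix to labels
#'
#' @param code integer vector or matrix using the on-disk coding
#'   (0 disconnected, 1 primary, 2 secondary, 3 tertiary, 4 higher).
#' @return character labels, same shape as the input.
#' @keywords internal
path_class_label <- function(code) {
  lab <- names(PATH_CLASS_CODES)[match(code, PATH_CLASS_CODES)]
  if (is.matrix(code)) {
    lab <- matrix(lab, nrow = nrow(code), dimnames = dimnames(code))
  }
  lab
}

# Rank of a class code on the path-order scale (1 = primary ... 5 = disconnected)
path_class_rank <- function(code) {
  match(path_class_label(code), PATH_CLASS_ORDER)
}

# Extract upper-triangle values of a square matrix (unordered pairs, no diagonal)
upper_pairs <- function(m) m[upper.tri(m)]
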
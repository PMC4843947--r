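# Structural path classification.
#
# A region pair is a primary path if one or more streamlines connect the two
# regions directly (shortest path length 1 in the binarized streamline
# graph), a secondary path if the regions share a direct neighbour (length
# 2), and a tertiary path if the shortest chain runs through two
# intermediaries (length 3).  Pairs at length >= 4 are labelled "higher"
# and pairs with no connecting chain "disconnected"; a policy flag decides
# whether higher-order pairs are pooled with tertiary downstream.

#' Binarize a streamline-count matrix
#'
#' An edge is present between two regions when the streamline count meets
#' the minimum threshold.  Raising the threshold can only remove edges.
#'
#' @param counts symmetric nonnegative integer matrix of streamline counts
#'   with zero diagonal.
#' @param min_streamlines smallest count treated as an edge (integer >= 1).
#' @return binary symmetric integer matrix with attribute `min_streamlines`.
#' @export
#' @examples
#' binarize_streamlines(matrix(c(0, 2, 2, 0), 2), min_streamlines = 3)
binarize_streamlines <- function(counts, min_streamlines = 1L) {
  if (!is_wholenumber(min_streamlines) || min_streamlines < 1) {
    abort_parameter("`min_streamlines` must be an integer >= 1")
  }
  validate_streamline_matrix(counts)
  adj <- (counts >= min_streamlines) * 1L
  diag(adj) <- 0L
  structure(adj, min_streamlines = as.integer(min_streamlines))
}

#' Classify region pairs by shortest structural path length
#'
#' Labels every unordered region pair by its shortest path length in the
#' binarized structural graph: 1 = primary, 2 = secondary, 3 = tertiary,
#' finite >= 4 = higher, unreachable = disconnected.  Distances are
#' breadth-first (unweighted, undirected).
#'
#' @param adj binary symmetric adjacency matrix (from
#'   [binarize_streamlines()]).
#' @return a `path_class_matrix`: N x N integer matrix coded
#'   0 = disconnected, 1 = primary, 2 = secondary, 3 = tertiary,
#'   4 = higher, with `NA` on the diagonal.
#' @export
classify_paths <- function(adj) {
  check_square(adj, "adjacency")
  if (any(adj != t(adj))) abort_validation("adjacency must be symmetric")
  if (!all(adj %in% c(0, 1))) abort_validation("adjacency must be binary")
  g <- igraph::graph_from_adjacency_matrix(adj != 0, mode = "undirected",
                                           diag = FALSE)
  d <- igraph::distances(g, algorithm = "unweighted")
  cls <- matrix(PATH_CLASS_CODES[["higher"]], nrow(adj), ncol(adj))
  cls[d == 1] <- PATH_CLASS_CODES[["primary"]]
  cls[d == 2] <- PATH_CLASS_CODES[["secondary"]]
  cls[d == 3] <- PATH_CLASS_CODES[["tertiary"]]
  cls[is.infinite(d)] <- PATH_CLASS_CODES[["disconnected"]]
  diag(cls) <- NA_integer_
  structure(cls, class = "path_class_matrix",
            min_streamlines = attr(adj, "min_streamlines"))
}

#' @export
print.path_class_matrix <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("<path_class_matrix> %d regions, %d unordered pairs\n",
              n, n * (n - 1) / 2))
  print(path_class_proportions(x), ...)
  invisible(x)
}

#' Proportions of path classes over all unordered region pairs
#'
#' @param pcm a `path_class_matrix`.
#' @param higher_order_policy `"separate"` or `"merge_into_tertiary"`;
#'   under the merge policy pairs at shortest path length >= 4 are counted
#'   as tertiary.
#' @return a tibble with columns `class`, `n_pairs`, `proportion`;
#'   proportions sum to 1 over the N(N-1)/2 unordered pairs.
#' @export
path_class_proportions <- function(pcm,
                                   higher_order_policy = c("separate",
                                                           "merge_into_tertiary")) {
  higher_order_policy <- match.arg(higher_order_policy)
  codes <- upper_pairs(unclass(pcm))
  if (higher_order_policy == "merge_into_tertiary") {
    codes[codes == PATH_CLASS_CODES[["higher"]]] <- PATH_CLASS_CODES[["tertiary"]]
  }
  lev <- if (higher_order_policy == "separate") PATH_CLASS_ORDER
         else setdiff(PATH_CLASS_ORDER, "higher")
  tab <- table(factor(path_class_label(codes), levels = lev))
  tibble::tibble(class = names(tab),
                 n_pairs = as.integer(tab),
                 proportion = as.integer(tab) / length(codes))
}

#' Consensus path-class matrix across subjects
#'
#' Per-pair modal class over a list of classifications (for example all
#' subjects of one group).  Ties are broken toward the lower path order
#' (primary < secondary < tertiary < higher < disconnected), the
#' conservative, structurally constrained reading.
#'
#' @param pcms non-empty list of `path_class_matrix` objects on the same
#'   region set.
#' @return a `path_class_matrix`.
#' @export
consensus_path_class <- function(pcms) {
  if (!length(pcms)) abort_parameter("need at least one classification")
  n <- nrow(pcms[[1]])
  if (!all(vapply(pcms, nrow, 0L) == n)) {
    abort_validation("all classifications must share the same region count")
  }
  # votes[r, pair]: count of subjects giving path-order rank r to that pair
  ranks <- vapply(pcms, function(p) path_class_rank(upper_pairs(unclass(p))),
                  integer(n * (n - 1) / 2))
  ranks <- matrix(ranks, ncol = length(pcms))
  modal_rank <- apply(ranks, 1, function(v) {
    tab <- tabulate(v, nbins = 5L)
    which.max(tab)  # first max = lowest path order on ties
  })
  code <- PATH_CLASS_CODES[PATH_CLASS_ORDER[modal_rank]]
  out <- matrix(NA_integer_, n, n)
  out[upper.tri(out)] <- code
  out <- pmax(out, t(out), na.rm = TRUE)
  diag(out) <- NA_integer_
  structure(out, class = "path_class_matrix")
}

#' Agreement between two path classifications
#'
#' Counts unordered pairs assigned the same class in both classifications.
#' Per-class agreement is reported under two denominators, because the
#' conventional choice is ambiguous: `frac_union` divides by the pairs
#' labelled with the class in either classification, `frac_conditional_a`
#' by the pairs labelled with the class in `a` alone.
#'
#' @param a,b `path_class_matrix` objects with the same region count.
#' @return a list with `n_pairs`, `n_agree`, `fraction`, and `per_class`
#'   (tibble: class, n_both, n_union, n_a, n_b, frac_union,
#'   frac_conditional_a).
#' @export
class_agreement <- function(a, b) {
  if (nrow(a) != nrow(b)) abort_validation("classifications differ in size")
  ca <- upper_pairs(unclass(a))
  cb <- upper_pairs(unclass(b))
  agree <- ca == cb
  per_class <- purrr::map_dfr(PATH_CLASS_ORDER, function(cl) {
    code <- PATH_CLASS_CODES[[cl]]
    in_a <- ca == code
    in_b <- cb == code
    both <- sum(in_a & in_b)
    uni <- sum(in_a | in_b)
    tibble::tibble(class = cl, n_both = both, n_union = uni,
                   n_a = sum(in_a), n_b = sum(in_b),
                   frac_union = if (uni > 0) both / uni else NA_real_,
                   frac_conditional_a = if (sum(in_a) > 0) both / sum(in_a)
                                        else NA_real_)
  })
  list(n_pairs = length(ca), n_agree = sum(agree),
       fraction = mean(agree), per_class = per_class)
}

#' Write / read a path-class matrix as integer-coded delimited text
#'
#' Coding: 0 disconnected, 1 primary, 2 secondary, 3 tertiary, 4 higher;
#' the diagonal is written as 0 and restored to `NA` on read.
#'
#' @param pcm a `path_class_matrix`.
#' @param path file path.
#' @export
write_path_class_matrix <- function(pcm, path) {
  m <- unclass(pcm)
  diag(m) <- 0L
  write_matrix(m, path, delimiter = "tab")
}

#' @rdname write_path_class_matrix
#' @export
read_path_class_matrix <- function(path) {
  m <- read_delim_matrix(path)
  check_square(m, sprintf("path-class matrix %s", path))
  if (!all(m %in% PATH_CLASS_CODES)) {
    abort_validation(sprintf("%s: invalid path-class code", path))
  }
  storage.mode(m) <- "integer"
  diag(m) <- NA_integer_
  structure(m, class = "path_class_matrix")
}
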
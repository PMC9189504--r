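#' XY gene-tree consistency of a window
#'
#' Builds a neighbour-joining tree from pairwise Hamming distances
#' among the haplotypes in the window and asks whether the X|Y
#' bipartition exists in the unrooted tree (equivalently, whether the Y
#' haplotypes are monophyletic when the tree is rooted at an X tip). In
#' the recombining PAR the labels are intermingled and the bipartition
#' is almost never present; in the non-recombining SDR the Y
#' haplotypes coalesce first and the bipartition holds.
#'
#' @param panel haplotype matrix (rows = haplotypes) or a labelled
#'   panel object; needs at least 3 X and 3 Y haplotypes.
#' @param labels `"X"`/`"Y"` labels per row (from the panel if omitted).
#' @param window optional `c(start, end)` bp window.
#' @param positions site positions (from the panel if omitted).
#' @return list with `consistent` (TRUE/FALSE, or NA when the window
#'   holds no variation) and `tree` (an [ape::phylo] object or NULL).
#' @export
gene_tree_consistency <- function(panel, labels = NULL, window = NULL,
                                  positions = NULL) {
  hap <- panel
  if (!is.matrix(hap)) {
    labels <- labels %||% panel$label
    positions <- positions %||% panel$positions
    hap <- panel$hap
  }
  if (sum(labels == "X") < 3 || sum(labels == "Y") < 3)
    stopf("gene_tree_consistency needs >= 3 X and >= 3 Y haplotypes")
  j <- window_cols(positions %||% seq_len(ncol(hap)), window)
  H <- hap[, j, drop = FALSE]
  H <- H[, colSums(is.na(H)) == 0, drop = FALSE]
  if (ncol(H) == 0 || all(apply(H, 2L, function(x) length(unique(x))) == 1L))
    return(list(consistent = NA, tree = NULL))
  d <- stats::dist(H, method = "manhattan")
  if (all(d == 0)) return(list(consistent = NA, tree = NULL))
  tips <- paste0(labels, "_", seq_along(labels))
  dm <- as.matrix(d); dimnames(dm) <- list(tips, tips)
  tr <- ape::nj(stats::as.dist(dm))
  # root at an X tip: the Y set is a clade iff the X|Y bipartition
  # exists in the unrooted tree
  rooted <- ape::root(tr, outgroup = tips[which(labels == "X")[1]],
                      resolve.root = TRUE)
  cons <- ape::is.monophyletic(rooted, tips[labels == "Y"])
  list(consistent = cons, tree = tr)
}

#' Locate the SDR/PAR boundary from an ordered window series
#'
#' Single binary-segmentation change point: the split of the series
#' into a left and a right segment that maximises the reduction in
#' within-segment sum of squares (for a boolean series, the difference
#' in proportions). Works on any of the boundary-informative series:
#' XY gene-tree consistency, X-Y divergence, or Y diversity.
#'
#' @param x numeric or logical series, ordered along the chromosome.
#' @param starts window start positions (bp) matching `x`; optional.
#' @return list with `index` (last window of the left segment),
#'   `boundary_bp` (start of the first right-segment window, or NA),
#'   and `score`. A constant series returns `index = NA` (no boundary).
#' @export
detect_boundary <- function(x, starts = NULL) {
  x <- as.numeric(x)
  keep <- !is.na(x)
  xs <- x[keep]
  n <- length(xs)
  if (n < 2 || stats::var(xs) == 0)
    return(list(index = NA_integer_, boundary_bp = NA_real_, score = 0))
  sse <- function(v) sum((v - mean(v))^2)
  tot <- sse(xs)
  red <- vapply(seq_len(n - 1L), function(k)
    tot - sse(xs[seq_len(k)]) - sse(xs[(k + 1L):n]), 0)
  k <- which.max(red)
  idx_all <- which(keep)
  index <- idx_all[k]
  boundary_bp <- if (!is.null(starts)) starts[idx_all[k + 1L]] else NA_real_
  list(index = index, boundary_bp = boundary_bp, score = red[k])
}
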
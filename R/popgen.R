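#' Tile a chromosome into non-overlapping half-open windows
#'
#' Windows tile from position 1 as `[start, start + size)`; reported
#' positions are 1-based to match VCF coordinates.
#'
#' @param chrom_length chromosome length in bp.
#' @param size window size in bp (10 kb for statistics, 100 kb for gene
#'   trees by convention).
#' @param from,to optional sub-interval: only windows fully inside
#'   `(from, to]` are returned (used for the focal-region scan). By
#'   default all windows tiling the chromosome are kept, including a
#'   final window overhanging the chromosome end.
#' @return data.table with `start` (1-based, inclusive) and `end`
#'   (exclusive).
#' @export
make_windows <- function(chrom_length, size = 1e4, from = 0, to = NULL) {
  check_positive(size, "size")
  starts <- seq(1, chrom_length, by = size)
  w <- data.table::data.table(start = starts, end = starts + size)
  keep <- w$start > from
  if (!is.null(to)) keep <- keep & w$end <= to + 1
  w[keep, ]
}

# Hudson FST building blocks from derived-allele counts.
# Hw: mean of the two within-group heterozygosities (unbiased,
# mean pairwise differences); Hb: between-group mean pairwise difference.
hudson_components <- function(cx, nx, cy, ny) {
  hx <- 2 * cx * (nx - cx) / (nx * (nx - 1))
  hy <- 2 * cy * (ny - cy) / (ny * (ny - 1))
  hw <- (hx + hy) / 2
  px <- cx / nx; py <- cy / ny
  hb <- px * (1 - py) + py * (1 - px)
  list(num = hb - hw, den = hb)
}

#' Per-site Hudson FST between two haplotype groups
#'
#' `1 - Hw/Hb` from mean pairwise differences within and between the
#' groups; undefined (NA) when the between-group heterozygosity is zero
#' (site monomorphic in both groups). Negative values are clamped to 0
#' for reporting; window aggregation ([window_fst()]) uses the
#' unclamped components to avoid truncation bias.
#'
#' @param freq_x,freq_y derived-allele frequencies in the two groups
#'   (or counts if `counts = TRUE`).
#' @param n_x,n_y haplotype sample sizes (each at least 2).
#' @param counts interpret `freq_*` as allele counts.
#' @param clamp clamp negative values to 0 (default TRUE).
#' @return FST in `[0, 1]`, or NA when undefined.
#' @export
site_fst <- function(freq_x, n_x, freq_y, n_y, counts = FALSE,
                     clamp = TRUE) {
  if (n_x < 2 || n_y < 2) stopf("site_fst needs >= 2 haplotypes per group")
  cx <- if (counts) freq_x else freq_x * n_x
  cy <- if (counts) freq_y else freq_y * n_y
  h <- hudson_components(cx, n_x, cy, n_y)
  fst <- ifelse(h$den > 0, h$num / h$den, NA_real_)
  if (clamp) fst <- pmax(fst, 0)
  fst
}

# select the columns of a panel-like object falling in a window
window_cols <- function(positions, window) {
  if (is.null(window)) seq_along(positions)
  else which(positions >= window[1] & positions < window[2])
}

hap_matrix <- function(x) {
  if (is.matrix(x)) x else x$hap
}

#' Window FST between X- and Y-labelled haplotypes
#'
#' Hudson estimator aggregated as a ratio of averages: the per-site
#' numerators (Hb - Hw) and denominators (Hb) are summed over sites
#' before taking the ratio. Sites monomorphic across both groups
#' contribute nothing. Undefined (NA) if no site is polymorphic.
#'
#' @param hap haplotype x site 0/1 matrix, or a `phased_panel` /
#'   `haplotype_panel`.
#' @param labels group labels (`"X"`/`"Y"`) per row; taken from the
#'   panel if omitted.
#' @param window optional `c(start, end)` half-open bp window; taken
#'   over all sites if omitted.
#' @param positions site positions (taken from the panel if omitted).
#' @return window FST (possibly negative; not clamped), or NA.
#' @export
window_fst <- function(hap, labels = NULL, window = NULL,
                       positions = NULL) {
  if (!is.matrix(hap)) {
    labels <- labels %||% hap$label
    positions <- positions %||% hap$positions
    hap <- hap$hap
  }
  j <- window_cols(positions %||% seq_len(ncol(hap)), window)
  if (!length(j)) return(NA_real_)
  H <- hap[, j, drop = FALSE]
  ix <- labels == "X"
  if (sum(ix) < 2 || sum(!ix) < 2)
    stopf("window_fst needs >= 2 haplotypes per group")
  cx <- colSums(H[ix, , drop = FALSE], na.rm = TRUE)
  cy <- colSums(H[!ix, , drop = FALSE], na.rm = TRUE)
  # per-site sample sizes account for unphased (NA) calls
  nx <- colSums(!is.na(H[ix, , drop = FALSE]))
  ny <- colSums(!is.na(H[!ix, , drop = FALSE]))
  ok <- nx >= 2 & ny >= 2
  if (!any(ok)) return(NA_real_)
  h <- hudson_components(cx[ok], nx[ok], cy[ok], ny[ok])
  den <- sum(h$den)
  if (den <= 0) return(NA_real_)
  sum(h$num) / den
}

#' Nucleotide diversity (pi) of a haplotype panel in a window
#'
#' Mean pairwise difference count across all haplotype pairs, divided by
#' the window length in bp.
#'
#' @inheritParams window_fst
#' @param len window length in bp for the per-bp normalisation; derived
#'   from `window` if given, else defaults to 1 (raw mean pairwise
#'   differences).
#' @return per-bp diversity, or NA with fewer than two haplotypes.
#' @export
window_pi <- function(hap, window = NULL, positions = NULL, len = NULL) {
  if (!is.matrix(hap)) {
    positions <- positions %||% hap$positions
    hap <- hap$hap
  }
  n <- nrow(hap)
  if (n < 2) return(NA_real_)
  j <- window_cols(positions %||% seq_len(ncol(hap)), window)
  len <- len %||% (if (!is.null(window)) diff(window) else 1)
  if (!length(j)) return(0)
  H <- hap[, j, drop = FALSE]
  c1 <- colSums(H, na.rm = TRUE)
  ns <- colSums(!is.na(H))
  ok <- ns >= 2
  sum(2 * c1[ok] * (ns[ok] - c1[ok]) / (ns[ok] * (ns[ok] - 1))) / len
}

#' Between-group per-bp divergence (K, a.k.a. Dxy) in a window
#'
#' Mean over all between-panel haplotype pairs of the per-bp difference
#' count. Symmetric in its panel arguments.
#'
#' @param hap_a,hap_b haplotype x site matrices (or panel objects) on
#'   the same site set.
#' @inheritParams window_pi
#' @return per-bp divergence K.
#' @export
window_dxy <- function(hap_a, hap_b, window = NULL, positions = NULL,
                       len = NULL) {
  if (!is.matrix(hap_a)) { positions <- positions %||% hap_a$positions
                           hap_a <- hap_a$hap }
  if (!is.matrix(hap_b)) hap_b <- hap_b$hap
  if (nrow(hap_a) < 1 || nrow(hap_b) < 1) stopf("empty panel in window_dxy")
  if (ncol(hap_a) != ncol(hap_b))
    stopf("panels must share the same site set")
  j <- window_cols(positions %||% seq_len(ncol(hap_a)), window)
  len <- len %||% (if (!is.null(window)) diff(window) else 1)
  if (!length(j)) return(0)
  A <- hap_a[, j, drop = FALSE]; B <- hap_b[, j, drop = FALSE]
  ca <- colSums(A, na.rm = TRUE); cb <- colSums(B, na.rm = TRUE)
  na <- colSums(!is.na(A)); nb <- colSums(!is.na(B))
  ok <- na >= 1 & nb >= 1
  sum((ca[ok] * (nb[ok] - cb[ok]) + cb[ok] * (na[ok] - ca[ok])) /
        (na[ok] * nb[ok])) / len
}

# Tajima (1989) constants for sample size n
tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D of a haplotype panel in a window
#'
#' `(pi - S/a1) / sqrt(e1 S + e2 S (S - 1))` with the standard 1989
#' constants, where `pi` is the total (not per-bp) mean pairwise
#' difference count and `S` the number of segregating sites. Undefined
#' (NA) when `S = 0` or fewer than four haplotypes.
#'
#' @inheritParams window_pi
#' @return Tajima's D, or NA.
#' @export
tajimas_d <- function(hap, window = NULL, positions = NULL) {
  if (!is.matrix(hap)) { positions <- positions %||% hap$positions
                         hap <- hap$hap }
  n <- nrow(hap)
  if (n < 4) return(NA_real_)
  j <- window_cols(positions %||% seq_len(ncol(hap)), window)
  if (!length(j)) return(NA_real_)
  H <- hap[, j, drop = FALSE]
  c1 <- colSums(H, na.rm = TRUE)
  ns <- colSums(!is.na(H))
  seg <- c1 > 0 & c1 < ns & ns >= 4
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  # with missing calls the constants use the median per-site sample size
  n_eff <- as.integer(round(median(ns[seg])))
  if (n_eff < 4) return(NA_real_)
  pi_tot <- sum(2 * c1[seg] * (ns[seg] - c1[seg]) / (ns[seg] * (ns[seg] - 1)))
  k <- tajima_constants(n_eff)
  (pi_tot - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Son/daughter read-depth ratio in a window
#'
#' Each individual's depths are first divided by that individual's mean
#' depth across all sites in the table (library-size normalisation);
#' the ratio of the son means to the daughter means is then taken over
#' sites in the window. A fully degenerate Y gives a ratio near 0.5
#' (sons retain only the X-derived half of their coverage).
#'
#' @param tab a `variant_table` with DP.
#' @param sons,daughters sample names of sons and daughters; defaults
#'   from the pedigree attached to the table.
#' @param window optional `c(start, end)` half-open window in bp.
#' @return depth ratio, or NA if daughters have zero depth there.
#' @export
depth_ratio <- function(tab, sons = NULL, daughters = NULL, window = NULL) {
  stopifnot(inherits(tab, "variant_table"))
  if (is.null(sons) || is.null(daughters)) {
    if (is.null(tab$ped)) stopf("no pedigree: pass sons/daughters explicitly")
    sons <- sons %||% tab$ped$child[tab$ped$sex == "M"]
    daughters <- daughters %||% tab$ped$child[tab$ped$sex == "F"]
  }
  if (!length(sons) || !length(daughters))
    stopf("depth_ratio needs at least one son and one daughter")
  dp <- tab$dp[, c(sons, daughters), drop = FALSE]
  norm <- sweep(dp, 2L, colMeans(dp, na.rm = TRUE), `/`)
  j <- window_cols(tab$pos, window)
  if (!length(j)) return(NA_real_)
  ms <- mean(norm[j, sons, drop = FALSE], na.rm = TRUE)
  md <- mean(norm[j, daughters, drop = FALSE], na.rm = TRUE)
  if (!is.finite(md) || md == 0) return(NA_real_)
  ms / md
}

#' Per-window population-genetic statistics for a phased panel
#'
#' Computes, for each window tiling the chromosome: the number of sites
#' polymorphic among the focal haplotypes, Hudson X-vs-Y FST (clamped
#' at 0 for reporting), per-bp pi for X, Y and combined, per-bp X-Y
#' divergence, per-bp divergence to a sister-species panel (if given),
#' Tajima's D of the combined panel, the son/daughter depth ratio (if a
#' variant table is given) and, on a coarser tiling, XY gene-tree
#' consistency.
#'
#' @param panel a `phased_panel` or `haplotype_panel` with X/Y labels.
#' @param sister optional sister-species panel on the same site set
#'   (for `k_species`).
#' @param tab optional `variant_table` (for `depth_ratio`).
#' @param chrom_length chromosome length in bp; inferred from the last
#'   position if missing.
#' @param size statistics window size in bp.
#' @param tree_size gene-tree window size in bp.
#' @return data.table of class `window_stats`: one row per window with
#'   the statistics above (`xy_consistent` reported on `tree_size`
#'   windows and joined onto the covering rows).
#' @export
window_stats <- function(panel, sister = NULL, tab = NULL,
                         chrom_length = NULL, size = 1e4,
                         tree_size = 1e5) {
  hap <- hap_matrix(panel)
  labels <- panel$label
  pos <- panel$positions
  chrom_length <- chrom_length %||% panel$chrom_length %||% max(pos)
  w <- make_windows(chrom_length, size)
  ix <- labels == "X"
  res <- lapply(seq_len(nrow(w)), function(k) {
    win <- c(w$start[k], w$end[k])
    j <- window_cols(pos, win)
    H <- hap[, j, drop = FALSE]
    cnt <- colSums(H, na.rm = TRUE)
    nn <- colSums(!is.na(H))
    n_snps <- sum(cnt > 0 & cnt < nn)
    data.table::data.table(
      start = win[1], end = win[2], n_snps = n_snps,
      fst = max(0, window_fst(H, labels)),
      pi_x = window_pi(H[ix, , drop = FALSE], len = size),
      pi_y = window_pi(H[!ix, , drop = FALSE], len = size),
      pi_all = window_pi(H, len = size),
      k_xy = window_dxy(H[ix, , drop = FALSE], H[!ix, , drop = FALSE],
                        len = size),
      k_species = if (!is.null(sister))
        window_dxy(H, hap_matrix(sister)[, j, drop = FALSE], len = size)
      else NA_real_,
      tajima_d = tajimas_d(H),
      depth_ratio = if (!is.null(tab)) depth_ratio(tab, window = win)
      else NA_real_)
  })
  out <- data.table::rbindlist(res)

  tw <- make_windows(chrom_length, tree_size)
  cons <- vapply(seq_len(nrow(tw)), function(k) {
    gene_tree_consistency(panel, window = c(tw$start[k], tw$end[k]))$consistent
  }, NA)
  out$xy_consistent <- cons[findInterval(out$start, tw$start)]
  data.table::setattr(out, "class", c("window_stats", class(out)))
  out[]
}
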
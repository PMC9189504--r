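#' Configuration of the focal-region SAS scan
#'
#' Defaults follow the published protocol for a young neo-sex
#' chromosome: a focal PAR interval of 7.5-11.5 Mb (starting 60 rho
#' from the SDR, ending around 460 rho), 10 kb windows with at least 10
#' SNPs, one million balanced label permutations per window and an FDR
#' of 0.2.
#'
#' @param focal_start_bp,focal_end_bp focal interval in bp (windows
#'   fully inside are tested).
#' @param window window size in bp.
#' @param min_snps minimum number of polymorphic sites for a window to
#'   be tested. The inclusive/exclusive reading of "10" is genuinely
#'   ambiguous in the field's usage, so both are exposed: the default
#'   keeps windows with `n_snps >= min_snps`; set `strict_min_snps =
#'   TRUE` for `>`.
#' @param strict_min_snps require strictly more than `min_snps`.
#' @param n_perm number of balanced label randomisations per window.
#' @param fdr false discovery rate for significance calls.
#' @param add_one use the conservative add-one permutation p-value
#'   `(b + 1)/(B + 1)` instead of the plain proportion `b/B`.
#' @param seed integer seed driving all permutation draws.
#' @return list of class `scan_config`.
#' @export
scan_config <- function(focal_start_bp = 7.5e6, focal_end_bp = 11.5e6,
                        window = 1e4, min_snps = 10L,
                        strict_min_snps = FALSE, n_perm = 1e6,
                        fdr = 0.2, add_one = FALSE, seed = 1L) {
  check_positive(window, "window")
  check_nonneg(min_snps, "min_snps")
  if (n_perm < 1e3) stopf("n_perm must be at least 1000")
  if (fdr <= 0 || fdr >= 1) stopf("fdr must lie in (0, 1)")
  if (focal_end_bp <= focal_start_bp) stopf("empty focal interval")
  structure(list(focal_start_bp = focal_start_bp,
                 focal_end_bp = focal_end_bp, window = window,
                 min_snps = as.integer(min_snps),
                 strict_min_snps = isTRUE(strict_min_snps),
                 n_perm = as.integer(n_perm), fdr = fdr,
                 add_one = isTRUE(add_one), seed = as.integer(seed)),
            class = "scan_config")
}

# balanced relabelings as a B x n logical matrix (TRUE = assigned to X)
balanced_labels <- function(n, B) {
  half <- n %/% 2L
  ord <- apply(matrix(runif(B * n), B, n), 1L, order)[seq_len(half), ,
                                                      drop = FALSE]
  Z <- matrix(FALSE, B, n)
  Z[cbind(rep(seq_len(B), each = half), as.vector(ord))] <- TRUE
  Z
}

# Hudson window FST for every row-relabeling in Z (B x n logical);
# H is the n x S 0/1 site matrix. Returns length-B vector.
perm_window_fst <- function(H, Z) {
  n <- nrow(H); half <- n %/% 2L
  storage.mode(H) <- "double"
  cx <- Z %*% H                      # B x S derived counts in group X
  tot <- matrix(colSums(H), nrow(Z), ncol(H), byrow = TRUE)
  cy <- tot - cx
  hx <- 2 * cx * (half - cx) / (half * (half - 1))
  hy <- 2 * cy * (half - cy) / (half * (half - 1))
  px <- cx / half; py <- cy / half
  hb <- px * (1 - py) + py * (1 - px)
  num <- rowSums(hb - (hx + hy) / 2)
  den <- rowSums(hb)
  ifelse(den > 0, num / den, NA_real_)
}

#' Permutation p-value of a window's X-vs-Y FST
#'
#' Randomises the X/Y labels of the haplotypes, keeping equal numbers
#' of Xs and Ys, and reports the proportion of randomisations whose
#' window FST is greater than or equal to the observed value (ties
#' count toward the numerator). Requires balanced labels; the null of
#' label exchangeability is only meaningful for a balanced design.
#'
#' @param hap haplotype x site 0/1 matrix (`NA` for unphased calls:
#'   such sites contribute with per-relabeling sample sizes, matching
#'   [window_fst()]), or a panel object.
#' @param labels `"X"`/`"Y"` labels per haplotype.
#' @param n_perm number of Monte-Carlo randomisations.
#' @param seed integer seed; same seed gives identical p-values.
#' @param add_one use `(b + 1)/(B + 1)` instead of `b/B`.
#' @param window,positions optional window selection as in
#'   [window_fst()].
#' @param chunk internal chunk size bounding memory use.
#' @return list with `p` (the empirical p-value), `observed` FST and
#'   `n_perm`.
#' @export
permutation_pvalue <- function(hap, labels = NULL, n_perm = 1e4,
                               seed = 1L, add_one = FALSE, window = NULL,
                               positions = NULL, chunk = 1e5) {
  if (!is.matrix(hap)) {
    labels <- labels %||% hap$label
    positions <- positions %||% hap$positions
    hap <- hap$hap
  }
  if (sum(labels == "X") != sum(labels == "Y"))
    stopf("permutation null requires equal numbers of X and Y haplotypes")
  j <- window_cols(positions %||% seq_len(ncol(hap)), window)
  H <- hap[, j, drop = FALSE]
  obs <- window_fst(H, labels)
  if (is.na(obs)) return(list(p = NA_real_, observed = NA_real_,
                              n_perm = n_perm))
  set.seed(seed)
  n <- nrow(H)
  storage.mode(H) <- "integer"
  hits <- 0
  left <- n_perm
  while (left > 0) {
    B <- as.integer(min(left, chunk))
    f <- perm_fst_null_cpp(H, B)
    hits <- hits + sum(f >= obs - 1e-12, na.rm = TRUE)
    left <- left - B
  }
  p <- if (add_one) (hits + 1) / (n_perm + 1) else hits / n_perm
  list(p = p, observed = obs, n_perm = n_perm)
}

#' Storey q-values with smoothed pi0 estimation
#'
#' Estimates the null proportion pi0 on a lambda grid
#' (0.05, 0.10, ..., 0.95) with a cubic smoothing spline evaluated at
#' the largest lambda, then converts p-values to q-values by the
#' step-up rule `q_i = min over {j : p_j >= p_i} of pi0 m p_j / rank_j`.
#' With fewer than 100 tests the spline estimate of pi0 is unstable, so
#' pi0 falls back to 1 and the procedure reduces to Benjamini-Hochberg
#' (the conservative limit).
#'
#' @param p vector of p-values in `[0, 1]`.
#' @param pi0 optionally force pi0 (e.g. `1` for plain BH).
#' @param lambda grid for pi0 estimation.
#' @return list with `q` (same order as `p`), `pi0` and `pi0_lambda`.
#' @export
storey_qvalues <- function(p, pi0 = NULL,
                           lambda = seq(0.05, 0.95, by = 0.05)) {
  if (length(p) < 1L) stopf("empty p-value vector")
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stopf("p-values must lie in [0, 1]")
  m <- length(p)
  pi0_lambda <- NULL
  if (is.null(pi0)) {
    if (m < 100L) {
      pi0 <- 1
    } else {
      pi0_lambda <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
      fit <- stats::smooth.spline(lambda, pi0_lambda, df = 3)
      pi0 <- stats::predict(fit, x = max(lambda))$y
      pi0 <- min(max(pi0, 0), 1)
      if (pi0 <= 0) pi0 <- 1 / m   # degenerate fit: all hypotheses non-null
    }
  }
  o <- order(p)
  r <- rank(p, ties.method = "max")
  q <- pi0 * m * p / r
  q[o] <- rev(cummin(rev(pmin(q[o], 1))))
  list(q = q, pi0 = pi0, pi0_lambda = pi0_lambda)
}

#' Scan the focal PAR region for high-FST outlier windows
#'
#' Tiles the focal interval into windows, filters them by SNP count,
#' computes a balanced-permutation p-value of the X-vs-Y FST for each
#' window, converts the p-values to Storey q-values, and flags windows
#' with `q <= fdr`. Each window's permutation stream is seeded from the
#' global seed and the window's ordinal position, so results do not
#' depend on the order windows are processed in.
#'
#' @param panel a `phased_panel` (or haplotype matrix with labels)
#'   covering the focal interval.
#' @param config a [scan_config()].
#' @return data.table of class `scan_result` (one row per tested
#'   window: `start`, `end`, `n_snps`, `fst`, `p_emp`, `q_value`,
#'   `significant`) with attributes `n_windows_tested`, `pi0`, `seed`,
#'   `n_perm`, `config`.
#' @export
scan_focal_region <- function(panel, config = scan_config()) {
  stopifnot(inherits(config, "scan_config"))
  hap <- hap_matrix(panel)
  labels <- panel$label
  pos <- panel$positions
  w <- make_windows(max(config$focal_end_bp, max(pos)), config$window,
                    from = config$focal_start_bp, to = config$focal_end_bp)
  rows <- lapply(seq_len(nrow(w)), function(k) {
    win <- c(w$start[k], w$end[k])
    j <- window_cols(pos, win)
    H <- hap[, j, drop = FALSE]
    cnt <- colSums(H, na.rm = TRUE)
    nn <- colSums(!is.na(H))
    n_snps <- sum(cnt > 0 & cnt < nn)
    pass <- if (config$strict_min_snps) n_snps > config$min_snps
            else n_snps >= config$min_snps
    if (!pass) return(NULL)
    pv <- permutation_pvalue(H, labels, n_perm = config$n_perm,
                             seed = derive_seed(config$seed, w$start[k]),
                             add_one = config$add_one)
    data.table::data.table(start = win[1], end = win[2], n_snps = n_snps,
                           fst = pv$observed, p_emp = pv$p)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    warning("no window passed the SNP-count filter in the focal region")
    out <- data.table::data.table(start = numeric(0), end = numeric(0),
                                  n_snps = integer(0), fst = numeric(0),
                                  p_emp = numeric(0), q_value = numeric(0),
                                  significant = logical(0))
    data.table::setattr(out, "class", c("scan_result", class(out)))
    return(out)
  }
  out <- data.table::rbindlist(rows)
  qv <- storey_qvalues(out$p_emp)
  out$q_value <- qv$q
  out$significant <- out$q_value <= config$fdr
  data.table::setattr(out, "class", c("scan_result", class(out)))
  data.table::setattr(out, "n_windows_tested", nrow(out))
  data.table::setattr(out, "pi0", qv$pi0)
  data.table::setattr(out, "seed", config$seed)
  data.table::setattr(out, "n_perm", config$n_perm)
  data.table::setattr(out, "config", config)
  out[]
}

#' Write a scan result as TSV (and significant windows as BED)
#'
#' @param scan a `scan_result`.
#' @param path TSV output path; a sibling `.bed` of significant windows
#'   is written when `bed = TRUE`.
#' @param chrom chromosome name for the BED file.
#' @param bed also write the BED of significant windows.
#' @return invisibly, the TSV path.
#' @export
write_scan_result <- function(scan, path, chrom = "chrSex", bed = TRUE) {
  cfg <- attr(scan, "config")
  write_tsv_header(as.data.frame(scan), path, attr(scan, "seed"),
                   if (!is.null(cfg)) config_hash(unclass(cfg)))
  if (bed) {
    sig <- scan[scan$significant, ]
    bed_df <- data.frame(chrom = chrom,
                         start = as.integer(sig$start) - 1L,
                         end = as.integer(sig$end) - 1L)
    write.table(bed_df, sub("\\.tsv$", ".bed", path), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
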
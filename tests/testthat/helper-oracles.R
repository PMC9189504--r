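# Independent brute-force oracles used to cross-check the vectorised
# estimators. These deliberately work from full pairwise difference
# matrices / explicit enumeration rather than allele counts.

oracle_window_fst <- function(hap, labels) {
  D <- as.matrix(stats::dist(hap, method = "manhattan"))
  ix <- which(labels == "X"); iy <- which(labels == "Y")
  pairs_mean <- function(idx) {
    if (length(idx) < 2) return(NA_real_)
    m <- D[idx, idx]
    mean(m[upper.tri(m)])
  }
  hw <- (pairs_mean(ix) + pairs_mean(iy)) / 2
  hb <- mean(D[ix, iy])
  if (hb == 0) return(NA_real_)
  1 - hw / hb
}

oracle_pi <- function(hap, len = 1) {
  if (nrow(hap) < 2) return(NA_real_)
  mean(stats::dist(hap, method = "manhattan")) / len
}

oracle_dxy <- function(a, b, len = 1) {
  tot <- 0
  for (i in seq_len(nrow(a)))
    for (j in seq_len(nrow(b)))
      tot <- tot + sum(a[i, ] != b[j, ])
  tot / (nrow(a) * nrow(b)) / len
}

# Tajima (1989) D written out independently from first principles
oracle_tajima <- function(hap) {
  n <- nrow(hap)
  cnt <- colSums(hap)
  seg <- cnt > 0 & cnt < n
  S <- sum(seg)
  if (S == 0 || n < 4) return(NA_real_)
  pi <- mean(stats::dist(hap[, seg, drop = FALSE], method = "manhattan"))
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# exact permutation p-value by exhaustive enumeration of balanced splits
oracle_exact_perm_p <- function(hap, labels) {
  n <- nrow(hap); half <- n / 2
  obs <- oracle_window_fst(hap, labels)
  splits <- utils::combn(n, half)
  fs <- apply(splits, 2, function(ix) {
    lab <- rep("Y", n); lab[ix] <- "X"
    oracle_window_fst(hap, lab)
  })
  mean(fs >= obs - 1e-12, na.rm = TRUE)
}

# a random haplotype panel with at least one polymorphic site
random_panel <- function(n = 30, S = 12, seed = 1) {
  set.seed(seed)
  repeat {
    hap <- matrix(rbinom(n * S, 1, runif(S, 0.1, 0.9)[rep(1:S, each = n)]),
                  n, S)
    cnt <- colSums(hap)
    if (any(cnt > 0 & cnt < n)) return(hap)
  }
}

# minimal variant_table constructor for filter/phasing unit tests
make_table <- function(gt, pos = seq_len(nrow(gt)), qual = 999,
                       ref = "A", alt = "G", gq = 99L, dp = 20L,
                       ped = NULL) {
  S <- nrow(gt); N <- ncol(gt)
  expand <- function(x, d1, d2) {
    if (is.matrix(x)) x else matrix(x, d1, d2)
  }
  structure(list(
    chrom = "chrT", pos = as.integer(pos),
    ref = rep(ref, length.out = S), alt = rep(alt, length.out = S),
    qual = rep(qual, length.out = S),
    gt = gt,
    gq = expand(gq, S, N) |> `colnames<-`(colnames(gt)),
    dp = expand(dp, S, N) |> `colnames<-`(colnames(gt)),
    samples = colnames(gt), ped = ped, seed = 1L,
    chrom_length = max(pos)), class = "variant_table")
}
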
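#' Variant filtering thresholds
#'
#' The hard filters applied before trio phasing: site quality of at
#' least 999 (the mpileup cap, i.e. essentially error-free calls),
#' per-genotype quality of at least 20 (genotypes below are set
#' missing, VCFtools `--minGQ` semantics), a minimum across-sample mean
#' depth of 10x, a paralog guard dropping sites whose mean depth
#' exceeds `max_depth_factor` times the chromosome median of site mean
#' depths, biallelic SNPs only, and (applied during phasing) removal of
#' sites where more than `max_missing_offspring` offspring across all
#' families lack a phased call.
#'
#' @param min_qual minimum site QUAL.
#' @param min_gq minimum genotype GQ; lower genotypes become missing.
#' @param min_mean_depth minimum across-sample mean DP at a site.
#' @param max_depth_factor multiple of the chromosome median site mean
#'   depth above which a site is dropped (must exceed 1).
#' @param biallelic_only drop sites that are not biallelic SNPs.
#' @param max_missing_offspring most offspring allowed to lack a phased
#'   call before the site is dropped panel-wide.
#' @return list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_qual = 999, min_gq = 20,
                              min_mean_depth = 10, max_depth_factor = 1.5,
                              biallelic_only = TRUE,
                              max_missing_offspring = 5L) {
  check_nonneg(min_qual, "min_qual"); check_nonneg(min_gq, "min_gq")
  check_nonneg(min_mean_depth, "min_mean_depth")
  check_nonneg(max_missing_offspring, "max_missing_offspring")
  if (max_depth_factor <= 1) stopf("max_depth_factor must exceed 1")
  structure(list(min_qual = min_qual, min_gq = min_gq,
                 min_mean_depth = min_mean_depth,
                 max_depth_factor = max_depth_factor,
                 biallelic_only = biallelic_only,
                 max_missing_offspring = as.integer(max_missing_offspring)),
            class = "filter_thresholds")
}

is_biallelic_snp <- function(ref, alt) {
  nchar(ref) == 1L & nchar(alt) == 1L & ref %in% c("A", "C", "G", "T") &
    alt %in% c("A", "C", "G", "T")
}

#' Apply hard variant filters
#'
#' Filters are applied in order: genotypes with GQ below threshold are
#' masked to missing; then sites failing QUAL, biallelic-SNP or minimum
#' mean-depth rules are dropped; finally the high-depth paralog cap is
#' applied against the median of site mean depths among the surviving
#' sites. Site order is preserved. The tally of removals by reason is
#' attached as attribute `"filter_report"` (also see
#' [filter_report()]).
#'
#' @param tab a `variant_table` with QUAL, GQ and DP.
#' @param thresholds a [filter_thresholds()].
#' @return the filtered `variant_table`.
#' @export
filter_variants <- function(tab, thresholds = filter_thresholds()) {
  stopifnot(inherits(tab, "variant_table"))
  if (is.null(tab$dp) || is.null(tab$gq))
    stopf("VCF format error: per-genotype DP and GQ are required for filtering")
  th <- thresholds
  S <- length(tab$pos)
  n_gq_masked <- sum(tab$gq < th$min_gq & tab$gt != "./.", na.rm = TRUE)
  tab$gt[!is.na(tab$gq) & tab$gq < th$min_gq] <- "./."

  keep <- rep(TRUE, S)
  reason <- integer(0)
  drop_for <- function(bad, why) {
    bad <- bad & keep
    reason <<- c(reason, setNames(sum(bad), why))
    keep <<- keep & !bad
  }
  drop_for(is.na(tab$qual) | tab$qual < th$min_qual, "low_qual")
  if (isTRUE(th$biallelic_only))
    drop_for(!is_biallelic_snp(tab$ref, tab$alt), "not_biallelic_snp")
  mean_dp <- rowMeans(tab$dp, na.rm = TRUE)
  drop_for(!is.finite(mean_dp) | mean_dp < th$min_mean_depth, "low_mean_depth")
  med <- median(mean_dp[keep])
  drop_for(mean_dp > th$max_depth_factor * med, "high_mean_depth")

  out <- tab
  for (f in c("pos", "ref", "alt", "qual")) out[[f]] <- tab[[f]][keep]
  for (f in c("gt", "gq", "dp")) out[[f]] <- tab[[f]][keep, , drop = FALSE]
  rep_df <- data.frame(reason = c(names(reason), "gq_masked_genotypes",
                                  "retained_sites"),
                       n = c(unname(reason), n_gq_masked, sum(keep)))
  attr(out, "filter_report") <- rep_df
  out
}

#' @rdname filter_variants
#' @param x a filtered `variant_table`.
#' @export
filter_report <- function(x) attr(x, "filter_report")

# split "a/b" (or "a|b") genotype strings into two integer allele matrices
split_gt <- function(gt) {
  a1 <- suppressWarnings(as.integer(substr(gt, 1L, 1L)))
  a2 <- suppressWarnings(as.integer(substr(gt, 3L, 3L)))
  list(a1 = a1, a2 = a2)
}

#' Phase one trio at one site
#'
#' For a heterozygous child the paternal allele is the child allele that
#' is present in the father and absent in the mother; if no unique such
#' allele exists (e.g. all three genotypes heterozygous) the site is
#' unphasable. A homozygous child trivially received its homozygous
#' allele from the father (flagged as `phased_hom`); a child homozygous
#' for an allele absent from either parent is a Mendelian error. Codes
#' are data, not exceptions.
#'
#' @param father_gt,mother_gt,child_gt genotype strings like `"0/1"`
#'   (`"./."` for missing).
#' @return list with `allele` (integer or `NA`) and `code`, one of
#'   `"phased_het"`, `"phased_hom"`, `"unphasable"`, `"mendel_error"`,
#'   `"uninformative"` (any genotype missing).
#' @export
phase_trio_site <- function(father_gt, mother_gt, child_gt) {
  f <- split_gt(father_gt); m <- split_gt(mother_gt); c <- split_gt(child_gt)
  if (anyNA(c(f$a1, f$a2, m$a1, m$a2, c$a1, c$a2)))
    return(list(allele = NA_integer_, code = "uninformative"))
  fa <- c(f$a1, f$a2); ma <- c(m$a1, m$a2)
  if (c$a1 == c$a2) {
    if (!(c$a1 %in% fa) || !(c$a1 %in% ma))
      return(list(allele = NA_integer_, code = "mendel_error"))
    return(list(allele = c$a1, code = "phased_hom"))
  }
  ca <- c(c$a1, c$a2)
  # a het child needs one allele donatable by each parent
  if (!((ca[1] %in% fa && ca[2] %in% ma) ||
          (ca[2] %in% fa && ca[1] %in% ma)))
    return(list(allele = NA_integer_, code = "mendel_error"))
  cand <- ca[ca %in% fa & !(ca %in% ma)]
  if (length(cand) == 1L)
    return(list(allele = cand, code = "phased_het"))
  list(allele = NA_integer_, code = "unphasable")
}

# vectorised trio phasing over all sites; returns allele vector + code vector
phase_trio_sites <- function(fgt, mgt, cgt) {
  f <- split_gt(fgt); m <- split_gt(mgt); c <- split_gt(cgt)
  S <- length(fgt)
  allele <- rep(NA_integer_, S)
  code <- rep("uninformative", S)
  ok <- !(is.na(f$a1) | is.na(f$a2) | is.na(m$a1) | is.na(m$a2) |
            is.na(c$a1) | is.na(c$a2))
  hom <- ok & c$a1 == c$a2
  in_f <- function(a) a == f$a1 | a == f$a2
  in_m <- function(a) a == m$a1 | a == m$a2
  me_hom <- hom & !(in_f(c$a1) & in_m(c$a1))
  code[hom & !me_hom] <- "phased_hom"
  allele[hom & !me_hom] <- c$a1[hom & !me_hom]
  code[me_hom] <- "mendel_error"
  het <- ok & c$a1 != c$a2
  me_het <- het & !((in_f(c$a1) & in_m(c$a2)) | (in_f(c$a2) & in_m(c$a1)))
  code[me_het] <- "mendel_error"
  het <- het & !me_het
  c1 <- in_f(c$a1) & !in_m(c$a1)
  c2 <- in_f(c$a2) & !in_m(c$a2)
  p1 <- het & c1 & !c2
  p2 <- het & c2 & !c1
  allele[p1] <- c$a1[p1]; allele[p2] <- c$a2[p2]
  code[p1 | p2] <- "phased_het"
  code[het & !(p1 | p2)] <- "unphasable"
  list(allele = allele, code = code)
}

#' Phase paternal haplotypes for a whole pedigree panel
#'
#' Applies the trio rule of [phase_trio_site()] column-wise for every
#' offspring, drops Mendelian-error calls for the affected trio only,
#' and then removes sites where more than
#' `thresholds$max_missing_offspring` offspring across all families are
#' missing a phased call. Sons' paternal haplotypes are labelled Y and
#' daughters' X.
#'
#' @param tab a (filtered) `variant_table`; its `ped` field or the `ped`
#'   argument supplies the pedigree.
#' @param ped pedigree data frame (`child`, `father`, `mother`, `sex`).
#' @param thresholds a [filter_thresholds()]; only
#'   `max_missing_offspring` is used here.
#' @return list of class `phased_panel`: `hap` (offspring x site integer
#'   matrix of paternal alleles, `NA` where unphased), `label` (X/Y per
#'   offspring), `cross` (father id), `positions`, `chrom`, `codes`
#'   (site x offspring provenance codes over retained sites), and
#'   `counts` (sites retained/dropped, calls by code).
#' @export
phase_panel <- function(tab, ped = tab$ped,
                        thresholds = filter_thresholds()) {
  stopifnot(inherits(tab, "variant_table"))
  if (is.null(ped)) stopf("phase_panel needs a pedigree")
  if (anyDuplicated(ped$child))
    stopf("duplicated offspring in pedigree: %s",
          paste(unique(ped$child[duplicated(ped$child)]), collapse = ","))
  miss <- setdiff(unique(c(ped$child, ped$father, ped$mother)), tab$samples)
  if (length(miss))
    stopf("pedigree references samples absent from the table: %s",
          paste(miss, collapse = ","))
  S <- length(tab$pos)
  n_off <- nrow(ped)
  allele <- matrix(NA_integer_, S, n_off, dimnames = list(NULL, ped$child))
  codes <- matrix(NA_character_, S, n_off, dimnames = list(NULL, ped$child))
  for (k in seq_len(n_off)) {
    r <- phase_trio_sites(tab$gt[, ped$father[k]], tab$gt[, ped$mother[k]],
                          tab$gt[, ped$child[k]])
    allele[, k] <- r$allele
    codes[, k] <- r$code
  }
  n_missing <- rowSums(is.na(allele))
  keep <- n_missing <= thresholds$max_missing_offspring
  counts <- list(
    sites_in = S, sites_retained = sum(keep),
    sites_dropped_missingness = sum(!keep),
    calls = table(codes[keep, , drop = FALSE]))
  structure(list(
    hap = t(allele[keep, , drop = FALSE]),
    label = ifelse(ped$sex == "M", "Y", "X"),
    cross = ped$father,
    offspring = ped$child,
    positions = tab$pos[keep],
    chrom = tab$chrom,
    codes = codes[keep, , drop = FALSE],
    counts = counts,
    seed = tab$seed), class = "phased_panel")
}

#' @export
print.phased_panel <- function(x, ...) {
  cat(sprintf(
    "<phased_panel> %s: %d paternal haplotypes (%d X, %d Y) x %d sites\n",
    x$chrom, nrow(x$hap), sum(x$label == "X"), sum(x$label == "Y"),
    ncol(x$hap)))
  cat(sprintf("  sites: %d in, %d retained, %d dropped by missingness\n",
              x$counts$sites_in, x$counts$sites_retained,
              x$counts$sites_dropped_missingness))
  invisible(x)
}

#' Write / read a phased panel as a site-by-haplotype TSV
#'
#' Columns: `pos`, then one column per offspring (`NA` for unphased
#' calls); the header records seed and labels.
#'
#' @param panel a `phased_panel`.
#' @param path file path.
#' @return `write_phased_panel()`: invisibly the path;
#'   `read_phased_panel()`: a `phased_panel` (without provenance codes).
#' @export
write_phased_panel <- function(panel, path) {
  stopifnot(inherits(panel, "phased_panel"))
  con <- file(path, "wt"); on.exit(close(con))
  writeLines(c(ps_header(panel$seed),
               paste0("# chrom=", panel$chrom),
               paste0("# label=", paste(panel$label, collapse = ",")),
               paste0("# cross=", paste(panel$cross, collapse = ","))), con)
  df <- data.frame(pos = panel$positions, t(panel$hap), check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phased_panel
#' @export
read_phased_panel <- function(path) {
  hdr <- readLines(path, n = 20L)
  hdr <- hdr[startsWith(hdr, "#")]
  get <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("# ", key, "="))]
    if (!length(ln)) return(NULL)
    strsplit(sub(paste0("^# ", key, "="), "", ln[1]), ",")[[1]]
  }
  df <- read_tsv_header(path)
  hap <- t(as.matrix(df[, -1]))
  storage.mode(hap) <- "integer"
  structure(list(hap = hap, label = get("label"),
                 cross = get("cross"),
                 offspring = rownames(hap),
                 positions = as.integer(df$pos),
                 chrom = get("chrom") %||% "chr",
                 codes = NULL,
                 counts = list(sites_in = NA,
                               sites_retained = ncol(hap),
                               sites_dropped_missingness = NA),
                 seed = get("seed")), class = "phased_panel")
}
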
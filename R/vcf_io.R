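#' Write a variant table as VCFv4.2
#'
#' Emits biallelic SNP records with `GT:GQ:DP` FORMAT fields, a contig
#' line and provenance (`##parscan_version`, `##parscan_seed`) in the
#' header. INFO is left empty.
#'
#' @param tab a `variant_table` (see [simulate_crosses()]).
#' @param path output file path (plain text, uncompressed).
#' @return invisibly, `path`.
#' @export
write_vcf <- function(tab, path) {
  stopifnot(inherits(tab, "variant_table"))
  S <- length(tab$pos)
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=parscan_v%s", parscan_version()),
    sprintf("##parscan_seed=%s", as.character(tab$seed)),
    sprintf("##contig=<ID=%s,length=%d>", tab$chrom,
            as.integer(tab$chrom_length %||% max(tab$pos))),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype Quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", tab$samples), collapse = "\t"))
  body <- matrix("", S, length(tab$samples))
  for (j in seq_along(tab$samples))
    body[, j] <- paste(tab$gt[, j], tab$gq[, j], tab$dp[, j], sep = ":")
  lines <- paste(tab$chrom, tab$pos, ".", tab$ref, tab$alt,
                 format(tab$qual, trim = TRUE), ".", ".", "GT:GQ:DP",
                 apply(body, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a multi-sample VCF into a variant table
#'
#' Thin wrapper around [VariantAnnotation::readVcf()]. Sites keep their
#' original order; multi-allelic records are retained (ALT joined with
#' commas) so that [filter_variants()] can drop them with an explicit
#' tally. Missing GQ or DP FORMAT fields raise an error because the
#' filtering rules need them.
#'
#' @param path VCF path (plain or bgzipped).
#' @param ped optional pedigree data frame or TSV path with columns
#'   `child`, `father`, `mother`, `sex` to attach to the table.
#' @return a `variant_table`.
#' @export
read_vcf <- function(path, ped = NULL) {
  v <- VariantAnnotation::readVcf(path)
  g <- VariantAnnotation::geno(v)
  if (!all(c("GT", "GQ", "DP") %in% names(g)))
    stopf("VCF format error: FORMAT must contain GT, GQ and DP (found: %s)",
          paste(names(g), collapse = ","))
  rr <- SummarizedExperiment::rowRanges(v)
  alt <- vapply(as.list(rr$ALT), function(a) paste(as.character(a),
                                                   collapse = ","), "")
  gq <- g$GQ; dp <- g$DP
  storage.mode(gq) <- "integer"; storage.mode(dp) <- "integer"
  gt <- g$GT
  gt[gt == "."] <- "./."
  if (is.character(ped) && length(ped) == 1L) ped <- read_pedigree(ped)
  structure(list(
    chrom = as.character(GenomeInfoDb::seqnames(rr))[1],
    pos = as.integer(IRanges::start(rr)),
    ref = as.character(rr$REF),
    alt = alt,
    qual = as.numeric(rr$QUAL),
    gt = unname(gt) |> `dimnames<-`(list(NULL, colnames(gt))),
    gq = unname(gq) |> `dimnames<-`(list(NULL, colnames(gq))),
    dp = unname(dp) |> `dimnames<-`(list(NULL, colnames(dp))),
    samples = colnames(gt),
    ped = ped, seed = NA,
    chrom_length = NA), class = "variant_table")
}

#' Write / read the pedigree TSV (child, father, mother, sex)
#'
#' @param ped data frame with columns `child`, `father`, `mother`, `sex`
#'   (`"M"` for sons, `"F"` for daughters).
#' @param path file path.
#' @return `write_pedigree()`: invisibly the path; `read_pedigree()`:
#'   the pedigree data frame.
#' @export
write_pedigree <- function(ped, path) {
  write.table(ped, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("child", "father", "mother", "sex")
  if (!all(need %in% names(ped)))
    stopf("pedigree must have columns %s", paste(need, collapse = ", "))
  ped
}
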
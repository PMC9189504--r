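# standard genetic code, indexed by codon
GENETIC_CODE_STD <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

BASES <- c("A", "C", "G", "T")

# Nei-Gojobori synonymous site count of one codon: at each position the
# fraction of the three possible changes that preserve the amino acid
# (changes to stop codons count as nonsynonymous).
ng_syn_sites <- function(codon) {
  aa <- GENETIC_CODE_STD[[codon]]
  s <- 0
  cv <- strsplit(codon, "")[[1]]
  for (p in 1:3) {
    for (b in setdiff(BASES, cv[p])) {
      mut <- cv; mut[p] <- b
      if (GENETIC_CODE_STD[[paste(mut, collapse = "")]] == aa) s <- s + 1 / 3
    }
  }
  s
}

# pathway-averaged (equal weights) synonymous/nonsynonymous difference
# counts between two codons
ng_diffs <- function(c1, c2) {
  v1 <- strsplit(c1, "")[[1]]; v2 <- strsplit(c2, "")[[1]]
  dpos <- which(v1 != v2)
  d <- length(dpos)
  if (d == 0L) return(c(sd = 0, nd = 0))
  perms <- switch(d, list(1L), list(1:2, 2:1),
                  list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                       c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  sd <- 0; nd <- 0
  for (ord in perms) {
    cur <- v1
    for (p in dpos[ord]) {
      nxt <- cur; nxt[p] <- v2[p]
      a1 <- GENETIC_CODE_STD[[paste(cur, collapse = "")]]
      a2 <- GENETIC_CODE_STD[[paste(nxt, collapse = "")]]
      if (a1 == a2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
  }
  c(sd = sd / length(perms), nd = nd / length(perms))
}

#' Nei-Gojobori dN/dS between two aligned coding sequences
#'
#' Counts synonymous and nonsynonymous sites (averaged between the two
#' sequences) and differences (averaged with equal weight over all
#' mutational pathways between differing codons), applies the
#' Jukes-Cantor correction `d = -3/4 log(1 - 4/3 p)` when the raw
#' proportion is below 3/4, and reports dN, dS and their ratio. Codons
#' containing ambiguous (non-ACGT) bases in either sequence are
#' skipped; a shared terminal stop codon is ignored; internal stop
#' codons are an error.
#'
#' @param cds_a,cds_b aligned CDS strings of equal length, a multiple
#'   of 3.
#' @param gene optional gene identifier carried into the record.
#' @return list of class `dnds_record` with `gene`, `Nd`, `Sd`,
#'   `N_sites`, `S_sites`, `pn`, `ps`, `dn`, `ds`, `ratio` (NA when
#'   `ds` is 0 or a correction is undefined) and `codons` compared.
#' @export
dnds <- function(cds_a, cds_b, gene = NA_character_) {
  a <- toupper(cds_a); b <- toupper(cds_b)
  if (nchar(a) != nchar(b)) stopf("CDS alignments must have equal length")
  if (nchar(a) %% 3 != 0) stopf("CDS length must be a multiple of 3")
  nc <- nchar(a) / 3
  ca <- substring(a, 3 * seq_len(nc) - 2, 3 * seq_len(nc))
  cb <- substring(b, 3 * seq_len(nc) - 2, 3 * seq_len(nc))
  valid <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb)
  ca <- ca[valid]; cb <- cb[valid]
  if (length(ca) == 0L) stopf("no comparable codons")
  is_stop <- GENETIC_CODE_STD[ca] == "*" | GENETIC_CODE_STD[cb] == "*"
  if (any(is_stop)) {
    if (all(which(is_stop) == length(ca)) &&
        GENETIC_CODE_STD[ca[length(ca)]] == "*" &&
        GENETIC_CODE_STD[cb[length(cb)]] == "*") {
      ca <- ca[-length(ca)]; cb <- cb[-length(cb)]
    } else stopf("internal stop codon in CDS")
  }
  S_sites <- (sum(vapply(ca, ng_syn_sites, 0)) +
                sum(vapply(cb, ng_syn_sites, 0))) / 2
  N_sites <- 3 * length(ca) - S_sites
  dmat <- vapply(seq_along(ca), function(i) ng_diffs(ca[i], cb[i]), c(0, 0))
  Sd <- sum(dmat["sd", ]); Nd <- sum(dmat["nd", ])
  jc <- function(p) if (is.finite(p) && p < 3 / 4 && p >= 0)
    -3 / 4 * log(1 - 4 / 3 * p) else NA_real_
  pn <- if (N_sites > 0) Nd / N_sites else NA_real_
  ps <- if (S_sites > 0) Sd / S_sites else NA_real_
  dn <- jc(pn); ds <- jc(ps)
  ratio <- if (!is.na(dn) && !is.na(ds) && ds > 0) dn / ds else NA_real_
  structure(list(gene = gene, Nd = Nd, Sd = Sd, N_sites = N_sites,
                 S_sites = S_sites, pn = pn, ps = ps, dn = dn, ds = ds,
                 ratio = ratio, codons = length(ca)),
            class = "dnds_record")
}

#' @export
print.dnds_record <- function(x, ...) {
  cat(sprintf("<dnds_record> %s: Nd=%.3g Sd=%.3g N=%.3g S=%.3g dn=%.4g ds=%.4g dn/ds=%s\n",
              x$gene, x$Nd, x$Sd, x$N_sites, x$S_sites,
              x$dn %||% NA, x$ds %||% NA,
              ifelse(is.na(x$ratio), "NA", sprintf("%.4g", x$ratio))))
  invisible(x)
}

#' Extract spliced CDS sequences from a GFF3 annotation and a FASTA
#'
#' Convenience wrapper (requires the rtracklayer and Biostrings
#' packages) returning, per gene or transcript, the concatenated CDS on
#' the coding strand, ready for [dnds()].
#'
#' @param gff_path GFF3 file with CDS features.
#' @param fasta_path reference FASTA.
#' @return named character vector of CDS sequences keyed by the CDS
#'   `Parent` (or `ID`) attribute.
#' @export
extract_cds <- function(gff_path, fasta_path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE) ||
      !requireNamespace("Biostrings", quietly = TRUE))
    stopf("extract_cds requires rtracklayer and Biostrings")
  gff <- rtracklayer::import(gff_path)
  cds <- gff[gff$type == "CDS"]
  if (length(cds) == 0L) stopf("no CDS features in %s", gff_path)
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  key <- vapply(seq_along(cds), function(i) {
    p <- cds$Parent[[i]]
    if (length(p)) as.character(p[1]) else as.character(cds$ID[i])
  }, "")
  out <- vapply(split(seq_along(cds), key), function(idx) {
    g <- cds[idx]
    g <- g[order(GenomicRanges::start(g))]
    seqs <- vapply(seq_along(g), function(k) {
      s <- genome[[as.character(GenomeInfoDb::seqnames(g)[k])]]
      as.character(s[GenomicRanges::start(g)[k]:GenomicRanges::end(g)[k]])
    }, "")
    s <- paste(seqs, collapse = "")
    if (as.character(GenomicRanges::strand(g)[1]) == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    s
  }, "")
  out
}
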
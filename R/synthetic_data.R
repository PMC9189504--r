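#' Configuration for the synthetic sex-chromosome haplotype generator
#'
#' Describes a neo-sex chromosome with a non-recombining sex-determining
#' region (SDR) adjacent to a recombining pseudoautosomal region (PAR),
#' segregating in a focal species that is crossed to a sister species.
#' Defaults mirror a young stickleback-like neo-sex chromosome: a 12.5 Mb
#' chromosome whose SDR ends at 6.9 Mb, about 10 SNPs per 10 kb window
#' among the 30 sampled focal haplotypes, and per-bp divergence between
#' the species of 5e-4.
#'
#' The generator is a parametric mosaic, not an ancestral-recombination
#' graph: per-site derived-allele counts are drawn from a neutral-like
#' 1/i frequency spectrum and X-Y divergence is injected per stratum.
#' This gives fully controlled truth for testing; model-faithful nulls
#' come from the structured-coalescent module instead.
#'
#' @param chrom_length chromosome length in bp.
#' @param sdr_boundary last bp of the SDR; the PAR is
#'   `(sdr_boundary, chrom_length]`. Use 0 for a chromosome that is all PAR.
#' @param snps_per_10kb expected polymorphic sites per 10 kb among the
#'   focal haplotypes (and, separately, among sister haplotypes).
#' @param n_fathers,n_mothers numbers of focal males (each contributing
#'   one X and one Y) and sister-species females (two X each).
#' @param species_divergence per-bp rate of fixed differences between
#'   the species' ancestral sequences.
#' @param strata data frame with columns `start`, `end`,
#'   `y_depth_factor`, `xy_divergence_scale` describing evolutionary
#'   strata inside the SDR. The default is a single young stratum with
#'   no Y degeneration (`y_depth_factor = 1`) and X-Y divergence of the
#'   same order as the species divergence.
#' @param y_polymorphism_share fraction of SDR polymorphic sites that
#'   segregate among Y haplotypes (the rest segregate among X); low
#'   values emulate the diversity-reducing Y sweep.
#' @param chrom chromosome name used in output.
#' @return a list of class `panel_config`.
#' @seealso [simulate_sex_panels()]
#' @export
panel_config <- function(chrom_length = 12.5e6,
                         sdr_boundary = 6.9e6,
                         snps_per_10kb = 10,
                         n_fathers = 15,
                         n_mothers = 13,
                         species_divergence = 5e-4,
                         strata = NULL,
                         y_polymorphism_share = 0.15,
                         chrom = "chrSex") {
  check_positive(chrom_length, "chrom_length")
  check_nonneg(sdr_boundary, "sdr_boundary")
  check_positive(snps_per_10kb, "snps_per_10kb")
  check_positive(n_fathers, "n_fathers")
  check_positive(n_mothers, "n_mothers")
  check_nonneg(species_divergence, "species_divergence")
  check_prob(y_polymorphism_share, "y_polymorphism_share")
  if (sdr_boundary >= chrom_length)
    stopf("invalid config: sdr_boundary must be below chrom_length")
  if (is.null(strata)) {
    strata <- if (sdr_boundary > 0) {
      data.frame(start = 1, end = sdr_boundary,
                 y_depth_factor = 1.0, xy_divergence_scale = 3e-4)
    } else {
      data.frame(start = numeric(0), end = numeric(0),
                 y_depth_factor = numeric(0),
                 xy_divergence_scale = numeric(0))
    }
  }
  strata <- as.data.frame(strata)
  if (nrow(strata) > 0) {
    stopifnot(all(c("start", "end", "y_depth_factor",
                    "xy_divergence_scale") %in% names(strata)))
    if (any(strata$y_depth_factor <= 0 | strata$y_depth_factor > 1))
      stopf("invalid config: y_depth_factor must lie in (0, 1]")
    if (any(strata$xy_divergence_scale < 0))
      stopf("invalid config: xy_divergence_scale must be >= 0")
    if (any(strata$end > sdr_boundary))
      stopf("invalid config: strata must lie inside the SDR")
  }
  structure(list(chrom_length = chrom_length, sdr_boundary = sdr_boundary,
                 snps_per_10kb = snps_per_10kb, n_fathers = n_fathers,
                 n_mothers = n_mothers,
                 species_divergence = species_divergence, strata = strata,
                 y_polymorphism_share = y_polymorphism_share,
                 chrom = chrom),
            class = "panel_config")
}

new_haplotype_panel <- function(hap, positions, label, species, chrom,
                                chrom_length, sdr_boundary, seed = NA) {
  stopifnot(ncol(hap) == length(positions), nrow(hap) == length(label))
  structure(list(hap = hap, positions = as.integer(positions),
                 label = label, species = species, chrom = chrom,
                 chrom_length = chrom_length, sdr_boundary = sdr_boundary,
                 seed = seed),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("<haplotype_panel> %s (%s): %d haplotypes x %d sites [%s]\n",
              x$chrom, x$species, nrow(x$hap), ncol(x$hap),
              paste(sprintf("%s=%d", names(table(x$label)),
                            as.integer(table(x$label))), collapse = ", ")))
  invisible(x)
}

# derived-allele count from a neutral-like 1/i spectrum, 1..n-1 copies
rsfs_count <- function(m, n) {
  i <- seq_len(n - 1L)
  sample(i, m, replace = TRUE, prob = 1 / i)
}

#' Simulate phased X/Y haplotype panels for two species
#'
#' Generates the stated world of the downstream analysis: 15 X and 15 Y
#' haplotypes of a focal species plus 26 X haplotypes of a sister
#' species, on a chromosome with an SDR and a PAR. Inside the PAR the X
#' and Y labels are exchangeable (no SAS unless planted afterwards with
#' [plant_sas_window()]); inside the SDR, fixed X-Y differences are
#' injected per stratum and polymorphism is mostly confined to the X,
#' so X-Y differences exceed within-class differences.
#'
#' @param config a [panel_config()].
#' @param seed integer seed; all randomness flows from it.
#' @return a list of class `sex_panels` with elements `focal` and
#'   `sister` ([new_haplotype_panel()] objects) and `truth` (a
#'   `truth_set`: strata, SDR boundary, planted SAS list, seed).
#' @export
simulate_sex_panels <- function(config = panel_config(), seed = 1L) {
  stopifnot(inherits(config, "panel_config"))
  set.seed(seed)
  L <- config$chrom_length
  nx <- config$n_fathers
  ny <- config$n_fathers
  ns <- 2L * config$n_mothers
  nf <- nx + ny
  lambda <- config$snps_per_10kb / 1e4
  sdr <- config$sdr_boundary

  # site classes, each a Poisson number of unique positions in its region
  draw_pos <- function(rate, lo, hi) {
    if (hi < lo || rate <= 0) return(integer(0))
    n <- rpois(1L, rate * (hi - lo + 1))
    if (n <= 0) return(integer(0))
    sort(sample.int(hi - lo + 1L, min(n, hi - lo + 1L)) + lo - 1L)
  }
  pos_poly_f <- draw_pos(lambda, 1L, L)                 # focal polymorphic
  pos_poly_s <- draw_pos(lambda, 1L, L)                 # sister polymorphic
  pos_div <- draw_pos(config$species_divergence, 1L, L) # fixed between species
  pos_xy <- integer(0)                                  # fixed X vs Y (SDR)
  if (nrow(config$strata) > 0) {
    pos_xy <- sort(unlist(lapply(seq_len(nrow(config$strata)), function(i) {
      draw_pos(config$strata$xy_divergence_scale[i],
               as.integer(config$strata$start[i]),
               as.integer(config$strata$end[i]))
    })))
  }

  cls <- c(rep("poly_f", length(pos_poly_f)), rep("poly_s", length(pos_poly_s)),
           rep("div", length(pos_div)), rep("xy", length(pos_xy)))
  pos <- c(pos_poly_f, pos_poly_s, pos_div, pos_xy)
  keep <- !duplicated(pos)
  pos <- pos[keep]; cls <- cls[keep]
  o <- order(pos); pos <- pos[o]; cls <- cls[o]
  S <- length(pos)

  focal <- matrix(0L, nf, S)
  sister <- matrix(0L, ns, S)
  in_sdr <- pos <= sdr

  idx_pf <- which(cls == "poly_f")
  for (j in idx_pf) {
    if (in_sdr[j]) {
      # post-sweep Y holds little diversity: polymorphism is X- or Y-private
      if (runif(1) < config$y_polymorphism_share) {
        cnt <- rsfs_count(1L, ny)
        focal[nx + sample.int(ny, cnt), j] <- 1L
      } else {
        cnt <- rsfs_count(1L, nx)
        focal[sample.int(nx, cnt), j] <- 1L
      }
    } else {
      cnt <- rsfs_count(1L, nf)
      focal[sample.int(nf, cnt), j] <- 1L
    }
  }
  idx_ps <- which(cls == "poly_s")
  for (j in idx_ps) {
    cnt <- rsfs_count(1L, ns)
    sister[sample.int(ns, cnt), j] <- 1L
  }
  sister[, cls == "div"] <- 1L
  focal[(nx + 1L):nf, cls == "xy"] <- 1L

  label_f <- rep(c("X", "Y"), c(nx, ny))
  truth <- structure(list(
    sdr_boundary_bp = sdr,
    strata = config$strata,
    planted_sas = list(),
    site_class = cls,
    positions = as.integer(pos),
    phase_truth = NULL,
    seed = seed,
    config = config), class = "truth_set")

  structure(list(
    focal = new_haplotype_panel(focal, pos, label_f, "focal", config$chrom,
                                L, sdr, seed),
    sister = new_haplotype_panel(sister, pos, rep("X", ns), "sister",
                                 config$chrom, L, sdr, seed),
    truth = truth), class = "sex_panels")
}

#' Plant a sexually antagonistic signal into a PAR window
#'
#' Sets the X-Y allele-frequency differential to `delta` at sites of one
#' PAR window, emulating a polymorphism maintained by SAS together with
#' the local LD it generates across the (~1 rho wide) window. By default
#' every existing polymorphic site in the window is set to the
#' differential; if the window holds no site, one is created at its
#' midpoint. Windows inside the SDR are refused: there the signal would
#' be confounded with recombination suppression itself.
#'
#' @param panels a `sex_panels` object from [simulate_sex_panels()].
#' @param window numeric `c(start, end)` in bp, half-open.
#' @param delta target `|freq_X - freq_Y|` in `[0, 1]`; `delta = 0`
#'   leaves the panel untouched.
#' @param n_sites number of sites in the window to modify (`"all"` or an
#'   integer).
#' @return the modified `sex_panels` object (truth records the planting).
#' @export
plant_sas_window <- function(panels, window, delta, n_sites = "all") {
  stopifnot(inherits(panels, "sex_panels"), length(window) == 2L)
  check_prob(delta, "delta")
  if (window[1] <= panels$truth$sdr_boundary_bp)
    stopf("refusing to plant SAS inside the SDR (window start %d <= boundary %d)",
          as.integer(window[1]), as.integer(panels$truth$sdr_boundary_bp))
  if (delta == 0) return(panels)
  p <- panels$focal
  nx <- sum(p$label == "X"); ny <- sum(p$label == "Y")
  j <- which(p$positions >= window[1] & p$positions < window[2])
  if (length(j) == 0L) {
    # insert a site at the window midpoint
    mid <- as.integer(floor((window[1] + window[2]) / 2))
    at <- findInterval(mid, p$positions)
    ins_col <- function(m, col, at) {
      cbind(m[, seq_len(at), drop = FALSE], col,
            if (at < ncol(m)) m[, (at + 1L):ncol(m), drop = FALSE])
    }
    p$hap <- ins_col(p$hap, 0L, at)
    panels$sister$hap <- ins_col(panels$sister$hap, 0L, at)
    p$positions <- append(p$positions, mid, after = at)
    panels$sister$positions <- p$positions
    panels$truth$positions <- p$positions
    panels$truth$site_class <- append(panels$truth$site_class, "planted",
                                      after = at)
    j <- at + 1L
  }
  if (!identical(n_sites, "all")) j <- j[seq_len(min(n_sites, length(j)))]
  cx <- as.integer(round(nx * (1 + delta) / 2))
  cy <- as.integer(round(ny * (1 - delta) / 2))
  ix <- which(p$label == "X"); iy <- which(p$label == "Y")
  for (jj in j) {
    p$hap[, jj] <- 0L
    if (cx > 0) p$hap[sample(ix, cx), jj] <- 1L
    if (cy > 0) p$hap[sample(iy, cy), jj] <- 1L
  }
  panels$focal <- p
  panels$truth$planted_sas <- c(panels$truth$planted_sas,
                                list(list(window = as.numeric(window),
                                          delta = delta,
                                          sites = p$positions[j])))
  panels
}

#' Pedigree cross design
#'
#' The default reproduces the study design the pipeline assumes: 15
#' interspecies crosses between focal-species fathers and sister-species
#' mothers, with 13 distinct mothers (one used three times), and one son
#' plus one daughter sequenced per cross: 15 + 13 + 30 = 58 individuals.
#'
#' @param n_crosses number of crosses (= fathers).
#' @param n_mothers number of distinct mothers.
#' @param mother_of_cross integer vector of length `n_crosses` giving the
#'   mother used in each cross; default reuses mother 1 three times.
#' @param mean_depth mean sequencing depth per individual (default 28,
#'   a typical short-read resequencing coverage).
#' @param depth_size negative-binomial size (overdispersion) of
#'   per-genotype depth.
#' @param depth_indiv_cv lognormal CV of per-individual mean depth
#'   (library-size variation).
#' @param error_rate per-genotype probability that one allele is
#'   miscalled.
#' @param missing_rate per-genotype missingness probability.
#' @param seed integer seed.
#' @return list of class `cross_design`.
#' @export
cross_design <- function(n_crosses = 15L, n_mothers = 13L,
                         mother_of_cross = NULL,
                         mean_depth = 28, depth_size = 8,
                         depth_indiv_cv = 0.15,
                         error_rate = 0.002, missing_rate = 0.02,
                         seed = 1L) {
  check_positive(n_crosses, "n_crosses")
  check_positive(n_mothers, "n_mothers")
  if (n_mothers > n_crosses)
    stopf("invalid config: more mothers than crosses")
  if (is.null(mother_of_cross))
    mother_of_cross <- c(rep(1L, n_crosses - n_mothers + 1L),
                         seq_len(n_mothers)[-1L])
  stopifnot(length(mother_of_cross) == n_crosses,
            all(mother_of_cross %in% seq_len(n_mothers)))
  check_positive(mean_depth, "mean_depth")
  check_prob(error_rate, "error_rate")
  check_prob(missing_rate, "missing_rate")
  d <- structure(list(n_crosses = as.integer(n_crosses),
                      n_mothers = as.integer(n_mothers),
                      mother_of_cross = as.integer(mother_of_cross),
                      mean_depth = mean_depth, depth_size = depth_size,
                      depth_indiv_cv = depth_indiv_cv,
                      error_rate = error_rate, missing_rate = missing_rate,
                      seed = as.integer(seed)),
                 class = "cross_design")
  d$n_individuals <- d$n_crosses + d$n_mothers + 2L * d$n_crosses
  d
}

#' Simulate pedigree crosses and genotype them into a variant table
#'
#' Transmits haplotypes through the cross design (sons receive the
#' father's Y, daughters the father's X, both receive one maternal
#' haplotype), then layers on the observation model: per-genotype depth
#' (negative-binomial per haplotype, with the Y contribution scaled by
#' the stratum's `y_depth_factor` in males), genotype qualities, allele
#' miscalls and missingness. Phase truth is recorded before noise.
#'
#' @param panels `sex_panels` from [simulate_sex_panels()].
#' @param design a [cross_design()].
#' @param seed seed; defaults to `design$seed`.
#' @return list with `table` (a `variant_table`) and `truth` (the input
#'   truth set with `phase_truth` filled in: a site x offspring matrix
#'   of transmitted paternal alleles).
#' @export
simulate_crosses <- function(panels, design = cross_design(),
                             seed = design$seed) {
  stopifnot(inherits(panels, "sex_panels"), inherits(design, "cross_design"))
  fo <- panels$focal; si <- panels$sister
  nc <- design$n_crosses
  ix <- which(fo$label == "X"); iy <- which(fo$label == "Y")
  if (nc > length(ix) || nc > length(iy))
    stopf("design requests %d crosses but only %d father haplotype pairs available",
          nc, min(length(ix), length(iy)))
  if (2L * design$n_mothers > nrow(si$hap))
    stopf("design requests %d mothers but only %d sister haplotypes available",
          design$n_mothers, nrow(si$hap))
  set.seed(seed)
  S <- ncol(fo$hap)
  pos <- fo$positions

  fathers <- sprintf("F%02d", seq_len(nc))
  mothers <- sprintf("M%02d", seq_len(design$n_mothers))
  sons <- sprintf("S%02d", seq_len(nc))
  daughters <- sprintf("D%02d", seq_len(nc))
  samples <- c(fathers, mothers, sons, daughters)
  N <- length(samples)

  ped <- data.frame(
    child = c(sons, daughters),
    father = c(fathers, fathers),
    mother = c(mothers[design$mother_of_cross],
               mothers[design$mother_of_cross]),
    sex = rep(c("M", "F"), each = nc),
    stringsAsFactors = FALSE)

  # haplotype pair (site x individual): A1 maternal-side, A2 paternal-side
  A1 <- matrix(0L, S, N, dimnames = list(NULL, samples))
  A2 <- A1
  is_y_hap2 <- logical(N)          # whether A2 is a Y haplotype (males)
  names(is_y_hap2) <- samples
  for (i in seq_len(nc)) {
    A1[, fathers[i]] <- fo$hap[ix[i], ]
    A2[, fathers[i]] <- fo$hap[iy[i], ]
    is_y_hap2[fathers[i]] <- TRUE
  }
  for (m in seq_len(design$n_mothers)) {
    A1[, mothers[m]] <- si$hap[2L * m - 1L, ]
    A2[, mothers[m]] <- si$hap[2L * m, ]
  }
  phase_truth <- matrix(NA_integer_, S, 2L * nc,
                        dimnames = list(NULL, c(sons, daughters)))
  for (i in seq_len(nc)) {
    m <- design$mother_of_cross[i]
    mat_s <- if (runif(1) < 0.5) si$hap[2L * m - 1L, ] else si$hap[2L * m, ]
    mat_d <- if (runif(1) < 0.5) si$hap[2L * m - 1L, ] else si$hap[2L * m, ]
    A1[, sons[i]] <- mat_s;       A2[, sons[i]] <- fo$hap[iy[i], ]
    A1[, daughters[i]] <- mat_d;  A2[, daughters[i]] <- fo$hap[ix[i], ]
    is_y_hap2[sons[i]] <- TRUE
    phase_truth[, sons[i]] <- fo$hap[iy[i], ]
    phase_truth[, daughters[i]] <- fo$hap[ix[i], ]
  }

  # depth: per-haplotype negative binomial; Y haplotypes thinned in
  # degenerate strata
  indiv_mean <- design$mean_depth *
    rlnorm(N, -design$depth_indiv_cv^2 / 2, design$depth_indiv_cv)
  yfac <- rep(1, S)
  st <- panels$truth$strata
  if (nrow(st) > 0) {
    for (k in seq_len(nrow(st)))
      yfac[pos >= st$start[k] & pos <= st$end[k]] <- st$y_depth_factor[k]
  }
  mu1 <- outer(rep(1, S), indiv_mean / 2)
  mu2 <- mu1
  mu2[, is_y_hap2] <- mu2[, is_y_hap2] * yfac
  DP <- matrix(rnbinom(S * N, mu = mu1, size = design$depth_size), S, N) +
    matrix(rnbinom(S * N, mu = mu2, size = design$depth_size), S, N)
  colnames(DP) <- samples
  GQ <- matrix(pmin(99L, rpois(S * N, 70)), S, N, dimnames = list(NULL, samples))

  # observation noise applied after truth is recorded
  err <- matrix(runif(S * N) < design$error_rate, S, N)
  flip <- matrix(sample(c(TRUE, FALSE), S * N, replace = TRUE), S, N)
  E1 <- A1; E2 <- A2
  E1[err & flip] <- 1L - E1[err & flip]
  E2[err & !flip] <- 1L - E2[err & !flip]
  gt <- matrix(paste(pmin(E1, E2), pmax(E1, E2), sep = "/"), S, N,
               dimnames = list(NULL, samples))
  gt[matrix(runif(S * N) < design$missing_rate, S, N)] <- "./."

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, S, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")

  tab <- structure(list(
    chrom = fo$chrom, pos = pos, ref = ref, alt = unname(alt),
    qual = rep(999, S), gt = gt, gq = GQ, dp = DP,
    samples = samples, ped = ped, seed = seed,
    chrom_length = fo$chrom_length), class = "variant_table")
  truth <- panels$truth
  truth$phase_truth <- phase_truth
  list(table = tab, truth = truth)
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("<variant_table> %s: %d sites x %d samples\n",
              x$chrom, length(x$pos), length(x$samples)))
  invisible(x)
}

#' Write the truth tables of a synthetic data set as TSV
#'
#' Writes `*_phase_truth.tsv` (site x offspring paternal alleles),
#' `*_planted.tsv` and `*_strata.tsv`, each with a provenance header.
#'
#' @param truth a `truth_set` with phase truth filled in.
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
write_truth_set <- function(truth, prefix) {
  h <- config_hash(truth$config %||% list())
  paths <- character(0)
  if (!is.null(truth$phase_truth)) {
    df <- data.frame(pos = truth$positions, truth$phase_truth,
                     check.names = FALSE)
    p <- paste0(prefix, "_phase_truth.tsv")
    write_tsv_header(df, p, truth$seed, h); paths <- c(paths, p)
  }
  pl <- truth$planted_sas
  df <- if (length(pl)) data.frame(
    start = vapply(pl, function(z) z$window[1], 0),
    end = vapply(pl, function(z) z$window[2], 0),
    delta = vapply(pl, function(z) z$delta, 0),
    n_sites = vapply(pl, function(z) length(z$sites), 0L))
  else data.frame(start = numeric(0), end = numeric(0),
                  delta = numeric(0), n_sites = integer(0))
  p <- paste0(prefix, "_planted.tsv")
  write_tsv_header(df, p, truth$seed, h); paths <- c(paths, p)
  p <- paste0(prefix, "_strata.tsv")
  write_tsv_header(truth$strata, p, truth$seed, h); paths <- c(paths, p)
  invisible(paths)
}
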
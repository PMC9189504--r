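#' End-to-end pipeline configuration
#'
#' Bundles the per-module configurations with a global seed and output
#' directory. The defaults are desk-scale: 10^4 permutations per window
#' and 100 calibration simulations; raise `scan$n_perm` to 10^6 and
#' `n_calib_sims` to 1000 for the full published protocol.
#'
#' @param out_dir output directory (created if needed).
#' @param seed global seed; every stage derives its stream from it.
#' @param generator a [panel_config()].
#' @param design a [cross_design()].
#' @param thresholds a [filter_thresholds()].
#' @param scan a [scan_config()].
#' @param coal a [coal_params()] template for calibration.
#' @param planted list of `list(window = c(start, end), delta = d)`
#'   SAS signals to plant.
#' @param n_calib_sims,calib_n_perm,calib_rate calibration scale: null
#'   scans, permutations per simulated window, familywise rate.
#' @param scaling a [rho_scaling()] converting window positions to rho
#'   distances from the SDR for calibration.
#' @param stats_window,tree_window window sizes for the statistics
#'   stage.
#' @param verbose print stage progress.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("parscan_"), seed = 1L,
                            generator = panel_config(),
                            design = cross_design(),
                            thresholds = filter_thresholds(),
                            scan = scan_config(n_perm = 1e4),
                            coal = coal_params(),
                            planted = list(),
                            n_calib_sims = 100L, calib_n_perm = 1000L,
                            calib_rate = 0.2,
                            scaling = rho_scaling(),
                            stats_window = 1e4, tree_window = 1e5,
                            verbose = TRUE) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 generator = generator, design = design,
                 thresholds = thresholds, scan = scan, coal = coal,
                 planted = planted, n_calib_sims = as.integer(n_calib_sims),
                 calib_n_perm = as.integer(calib_n_perm),
                 calib_rate = calib_rate, scaling = scaling,
                 stats_window = stats_window, tree_window = tree_window,
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Compare model-free FDR calls with simulation-calibrated calls
#'
#' Annotates a scan result with significance under the
#' coalescent-calibrated familywise critical p-value and flags
#' agreement per window. The model-free q-value calls ask "is this
#' window extreme given label exchangeability"; the calibrated calls
#' ask the stricter "is it extreme given the demographic history and
#' the Y sweep".
#'
#' @param model_free a `scan_result` from [scan_focal_region()].
#' @param p_star calibrated critical p-value from
#'   [calibrate_critical_p()].
#' @return data.table: per window `significant_q`, `significant_pstar`
#'   and `agree`.
#' @export
compare_calls <- function(model_free, p_star) {
  stopifnot(inherits(model_free, "scan_result"))
  check_prob(p_star, "p_star")
  out <- data.table::data.table(
    start = model_free$start, end = model_free$end,
    p_emp = model_free$p_emp, q_value = model_free$q_value,
    significant_q = model_free$significant,
    significant_pstar = model_free$p_emp <= p_star)
  out$agree <- out$significant_q == out$significant_pstar
  out
}

#' Run the full synthetic pipeline
#'
#' synthesize -> write VCF/pedigree -> read back -> filter -> phase ->
#' windowed statistics (with SDR/PAR boundary detection) -> focal-region
#' permutation scan -> coalescent null calibration -> comparison report.
#' Any stage failure aborts with a stage-tagged error; outputs written
#' before the failure are preserved. A machine-readable `summary.json`
#' (deterministic for a given config and seed) is written last.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the summary list.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(lapply(unclass(config)[setdiff(names(config),
                                                     c("out_dir", "verbose"))],
                             unclass))
  say <- function(...) if (config$verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage [%s] failed: %s", name, conditionMessage(e)))
  }
  pth <- function(f) file.path(config$out_dir, f)

  say("stage synthesize")
  sim <- stage("synthesize", {
    panels <- simulate_sex_panels(config$generator,
                                  seed = derive_seed(config$seed, 1L))
    for (pl in config$planted)
      panels <- plant_sas_window(panels, pl$window, pl$delta)
    cr <- simulate_crosses(panels, config$design,
                           seed = derive_seed(config$seed, 2L))
    write_vcf(cr$table, pth("crosses.vcf"))
    write_pedigree(cr$table$ped, pth("pedigree.tsv"))
    write_truth_set(cr$truth, pth("truth"))
    writeLines(jsonlite::toJSON(list(seed = config$seed,
                                     config_hash = hash),
                                auto_unbox = TRUE), pth("config_echo.json"))
    c(cr, list(panels = panels))
  })

  say("stage phase")
  phased <- stage("phase", {
    tab <- read_vcf(pth("crosses.vcf"), ped = pth("pedigree.tsv"))
    tab$seed <- config$seed
    ft <- filter_variants(tab, config$thresholds)
    pp <- phase_panel(ft, thresholds = config$thresholds)
    write_phased_panel(pp, pth("phased.tsv"))
    write_tsv_header(filter_report(ft), pth("filter_report.tsv"),
                     config$seed, hash)
    list(panel = pp, table = ft)
  })

  say("stage stats")
  wstats <- stage("stats", {
    ws <- window_stats(phased$panel, tab = phased$table,
                       chrom_length = config$generator$chrom_length,
                       size = config$stats_window,
                       tree_size = config$tree_window)
    write_tsv_header(as.data.frame(ws), pth("window_stats.tsv"),
                     config$seed, hash)
    ws
  })
  boundary <- stage("stats", {
    tw <- make_windows(config$generator$chrom_length, config$tree_window)
    cons <- vapply(seq_len(nrow(tw)), function(k)
      gene_tree_consistency(phased$panel,
                            window = c(tw$start[k], tw$end[k]))$consistent,
      NA)
    detect_boundary(cons, tw$start)
  })

  say("stage scan")
  scan_cfg <- config$scan
  scan_cfg$seed <- derive_seed(config$seed, 3L)
  scan <- stage("scan", {
    sc <- scan_focal_region(phased$panel, scan_cfg)
    write_scan_result(sc, pth("scan.tsv"), chrom = config$generator$chrom)
    sc
  })

  say("stage calibrate (%d null scans)", config$n_calib_sims)
  calib <- stage("calibrate", {
    if (nrow(scan) == 0) list(p_star = NA_real_, min_p = numeric(0))
    else {
      dist_rho <- physical_to_rho(
        pmax(scan$start - config$generator$sdr_boundary, 0), config$scaling)
      minp <- simulate_null_scans(config$coal, dist_rho,
                                  n_sim = config$n_calib_sims,
                                  n_perm = config$calib_n_perm,
                                  seed = derive_seed(config$seed, 4L))
      p_star <- calibrate_critical_p(minp, config$calib_rate)
      write_tsv_header(data.frame(min_p = minp), pth("null_min_p.tsv"),
                       config$seed, hash)
      list(p_star = p_star, min_p = minp)
    }
  })

  say("stage report")
  summary <- stage("report", {
    cmp <- if (nrow(scan) > 0) compare_calls(scan, calib$p_star %||% 0)
           else NULL
    if (!is.null(cmp))
      write_tsv_header(as.data.frame(cmp), pth("calls_comparison.tsv"),
                       config$seed, hash)
    planted_windows <- lapply(sim$truth$planted_sas, function(z)
      list(start = z$window[1], end = z$window[2], delta = z$delta))
    sig <- scan[scan$significant, ]
    planted_recovered <- vapply(planted_windows, function(pw)
      any(sig$start < pw$end & sig$end > pw$start), NA)
    s <- list(
      version = parscan_version(), seed = config$seed, config_hash = hash,
      n_sites_simulated = length(sim$table$pos),
      n_sites_phased = phased$panel$counts$sites_retained,
      boundary_truth_bp = config$generator$sdr_boundary,
      boundary_detected_bp = boundary$boundary_bp,
      n_windows_tested = nrow(scan),
      n_significant_q = sum(scan$significant),
      p_star = calib$p_star,
      n_significant_pstar = if (nrow(scan)) sum(scan$p_emp <= (calib$p_star %||% 0))
                            else 0L,
      planted = planted_windows,
      planted_recovered = as.list(planted_recovered))
    writeLines(jsonlite::toJSON(s, auto_unbox = TRUE, digits = NA,
                                null = "null", pretty = TRUE),
               pth("summary.json"))
    s
  })
  invisible(summary)
}
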
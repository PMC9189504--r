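test_that("invalid generator configurations are rejected", {
  expect_error(panel_config(chrom_length = -1), "positive")
  expect_error(panel_config(snps_per_10kb = 0), "positive")
  expect_error(panel_config(sdr_boundary = 2e6, chrom_length = 1e6),
               "below chrom_length")
  expect_error(panel_config(strata = data.frame(
    start = 1, end = 1e5, y_depth_factor = 0, xy_divergence_scale = 0),
    sdr_boundary = 2e5), "y_depth_factor")
})

test_that("polymorphic site count follows the configured Poisson intensity", {
  cfg <- panel_config(chrom_length = 1e6, sdr_boundary = 0,
                      snps_per_10kb = 10)
  panels <- simulate_sex_panels(cfg, seed = 21)
  cnt <- colSums(panels$focal$hap)
  n_poly <- sum(cnt > 0 & cnt < nrow(panels$focal$hap))
  expect_gt(n_poly, 1000 - 3 * sqrt(1000))
  expect_lt(n_poly, 1000 + 3 * sqrt(1000))
})

test_that("X and Y labels are exchangeable in the PAR without planted SAS", {
  cfg <- panel_config(chrom_length = 2e6, sdr_boundary = 0,
                      snps_per_10kb = 10)
  panels <- simulate_sex_panels(cfg, seed = 22)
  w <- make_windows(2e6, 1e4)
  fst <- vapply(seq_len(nrow(w)), function(k)
    window_fst(panels$focal, window = c(w$start[k], w$end[k])), 0)
  expect_equal(length(fst), 200)
  expect_lt(mean(fst, na.rm = TRUE), 0.05)
})

test_that("zero species divergence plants no fixed interspecies differences", {
  cfg <- panel_config(chrom_length = 5e5, sdr_boundary = 0,
                      species_divergence = 0)
  panels <- simulate_sex_panels(cfg, seed = 23)
  expect_equal(sum(panels$truth$site_class == "div"), 0)
  # the divergence component of K is exactly zero: restricted to
  # fixed-difference sites Dxy vanishes (segregating variation still
  # contributes to the all-pairs Dxy, as it does in real data)
  div_sites <- panels$truth$positions[panels$truth$site_class == "div"]
  expect_length(div_sites, 0)
  # turning divergence on raises K by the configured per-bp scale
  cfg2 <- panel_config(chrom_length = 5e5, sdr_boundary = 0,
                       species_divergence = 5e-4)
  p2 <- simulate_sex_panels(cfg2, seed = 23)
  k0 <- window_dxy(panels$focal, panels$sister, len = 5e5)
  k1 <- window_dxy(p2$focal, p2$sister, len = 5e5)
  expect_equal(k1 - k0, 5e-4, tolerance = 0.15)
})

test_that("the SDR carries X-Y differentiation exceeding within-class variation", {
  cfg <- panel_config(chrom_length = 1e6, sdr_boundary = 5e5)
  panels <- simulate_sex_panels(cfg, seed = 24)
  ix <- panels$focal$label == "X"
  sdr <- c(1, 5e5); par <- c(5e5 + 1, 1e6)
  k_xy_sdr <- window_dxy(panels$focal$hap[ix, ], panels$focal$hap[!ix, ],
                         positions = panels$focal$positions, window = sdr)
  pi_sdr <- window_pi(panels$focal$hap[!ix, ],
                      positions = panels$focal$positions, window = sdr)
  expect_gt(k_xy_sdr, 2 * pi_sdr)
  expect_gt(window_fst(panels$focal, window = sdr), 0.5)
  expect_lt(window_fst(panels$focal, window = par), 0.1)
})

test_that("plant_sas_window sets the frequency differential and nothing else", {
  cfg <- panel_config(chrom_length = 1e6, sdr_boundary = 2e5)
  base <- simulate_sex_panels(cfg, seed = 25)
  win <- c(600001, 610001)
  # delta = 0 leaves the panel untouched
  expect_identical(plant_sas_window(base, win, 0)$focal$hap,
                   base$focal$hap)
  # delta = 1 creates a fixed X-Y difference: site FST = 1
  p1 <- plant_sas_window(base, win, 1)
  j <- which(p1$focal$positions >= win[1] & p1$focal$positions < win[2])
  ix <- p1$focal$label == "X"
  fx <- colMeans(p1$focal$hap[ix, j, drop = FALSE])
  fy <- colMeans(p1$focal$hap[!ix, j, drop = FALSE])
  expect_true(all(abs(fx - fy) == 1))
  expect_equal(window_fst(p1$focal, window = win), 1)
  # other windows untouched
  out <- p1$focal$positions < win[1] | p1$focal$positions >= win[2]
  expect_identical(p1$focal$hap[, out], base$focal$hap[, out])
  # delta = 0.8 within rounding given 15+15 haplotypes
  p08 <- plant_sas_window(base, win, 0.8)
  j8 <- which(p08$focal$positions >= win[1] & p08$focal$positions < win[2])
  dd <- abs(colMeans(p08$focal$hap[ix, j8, drop = FALSE]) -
              colMeans(p08$focal$hap[!ix, j8, drop = FALSE]))
  expect_true(all(abs(dd - 0.8) <= 1 / 15 + 1e-9))
  # refused inside the SDR
  expect_error(plant_sas_window(base, c(100001, 110001), 0.5),
               "refusing to plant")
  expect_error(plant_sas_window(base, win, 1.2), "delta")
})

test_that("a delta-0.8 window exceeds the 99th percentile of neutral windows", {
  cfg <- panel_config(chrom_length = 2e6, sdr_boundary = 0)
  panels <- plant_sas_window(simulate_sex_panels(cfg, seed = 26),
                             c(1500001, 1510001), 0.8)
  w <- make_windows(2e6, 1e4)
  fst <- vapply(seq_len(nrow(w)), function(k)
    window_fst(panels$focal, window = c(w$start[k], w$end[k])), 0)
  planted <- which(w$start == 1500001)
  expect_gt(fst[planted],
            quantile(fst[-planted], 0.99, na.rm = TRUE))
})

test_that("window FST is non-decreasing in the planted differential", {
  deltas <- c(0, 0.4, 0.8, 1.0)
  means <- sapply(deltas, function(d) {
    mean(sapply(1:50, function(s) {
      cfg <- panel_config(chrom_length = 1e5, sdr_boundary = 0)
      p <- simulate_sex_panels(cfg, seed = 700 + s)
      if (d > 0) p <- plant_sas_window(p, c(40001, 50001), d)
      max(0, window_fst(p$focal, window = c(40001, 50001)))
    }))
  })
  expect_true(all(diff(means) >= 0))
})

test_that("the default cross design reproduces the 58-individual study shape", {
  d <- cross_design()
  expect_equal(d$n_crosses, 15L)
  expect_equal(d$n_mothers, 13L)
  expect_equal(d$n_individuals, 58L)
  expect_equal(sum(d$mother_of_cross == 1L), 3L)   # one mother used thrice
  expect_error(cross_design(n_crosses = 5, n_mothers = 13), "more mothers")
})

test_that("simulate_crosses writes 58 VCF sample columns and valid truth", {
  cfg <- panel_config(chrom_length = 1e5, sdr_boundary = 0)
  panels <- simulate_sex_panels(cfg, seed = 27)
  cr <- simulate_crosses(panels, cross_design(seed = 27))
  expect_equal(length(cr$table$samples), 58L)
  expect_equal(dim(cr$truth$phase_truth),
               c(length(cr$table$pos), 30L))
  # sons carry the father's Y haplotype, daughters the X, in truth
  iy <- which(panels$focal$label == "Y")
  expect_identical(cr$truth$phase_truth[, "S03"], panels$focal$hap[iy[3], ])
  expect_error(simulate_crosses(panels, cross_design(n_crosses = 40,
                                                     n_mothers = 13)),
               "crosses")
})

test_that("Y depth thinning yields the mixture-expected son/daughter ratio", {
  cfg <- panel_config(
    chrom_length = 4e5, sdr_boundary = 2e5, snps_per_10kb = 30,
    strata = data.frame(start = 1, end = 2e5, y_depth_factor = 0.5,
                        xy_divergence_scale = 3e-4))
  panels <- simulate_sex_panels(cfg, seed = 28)
  cr <- simulate_crosses(panels, cross_design(seed = 28))
  r_stratum <- depth_ratio(cr$table, window = c(1, 2e5))
  r_par <- depth_ratio(cr$table, window = c(2e5 + 1, 4e5))
  # one of the son's two haplotypes at half depth: (1 + 0.5)/2 = 0.75,
  # relative to the PAR baseline
  expect_equal(r_stratum / r_par, 0.75, tolerance = 0.04)
})

test_that("truth tables and config echo are written with headers", {
  cfg <- panel_config(chrom_length = 5e4, sdr_boundary = 0)
  panels <- plant_sas_window(simulate_sex_panels(cfg, seed = 29),
                             c(20001, 30001), 0.6)
  cr <- simulate_crosses(panels, cross_design(seed = 29))
  pre <- tempfile()
  paths <- write_truth_set(cr$truth, pre)
  expect_true(all(file.exists(paths)))
  planted <- utils::read.table(
    paste0(pre, "_planted.tsv"), header = TRUE, sep = "\t",
    comment.char = "#")
  expect_equal(planted$delta, 0.6)
  expect_true(any(grepl("^# seed=", readLines(paths[1], n = 3))))
  unlink(paths)
})
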
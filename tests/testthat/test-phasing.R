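samples4 <- c("F01", "M01", "S01", "D01")
ped1 <- data.frame(child = c("S01", "D01"), father = "F01", mother = "M01",
                   sex = c("M", "F"), stringsAsFactors = FALSE)

test_that("filter_variants applies each hard filter with a tally", {
  gt <- matrix("0/1", 6, 4, dimnames = list(NULL, samples4))
  tab <- make_table(gt, qual = c(999, 998, 999, 999, 999, 1200),
                    alt = c("G", "G", "G,T", "G", "G", "G"),
                    dp = matrix(c(rep(20L, 4 * 3),
                                  rep(5L, 4),      # mean depth 5 < 10
                                  rep(31L, 4),     # 31 > 1.5 * median(20)
                                  rep(20L, 4)), 6, 4, byrow = TRUE))
  ft <- filter_variants(tab)
  expect_equal(ft$pos, c(1L, 6L))
  rep_df <- filter_report(ft)
  get <- function(r) rep_df$n[rep_df$reason == r]
  expect_equal(get("low_qual"), 1)
  expect_equal(get("not_biallelic_snp"), 1)
  expect_equal(get("low_mean_depth"), 1)
  expect_equal(get("high_mean_depth"), 1)
  expect_equal(get("retained_sites"), 2)
})

test_that("genotypes below the GQ threshold become missing", {
  gt <- matrix("0/1", 4, 4, dimnames = list(NULL, samples4))
  gq <- matrix(99L, 4, 4); gq[2, 3] <- 19L
  tab <- make_table(gt, gq = gq)
  ft <- filter_variants(tab)
  expect_equal(unname(ft$gt[2, 3]), "./.")
  expect_equal(sum(ft$gt == "./."), 1)
})

test_that("missing DP/GQ is an explicit format error", {
  gt <- matrix("0/1", 3, 4, dimnames = list(NULL, samples4))
  tab <- make_table(gt)
  tab$dp <- NULL
  expect_error(filter_variants(tab), "DP and GQ")
})

test_that("phase_trio_site implements the paternal-allele rule and codes", {
  # father A/G (0/1), mother A/A (0/0), child A/G -> paternal G (=1)
  r <- phase_trio_site("0/1", "0/0", "0/1")
  expect_equal(r$allele, 1L); expect_equal(r$code, "phased_het")
  # all heterozygous -> unphasable
  r <- phase_trio_site("0/1", "0/1", "0/1")
  expect_true(is.na(r$allele)); expect_equal(r$code, "unphasable")
  # child homozygous for an allele absent in a parent -> mendel error
  r <- phase_trio_site("0/0", "0/0", "1/1")
  expect_equal(r$code, "mendel_error")
  # homozygous child with compatible parents -> trivially transmitted
  r <- phase_trio_site("0/1", "0/1", "0/0")
  expect_equal(r$allele, 0L); expect_equal(r$code, "phased_hom")
  # fixed interspecies difference: father 1/1, mother 0/0, child het
  r <- phase_trio_site("1/1", "0/0", "0/1")
  expect_equal(r$allele, 1L); expect_equal(r$code, "phased_het")
  # missing genotype -> uninformative
  r <- phase_trio_site("./.", "0/0", "0/1")
  expect_equal(r$code, "uninformative")
  # heterozygous child carrying an allele absent from both parents
  r <- phase_trio_site("0/0", "0/0", "0/1")
  expect_equal(r$code, "mendel_error")
})

test_that("vectorised trio phasing agrees with the scalar rule", {
  gts <- c("0/0", "0/1", "1/1", "./.")
  grid <- expand.grid(f = gts, m = gts, c = gts, stringsAsFactors = FALSE)
  vec <- parscan:::phase_trio_sites(grid$f, grid$m, grid$c)
  for (i in seq_len(nrow(grid))) {
    r <- phase_trio_site(grid$f[i], grid$m[i], grid$c[i])
    expect_identical(vec$code[i], r$code,
                     label = paste(grid[i, ], collapse = " "))
    expect_identical(vec$allele[i], r$allele)
  }
})

test_that("phase_panel drops sites by the offspring-missingness rule", {
  # 30 offspring across 15 crosses; sites differ in number of missing calls
  cfg <- panel_config(chrom_length = 5e4, sdr_boundary = 0,
                      snps_per_10kb = 20)
  panels <- simulate_sex_panels(cfg, seed = 2)
  cr <- simulate_crosses(panels, cross_design(error_rate = 0,
                                              missing_rate = 0, seed = 2))
  tab <- cr$table
  # site 1: exactly 6 offspring missing -> dropped; site 2: 5 -> retained
  offspring <- tab$ped$child
  tab$gt[1, offspring[1:6]] <- "./."
  tab$gt[2, offspring[1:5]] <- "./."
  pp <- phase_panel(tab)
  expect_false(tab$pos[1] %in% pp$positions)
  expect_true(tab$pos[2] %in% pp$positions)
})

test_that("noiseless crosses phase to the recorded truth exactly", {
  cfg <- panel_config(chrom_length = 2e5, sdr_boundary = 5e4)
  panels <- simulate_sex_panels(cfg, seed = 11)
  cr <- simulate_crosses(panels, cross_design(error_rate = 0,
                                              missing_rate = 0, seed = 11))
  pp <- phase_panel(cr$table)
  est <- t(pp$hap)
  tru <- cr$truth$phase_truth[match(pp$positions, cr$table$pos),
                              colnames(est)]
  ok <- !is.na(est)
  expect_gt(sum(ok), 1000)
  expect_identical(sum(est[ok] != tru[ok]), 0L)
  # labels follow offspring sex
  expect_identical(pp$label, ifelse(cr$table$ped$sex == "M", "Y", "X"))
})

test_that("phasing never invents alleles absent from the father", {
  cfg <- panel_config(chrom_length = 1e5, sdr_boundary = 0)
  panels <- simulate_sex_panels(cfg, seed = 4)
  cr <- simulate_crosses(panels, cross_design(error_rate = 0.05,
                                              missing_rate = 0.05, seed = 4))
  pp <- phase_panel(cr$table)
  ped <- cr$table$ped
  keep <- match(pp$positions, cr$table$pos)
  for (k in seq_len(nrow(ped))) {
    fgt <- parscan:::split_gt(cr$table$gt[keep, ped$father[k]])
    al <- pp$hap[k, ]
    ok <- !is.na(al) & !is.na(fgt$a1)
    expect_true(all(al[ok] == fgt$a1[ok] | al[ok] == fgt$a2[ok]))
  }
})

test_that("duplicate offspring and unknown samples are rejected", {
  gt <- matrix("0/1", 3, 4, dimnames = list(NULL, samples4))
  tab <- make_table(gt, ped = ped1)
  bad <- rbind(ped1, ped1[1, ])
  expect_error(phase_panel(tab, ped = bad), "duplicated offspring")
  bad2 <- ped1; bad2$father <- "NOPE"
  expect_error(phase_panel(tab, ped = bad2), "absent from the table")
})

test_that("phasing output is deterministic and round-trips through TSV", {
  cfg <- panel_config(chrom_length = 1e5, sdr_boundary = 0)
  panels <- simulate_sex_panels(cfg, seed = 9)
  cr <- simulate_crosses(panels, cross_design(seed = 9))
  p1 <- phase_panel(cr$table)
  p2 <- phase_panel(cr$table)
  f1 <- tempfile(); f2 <- tempfile()
  write_phased_panel(p1, f1); write_phased_panel(p2, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_phased_panel(f1)
  expect_equal(unname(back$hap), unname(p1$hap))
  expect_equal(rownames(back$hap), p1$offspring)
  expect_equal(back$positions, p1$positions)
  expect_identical(back$label, p1$label)
  unlink(c(f1, f2))
})
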
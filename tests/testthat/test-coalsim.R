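test_that("coalescent parameters are validated", {
  expect_error(coal_params(Ne = -1), "positive")
  expect_error(coal_params(rho_distance = -2), "non-negative")
  expect_error(coal_params(demography = data.frame(time_gen = c(5, 0),
                                                   size = c(1, 1))),
               "increasing")
  expect_error(coal_params(demography = data.frame(time_gen = c(0, 10),
                                                   size = c(1, 0))),
               "positive")
})

test_that("two isolated demes without a sweep cannot coalesce", {
  p <- coal_params(rho_distance = 0, sweep = FALSE,
                   demography = data.frame(time_gen = 0, size = 1))
  expect_error(simulate_window(p, seed = 1), "cannot coalesce")
})

test_that("zero recombination after a recent sweep forces Y monophyly", {
  for (s in 1:50) {
    sim <- simulate_window(coal_params(rho_distance = 0, t_sweep = 100),
                           seed = 4000 + s)
    expect_true(sim$summary$y_monophyletic)
  }
})

test_that("the monophyly flag from branch counts matches the ape oracle", {
  for (s in 1:30) {
    p <- coal_params(rho_distance = c(0, 5, 60)[1 + s %% 3],
                     t_sweep = 50000, theta = 5)
    sim <- simulate_window(p, tree = TRUE, seed = 4100 + s)
    tr <- sim$tree
    ylab <- grep("^Y", tr$tip.label, value = TRUE)
    rooted <- ape::root(tr, outgroup = grep("^X", tr$tip.label,
                                            value = TRUE)[1],
                        resolve.root = TRUE)
    expect_equal(sim$summary$y_monophyletic,
                 ape::is.monophyletic(rooted, ylab),
                 label = paste("seed", s))
  }
})

test_that("genealogies are ultrametric with matched summary statistics", {
  for (s in 1:20) {
    p <- coal_params(rho_distance = 10, theta = 6)
    sim <- simulate_window(p, haplotypes = TRUE, tree = TRUE,
                           seed = 4300 + s)
    # all tips sampled at the same time
    depth <- ape::node.depth.edgelength(sim$tree)
    tipd <- depth[seq_len(length(sim$tree$tip.label))]
    expect_lt(max(tipd) - min(tipd), 1e-8)
    expect_equal(max(tipd), sim$summary$t_mrca, tolerance = 1e-8)
    # summary statistics computed from branch counts equal the
    # matrix-based estimators on the emitted haplotypes (dual route)
    expect_equal(sim$summary$pi, oracle_pi(sim$hap), tolerance = 1e-9)
    if (!is.na(sim$summary$fst))
      expect_equal(sim$summary$fst,
                   window_fst(sim$hap, sim$labels), tolerance = 1e-9)
    expect_equal(sim$summary$S, ncol(sim$hap))
    if (!is.na(sim$summary$tajima_d))
      expect_equal(sim$summary$tajima_d, oracle_tajima(sim$hap),
                   tolerance = 1e-9)
  }
})

test_that("single-deme constant-size expectations hold (scaled check)", {
  p <- coal_params(single_deme = TRUE, theta = 2.5,
                   demography = data.frame(time_gen = 0, size = 1))
  n_rep <- 2000
  pis <- tmr <- lens <- S <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    s <- simulate_window(p, seed = 5000 + i)$summary
    pis[i] <- s$pi; tmr[i] <- s$t_mrca; lens[i] <- s$tree_length
    S[i] <- s$S
  }
  n <- 30
  expect_lt(abs(mean(pis) - 2.5), 3 * sd(pis) / sqrt(n_rep))
  expect_lt(abs(mean(tmr) - 2 * (1 - 1 / n)),
            3 * sd(tmr) / sqrt(n_rep))
  # E[L] = 2 * sum 1/i ; mutations are Poisson(theta/2 * L)
  expect_lt(abs(mean(lens) - 2 * sum(1 / seq_len(n - 1))),
            3 * sd(lens) / sqrt(n_rep))
  diffs <- S - 2.5 / 2 * lens
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(n_rep))
})

test_that("post-sweep Y diversity grows with time since the sweep", {
  mean_pi_y <- sapply(c(2e4, 1e5, 3e5), function(ts) {
    mean(sapply(1:300, function(i)
      simulate_window(coal_params(rho_distance = 0, t_sweep = ts,
                                  theta = 5),
                      seed = 6000 + i)$summary$pi_y), na.rm = TRUE)
  })
  expect_true(all(diff(mean_pi_y) > 0))
})

test_that("a sweep elevates near-SDR FST relative to no sweep", {
  f_sweep <- f_null <- numeric(300)
  for (i in 1:300) {
    f_sweep[i] <- simulate_window(coal_params(rho_distance = 5),
                                  seed = 7000 + i)$summary$fst
    f_null[i] <- simulate_window(coal_params(rho_distance = 5,
                                             sweep = FALSE),
                                 seed = 7000 + i)$summary$fst
  }
  expect_gt(mean(f_sweep, na.rm = TRUE), mean(f_null, na.rm = TRUE))
})

test_that("simulate_region summarises by distance and handles empty input", {
  r <- simulate_region(coal_params(), distances = c(1, 60),
                       n_reps = 50, seed = 3)
  expect_equal(nrow(r$summary), 2)
  expect_equal(r$summary$n, c(50, 50))
  expect_gt(r$summary$mean_fst[r$summary$distance == 1],
            r$summary$mean_fst[r$summary$distance == 60])
  empty <- simulate_region(coal_params(), distances = numeric(0))
  expect_equal(nrow(empty$summary), 0)
})

test_that("calibrate_critical_p recovers thresholds on constructed inputs", {
  minp <- seq(0.001, 1, by = 0.001)
  expect_equal(suppressWarnings(calibrate_critical_p(minp, 0.2)), 0.2)
  expect_equal(calibrate_critical_p(rep(1, 500), 0.2), 0)
  expect_equal(calibrate_critical_p(rep(0.5, 200), 1.0), 1)
  expect_error(calibrate_critical_p(numeric(0)), "empty")
  expect_error(calibrate_critical_p(c(0.2, 1.5)), "\\[0, 1\\]")
  expect_warning(calibrate_critical_p(runif(50), 0.2), "fewer than 100")
  # property: the returned threshold achieves the rate, the next
  # candidate does not
  for (s in 1:10) {
    set.seed(s)
    mp <- runif(200)^2
    ps <- calibrate_critical_p(mp, 0.2)
    expect_lte(mean(mp <= ps), 0.2)
    above <- mp[mp > ps]
    if (length(above))
      expect_gt(mean(mp <= min(above)), 0.2)
  }
})

test_that("simulated null scans feed calibration end to end", {
  minp <- simulate_null_scans(coal_params(theta = 5),
                              distances = c(60, 150, 300),
                              n_sim = 30, n_perm = 500, seed = 77)
  expect_length(minp, 30)
  expect_true(all(minp >= 0 & minp <= 1))
  ps <- suppressWarnings(calibrate_critical_p(minp, 0.2))
  expect_lte(mean(minp <= ps), 0.2)
})
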
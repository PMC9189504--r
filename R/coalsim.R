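#' Parameters of the structured-coalescent null for a PAR window
#'
#' A PAR locus linked to the SDR is modelled as a two-deme structured
#' coalescent: Y-linked copies form a deme of relative size 1/4 (one
#' copy per male), X-linked copies a deme of relative size 3/4, both
#' relative to the `2 Ne` copies of an autosomal locus. Looking
#' backward in time, a Y-linked copy moves to the X deme when it
#' recombined off the Y in a father's meiosis, at rate `r` per
#' generation; an X-linked copy moves to the Y deme at `r/3` (only the
#' third of X-linked copies residing in males can have come off a Y).
#' Female meiosis never moves a PAR copy between X- and Y-linked states
#' and is ignored. In coalescent time (units of `2 Ne` generations)
#' the migration rates are `rho/2` and `rho/6`, with
#' `rho = 4 Ne r` the population-scaled recombination distance of the
#' window from the SDR.
#'
#' At `t_sweep` generations before the present the neo-Y originated:
#' all lineages then in the Y deme merge instantaneously (the
#' zero-duration limit of the Y sweep) and the process continues as a
#' single panmictic deme (the locus was autosomal before the fusion).
#' Population-size epochs rescale both demes.
#'
#' @param Ne diploid effective population size.
#' @param n_x,n_y numbers of sampled X- and Y-linked copies.
#' @param rho_distance distance from the window to the SDR in rho
#'   units.
#' @param theta per-window scaled mutation rate `4 Ne mu L`; the
#'   default 2.5 gives about 10 segregating sites per window in a
#'   sample of 30.
#' @param t_sweep sweep (fusion) time in generations before present.
#' @param sweep include the sweep event; without it the two demes
#'   persist indefinitely (requires `rho_distance > 0` to coalesce).
#' @param single_deme ignore structure entirely (panmictic control,
#'   the infinite-migration limit).
#' @param demography data.frame of epochs with columns `time_gen`
#'   (start looking backward, first must be 0, increasing) and `size`
#'   (relative to `Ne`). The default places a 5-fold expansion half a
#'   sweep-time ago (ancestral size `0.2 Ne`), an explicitly arbitrary
#'   placeholder for a recently expanded population; override for
#'   anything quantitative.
#' @param seed integer seed.
#' @return list of class `coal_params`.
#' @export
coal_params <- function(Ne = 1e5, n_x = 15L, n_y = 15L,
                        rho_distance = 60, theta = 2.5,
                        t_sweep = 306000, sweep = TRUE,
                        single_deme = FALSE, demography = NULL,
                        seed = 1L) {
  check_positive(Ne, "Ne")
  check_nonneg(rho_distance, "rho_distance")
  check_positive(theta, "theta")
  check_nonneg(t_sweep, "t_sweep")
  if (is.null(demography))
    demography <- data.frame(time_gen = c(0, 0.5 * t_sweep),
                             size = c(1, 0.2))
  demography <- as.data.frame(demography)
  stopifnot(all(c("time_gen", "size") %in% names(demography)))
  if (demography$time_gen[1] != 0 || is.unsorted(demography$time_gen,
                                                 strictly = TRUE))
    stopf("demography epochs must start at 0 with strictly increasing times")
  if (any(demography$size <= 0)) stopf("epoch sizes must be positive")
  structure(list(Ne = Ne, n_x = as.integer(n_x), n_y = as.integer(n_y),
                 rho_distance = rho_distance, theta = theta,
                 t_sweep = t_sweep, sweep = isTRUE(sweep),
                 single_deme = isTRUE(single_deme),
                 demography = demography, seed = as.integer(seed)),
            class = "coal_params")
}

# simulate one genealogy; returns edge table + node times + labels
coal_genealogy <- function(p) {
  n <- p$n_x + p$n_y
  fx <- 3 / 4; fy <- 1 / 4
  rho <- p$rho_distance
  tau_sweep <- if (p$sweep && !p$single_deme) p$t_sweep / (2 * p$Ne) else Inf
  ep_tau <- p$demography$time_gen / (2 * p$Ne)
  ep_size <- p$demography$size
  n_ep <- length(ep_tau)

  deme <- if (p$single_deme) rep(1L, n) else rep(c(1L, 2L), c(p$n_x, p$n_y))
  node <- seq_len(n)
  btime <- numeric(n)
  alive <- rep(TRUE, n)
  struct <- !p$single_deme

  e_child <- integer(0); e_parent <- integer(0); e_len <- numeric(0)
  e_dx <- integer(0); e_dy <- integer(0)
  dx <- as.integer(seq_len(n) <= p$n_x)
  dy <- 1L - dx
  next_id <- n + 1L
  tau <- 0
  ep <- 1L

  close_edges <- function(idx, parent_id, t) {
    e_child <<- c(e_child, node[idx])
    e_parent <<- c(e_parent, rep(parent_id, length(idx)))
    e_len <<- c(e_len, t - btime[idx])
    e_dx <<- c(e_dx, dx[idx])
    e_dy <<- c(e_dy, dy[idx])
  }

  repeat {
    act <- which(alive)
    if (length(act) == 1L) break
    while (ep < n_ep && ep_tau[ep + 1L] <= tau) ep <- ep + 1L
    s <- ep_size[ep]
    if (struct) {
      ax <- act[deme[act] == 1L]; ay <- act[deme[act] == 2L]
      kx <- length(ax); ky <- length(ay)
      rates <- c(kx * (kx - 1) / 2 / (fx * s),
                 ky * (ky - 1) / 2 / (fy * s),
                 ky * rho / 2,
                 kx * rho / 6)
    } else {
      k <- length(act)
      rates <- k * (k - 1) / 2 / s
    }
    R <- sum(rates)
    nxt_ep <- if (ep < n_ep) ep_tau[ep + 1L] else Inf
    bp <- min(nxt_ep, tau_sweep)
    dt <- if (R > 0) rexp(1L, R) else Inf
    if (tau + dt >= bp) {
      if (!is.finite(bp))
        stopf("lineages cannot coalesce: zero migration between demes and no sweep")
      tau <- bp
      if (bp == tau_sweep) {
        # sweep: all Y-deme lineages merge; the locus becomes panmictic
        ay <- act[deme[act] == 2L]
        if (length(ay) >= 2L) {
          close_edges(ay, next_id, tau)
          keep <- ay[1L]
          alive[ay[-1L]] <- FALSE
          node[keep] <- next_id
          btime[keep] <- tau
          dx[keep] <- sum(dx[ay]); dy[keep] <- sum(dy[ay])
          next_id <- next_id + 1L
        }
        deme[alive] <- 1L
        struct <- FALSE
        tau_sweep <- Inf
      }
      next
    }
    tau <- tau + dt
    if (struct) {
      ev <- sample.int(4L, 1L, prob = rates)
      if (ev == 1L || ev == 2L) {
        pool <- if (ev == 1L) ax else ay
        pair <- pool[sample.int(length(pool), 2L)]
        close_edges(pair, next_id, tau)
        keep <- pair[1L]
        alive[pair[2L]] <- FALSE
        node[keep] <- next_id
        btime[keep] <- tau
        dx[keep] <- dx[pair[1L]] + dx[pair[2L]]
        dy[keep] <- dy[pair[1L]] + dy[pair[2L]]
        next_id <- next_id + 1L
      } else if (ev == 3L) {
        deme[ay[sample.int(length(ay), 1L)]] <- 1L
      } else {
        deme[ax[sample.int(length(ax), 1L)]] <- 2L
      }
    } else {
      pair <- act[sample.int(length(act), 2L)]
      close_edges(pair, next_id, tau)
      keep <- pair[1L]
      alive[pair[2L]] <- FALSE
      node[keep] <- next_id
      btime[keep] <- tau
      dx[keep] <- dx[pair[1L]] + dx[pair[2L]]
      dy[keep] <- dy[pair[1L]] + dy[pair[2L]]
      next_id <- next_id + 1L
    }
  }
  list(child = e_child, parent = e_parent, len = e_len,
       dx = e_dx, dy = e_dy, t_mrca = tau, n = n,
       root = node[which(alive)], n_nodes = next_id - 1L,
       labels = rep(c("X", "Y"), c(p$n_x, p$n_y)))
}

coal_newick <- function(g) {
  n <- g$n
  kids <- split(seq_along(g$child), g$parent)
  lens <- g$len
  tip_lab <- paste0(g$labels, seq_len(n))
  rec <- function(node_id, len) {
    s <- if (node_id <= n) tip_lab[node_id] else {
      ei <- kids[[as.character(node_id)]]
      paste0("(", paste(vapply(ei, function(e)
        rec(g$child[e], lens[e]), ""), collapse = ","), ")")
    }
    if (is.na(len)) s else paste0(s, ":", format(len, digits = 10))
  }
  paste0(rec(g$root, NA), ";")
}

# tip sets below each edge (list parallel to g$child)
coal_tipsets <- function(g) {
  n <- g$n
  sets <- vector("list", g$n_nodes)
  for (i in seq_len(n)) sets[[i]] <- i
  o <- order(g$parent)            # parents created in time order
  for (e in o)
    sets[[g$parent[e]]] <- c(sets[[g$parent[e]]], sets[[g$child[e]]])
  lapply(g$child, function(ch) sets[[ch]])
}

#' Simulate one PAR window under the structured-coalescent null
#'
#' Draws a genealogy of `n_x + n_y` copies under the model of
#' [coal_params()] and drops infinite-sites mutations on it at rate
#' `theta/2` per unit branch length (time in `2 Ne` generations), so a
#' panmictic constant-size control has `E[pi] = theta`.
#'
#' @param params a [coal_params()].
#' @param haplotypes also return the 0/1 haplotype matrix (rows
#'   labelled X/Y).
#' @param tree also return the genealogy as [ape::phylo] and Newick.
#' @param seed integer seed; defaults to `params$seed`.
#' @return list of class `sim_sample` with `summary` (window FST
#'   between X and Y labels, `pi`, `pi_x`, `pi_y` as mean pairwise
#'   differences, segregating sites `S`, `tajima_d`, `t_mrca` and
#'   `tree_length` in `2 Ne` generations, and `y_monophyletic`), plus
#'   `hap`, `labels`, `newick`, `tree` when requested.
#' @export
simulate_window <- function(params = coal_params(), haplotypes = FALSE,
                            tree = FALSE, seed = params$seed) {
  stopifnot(inherits(params, "coal_params"))
  if (!is.null(seed)) set.seed(seed)
  g <- coal_genealogy(params)
  L <- sum(g$len)
  nmut <- rpois(1L, params$theta / 2 * L)
  medge <- if (nmut > 0)
    sample.int(length(g$len), nmut, replace = TRUE, prob = g$len)
  else integer(0)
  n <- g$n; nx <- params$n_x; ny <- params$n_y
  cx <- g$dx[medge]; cy <- g$dy[medge]
  ct <- cx + cy

  pi_of <- function(c1, nn) if (nn >= 2)
    sum(2 * c1 * (nn - c1) / (nn * (nn - 1))) else NA_real_
  pi_all <- pi_of(ct, n)
  S <- nmut
  taj <- NA_real_
  if (S > 0 && n >= 4) {
    k <- tajima_constants(n)
    taj <- (pi_all - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
  }
  fst <- NA_real_
  if (nx >= 2 && ny >= 2 && length(cx)) {
    h <- hudson_components(cx, nx, cy, ny)
    den <- sum(h$den)
    if (den > 0) fst <- sum(h$num) / den
  }
  y_mono <- any((g$dx == 0L & g$dy == ny) | (g$dx == nx & g$dy == 0L)) ||
    ny <= 1L
  out <- list(summary = list(
    fst = fst, pi = pi_all, pi_x = pi_of(cx, nx), pi_y = pi_of(cy, ny),
    S = S, tajima_d = taj, t_mrca = g$t_mrca, tree_length = L,
    y_monophyletic = y_mono),
    labels = g$labels, params = params, seed = seed)
  if (tree) {
    out$newick <- coal_newick(g)
    out$tree <- ape::read.tree(text = out$newick)
  }
  if (haplotypes) {
    hap <- matrix(0L, n, nmut)
    if (nmut > 0) {
      sets <- coal_tipsets(g)
      for (j in seq_len(nmut)) hap[sets[[medge[j]]], j] <- 1L
    }
    rownames(hap) <- paste0(g$labels, seq_len(n))
    out$hap <- hap
  }
  class(out) <- "sim_sample"
  out
}

#' @export
print.sim_sample <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<sim_sample> n=%d (X=%d,Y=%d) S=%d fst=%.3f pi=%.2f D=%.2f Ymono=%s\n",
    length(x$labels), x$params$n_x, x$params$n_y, s$S,
    ifelse(is.na(s$fst), NaN, s$fst), s$pi,
    ifelse(is.na(s$tajima_d), NaN, s$tajima_d), s$y_monophyletic))
  invisible(x)
}

#' Simulate null FST distributions for windows at given SDR distances
#'
#' Runs `n_reps` independent replicates of [simulate_window()] at each
#' rho-distance and summarises the per-distance null FST distribution.
#'
#' @param params template [coal_params()]; `rho_distance` is replaced
#'   per window.
#' @param distances vector of rho distances (>= 0).
#' @param n_reps replicates per distance.
#' @param seed integer seed.
#' @return list with `replicates` (data.table: distance, rep, fst, pi,
#'   S, tajima_d, y_monophyletic) and `summary` (per distance: mean
#'   FST, upper quantiles, monophyly rate).
#' @export
simulate_region <- function(params = coal_params(), distances,
                            n_reps = 1000L, seed = params$seed) {
  if (length(distances) == 0L)
    return(list(replicates = data.table::data.table(),
                summary = data.table::data.table()))
  if (any(distances < 0)) stopf("distances must be >= 0")
  rows <- vector("list", length(distances) * n_reps)
  i <- 0L
  for (di in seq_along(distances)) {
    pp <- params
    pp$rho_distance <- distances[di]
    for (r in seq_len(n_reps)) {
      i <- i + 1L
      s <- simulate_window(pp, seed = derive_seed(seed, i))$summary
      rows[[i]] <- data.table::data.table(
        distance = distances[di], rep = r, fst = s$fst, pi = s$pi,
        S = s$S, tajima_d = s$tajima_d,
        y_monophyletic = s$y_monophyletic)
    }
  }
  reps <- data.table::rbindlist(rows)
  distance <- fst <- y_monophyletic <- NULL # R CMD check NSE guards
  summ <- reps[, list(
    mean_fst = mean(fst, na.rm = TRUE),
    q95_fst = as.numeric(quantile(fst, 0.95, na.rm = TRUE)),
    q99_fst = as.numeric(quantile(fst, 0.99, na.rm = TRUE)),
    mono_rate = mean(y_monophyletic),
    n = .N), by = distance]
  list(replicates = reps, summary = summ)
}

#' Simulate whole-region null scans and collect minimum p-values
#'
#' For each simulated scan, every window is drawn independently from
#' the structured-coalescent null at its distance from the SDR, a
#' balanced-permutation p-value is computed for its FST exactly as in
#' the observed scan, and the scan is reduced to its minimum window
#' p-value. The resulting list feeds [calibrate_critical_p()].
#'
#' @param params template [coal_params()].
#' @param distances rho distances of the scan's windows.
#' @param n_sim number of simulated scans.
#' @param n_perm permutations per window p-value.
#' @param seed integer seed.
#' @return numeric vector of per-scan minimum p-values.
#' @export
simulate_null_scans <- function(params = coal_params(), distances,
                                n_sim = 100L, n_perm = 1000L,
                                seed = params$seed) {
  vapply(seq_len(n_sim), function(s) {
    pmin_s <- 1
    for (di in seq_along(distances)) {
      pp <- params
      pp$rho_distance <- distances[di]
      ws <- derive_seed(seed, (s - 1L) * length(distances) + di)
      sim <- simulate_window(pp, haplotypes = TRUE, seed = ws)
      if (ncol(sim$hap) == 0L) next
      pv <- permutation_pvalue(sim$hap, sim$labels, n_perm = n_perm,
                               seed = derive_seed(ws, 1L))
      if (!is.na(pv$p)) pmin_s <- min(pmin_s, pv$p)
    }
    pmin_s
  }, 0)
}

#' Familywise critical p-value from null scans
#'
#' Given the minimum window p-value of each simulated null scan,
#' returns the largest threshold `p_star` among the observed minima
#' such that at most a fraction `familywise_rate` of null scans would
#' produce at least one call (`min p <= p_star`); 0 if no threshold
#' achieves the rate, 1 if the rate is >= 1.
#'
#' @param min_p vector of per-scan minimum p-values (>= 100 scans
#'   recommended for a stable threshold).
#' @param familywise_rate target probability of at least one
#'   significant window under the null.
#' @return the critical p-value `p_star`.
#' @export
calibrate_critical_p <- function(min_p, familywise_rate = 0.2) {
  if (length(min_p) == 0L) stopf("empty min-p input")
  if (any(is.na(min_p) | min_p < 0 | min_p > 1))
    stopf("min_p values must lie in [0, 1]")
  check_nonneg(familywise_rate, "familywise_rate")
  if (length(min_p) < 100L)
    warning("fewer than 100 null scans: p_star will be coarse")
  if (familywise_rate >= 1) return(1)
  n <- length(min_p)
  cand <- sort(unique(min_p))
  frac <- vapply(cand, function(t) mean(min_p <= t), 0)
  ok <- frac <= familywise_rate
  if (!any(ok)) return(0)
  max(cand[ok])
}
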
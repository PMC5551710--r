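make_count_track <- function(..., bin_size = 10000, library_size = NULL) {
  vals <- list(...)
  names(vals) <- sprintf("chr%d", seq_along(vals))
  if (is.null(library_size)) library_size <- sum(unlist(vals))
  binned_track(vals, bin_size, "count", library_size = library_size)
}

test_that("log2 ratio matches hand computations", {
  treat <- make_count_track(c(8, 8, 8), library_size = 24)
  ctrl <- make_count_track(c(2, 2, 2), library_size = 6)
  # equal CPM libraries: treat bin 8 of 24, control 2 of 6 -> cpm equal -> 0
  expect_equal(compute_log2_ratio(treat, ctrl, 0)$values$chr1, c(0, 0, 0))

  # same library sizes: counts 8 vs 2 at p = 0 -> log2(4) = 2
  treat <- make_count_track(c(8, 2), library_size = 10)
  ctrl <- make_count_track(c(2, 2), library_size = 10)
  expect_equal(compute_log2_ratio(treat, ctrl, 0)$values$chr1, c(2, 0))

  # identical tracks -> all zero at any pseudocount
  t1 <- make_count_track(c(3, 5, 9, 0, 2))
  expect_equal(compute_log2_ratio(t1, t1, 1)$values$chr1, rep(0, 5))
})

test_that("CPM scaling cancels a depth difference", {
  # treat library 2x control, raw counts equal per bin -> all-zero ratio
  v <- c(4, 9, 1, 7, 3)
  treat <- make_count_track(v, library_size = 2000)
  ctrl <- make_count_track(v, library_size = 1000)
  treat$values$chr1 <- v * 2            # doubled depth, same profile
  treat$library_size <- 2000
  expect_equal(compute_log2_ratio(treat, ctrl, 0)$values$chr1, rep(0, 5))
})

test_that("log2 ratio is antisymmetric in treat/control at zero pseudocount", {
  set.seed(5)
  a <- make_count_track(rpois(50, 60) + 1, rpois(30, 60) + 1)
  b <- make_count_track(rpois(50, 80) + 1, rpois(30, 80) + 1)
  ab <- compute_log2_ratio(a, b, 0)
  ba <- compute_log2_ratio(b, a, 0)
  for (ch in track_chroms(ab))
    expect_equal(ab$values[[ch]], -ba$values[[ch]])
})

test_that("bin grid mismatches are rejected", {
  a <- make_count_track(c(1, 2, 3))
  b <- make_count_track(c(1, 2, 3), bin_size = 5000)
  expect_error(compute_log2_ratio(a, b), "bin grid")
  d <- make_count_track(c(1, 2))
  expect_error(compute_log2_ratio(a, d), "bin grid")
})

test_that("peak seeds: simple shapes behave as specified", {
  tr <- ratio_track(c(0, 1, 3, 1, 0))
  expect_equal(find_peak_seeds(tr, min_height = 0, min_prominence = 0)$seed_bin, 2L)
  # constant vector: no seeds
  expect_equal(nrow(find_peak_seeds(ratio_track(rep(2, 10)), 0, 0)), 0L)
  # plateau takes the leftmost bin
  tr <- ratio_track(c(0, 2, 2, 2, 0))
  expect_equal(find_peak_seeds(tr, 0, 0)$seed_bin, 1L)
  # shorter than 3 bins: empty
  expect_equal(nrow(find_peak_seeds(ratio_track(c(1, 2)), 0, 0)), 0L)
})

test_that("peak seeds equal brute-force local maxima at zero prominence", {
  set.seed(31)
  for (rep in 1:50) {
    v <- rnorm(300)
    tr <- ratio_track(v, bin_size = 1000)
    got <- find_peak_seeds(tr, min_height = -Inf, min_prominence = 0)$seed_bin
    expect_equal(got + 1L, oracle_local_maxima(v))
    # with a positive prominence threshold, seeds are a subset
    sel <- find_peak_seeds(tr, min_height = -Inf, min_prominence = 1)$seed_bin
    expect_true(all(sel %in% got))
  }
})

test_that("extension stops only at a full run of non-positive bins", {
  # exactly the 3 positive bins between two 8-bin non-positive runs
  v <- c(rep(-1, 8), 2, 5, 2, rep(-1, 8))
  tr <- ratio_track(v)
  d <- extend_domain(tr, "chr1", seed_bin = 9L, stop_run = 8)
  expect_equal(d$start, 8 * 10000)
  expect_equal(d$end, 11 * 10000)
  expect_equal(d$summit_value, 5)

  # a 7-bin gap is traversed, and the gap stays inside the domain
  v <- c(rep(-1, 8), 1, 3, rep(-0.5, 7), 2, 1, rep(-1, 8))
  tr <- ratio_track(v)
  d <- extend_domain(tr, "chr1", seed_bin = 9L, stop_run = 8)
  expect_equal(d$start, 8 * 10000)
  expect_equal(d$end, 19 * 10000)   # bins 9..19 (1-based) retained

  # seed at the chromosome edge with no stop run: reaches the boundary
  v <- c(3, 2, 1, 0.5, rep(-1, 4))
  d <- extend_domain(ratio_track(v), "chr1", 0L)
  expect_equal(d$start, 0)
  expect_equal(d$end, 8 * 10000)

  expect_error(extend_domain(ratio_track(c(1, -1, 1)), "chr1", 1L), "> 0")
})

test_that("extension boundaries equal the exhaustive-scan oracle", {
  set.seed(77)
  for (rep in 1:30) {
    v <- rnorm(120, mean = -0.2)
    tr <- ratio_track(v)
    seeds <- intersect(oracle_local_maxima(v), which(v > 0))
    for (s1 in seeds) {
      d <- extend_domain(tr, "chr1", s1 - 1L)
      ora <- oracle_extend(v, s1)
      expect_equal(d$start / 10000 + 1L, unname(ora["left"]))
      expect_equal(d$end / 10000, unname(ora["right"]))
    }
  }
})

test_that("extension is direction-order independent by construction", {
  # asymmetric track: left run just under threshold, right over it
  v <- c(rep(-1, 7), 1, rep(-1, 7), 4, rep(-1, 9), 2, rep(-1, 8))
  tr <- ratio_track(v)
  d <- extend_domain(tr, "chr1", 15L)
  ora <- oracle_extend(v, 16L)
  expect_equal(d$start / 10000 + 1, unname(ora["left"]))
  expect_equal(d$end / 10000, unname(ora["right"]))
})

test_that("domain calling drops sub-40-kb calls and keeps 40-kb calls", {
  pad <- rep(-1, 8)
  # one 3-bin (30 kb) and one 4-bin (40 kb) region
  v <- c(pad, 1, 2, 1, pad, 1, 2, 2, 1, pad)
  doms <- call_damage_domains(ratio_track(v), min_prominence = 0)
  expect_equal(nrow(doms), 1L)
  expect_equal(doms$end - doms$start, 40000)
  # lowering the filter recovers both
  doms2 <- call_damage_domains(ratio_track(v), min_prominence = 0,
                               min_length = 30000)
  expect_equal(nrow(doms2), 2L)
})

test_that("called domains never overlap and each contains a positive bin", {
  set.seed(19)
  for (rep in 1:10) {
    v <- rnorm(200, mean = -0.3, sd = 1.2)
    doms <- call_damage_domains(ratio_track(v), min_prominence = 0,
                                min_length = 20000)
    if (nrow(doms) > 1) {
      expect_true(all(doms$start[-1] >= doms$end[-nrow(doms)]))
    }
    for (i in seq_len(nrow(doms))) {
      bins <- (doms$start[i] / 10000 + 1):(doms$end[i] / 10000)
      expect_true(any(v[bins] > 0))
      expect_true(doms$summit_value[i] > 0)
    }
  }
})

test_that("planted domains are recovered with no false calls", {
  # ten 100-kb domains, height 3, Poisson(100) background, five seeds
  for (sd in 1:5) {
    cfg <- simulation_config(seed = sd, n_sites = 20, frac_cut = 0.5,
                             min_site_gap = 180000, min_cut_gap = 180000,
                             site_margin = 60000, domain_halfwidth = 50000)
    sim <- simulate_genome(cfg)
    tracks <- simulate_damage_tracks(sim$sites, cfg)
    ratio <- compute_log2_ratio(tracks$gamma, tracks$h2ax)
    doms <- call_damage_domains(ratio)
    cut <- sim$sites[sim$sites$cut, ]
    in_dom <- vapply(seq_len(nrow(cut)), function(i) {
      d <- doms[doms$chrom == cut$chrom[i], ]
      any(cut$start[i] >= d$start & cut$start[i] < d$end)
    }, logical(1))
    expect_true(all(in_dom), info = paste("seed", sd))
    has_cut <- vapply(seq_len(nrow(doms)), function(i) {
      s <- cut[cut$chrom == doms$chrom[i], ]
      any(s$start >= doms$start[i] & s$start < doms$end[i])
    }, logical(1))
    expect_true(all(has_cut), info = paste("seed", sd))
    expect_equal(nrow(doms), 10L, info = paste("seed", sd))
  }
})
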
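bp_track <- function(..., library_size = NULL) {
  vals <- list(...)
  names(vals) <- sprintf("chr%d", seq_along(vals))
  if (is.null(library_size)) library_size <- sum(unlist(vals))
  binned_track(vals, 1L, "count", library_size = library_size)
}

test_that("profile matrix: uniform coverage gives the RPM constant", {
  cov <- bp_track(rep(2, 50000), library_size = 1e6)
  sites <- data.frame(chrom = "chr1", start = 25000)
  m <- build_profile_matrix(cov, sites, half_width = 1000, profile_bin = 50)
  expect_equal(dim(m), c(1L, 40L))
  expect_true(all(abs(m - 2 * 1e6 / 1e6) < 1e-12))
})

test_that("profile matrix: a coverage spike lands in the cell containing it", {
  v <- rep(0, 50000); v[25000 + 500 + 1] <- 100   # delta at offset +500
  cov <- bp_track(v, library_size = 1e6)
  sites <- data.frame(chrom = "chr1", start = 25000)
  m <- build_profile_matrix(cov, sites, half_width = 1000, profile_bin = 50)
  pos <- attr(m, "positions")
  expect_equal(pos[which.max(m[1, ])], 525)   # cell [500, 550) centre
})

test_that("profile matrix rows equal directly computed windowed means", {
  set.seed(15)
  v <- rpois(200000, 1.5)
  cov <- bp_track(v, library_size = 5e5)
  sites <- data.frame(chrom = "chr1", start = sort(sample(20000:180000, 10)))
  m <- build_profile_matrix(cov, sites, half_width = 2000, profile_bin = 100)
  for (i in seq_len(nrow(sites))) {
    p <- sites$start[i]
    expected <- vapply(seq_len(40), function(k) {
      lo <- p - 2000 + (k - 1) * 100
      mean(v[(lo + 1):(lo + 100)]) * 1e6 / 5e5
    }, numeric(1))
    expect_equal(unname(m[i, ]), expected)
  }
})

test_that("cells beyond chromosome ends read as zero coverage", {
  cov <- bp_track(rep(1, 1000), library_size = 1e6)
  sites <- data.frame(chrom = "chr1", start = 100)
  m <- build_profile_matrix(cov, sites, half_width = 500, profile_bin = 100)
  expect_equal(unname(m[1, ]), c(0, 0, 0, 0, rep(1, 6)))
  expect_error(build_profile_matrix(cov, sites[0, ], 500, 100), "empty")
  expect_error(build_profile_matrix(cov, sites, 500, 99), "divide")
})

test_that("trimmed mean drops floor(trim*n) values from each end", {
  m <- matrix(1:100, ncol = 1)
  expect_equal(trimmed_mean_profile(m, 0.02), 50.5)   # mean of 3..98
  expect_equal(trimmed_mean_profile(m, 0), 50.5)      # symmetric: same mean
  m2 <- cbind(1:100, c(1:99, 1e6))
  expect_equal(trimmed_mean_profile(m2, 0)[2], mean(c(1:99, 1e6)))
  expect_equal(trimmed_mean_profile(m2, 0.02)[2], mean(3:98))
  # constant column is invariant to any trim
  m3 <- matrix(7, nrow = 50, ncol = 2)
  expect_equal(trimmed_mean_profile(m3, 0.1), c(7, 7))
  expect_error(trimmed_mean_profile(m, 0.5), "trim")
  expect_error(trimmed_mean_profile(m[1:2, , drop = FALSE]), "3 rows")
})

test_that("trimmed mean stays within range and respects constant shifts", {
  set.seed(4)
  m <- matrix(rnorm(500), nrow = 50)
  tm <- trimmed_mean_profile(m, 0.04)
  expect_true(all(tm >= apply(m, 2, min) & tm <= apply(m, 2, max)))
  expect_equal(trimmed_mean_profile(m + 3, 0.04), tm + 3)
})

test_that("rolling statistics match the naive recomputation", {
  expect_equal(rolling_stats(c(1, 2, 3, 4, 5), 3, 1)$mean, c(2, 3, 4))
  expect_equal(rolling_stats(rep(5, 10), 4, 1)$sd, rep(0, 7))
  set.seed(8)
  v <- rnorm(300)
  got <- rolling_stats(v, window_bp = 20, profile_bin = 1)
  ora <- oracle_rolling(v, 20L)
  expect_equal(got$mean, ora$mean)
  expect_equal(got$sd, ora$sd)
  expect_length(got$mean, 300 - 20 + 1)
  expect_error(rolling_stats(v, 400, 1), "exceeds")
  expect_error(rolling_stats(v, 30, 7), "integer")
})

test_that("signal sums use half-open windows truncated at chromosome ends", {
  cov <- bp_track(rep(1, 10000))
  sites <- data.frame(chrom = "chr1", start = c(5000, 200))
  s <- signal_sum_at_sites(cov, sites, half = 500)
  expect_equal(s, c(1000, 700))   # second site truncated at the start
  zero <- bp_track(rep(0, 10000), library_size = 1)
  expect_equal(signal_sum_at_sites(zero, sites), c(0, 0))
})

test_that("signal sums agree with profile-matrix row sums at bp resolution", {
  set.seed(21)
  v <- rpois(60000, 2)
  cov <- bp_track(v, library_size = 1e6)
  sites <- data.frame(chrom = "chr1", start = sort(sample(2000:58000, 8)))
  sums <- signal_sum_at_sites(cov, sites, half = 500, normalize = TRUE)
  m <- build_profile_matrix(cov, sites, half_width = 500, profile_bin = 1)
  expect_equal(unname(rowSums(m)), sums)
})

test_that("condition ratios behave as log2 of scaled sums", {
  expect_equal(site_condition_ratio(c(1, 2, 3), c(1, 2, 3), 0), c(0, 0, 0))
  expect_equal(site_condition_ratio(c(2, 4), c(1, 2), 0), c(1, 1))
  expect_error(site_condition_ratio(1:3, 1:2), "length")
})

test_that("metagene summaries are invariant to site ordering", {
  set.seed(12)
  v <- rpois(100000, 2)
  cov <- bp_track(v, library_size = 2e5)
  sites <- data.frame(chrom = "chr1", start = sort(sample(10000:90000, 12)))
  p1 <- metagene_profile(cov, sites, half_width = 2000, profile_bin = 50)
  p2 <- metagene_profile(cov, sites[sample(nrow(sites)), ],
                         half_width = 2000, profile_bin = 50)
  expect_equal(p1$profile, p2$profile)
  expect_equal(p1$rolling, p2$rolling)
})

test_that("synthetic occupancy peaks where planted and separates cut sites", {
  cfg <- tiny_config(5, dicer_peak_offset = 500)
  sim <- simulate_genome(cfg)
  dicer <- simulate_dicer_coverage(sim$sites, cfg)
  cut <- sim$sites[sim$sites$cut, ]
  prof <- metagene_profile(dicer$plus, cut, half_width = 5000,
                           profile_bin = 50, trim = 0.02, roll_bp = 1000)
  pk <- prof$rolling$position[which.max(prof$rolling$rolling_mean)]
  expect_lte(abs(pk - 500), 50)
  sp <- signal_sum_at_sites(dicer$plus, sim$sites, 500, normalize = TRUE)
  sm <- signal_sum_at_sites(dicer$minus, sim$sites, 500, normalize = TRUE)
  r <- site_condition_ratio(sp, sm)
  w <- stats::wilcox.test(r[sim$sites$cut], r[!sim$sites$cut],
                          alternative = "greater")
  expect_lt(w$p.value, 0.01)
})
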
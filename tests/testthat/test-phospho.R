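test_that("phosphopeptide quality filter applies the documented thresholds", {
  tbl <- data.frame(score = c(40, 39.9, 80, 80, 80),
                    localization_probability = c(0.71, 0.99, 0.70, 0.701, 0.9),
                    fdr_pass = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  got <- filter_phosphopeptides(tbl)
  expect_equal(rownames(got), c("1", "4"))  # score-40/0.71 kept; 0.70 dropped
  expect_equal(nrow(filter_phosphopeptides(tbl[0, ])), 0L)
  expect_error(filter_phosphopeptides(tbl[, 1:2]), "fdr_pass")
})

test_that("normalisation matches the closed form and is idempotent", {
  x <- matrix(c(4, 8, 16), ncol = 1)
  got <- normalize_intensities(x)
  expect_equal(as.vector(got), c(-1, 0, 1) / 1.4826, tolerance = 1e-9)
  expect_equal(round(as.vector(got), 4), c(-0.6745, 0, 0.6745))
  # column medians return to 0 when renormalising (already-logged input)
  y <- matrix(rnorm(60, 5, 2), ncol = 3)
  n1 <- normalize_intensities(y, log2_transform = FALSE)
  expect_equal(apply(n1, 2, median), rep(0, 3))
  expect_equal(apply(n1, 2, mad), rep(1, 3))
  n2 <- normalize_intensities(n1, log2_transform = FALSE)
  expect_equal(n1, n2, tolerance = 1e-12)
  expect_error(normalize_intensities(matrix(c(-1, 2, 3), ncol = 1)), "> 0")
  expect_error(normalize_intensities(matrix(1, 3, 1), log2_transform = FALSE),
               "MAD")
})

test_that("missingness filter keeps proteins with one complete condition", {
  cond <- c("control", "control", "damage", "damage")
  x <- rbind(a = c(5.1, NA, NA, NA),     # discarded
             b = c(5.1, 6.0, NA, NA),    # kept: control qualifies
             c = c(1, 2, 3, 4),          # complete
             d = c(NA, NA, 3, NA))       # discarded
  got <- filter_missing(x, cond)
  expect_equal(rownames(got), c("b", "c"))
})

test_that("tier-1 imputation draws from the documented normal", {
  cond <- c("control", "control", "damage", "damage")
  # same-condition value 5.0; other condition [4, 6] -> N(5, sqrt(2))
  row <- matrix(c(5, NA, 4, 6), 1, dimnames = list("p1", NULL))
  set.seed(101)
  draws <- replicate(1e5, impute_one_missing(row, cond)$x[1, 2])
  expect_lt(abs(mean(draws) - 5.0), 0.02)
  expect_lt(abs(sd(draws) - sqrt(2)), 0.02)

  # other condition constant -> deterministic imputation at the mean
  row2 <- matrix(c(5, NA, 4, 4), 1)
  expect_equal(impute_one_missing(row2, cond)$x[1, 2], 5)

  # fixed seed reproducibility
  set.seed(7); a <- impute_one_missing(row, cond)$x
  set.seed(7); b <- impute_one_missing(row, cond)$x
  expect_identical(a, b)

  # other condition incomplete: falls through untouched
  row3 <- matrix(c(5, NA, 4, NA), 1)
  got <- impute_one_missing(row3, cond)
  expect_true(is.na(got$x[1, 2]))
  expect_false(any(got$imputed))
})

test_that("QRILC fit recovers normal parameters from uncensored samples", {
  set.seed(55)
  x <- rnorm(5000)
  fit <- qrilc_fit(x, 0)
  expect_lt(abs(fit$mu), 0.05)
  expect_lt(abs(fit$sigma - 1), 0.05)
  expect_error(qrilc_fit(rnorm(5), 0), "at least 10")
})

test_that("QRILC imputation restores a censored normal, below the cut point", {
  cond <- rep("control", 4)
  for (sd in 1:3) {
    set.seed(sd * 1000)
    x <- matrix(rnorm(2000, 20, 1), ncol = 4)
    thr <- quantile(x, 0.2)
    xc <- x; xc[xc < thr] <- NA
    got <- impute_qrilc(xc, cond)
    expect_false(anyNA(got$x))
    expect_lt(abs(mean(got$x) - 20), 0.1)
    expect_true(all(got$x[is.na(xc)] <= got$fits$control$censor_point))
    expect_lt(abs(got$fits$control$mu - 20), 0.15)
  }
  # no missing entries: a no-op
  set.seed(2)
  x <- matrix(rnorm(100, 20, 1), ncol = 4)
  got <- impute_qrilc(x, cond)
  expect_identical(got$x, x)
  expect_equal(sum(got$imputed), 0L)
})

test_that("recentre/rescale zeroes medians, units MADs, and is idempotent", {
  set.seed(14)
  x <- matrix(rnorm(400, 3, 2), ncol = 4)
  r1 <- recenter_rescale(x)
  expect_equal(apply(r1, 2, median), rep(0, 4))
  expect_equal(apply(r1, 2, mad), rep(1, 4))
  expect_equal(recenter_rescale(r1), r1, tolerance = 1e-9)
  x[1] <- NA
  expect_error(recenter_rescale(x), "complete")
})

test_that("paired t-test matches closed form and the reference distribution", {
  cond <- c("control", "control", "control", "damage", "damage", "damage")
  pair <- c("1", "2", "3", "1", "2", "3")
  x <- matrix(c(1, 2, 3, 2, 4, 5), 1)   # d = (1, 2, 2)
  got <- paired_t_test(x, cond, pair)
  expect_equal(got$log_fc, 5 / 3)
  expect_equal(got$t, 5)
  expect_equal(got$df, 2)
  expect_equal(got$p, 2 * pt(-5, 2))
  expect_equal(got$p, 0.03775, tolerance = 1e-4)

  # agreement with stats::t.test on non-degenerate data
  set.seed(17)
  y <- matrix(rnorm(6), 1)
  ref <- t.test(y[1, 4:6], y[1, 1:3], paired = TRUE)
  mine <- paired_t_test(y, cond, pair)
  expect_equal(mine$t, unname(ref$statistic))
  expect_equal(mine$p, ref$p.value)

  # degenerate rows
  z <- rbind(c(1, 2, 3, 1, 2, 3),   # d = 0 everywhere
             c(1, 2, 3, 2, 3, 4))   # d = 1 everywhere
  got <- paired_t_test(z, cond, pair)
  expect_equal(got$log_fc, c(0, 1))
  expect_equal(got$t, c(0, Inf))
  expect_equal(got$p, c(1, 0))
  expect_equal(got$degenerate, c(TRUE, TRUE))
})

test_that("q-values reduce to Benjamini-Hochberg at pi0 = 1", {
  got <- qvalues_bootstrap(c(0.01, 0.02, 0.03), pi0 = 1)
  expect_equal(got$q, c(0.03, 0.03, 0.03))
  # monotone in sorted p and never above 1
  set.seed(6)
  p <- runif(500)^2
  q <- qvalues_bootstrap(p, B = 50)$q
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
  expect_true(all(q <= 1))
})

test_that("pi0 estimates are calibrated on uniform p-values", {
  for (sd in 1:5) {
    set.seed(sd)
    r <- qvalues_bootstrap(runif(2000))
    expect_gte(r$pi0, 0.9)
    expect_lte(r$pi0, 1.0)
  }
  # degenerate all-equal p-values clamp pi0 to 1
  set.seed(1)
  expect_equal(qvalues_bootstrap(rep(0.5, 100))$pi0, 1)
  expect_error(qvalues_bootstrap(c(-0.1, 0.5)), "0, 1")
})

test_that("pipeline conserves protein counts through its stages", {
  cfg <- tiny_config(10, n_proteins = 400, n_pairs = 2, censor_quantile = 0.15)
  ps <- simulate_phospho_matrix(cfg)
  r <- run_phospho_pipeline(ps$intensities, ps$condition, ps$pair, seed = 5)
  expect_equal(unname(r$counts["input"]), 400)
  expect_equal(nrow(r$results), unname(r$counts["after_missing_filter"]))
  expect_equal(unname(r$counts["tested"]), nrow(r$results))
  expect_false(anyNA(r$matrix))
  expect_true(all(r$results$q >= 0 & r$results$q <= 1))
})

test_that("permuting protein rows permutes but does not change results", {
  cfg <- tiny_config(11, n_proteins = 300, censor_quantile = 0.1)
  ps <- simulate_phospho_matrix(cfg)
  r1 <- run_phospho_pipeline(ps$intensities, ps$condition, ps$pair, seed = 42)
  perm <- sample(nrow(ps$intensities))
  r2 <- run_phospho_pipeline(ps$intensities[perm, ], ps$condition, ps$pair,
                             seed = 42)
  m <- merge(r1$results, r2$results, by = "protein")
  expect_equal(m$p.x, m$p.y)
  expect_equal(m$q.x, m$q.y)
  expect_equal(m$log_fc.x, m$log_fc.y)
  expect_equal(r1$pi0, r2$pi0)
})

test_that("pipeline p-values are near-uniform under the complete null", {
  cfg <- simulation_config(seed = 1, effect_fold = 1, n_pairs = 4,
                           censor_quantile = 0)
  ps <- simulate_phospho_matrix(cfg)
  r <- run_phospho_pipeline(ps$intensities, ps$condition, ps$pair, seed = 101)
  expect_gt(stats::ks.test(r$results$p, "punif")$p.value, 0.01)
})

test_that("phospho TSV round-trips the matrix and design labels", {
  cfg <- tiny_config(12, n_proteins = 50, censor_quantile = 0.2)
  ps <- simulate_phospho_matrix(cfg)
  f <- tempfile(fileext = ".tsv")
  write_phospho_tsv(ps$intensities, ps$condition, ps$pair, f)
  back <- read_phospho_tsv(f)
  expect_equal(back$condition, ps$condition)
  expect_equal(back$pair, ps$pair)
  expect_equal(back$x, ps$intensities, tolerance = 1e-12)
})
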
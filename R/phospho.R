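#' Filter a phosphopeptide table on search-engine quality flags
#'
#' Keeps rows with `score >= min_score`, `localization_probability`
#' strictly greater than `min_loc_prob`, and a TRUE `fdr_pass` flag (the
#' upstream search's FDR set membership; it is not recomputed here). A row
#' with score exactly 40 and probability 0.71 is kept; probability exactly
#' 0.70 is dropped.
#'
#' @param peptides Data.frame with columns `score`,
#'   `localization_probability` and logical `fdr_pass`.
#' @param min_score Minimum score, inclusive (default 40).
#' @param min_loc_prob Localisation-probability threshold, exclusive
#'   (default 0.7).
#' @return The filtered data.frame (possibly empty).
#' @export
filter_phosphopeptides <- function(peptides, min_score = 40, min_loc_prob = 0.7) {
  need <- c("score", "localization_probability", "fdr_pass")
  miss <- setdiff(need, names(peptides))
  if (length(miss) > 0L)
    stop("missing column(s): ", paste(miss, collapse = ", "))
  keep <- peptides$score >= min_score &
    peptides$localization_probability > min_loc_prob &
    peptides$fdr_pass
  peptides[which(keep), , drop = FALSE]
}

#' Log-transform and median/MAD normalise an intensity matrix
#'
#' Raw intensities are log2-transformed, then each sample column is median
#' centred and scaled by its median absolute deviation (MAD, with the usual
#' 1.4826 consistency constant), computed over non-missing entries. A column
#' with zero MAD cannot be scaled and is rejected.
#'
#' @param x Proteins x samples matrix; missing values as NA.
#' @param log2_transform Log2-transform first (default TRUE; requires all
#'   non-missing values > 0). Set FALSE for already-logged data.
#' @return The normalised matrix.
#' @export
normalize_intensities <- function(x, log2_transform = TRUE) {
  x <- as.matrix(x)
  if (log2_transform) {
    if (any(x[!is.na(x)] <= 0))
      stop("raw intensities must be > 0 where present")
    x <- log2(x)
  }
  center_scale_columns(x)
}

center_scale_columns <- function(x) {
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    m <- stats::median(v, na.rm = TRUE)
    s <- stats::mad(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0)
      stop("column ", j, " has zero MAD; cannot scale")
    x[, j] <- (v - m) / s
  }
  x
}

#' Drop proteins without two non-missing values in at least one condition
#'
#' A protein is kept iff at least one condition holds >= 2 non-missing
#' values; proteins for which neither condition does are discarded.
#'
#' @param x Proteins x samples matrix with NAs.
#' @param condition Character/factor vector of per-sample condition labels.
#' @return The row-filtered matrix.
#' @export
filter_missing <- function(x, condition) {
  x <- as.matrix(x)
  stopifnot(length(condition) == ncol(x))
  ok <- rep(FALSE, nrow(x))
  for (cc in unique(condition)) {
    ok <- ok | rowSums(!is.na(x[, condition == cc, drop = FALSE])) >= 2L
  }
  x[ok, , drop = FALSE]
}

#' Tier-1 imputation: single missing value within a condition
#'
#' For each protein and condition with exactly one missing value, the missing
#' entry is drawn from a normal distribution with mean equal to the mean of
#' the same condition's non-missing values and SD equal to the sample SD of
#' the other condition's values (with two replicates per condition this is
#' exactly the one-observed-value, SD-from-the-other-pair rule). When the
#' other condition has fewer than two non-missing values, or its SD is not
#' defined, the entry is left missing and falls through to the QRILC tier.
#' A zero SD gives a deterministic imputation at the mean.
#'
#' Draws consume the current RNG stream; seed beforehand for
#' reproducibility.
#'
#' @param x Proteins x samples matrix with NAs.
#' @param condition Per-sample condition labels (exactly two conditions).
#' @return List: `x` (matrix with tier-1 entries filled) and `imputed`
#'   (logical matrix flagging the filled cells).
#' @export
impute_one_missing <- function(x, condition) {
  x <- as.matrix(x)
  stopifnot(length(condition) == ncol(x))
  conds <- unique(condition)
  if (length(conds) != 2L) stop("exactly two conditions are required")
  flags <- matrix(FALSE, nrow(x), ncol(x), dimnames = dimnames(x))
  for (i in seq_len(nrow(x))) {
    for (k in 1:2) {
      same <- which(condition == conds[k])
      other <- which(condition == conds[3 - k])
      miss <- same[is.na(x[i, same])]
      if (length(miss) != 1L) next
      obs_same <- x[i, same[!is.na(x[i, same])]]
      obs_other <- x[i, other[!is.na(x[i, other])]]
      if (length(obs_same) < 1L || length(obs_other) < 2L) next
      s <- stats::sd(obs_other)
      x[i, miss] <- stats::rnorm(1L, mean = mean(obs_same), sd = s)
      flags[i, miss] <- TRUE
    }
  }
  list(x = x, imputed = flags)
}

#' Fit a normal to left-censored observations by quantile regression
#'
#' Least-squares regression of the sorted observed values on standard-normal
#' quantiles restricted to the upper `1 - missing_rate` portion of the
#' distribution: observation of rank i among k maps to the overall quantile
#' `missing_rate + (1 - missing_rate) * (i - 0.5) / k`. On uncensored data
#' (`missing_rate = 0`) this is an ordinary QQ-regression estimator of
#' (mean, sd).
#'
#' @param observed Numeric vector of observed (non-missing) values.
#' @param missing_rate Fraction of the underlying values that are censored,
#'   in [0, 1).
#' @return List: `mu`, `sigma`, and `censor_point`
#'   (`mu + sigma * qnorm(max(missing_rate, 0.01))`).
#' @export
qrilc_fit <- function(observed, missing_rate) {
  k <- length(observed)
  if (k < 10L) stop("need at least 10 observed values to fit")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  xs <- sort(observed)
  p <- missing_rate + (1 - missing_rate) * (seq_len(k) - 0.5) / k
  q <- stats::qnorm(p)
  slope <- stats::cov(q, xs) / stats::var(q)
  mu <- mean(xs) - slope * mean(q)
  if (!is.finite(slope) || slope <= 0)
    stop("degenerate quantile-regression fit (non-positive sigma)")
  list(mu = mu, sigma = slope,
       censor_point = mu + slope * stats::qnorm(max(missing_rate, 0.01)))
}

#' Tier-2 imputation: QRILC-style truncated-normal draws
#'
#' Remaining missing entries (typically whole-condition missing after the
#' tier-1 rule) are treated as left-censored. Per condition, all observed
#' values are pooled, a normal (mu, sigma) is fitted with [qrilc_fit()] at
#' the condition's observed missing rate, and each missing entry is drawn
#' from `Normal(mu, (tune * sigma)^2)` truncated above at the estimated
#' censoring point, so no imputed value exceeds it.
#'
#' @param x Proteins x samples matrix with NAs.
#' @param condition Per-sample condition labels.
#' @param tune Multiplier on the fitted sigma for the truncated draws
#'   (default 1.0).
#' @return List: `x` (complete matrix), `imputed` (logical matrix of filled
#'   cells) and `fits` (per-condition mu/sigma/censor_point/missing_rate).
#' @export
impute_qrilc <- function(x, condition, tune = 1.0) {
  x <- as.matrix(x)
  stopifnot(length(condition) == ncol(x))
  if (tune <= 0) stop("`tune` must be > 0")
  flags <- matrix(FALSE, nrow(x), ncol(x), dimnames = dimnames(x))
  fits <- list()
  for (cc in unique(condition)) {
    cols <- which(condition == cc)
    sub <- x[, cols, drop = FALSE]
    na_idx <- which(is.na(sub))
    r <- length(na_idx) / length(sub)
    if (length(na_idx) == 0L) {
      fits[[cc]] <- list(mu = NA_real_, sigma = NA_real_,
                         censor_point = NA_real_, missing_rate = 0)
      next
    }
    fit <- qrilc_fit(sub[!is.na(sub)], r)
    fit$missing_rate <- r
    fits[[cc]] <- fit
    ub <- stats::pnorm((fit$censor_point - fit$mu) / (tune * fit$sigma))
    u <- stats::runif(length(na_idx), 0, ub)
    u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
    sub[na_idx] <- fit$mu + tune * fit$sigma * stats::qnorm(u)
    x[, cols] <- sub
    fl <- flags[, cols, drop = FALSE]
    fl[na_idx] <- TRUE
    flags[, cols] <- fl
  }
  list(x = x, imputed = flags, fits = fits)
}

#' Re-centre and re-scale sample columns after imputation
#'
#' Re-applies per-column median centring and MAD scaling (see
#' [normalize_intensities()]) on the now-complete matrix, so each condition's
#' samples sit on a common scale before testing. Idempotent up to numerical
#' precision.
#'
#' @param x Complete (no NA) proteins x samples matrix.
#' @return The re-scaled matrix.
#' @export
recenter_rescale <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("matrix must be complete (impute first)")
  center_scale_columns(x)
}

#' Paired two-tailed t-tests across proteins
#'
#' For each protein the per-pair differences `d_k = damage_k - control_k`
#' give `log_fc = mean(d)`, `t = mean(d) / (sd(d) / sqrt(n))`, `df = n - 1`
#' and a two-tailed p-value from the t distribution. Degenerate rows with
#' `sd(d) = 0` are flagged: all-zero differences give t = 0, p = 1; a
#' non-zero constant difference gives t = +/-Inf, p = 0.
#'
#' @param x Complete proteins x samples matrix.
#' @param condition Per-sample labels; `reference` identifies the control
#'   level, the other level is the treatment.
#' @param pair Per-sample pair identifiers linking one control to one
#'   treatment sample.
#' @param reference Control condition label (default `"control"`).
#' @return Data.frame with `log_fc`, `t`, `df`, `p`, and logical
#'   `degenerate`, one row per protein (rownames preserved).
#' @export
paired_t_test <- function(x, condition, pair, reference = "control") {
  x <- as.matrix(x)
  if (anyNA(x)) stop("matrix must be complete (impute first)")
  stopifnot(length(condition) == ncol(x), length(pair) == ncol(x))
  conds <- unique(condition)
  if (length(conds) != 2L || !(reference %in% conds))
    stop("need exactly two conditions including the reference")
  treat <- setdiff(conds, reference)
  ctl <- which(condition == reference)
  trt <- which(condition == treat)
  ctl <- ctl[order(pair[ctl])]
  trt <- trt[order(pair[trt])]
  if (!identical(pair[ctl], pair[trt]))
    stop("pair ids must appear exactly once per condition")
  n <- length(ctl)
  if (n < 2L) stop("need at least 2 pairs for a paired t-test")
  D <- x[, trt, drop = FALSE] - x[, ctl, drop = FALSE]
  m <- rowMeans(D)
  s <- apply(D, 1L, stats::sd)
  tstat <- m / (s / sqrt(n))
  degen <- s == 0
  tstat[degen & m == 0] <- 0
  tstat[degen & m > 0] <- Inf
  tstat[degen & m < 0] <- -Inf
  p <- 2 * stats::pt(-abs(tstat), df = n - 1L)
  p[degen & m == 0] <- 1
  p[degen & m != 0] <- 0
  data.frame(log_fc = m, t = tstat, df = n - 1L, p = p, degenerate = degen,
             row.names = rownames(x))
}

#' q-values with bootstrap pi0 estimation
#'
#' Storey-style q-values. `pi0(lambda) = #\{p > lambda\} / (m (1 - lambda))`
#' on a grid of lambda; `B` bootstrap resamples of the p-vector select the
#' lambda minimising the mean squared deviation of the bootstrap estimates
#' from a low quantile (0.1) of the grid estimates -- the stabilised target
#' of the method's published implementation, markedly less down-biased on
#' null data than the raw grid minimum; pi0 is the estimate at that lambda,
#' capped at 1
#' (and set to 1 when the estimate degenerates to <= 0, e.g. for all-equal
#' p-values). q-values are the step-up transform
#' `q_(i) = min_{j >= i} pi0 * m * p_(j) / j` on the ascending-sorted
#' p-values, mapped back to input order; they are monotone in p and <= 1.
#' With `pi0 = 1` supplied directly the procedure reduces to
#' Benjamini-Hochberg.
#'
#' @param p P-values in [0, 1]; at least 10 unless `pi0` is supplied.
#' @param lambda Grid for pi0 estimation (default 0.05..0.95 by 0.05).
#' @param B Bootstrap resamples (default 100); consumes the RNG stream.
#' @param pi0 Optional fixed pi0 in (0, 1], skipping estimation.
#' @return List of class `qvalue_result`: `pi0`, `lambda`, `lambda_star`,
#'   `pi0_lambda` (the grid estimates) and `q`.
#' @export
qvalues_bootstrap <- function(p, lambda = seq(0.05, 0.95, by = 0.05), B = 100,
                              pi0 = NULL) {
  if (any(p < 0 | p > 1 | is.na(p))) stop("p-values must lie in [0, 1]")
  m <- length(p)
  lambda_star <- NA_real_
  pi0_lambda <- NULL
  if (is.null(pi0)) {
    if (m < 10L) stop("need at least 10 p-values to estimate pi0")
    pi0_lambda <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    min_pi0 <- stats::quantile(pi0_lambda, 0.1, names = FALSE)
    mse <- numeric(length(lambda))
    for (b in seq_len(B)) {
      pb <- p[sample.int(m, m, replace = TRUE)]
      pi0_b <- vapply(lambda, function(l) mean(pb > l) / (1 - l), numeric(1))
      mse <- mse + (pi0_b - min_pi0)^2
    }
    lambda_star <- lambda[which.min(mse)]
    pi0 <- min(pi0_lambda[which.min(mse)], 1)
    if (!is.finite(pi0) || pi0 <= 0) pi0 <- 1
  } else {
    if (pi0 <= 0 || pi0 > 1) stop("`pi0` must be in (0, 1]")
  }
  o <- order(p)
  q_sorted <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  structure(list(pi0 = pi0, lambda = lambda, lambda_star = lambda_star,
                 pi0_lambda = pi0_lambda, q = q),
            class = "qvalue_result")
}

#' Protein-level phosphoproteomics differential pipeline
#'
#' Runs the full chain on a raw proteins x samples intensity matrix:
#' log2 + median/MAD normalisation -> missingness filter -> tier-1
#' one-missing imputation -> tier-2 QRILC imputation -> per-column
#' re-centre/re-scale -> paired t-tests -> bootstrap-pi0 q-values.
#' Stage-by-stage protein counts are recorded (and printed with
#' `verbose = TRUE`).
#'
#' Rows are processed in protein-name order internally and returned in input
#' order, so permuting the input rows permutes, but never changes, the
#' results under a fixed seed.
#'
#' @param x Raw proteins x samples matrix (unique rownames; NAs for missing).
#' @param condition,pair Per-sample condition labels and pair ids.
#' @param seed Optional RNG seed for the imputation draws and bootstrap.
#' @param tune QRILC sigma multiplier (default 1).
#' @param lambda,B q-value grid and bootstrap count.
#' @param log2_transform Passed to [normalize_intensities()].
#' @param reference Control condition label.
#' @param verbose Print stage counts (default FALSE).
#' @return List of class `phospho_result`: `results` (data.frame `protein`,
#'   `log_fc`, `t`, `df`, `p`, `q`, `n_imputed_tier1`, `n_imputed_qrilc`,
#'   `degenerate`), `pi0`, `counts` (stage log), `matrix` (final complete
#'   matrix, input row order), `fits` (QRILC fits).
#' @export
run_phospho_pipeline <- function(x, condition, pair, seed = NULL, tune = 1.0,
                                 lambda = seq(0.05, 0.95, by = 0.05), B = 100,
                                 log2_transform = TRUE, reference = "control",
                                 verbose = FALSE) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- sprintf("protein_%05d", seq_len(nrow(x)))
  if (anyDuplicated(rownames(x))) stop("protein rownames must be unique")
  if (!is.null(seed)) set.seed(seed)
  counts <- c(input = nrow(x))

  xn <- normalize_intensities(x, log2_transform = log2_transform)
  xn <- xn[order(rownames(xn)), , drop = FALSE]   # canonical order: see Details
  xf <- filter_missing(xn, condition)
  counts["after_missing_filter"] <- nrow(xf)

  t1 <- impute_one_missing(xf, condition)
  counts["tier1_imputed_values"] <- sum(t1$imputed)
  t2 <- impute_qrilc(t1$x, condition, tune = tune)
  counts["qrilc_imputed_values"] <- sum(t2$imputed)

  xr <- recenter_rescale(t2$x)
  tt <- paired_t_test(xr, condition, pair, reference = reference)
  qv <- qvalues_bootstrap(tt$p, lambda = lambda, B = B)
  counts["tested"] <- nrow(tt)

  res <- data.frame(protein = rownames(xf),
                    log_fc = tt$log_fc, t = tt$t, df = tt$df, p = tt$p,
                    q = qv$q,
                    n_imputed_tier1 = rowSums(t1$imputed),
                    n_imputed_qrilc = rowSums(t2$imputed),
                    degenerate = tt$degenerate,
                    stringsAsFactors = FALSE)
  keep <- intersect(rownames(x), res$protein)      # restore input order
  res <- res[match(keep, res$protein), , drop = FALSE]
  rownames(res) <- NULL
  if (verbose) {
    for (nm in names(counts)) message(sprintf("  %-24s %d", nm, counts[[nm]]))
  }
  structure(list(results = res, pi0 = qv$pi0, counts = counts,
                 matrix = xr[match(keep, rownames(xr)), , drop = FALSE],
                 fits = t2$fits),
            class = "phospho_result")
}

#' @export
print.phospho_result <- function(x, ...) {
  cat(sprintf("<phospho_result> %d proteins tested, pi0 = %.3f, %d at q < 0.05\n",
              nrow(x$results), x$pi0, sum(x$results$q < 0.05)))
  invisible(x)
}

#' Read / write a phospho intensity matrix as TSV
#'
#' Columns are samples with headers `<condition>_<pair>`; empty cells are
#' missing values; the first column holds protein identifiers.
#'
#' @param file TSV path.
#' @return List: `x` (matrix), `condition`, `pair`.
#' @export
read_phospho_tsv <- function(file) {
  d <- utils::read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  x <- as.matrix(d[, -1, drop = FALSE])
  rownames(x) <- d[[1]]
  hdr <- colnames(x)
  parts <- regmatches(hdr, regexec("^(.*)_([^_]+)$", hdr))
  if (any(vapply(parts, length, integer(1)) != 3L))
    stop("sample headers must have the form <condition>_<pair>")
  list(x = x,
       condition = vapply(parts, `[`, character(1), 2L),
       pair = vapply(parts, `[`, character(1), 3L))
}

#' @rdname read_phospho_tsv
#' @param x Matrix of intensities with protein rownames.
#' @param condition,pair Per-sample labels used to build the headers.
#' @export
write_phospho_tsv <- function(x, condition, pair, file) {
  colnames(x) <- paste(condition, pair, sep = "_")
  d <- data.frame(protein = rownames(x), x, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
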
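#' Intraclass correlation for paired gold/alternate measurements
#'
#' One-way random-effects ICC(1) for the balanced two-replicate design
#' (gold-standard sample + alternate-method sample per subject): with MSB
#' the between-subject and MSW the within-subject mean square over k = 2
#' replicates,
#' \deqn{ICC = (MSB - MSW) / (MSB + (k - 1) MSW).}
#' Negative estimates are reported unmodified — truncating them to zero
#' would hide concordance failures. When `n_bootstrap > 0` a subject-level
#' percentile bootstrap confidence interval is attached (see
#' [bootstrap_ci()]).
#'
#' @param pairs a `paired_measurements` object (see [pair_by_subject()]) or
#'   anything with numeric `gold` and `alt` fields of equal length.
#' @param n_bootstrap number of bootstrap resamples for the CI (0 = none).
#' @param seed RNG seed, required when `n_bootstrap > 0`.
#' @param level CI level (default 0.95).
#' @return an `icc_estimate`: `estimate`, `ci_low`, `ci_high`, `n_subjects`,
#'   `k_replicates`, `estimator`, `n_bootstrap`, `seed`.
#' @export
icc_oneway <- function(pairs, n_bootstrap = 0, seed = NULL, level = 0.95) {
  g <- pairs$gold
  m <- pairs$alt
  n <- length(g)
  if (n < 3) stopf("icc_oneway needs at least 3 subjects")
  if (length(m) != n) stopf("gold and alternate vectors must align")
  est <- .icc1(g, m)
  ci <- c(NA_real_, NA_real_)
  if (n_bootstrap > 0) {
    if (is.null(seed)) stopf("a seed is required for the bootstrap CI")
    ci <- bootstrap_ci(pairs, B = n_bootstrap, seed = seed, level = level)
  }
  icc_estimate(est, ci[1], ci[2], n, estimator = "anova_oneway",
               n_bootstrap = n_bootstrap, seed = seed)
}

# Core balanced one-way ANOVA ICC for k = 2; errors on zero total variance.
.icc1 <- function(g, m) {
  n <- length(g)
  rm_ <- (g + m) / 2
  msb <- 2 * sum((rm_ - mean(rm_))^2) / (n - 1)
  msw <- sum((g - m)^2) / (2 * n)
  if (msb + msw == 0) stopf("zero total variance: ICC undefined")
  (msb - msw) / (msb + msw)
}

icc_estimate <- function(estimate, ci_low, ci_high, n_subjects,
                         estimator, n_bootstrap = 0, seed = NULL,
                         k_replicates = 2) {
  structure(list(estimate = estimate, ci_low = ci_low, ci_high = ci_high,
                 n_subjects = n_subjects, k_replicates = k_replicates,
                 estimator = estimator, n_bootstrap = n_bootstrap,
                 seed = if (is.null(seed)) NA_integer_ else seed),
            class = "icc_estimate")
}

#' @export
print.icc_estimate <- function(x, ...) {
  ci <- if (is.na(x$ci_low)) "" else sprintf(" [%.3f, %.3f]", x$ci_low, x$ci_high)
  cat(sprintf("<icc_estimate> %s: %.3f%s (n = %d subjects)\n",
              x$estimator, x$estimate, ci, x$n_subjects))
  invisible(x)
}

#' Subject-level percentile bootstrap CI for the one-way ICC
#'
#' Subjects are resampled with replacement, keeping each (gold, alternate)
#' pair intact; the interval is the percentile interval of the resampled
#' ICC estimates. Resamples with undefined ICC (zero total variance) are
#' redrawn; the redraw count is attached as attribute `n_redraws`.
#'
#' @inheritParams icc_oneway
#' @param B number of bootstrap resamples (>= 1).
#' @return numeric vector `c(ci_low, ci_high)`.
#' @export
bootstrap_ci <- function(pairs, B = 1000, seed, level = 0.95) {
  g <- pairs$gold
  m <- pairs$alt
  n <- length(g)
  if (n < 3) stopf("too few subjects to resample (< 3)")
  if (B < 1) stopf("B must be >= 1")
  if (missing(seed) || is.null(seed)) stopf("a seed is required")
  redraws <- 0L
  est <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        v <- tryCatch(.icc1(g[idx], m[idx]), error = function(e) NA_real_)
        if (!is.na(v)) return(v)
        redraws <<- redraws + 1L
        if (redraws > 1000L * B) stopf("bootstrap degenerate: ICC undefined in every resample")
      }
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(est, c(alpha, 1 - alpha), type = 7))
  attr(ci, "n_redraws") <- redraws
  ci
}

# Squared-distance lookups between each subject's gold and method samples.
# Returns list(GG, MM, GM) of n x n matrices: GG[i,j] = d(g_i, g_j)^2 etc.
.dicc_blocks <- function(D, design, method) {
  D <- as_dist_matrix(D)
  gmap <- design_subject_of(design, design$gold_method)
  mmap <- design_subject_of(design, method)
  gmap <- gmap[names(gmap) %in% rownames(D)]
  mmap <- mmap[names(mmap) %in% rownames(D)]
  subjects <- intersect(gmap, mmap)
  if (length(subjects) < 3) stopf("fewer than 3 subjects with both samples in D")
  gs <- names(gmap)[match(subjects, gmap)]
  ms <- names(mmap)[match(subjects, mmap)]
  d2 <- D^2
  list(GG = d2[gs, gs, drop = FALSE], MM = d2[ms, ms, drop = FALSE],
       GM = d2[gs, ms, drop = FALSE], subjects = subjects)
}

# Distance-based ICC for one subject resample `s` (indices into blocks).
# Within: each draw's own gold-method squared distance.
# Between: all cross pairs of distinct draws (4 sample pairs per draw pair),
# including zero distances between copies of the same physical sample.
.dicc <- function(blocks, s) {
  n <- length(s)
  w <- sum(blocks$GM[cbind(s, s)]) / (2 * n)
  gg <- blocks$GG[s, s, drop = FALSE]
  mm <- blocks$MM[s, s, drop = FALSE]
  gm <- blocks$GM[s, s, drop = FALSE]
  up <- upper.tri(gg)
  # d^2/2 averaged over the 4 cross pairs for each of the C(n,2) draw pairs
  tot <- (sum(gg[up]) + sum(mm[up]) + sum(gm[up]) + sum(t(gm)[up])) /
    (4 * sum(up)) / 2
  if (tot == 0) stopf("zero total variance: distance ICC undefined")
  (tot - w) / tot
}

#' Distance-based ICC for beta-diversity
#'
#' ICC analogue computed directly from a sample dissimilarity matrix:
#' within-subject variance is estimated from each subject's gold-vs-method
#' squared distance, sigma_w^2 = (1/2n) sum d(g_i, m_i)^2, and total
#' variance from all between-subject sample pairs, sigma_t^2 = mean(d^2/2);
#' ICC = (sigma_t^2 - sigma_w^2) / sigma_t^2. At most 1 by construction,
#' and negative when paired samples are farther apart than unrelated ones.
#' On 1-D Euclidean data this reduces to the moment estimate of the scalar
#' one-way ICC (the correctness anchor used in the tests).
#'
#' @param D distance matrix over samples (must contain one gold and one
#'   `method` sample per included subject).
#' @param design a `sample_design`.
#' @param method alternate method label.
#' @return an `icc_estimate` with `estimator = "distance_based"`.
#' @export
distance_icc <- function(D, design, method) {
  if (method == design$gold_method) stopf("method must differ from the gold standard")
  blocks <- .dicc_blocks(D, design, method)
  n <- length(blocks$subjects)
  icc_estimate(.dicc(blocks, seq_len(n)), NA_real_, NA_real_, n,
               estimator = "distance_based")
}

#' Distance-based ICC with subject bootstrap CI
#'
#' Subjects are resampled with replacement; each resample's ICC is computed
#' on the induced distance submatrix, with duplicated subjects entering as
#' distinct copies (distance zero between two copies of the same physical
#' sample). The percentile interval over `B` resamples is attached.
#' Degenerate resamples are redrawn and counted (attribute `n_redraws`).
#'
#' @inheritParams distance_icc
#' @param B number of bootstrap resamples (default 1000).
#' @param seed RNG seed (required).
#' @param level CI level (default 0.95).
#' @return an `icc_estimate` with bootstrap CI fields populated.
#' @export
bootstrap_distance_icc <- function(D, design, method, B = 1000, seed,
                                   level = 0.95) {
  if (missing(seed) || is.null(seed)) stopf("a seed is required")
  if (B < 1) stopf("B must be >= 1")
  if (method == design$gold_method) stopf("method must differ from the gold standard")
  blocks <- .dicc_blocks(D, design, method)
  n <- length(blocks$subjects)
  point <- .dicc(blocks, seq_len(n))
  redraws <- 0L
  est <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      repeat {
        s <- sample.int(n, n, replace = TRUE)
        v <- tryCatch(.dicc(blocks, s), error = function(e) NA_real_)
        if (!is.na(v)) return(v)
        redraws <<- redraws + 1L
        if (redraws > 1000L * B) stopf("bootstrap degenerate: ICC undefined in every resample")
      }
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(est, c(alpha, 1 - alpha), type = 7))
  out <- icc_estimate(point, ci[1], ci[2], n, estimator = "distance_based",
                      n_bootstrap = B, seed = seed)
  attr(out, "n_redraws") <- redraws
  out
}
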
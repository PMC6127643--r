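#' Kruskal-Wallis rank test across collection methods
#'
#' Tie-corrected H statistic with a chi-square reference on (groups - 1)
#' degrees of freedom. If every observation is identical there is no rank
#' variation and the test degenerates; H = 0, p = 1 is returned rather than
#' NaN.
#'
#' @param values numeric vector of per-sample scalars.
#' @param groups group labels aligned with `values`.
#' @return a `group_test` list: `statistic`, `p_value`, `n_groups`,
#'   `n_samples`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2) stopf("need at least 2 groups")
  if (length(values) != length(groups)) stopf("values and groups must align")
  if (length(unique(values)) == 1) {
    res <- list(statistic = 0, p_value = 1)
  } else {
    kt <- stats::kruskal.test(values, groups)
    res <- list(statistic = unname(kt$statistic), p_value = kt$p.value)
  }
  structure(c(res, list(n_groups = nlevels(groups),
                        n_samples = length(values),
                        test = "kruskal_wallis")),
            class = "group_test")
}

# Anderson's pseudo-F from a squared-distance partition. d2: squared
# distance matrix; groups: factor. SS_total = sum_{i<j} d2/N;
# SS_within = sum_g (1/n_g) sum_{i<j in g} d2.
permanova_f <- function(d2, groups) {
  n <- nrow(d2)
  a <- nlevels(groups)
  ss_total <- sum(d2) / 2 / n
  ss_within <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    ss_within <- ss_within + sum(d2[idx, idx]) / 2 / length(idx)
  }
  ss_between <- ss_total - ss_within
  (ss_between / (a - 1)) / (ss_within / (n - a))
}

#' PERMANOVA on a distance matrix
#'
#' One-factor permutational multivariate analysis of variance: the pseudo-F
#' statistic partitions squared dissimilarities between and within groups,
#' and its null distribution is built by freely permuting sample labels.
#' The p-value uses the add-one convention
#' p = (1 + #\{permuted F >= observed F\}) / (n_permutations + 1), so it can
#' never be exactly zero.
#'
#' @param D distance matrix (square matrix or `dist`) over samples.
#' @param groups group labels in `D`'s sample order.
#' @param n_permutations number of label permutations (default 999).
#' @param seed RNG seed (required, for reproducible reports).
#' @return a `group_test` list: `statistic` (pseudo-F), `p_value`,
#'   `n_groups`, `n_samples`, `n_permutations`, `seed`.
#' @export
permanova <- function(D, groups, n_permutations = 999, seed) {
  D <- as_dist_matrix(D)
  if (missing(seed) || is.null(seed)) stopf("a seed is required")
  if (n_permutations < 1) stopf("n_permutations must be >= 1")
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2) stopf("need at least 2 groups")
  if (length(groups) != nrow(D)) stopf("groups must align with the distance matrix")
  d2 <- D^2
  f_obs <- permanova_f(d2, groups)
  n <- nrow(D)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_permutations), function(i) {
      permanova_f(d2, groups[sample.int(n)]) >= f_obs
    }, logical(1)))
  })
  structure(list(statistic = f_obs,
                 p_value = (1 + exceed) / (n_permutations + 1),
                 n_groups = nlevels(groups), n_samples = n,
                 n_permutations = n_permutations, seed = seed,
                 test = "permanova"),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("<group_test> %s: statistic = %.4g, p = %.4g (%d groups, %d samples)\n",
              x$test, x$statistic, x$p_value, x$n_groups, x$n_samples))
  invisible(x)
}
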
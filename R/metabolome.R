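#' Per-feature detectability within one collection method
#'
#' Detectability is the fraction of participants whose sample from `method`
#' has a non-missing (detected) value for the feature. Always computed on
#' raw, pre-imputation intensities.
#'
#' @param x an intensity `feature_table`.
#' @param design a `sample_design`.
#' @param method collection-method label.
#' @return named numeric vector of detected fractions, one per feature.
#' @export
detectability <- function(x, design, method) {
  stopifnot(inherits(x, "feature_table"))
  samples <- intersect(design_samples(design, method), colnames(x$values))
  if (length(samples) == 0) stopf("method '%s' has no samples in the table", method)
  rowMeans(!is.na(x$values[, samples, drop = FALSE]))
}

#' Minimum detected-participant count for a detectability level
#'
#' The smallest integer c with c/n >= level, i.e. ceiling(level * n);
#' level 0.75 with n = 8 participants gives 6.
#'
#' @param level detectability level in (0, 1].
#' @param n_participants number of participants with a sample.
#' @return integer count.
#' @export
min_detected_count <- function(level, n_participants) {
  if (level <= 0 || level > 1) stopf("level must be in (0, 1]")
  as.integer(ceiling(level * n_participants - 1e-12))
}

#' Filter features by detectability within one method
#'
#' @inheritParams detectability
#' @param level required detected fraction (0 retains everything). An empty
#'   result is allowed (a method may simply detect nothing at a level).
#' @return a `feature_table` restricted to the method's samples and to
#'   features with detectability >= level.
#' @export
filter_by_detectability <- function(x, design, method, level) {
  frac <- detectability(x, design, method)
  keep <- names(frac)[frac >= level - 1e-12]
  samples <- intersect(design_samples(design, method), colnames(x$values))
  structure(list(values = x$values[keep, samples, drop = FALSE], kind = x$kind),
            class = "feature_table")
}

#' Overlap of a method's detected features with the gold standard's
#'
#' @param gold_features,method_features character vectors of feature ids.
#' @return list with `shared` (count) and `percent`
#'   (100 * shared / |gold|, one decimal, half away from zero).
#' @export
overlap_with_gold <- function(gold_features, method_features) {
  if (length(gold_features) == 0) stopf("empty gold-standard feature set")
  shared <- length(intersect(gold_features, method_features))
  list(shared = shared,
       percent = round_half_up(100 * shared / length(gold_features), 1))
}

#' Half-minimum imputation of missing intensities
#'
#' Each missing cell is replaced by half the minimum detected value of that
#' feature within the same collection method (methods impute independently,
#' since detection limits are method-specific). Detected cells are never
#' touched.
#'
#' @param x an intensity `feature_table`.
#' @param design a `sample_design`.
#' @param method a single method to impute, or `NULL` (default) to impute
#'   every method present in the design.
#' @return the imputed `feature_table`.
#' @export
half_min_impute <- function(x, design, method = NULL) {
  stopifnot(inherits(x, "feature_table"))
  v <- x$values
  methods <- if (is.null(method)) design_methods(design) else method
  for (m in methods) {
    samples <- intersect(design_samples(design, m), colnames(v))
    if (length(samples) == 0) next
    block <- v[, samples, drop = FALSE]
    miss <- is.na(block)
    if (!any(miss)) next
    mins <- apply(block, 1, function(r) suppressWarnings(min(r, na.rm = TRUE)))
    bad <- rownames(block)[!is.finite(mins) & rowSums(miss) > 0]
    if (length(bad)) {
      stopf("feature(s) with no detected value in method '%s': %s", m,
            paste(utils::head(bad, 3), collapse = ", "))
    }
    block[miss] <- (mins / 2)[row(block)[miss]]
    v[, samples] <- block
  }
  feature_table(v, kind = x$kind)
}

#' Quantile normalization (within one method's samples)
#'
#' Forces every sample to share one empirical distribution: each sample's
#' order statistics are replaced by the across-sample mean of order
#' statistics; tied values within a sample receive the mean of the
#' reference values their ranks span. Run after imputation — the input must
#' be complete.
#'
#' @param x an intensity `feature_table` with no missing values (restrict
#'   to one method's samples before calling, or pass `design`/`method`).
#' @param design,method optional; when given, only that method's columns
#'   are normalized (independently of the rest of the table).
#' @return the normalized `feature_table`.
#' @export
quantile_normalize <- function(x, design = NULL, method = NULL) {
  stopifnot(inherits(x, "feature_table"))
  v <- x$values
  cols <- if (is.null(design)) colnames(v) else {
    intersect(design_samples(design, method), colnames(v))
  }
  block <- v[, cols, drop = FALSE]
  if (anyNA(block)) stopf("quantile normalization requires complete data (impute first)")
  if (length(cols) < 2) {
    warning("single-sample method: quantile normalization is the identity")
    return(x)
  }
  ref <- rowMeans(apply(block, 2, sort))
  out <- apply(block, 2, function(col) {
    r <- rank(col, ties.method = "average")
    lo <- ref[floor(r)]
    hi <- ref[ceiling(r)]
    (lo + hi) / 2
  })
  dimnames(out) <- dimnames(block)
  v[, cols] <- out
  feature_table(v, kind = x$kind)
}

#' Log10 transform of intensities
#'
#' @param x an intensity `feature_table` with all values strictly positive
#'   (impute below-detection cells first).
#' @return a `feature_table` with `kind = "log_intensity"`.
#' @export
log10_transform <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  if (any(x$values <= 0, na.rm = TRUE) || anyNA(x$values)) {
    stopf("log10 requires strictly positive, complete values")
  }
  feature_table(log10(x$values), kind = "log_intensity")
}

#' Per-metabolite ICC profile between gold standard and one method
#'
#' Computes the one-way ICC feature by feature on preprocessed (imputed,
#' quantile-normalized, log10) tables whose columns are participants, then
#' summarizes the distribution by median and interquartile range — the
#' method-level concordance summary for untargeted metabolomics.
#'
#' @param gold_table,method_table `feature_table`s with identical column
#'   names (subject ids), one column per participant.
#' @param features features to profile; default is the row intersection.
#' @return list with `summary` (data.frame: `n_features`, `median`, `q1`,
#'   `q3`) and `estimates` (data.frame: `feature_id`, `estimate`).
#' @export
metabolite_icc_profile <- function(gold_table, method_table, features = NULL) {
  g <- gold_table$values
  m <- method_table$values
  subjects <- intersect(colnames(g), colnames(m))
  if (length(subjects) < 3) stopf("fewer than 3 shared participants")
  if (is.null(features)) features <- intersect(rownames(g), rownames(m))
  if (length(features) == 0) stopf("no shared features to profile")
  est <- vapply(features, function(f) {
    tryCatch(.icc1(g[f, subjects], m[f, subjects]),
             error = function(e) NA_real_)
  }, numeric(1))
  ok <- est[!is.na(est)]
  q <- unname(stats::quantile(ok, c(0.25, 0.5, 0.75), type = 7))
  list(summary = data.frame(n_features = length(features),
                            median = q[2], q1 = q[1], q3 = q[3]),
       estimates = data.frame(feature_id = features, estimate = unname(est),
                              stringsAsFactors = FALSE))
}
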
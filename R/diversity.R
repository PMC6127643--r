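#' Relative abundance (column-wise normalization)
#'
#' @param x a counts `feature_table`; every sample must have a positive
#'   total.
#' @return a `feature_table` with `kind = "proportion"`.
#' @export
relative_abundance <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  cs <- colSums(x$values)
  if (any(cs <= 0)) {
    stopf("zero-total sample(s): %s",
          paste(colnames(x$values)[cs <= 0], collapse = ", "))
  }
  feature_table(sweep(x$values, 2, cs, "/"), kind = "proportion")
}

#' Square-root transform of relative abundances
#'
#' The standard variance-stabilizing transform applied to taxonomic
#' proportions before concordance analysis.
#'
#' @param x a proportion `feature_table`.
#' @return a `feature_table` with `kind = "sqrt_proportion"`.
#' @export
sqrt_transform <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  if (x$kind != "proportion") stopf("sqrt_transform expects a proportion table")
  feature_table(sqrt(x$values), kind = "sqrt_proportion")
}

#' Alpha-diversity indices for one sample
#'
#' `shannon()` is the Shannon entropy in nats, H = -sum p_i log p_i;
#' `simpson()` is the Gini-Simpson index 1 - sum p_i^2 (the probability two
#' random reads are from different taxa); `chao1()` is the bias-corrected
#' Chao1 richness estimate S_obs + F1(F1-1) / (2(F2+1)), with F1 and F2 the
#' singleton and doubleton counts. Shannon and Simpson accept counts or
#' proportions (they are scale-invariant); Chao1 needs raw integer counts.
#'
#' @param x nonnegative numeric vector of abundances for a single sample.
#' @return a single number.
#' @export
shannon <- function(x) {
  p <- .as_props(x)
  -sum(p * log(p))
}

#' @rdname shannon
#' @export
simpson <- function(x) {
  p <- .as_props(x)
  1 - sum(p^2)
}

.as_props <- function(x) {
  if (any(x < 0, na.rm = TRUE) || anyNA(x)) stopf("abundances must be nonnegative and complete")
  tot <- sum(x)
  if (tot <= 0) stopf("all-zero abundance vector")
  p <- x / tot
  p[p > 0]
}

#' @rdname shannon
#' @export
chao1 <- function(x) {
  if (anyNA(x) || any(x < 0) || any(x != round(x))) {
    stopf("chao1 requires nonnegative integer counts")
  }
  s_obs <- sum(x > 0)
  if (s_obs == 0) stopf("all-zero abundance vector")
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Per-sample alpha diversity for a count table
#'
#' @param x a counts `feature_table`.
#' @return data.frame with columns `sample_id`, `shannon`, `simpson`,
#'   `chao1`.
#' @export
alpha_diversity <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  if (x$kind != "counts") stopf("alpha diversity is computed on raw counts")
  v <- x$values
  data.frame(sample_id = colnames(v),
             shannon = apply(v, 2, shannon),
             simpson = apply(v, 2, simpson),
             chao1 = apply(v, 2, chao1),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' sum |x - y| / sum (x + y); 0 for identical vectors, 1 for disjoint
#' supports.
#'
#' @param x,y aligned nonnegative numeric vectors, not both all-zero.
#' @return dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stopf("vectors must have equal length")
  if (any(x < 0) || any(y < 0)) stopf("abundances must be nonnegative")
  denom <- sum(x + y)
  if (denom == 0) stopf("both vectors are all-zero")
  sum(abs(x - y)) / denom
}

#' Pairwise sample distance matrix
#'
#' Computes the sample-by-sample dissimilarity matrix (Bray-Curtis by
#' default, delegated to [vegan::vegdist()]); either on the table as
#' supplied or after conversion to relative abundances.
#'
#' @param x a `feature_table`.
#' @param metric dissimilarity index understood by [vegan::vegdist()].
#' @param use_relative if `TRUE`, normalize counts to proportions first.
#' @return symmetric numeric matrix with sample ids as dimnames.
#' @export
distance_matrix <- function(x, metric = "bray", use_relative = FALSE) {
  stopifnot(inherits(x, "feature_table"))
  if (ncol(x$values) < 2) stopf("need at least 2 samples")
  if (use_relative) x <- relative_abundance(x)
  d <- vegan::vegdist(t(x$values), method = metric)
  as.matrix(d)
}

as_dist_matrix <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || any(abs(D - t(D)) > 1e-10) ||
      any(diag(D) != 0) || any(D < 0)) {
    stopf("not a valid distance matrix (square, symmetric, zero diagonal, nonnegative)")
  }
  D
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers -1/2 D^2 and eigendecomposes it ([stats::cmdscale()]).
#' Negative eigenvalues, which arise for non-Euclidean dissimilarities such
#' as Bray-Curtis, are reported as-is and excluded from the
#' proportion-explained denominator; no correction is applied.
#'
#' @param D distance matrix (square matrix or `dist`).
#' @param n_axes number of coordinate axes to keep (at most n samples - 1).
#' @return list with `coordinates` (samples x axes), `eigenvalues` (all),
#'   and `proportion_explained` (per retained axis, over positive
#'   eigenvalues).
#' @export
pcoa <- function(D, n_axes = 2) {
  D <- as_dist_matrix(D)
  n <- nrow(D)
  if (n_axes < 1 || n_axes > n - 1) {
    stopf("n_axes must be between 1 and %d", n - 1)
  }
  fit <- stats::cmdscale(stats::as.dist(D), k = n_axes, eig = TRUE)
  coords <- fit$points
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 1)
  rownames(coords) <- rownames(D)
  pos <- fit$eig[fit$eig > 0]
  structure(list(coordinates = coords,
                 eigenvalues = fit$eig,
                 proportion_explained = fit$eig[seq_len(ncol(coords))] / sum(pos)),
            class = "pcoa_result")
}

#' Write a distance matrix as square TSV
#' @param D distance matrix.
#' @param path output path.
#' @export
write_distance_matrix <- function(D, path) {
  D <- as_dist_matrix(D)
  df <- data.frame(sample_id = rownames(D), D, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
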
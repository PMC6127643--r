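# Cache of permutation matrices for the exact Spearman test (n! x n).
.perm_cache <- new.env(parent = emptyenv())

.permutations <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  build <- function(v) {
    if (length(v) == 1) return(matrix(v, 1, 1))
    do.call(rbind, lapply(seq_along(v), function(i) {
      cbind(v[i], build(v[-i]))
    }))
  }
  p <- build(seq_len(n))
  .perm_cache[[key]] <- p
  p
}

#' Spearman rank correlation with small-sample exact p-value
#'
#' Correlation of average ranks. For n <= `exact_max_n` (default 9, so the
#' study's n = 8 design is covered) the two-sided p-value is computed by
#' full enumeration of all n! orderings — valid with ties, where the
#' classical S-statistic tables are not. For larger n the usual
#' t-approximation t = rho sqrt((n - 2) / (1 - rho^2)) on n - 2 df is used.
#' Pairs with a missing member are dropped listwise.
#'
#' @param x,y aligned numeric vectors, at least 4 complete pairs.
#' @param exact_max_n largest n for which the exact permutation p is used.
#' @return list: `rho`, `p_value`, `n`, `method` ("exact" or "t-approx").
#' @export
spearman <- function(x, y, exact_max_n = 9) {
  if (length(x) != length(y)) stopf("vectors must align")
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) stopf("need at least 4 complete pairs")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    stopf("constant vector: Spearman correlation undefined")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exact_max_n) {
    perms <- .permutations(n)
    rx0 <- rx - mean(rx)
    ry0 <- ry - mean(ry)
    scale <- sqrt(sum(rx0^2) * sum(ry0^2))
    rho_perm <- (matrix(ry0[perms], nrow(perms), n) %*% rx0) / scale
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- min(1, 2 * stats::pt(-abs(tt), df = n - 2))
    p <- max(p, .Machine$double.xmin)
    method <- "t-approx"
  }
  list(rho = unname(rho), p_value = p, n = n, method = method)
}

#' Bonferroni-corrected critical p-value
#'
#' @param alpha family-wise error rate.
#' @param m number of tests (>= 1).
#' @return alpha / m.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (m < 1) stopf("m must be >= 1")
  alpha / m
}

#' Screen taxon-metabolite Spearman correlations within one method
#'
#' Tests every taxon x metabolite pair within a collection method (e.g.
#' genus relative abundances against SCFA concentrations), flagging results
#' at the nominal `alpha` and after Bonferroni correction over the number
#' of tests actually performed (overridable via `m`, since published
#' critical values sometimes imply a different family size).
#'
#' Columns of the two tables are aligned by participant: either pass tables
#' whose columns are already subject ids, or supply `design` and `method`
#' so sample columns can be mapped to subjects.
#'
#' @param taxa a `feature_table` of taxon abundances.
#' @param metabolites a `feature_table` of metabolite values.
#' @param design optional `sample_design` used to map samples to subjects.
#' @param method method label (required with `design`).
#' @param alpha nominal significance level (default 0.05).
#' @param m Bonferroni family size; default = number of tests performed.
#' @return data.frame sorted by p-value: `taxon`, `metabolite`, `method`,
#'   `rho`, `p_value`, `n`, `significant_nominal`, `significant_bonferroni`.
#' @export
correlation_screen <- function(taxa, metabolites, design = NULL, method = NULL,
                               alpha = 0.05, m = NULL) {
  tv <- taxa$values
  mv <- metabolites$values
  if (!is.null(design)) {
    if (is.null(method)) stopf("method is required when design is given")
    tmap <- design_subject_of(design, method)
    mmap <- design_subject_of(design, method)
    tcol <- intersect(names(tmap), colnames(tv))
    mcol <- intersect(names(mmap), colnames(mv))
    tv <- tv[, tcol, drop = FALSE]; colnames(tv) <- tmap[tcol]
    mv <- mv[, mcol, drop = FALSE]; colnames(mv) <- mmap[mcol]
  }
  subjects <- intersect(colnames(tv), colnames(mv))
  if (length(subjects) < 4) stopf("fewer than 4 overlapping participants")
  res <- list()
  for (tx in rownames(tv)) {
    for (mb in rownames(mv)) {
      s <- tryCatch(spearman(tv[tx, subjects], mv[mb, subjects]),
                    error = function(e) NULL)
      if (is.null(s)) next
      res[[length(res) + 1L]] <- data.frame(
        taxon = tx, metabolite = mb,
        method = method %||% NA_character_,
        rho = s$rho, p_value = s$p_value, n = s$n,
        stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0) stopf("no testable taxon-metabolite pairs")
  out <- do.call(rbind, res)
  m_tests <- m %||% nrow(out)
  crit <- bonferroni_threshold(alpha, m_tests)
  out$significant_nominal <- out$p_value < alpha
  out$significant_bonferroni <- out$p_value < crit
  out <- out[order(out$p_value, out$taxon, out$metabolite), ]
  rownames(out) <- NULL
  attr(out, "m_tests") <- m_tests
  attr(out, "bonferroni_critical") <- crit
  out
}
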
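#' Synthetic ground truth record
#'
#' Every generator returns, alongside the data, a `synthetic_truth` list
#' recording the variance components actually used (hence the true ICC
#' sigma_b^2 / (sigma_b^2 + sigma_w^2) per feature), any censoring
#' configuration, and the seed — enough to compute every expected estimate
#' in the tests with no hidden parameters.
#'
#' @name synthetic_truth
NULL

new_truth <- function(...) structure(list(...), class = "synthetic_truth")

#' Simulate paired gold/alternate scalar measurements
#'
#' One-way variance-components model: subject effect ~ N(0, icc * sigma2),
#' each of the two replicates adds independent N(0, (1 - icc) * sigma2)
#' noise, so the population ICC is exactly `true_icc`.
#'
#' @param n_subjects number of subjects (>= 3).
#' @param true_icc target intraclass correlation in \[0, 1\].
#' @param total_variance sigma2, the total variance per measurement.
#' @param seed RNG seed (required; generation is bit-reproducible).
#' @param method label attached to the pairing (cosmetic).
#' @return list with `pairs` (a `paired_measurements`) and `truth`
#'   (a `synthetic_truth`).
#' @export
generate_paired_scalars <- function(n_subjects, true_icc, total_variance = 1,
                                    seed, method = "simulated") {
  if (true_icc < 0 || true_icc > 1) stopf("true_icc must be in [0, 1]")
  if (total_variance <= 0) stopf("total_variance must be positive")
  if (n_subjects < 3) stopf("need at least 3 subjects")
  if (missing(seed) || is.null(seed)) stopf("a seed is required")
  sb2 <- true_icc * total_variance
  sw2 <- (1 - true_icc) * total_variance
  dat <- with_seed(seed, {
    u <- stats::rnorm(n_subjects, 0, sqrt(sb2))
    list(g = u + stats::rnorm(n_subjects, 0, sqrt(sw2)),
         m = u + stats::rnorm(n_subjects, 0, sqrt(sw2)))
  })
  pairs <- structure(list(subject_id = paste0("S", seq_len(n_subjects)),
                          gold = dat$g, alt = dat$m,
                          variable = "simulated_scalar", method = method),
                     class = "paired_measurements")
  list(pairs = pairs,
       truth = new_truth(true_icc = true_icc, sigma_b2 = sb2, sigma_w2 = sw2,
                         seed = seed))
}

#' Simulate a paired-design microbial community count table
#'
#' Emulates the collection-method study shape (default 8 subjects x 5
#' methods = 40 samples): each subject owns a log-abundance profile drawn
#' around a common base composition with spread `subject_sd`; every sample
#' perturbs it with method noise of spread `method_sd`; counts are drawn
#' Multinomial(depth, softmax(log-abundances)) with Poisson depths around
#' `depth_mean`. A larger `subject_sd`/`method_sd` ratio yields stronger
#' subject clustering in Bray-Curtis space (the inter-individual-dominance
#' regime the method-comparison design assumes).
#'
#' @param n_subjects number of subjects (default 8).
#' @param methods method labels; the first is the gold standard.
#' @param n_taxa number of taxa (default 200).
#' @param subject_sd between-subject log-abundance SD (default 1).
#' @param method_sd within-subject method-noise SD (default 0.3).
#' @param depth_mean mean sequencing depth (default 18000, the study's
#'   average per-sample coverage).
#' @param seed RNG seed (required).
#' @return list: `table` (counts `feature_table`), `design`
#'   (`sample_design`), `truth` (`synthetic_truth` incl. drawn depths).
#' @export
generate_community <- function(n_subjects = 8,
                               methods = c("immediate_freezing", "omnigene_gut",
                                           "ethanol_95", "rnalater", "fta_card"),
                               n_taxa = 200, subject_sd = 1, method_sd = 0.3,
                               depth_mean = 18000, seed) {
  if (length(methods) < 2) stopf("need at least 2 methods (gold + alternates)")
  if (depth_mean < 1) stopf("depth_mean must be >= 1")
  if (missing(seed) || is.null(seed)) stopf("a seed is required")
  out <- with_seed(seed, {
    base <- stats::rnorm(n_taxa, 0, 2)   # heavy-tailed base composition
    counts <- NULL
    ids <- character(0); subj <- character(0); meth <- character(0)
    depths <- integer(0)
    for (i in seq_len(n_subjects)) {
      profile <- base + stats::rnorm(n_taxa, 0, subject_sd)
      for (m in methods) {
        lam <- profile + stats::rnorm(n_taxa, 0, method_sd)
        p <- exp(lam - max(lam)); p <- p / sum(p)
        depth <- max(1L, stats::rpois(1, depth_mean))
        counts <- cbind(counts, stats::rmultinom(1, depth, p))
        ids <- c(ids, paste0("S", i, ".", m))
        subj <- c(subj, paste0("S", i)); meth <- c(meth, m)
        depths <- c(depths, depth)
      }
    }
    list(counts = counts, ids = ids, subj = subj, meth = meth, depths = depths)
  })
  rownames(out$counts) <- paste0("OTU", seq_len(n_taxa))
  colnames(out$counts) <- out$ids
  list(table = feature_table(out$counts, kind = "counts"),
       design = sample_design(out$ids, out$subj, out$meth,
                              gold_method = methods[1]),
       truth = new_truth(subject_sd = subject_sd, method_sd = method_sd,
                         depth_mean = depth_mean,
                         depths = stats::setNames(out$depths, out$ids),
                         seed = seed))
}

#' Simulate a paired-design metabolite intensity table with censoring
#'
#' Per feature: a latent log-intensity follows the variance-components
#' model with a true ICC drawn uniformly in `icc_range` (unit total latent
#' variance, feature-specific mean level). Intensities are exp(latent).
#' Cells whose latent value falls below the feature's marginal
#' `censor_quantile` (plus an optional per-method shift of the threshold)
#' are set missing, emulating detection-limit censoring that differs
#' between collection methods.
#'
#' @param n_subjects number of participants (default 8).
#' @param methods method labels; the first is the gold standard.
#' @param n_features number of metabolites (default 200).
#' @param icc_range range the per-feature true ICC is drawn from.
#' @param censor_quantile fraction of each feature's latent values censored
#'   at shift 0 (default 0.25, in \[0, 1)).
#' @param method_shifts named numeric vector of per-method threshold shifts
#'   in latent-SD units (positive = more censoring); default all zero.
#' @param seed RNG seed (required).
#' @return list: `table` (intensity `feature_table` with NAs), `design`,
#'   `truth` (per-feature `true_icc`, variances, censoring setup, seed).
#' @export
generate_metabolome <- function(n_subjects = 8,
                                methods = c("immediate_freezing", "omnigene_gut",
                                            "ethanol_95", "fta_card"),
                                n_features = 200, icc_range = c(0.2, 0.9),
                                censor_quantile = 0.25, method_shifts = NULL,
                                seed) {
  if (censor_quantile < 0 || censor_quantile >= 1) {
    stopf("censor_quantile must be in [0, 1)")
  }
  if (length(icc_range) != 2 || icc_range[1] > icc_range[2] ||
      icc_range[1] < 0 || icc_range[2] > 1) {
    stopf("icc_range must be an ordered pair within [0, 1]")
  }
  if (missing(seed) || is.null(seed)) stopf("a seed is required")
  if (is.null(method_shifts)) {
    method_shifts <- stats::setNames(rep(0, length(methods)), methods)
  }
  n_m <- length(methods)
  out <- with_seed(seed, {
    icc <- stats::runif(n_features, icc_range[1], icc_range[2])
    mu <- stats::rnorm(n_features, 7, 1)
    latent <- matrix(NA_real_, n_features, n_subjects * n_m)
    for (f in seq_len(n_features)) {
      u <- stats::rnorm(n_subjects, 0, sqrt(icc[f]))
      e <- matrix(stats::rnorm(n_subjects * n_m, 0, sqrt(1 - icc[f])),
                  n_subjects, n_m)
      latent[f, ] <- as.vector(t(u + e)) + mu[f]  # sample order: subj x method
    }
    list(icc = icc, mu = mu, latent = latent)
  })
  ids <- as.vector(vapply(seq_len(n_subjects), function(i)
    paste0("S", i, ".", methods), character(n_m)))
  subj <- rep(paste0("S", seq_len(n_subjects)), each = n_m)
  meth <- rep(methods, times = n_subjects)
  intensities <- exp(out$latent)
  if (censor_quantile > 0 || any(method_shifts != 0)) {
    for (f in seq_len(nrow(out$latent))) {
      thr0 <- stats::quantile(out$latent[f, ], censor_quantile, type = 7)
      miss <- out$latent[f, ] < thr0 + method_shifts[meth]
      intensities[f, miss] <- NA_real_
    }
  }
  rownames(intensities) <- paste0("MET", seq_len(n_features))
  colnames(intensities) <- ids
  list(table = feature_table(intensities, kind = "intensity"),
       design = sample_design(ids, subj, meth, gold_method = methods[1]),
       truth = new_truth(true_icc = stats::setNames(out$icc, rownames(intensities)),
                         sigma_b2 = stats::setNames(out$icc, rownames(intensities)),
                         sigma_w2 = stats::setNames(1 - out$icc, rownames(intensities)),
                         censor_quantile = censor_quantile,
                         method_shifts = method_shifts, seed = seed))
}
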
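# Fill in defaults for a pipeline configuration list.
pipeline_config <- function(config = list()) {
  defaults <- list(seed = 1L, min_reads = 1000, n_permutations = 999,
                   bootstrap = 1000, detectability_levels = c(0.5, 0.75, 1),
                   icc_level = 0.75, taxa = NULL, n_top_taxa = 3,
                   scfas = NULL, known_features = NULL, alpha = 0.05,
                   bonferroni_m = NULL, use_relative = FALSE,
                   correlation_methods = NULL)
  defaults[names(config)] <- config
  defaults
}

# Deterministic per-call seed stream derived from the base seed; stays
# well below 2^31.
seed_stream <- function(base) {
  i <- 0L
  function() {
    i <<- i + 1L
    (as.integer(base) + 7919L * i) %% 2000000011L
  }
}

#' Microbiome concordance analysis
#'
#' The full 16S-side analysis: depth QC, per-sample alpha diversity with
#' Kruskal-Wallis across methods, per-method ICC (with bootstrap CI) of
#' each alpha index against the gold standard, Bray-Curtis distances with
#' PERMANOVA and PCoA, per-method distance-based ICC with bootstrap CI, and
#' per-phylum ICCs on square-root relative abundances for the dominant
#' phyla.
#'
#' @param counts a counts `feature_table` (OTU/taxon level).
#' @param taxonomy a `taxonomy_map`.
#' @param design a `sample_design` (gold method designated).
#' @param config named list of options; see Details of [run_all()].
#' @return list of report sections.
#' @export
run_microbiome_concordance <- function(counts, taxonomy, design,
                                       config = list()) {
  cfg <- pipeline_config(config)
  next_seed <- seed_stream(cfg$seed)
  qc <- filter_low_depth(counts, cfg$min_reads)
  tab <- qc$table
  meta <- design$samples[design$samples$sample_id %in% colnames(tab$values), ]
  methods <- setdiff(unique(meta$method), design$gold_method)

  alpha <- alpha_diversity(tab)
  groups <- meta$method[match(alpha$sample_id, meta$sample_id)]
  kruskal <- lapply(c("shannon", "simpson", "chao1"), function(ix) {
    kt <- kruskal_wallis(alpha[[ix]], groups)
    data.frame(index = ix, statistic = kt$statistic, p_value = kt$p_value)
  })
  kruskal <- do.call(rbind, kruskal)

  alpha_icc <- list()
  for (ix in c("shannon", "simpson", "chao1")) {
    vals <- stats::setNames(alpha[[ix]], alpha$sample_id)
    for (m in methods) {
      est <- tryCatch({
        pr <- pair_by_subject(vals, design, m, variable = ix)
        icc_oneway(pr, n_bootstrap = cfg$bootstrap, seed = next_seed())
      }, error = function(e) NULL)
      if (is.null(est)) next
      alpha_icc[[length(alpha_icc) + 1L]] <- data.frame(
        index = ix, method = m, estimate = est$estimate,
        ci_low = est$ci_low, ci_high = est$ci_high,
        n_subjects = est$n_subjects, stringsAsFactors = FALSE)
    }
  }
  alpha_icc <- do.call(rbind, alpha_icc)

  D <- distance_matrix(tab, use_relative = cfg$use_relative)
  perm <- permanova(D, groups, n_permutations = cfg$n_permutations,
                    seed = next_seed())
  ord <- pcoa(D, n_axes = min(2, nrow(D) - 1))

  beta_icc <- do.call(rbind, lapply(methods, function(m) {
    est <- bootstrap_distance_icc(D, design, m, B = cfg$bootstrap,
                                  seed = next_seed())
    data.frame(method = m, estimate = est$estimate, ci_low = est$ci_low,
               ci_high = est$ci_high, n_subjects = est$n_subjects,
               stringsAsFactors = FALSE)
  }))

  phy <- sqrt_transform(relative_abundance(aggregate_by_rank(tab, taxonomy,
                                                             "phylum")))
  taxa <- cfg$taxa
  if (is.null(taxa)) {
    taxa <- names(sort(rowMeans(phy$values^2), decreasing = TRUE))
    taxa <- utils::head(taxa, cfg$n_top_taxa)
  }
  taxon_icc <- list()
  for (tx in intersect(taxa, rownames(phy$values))) {
    vals <- stats::setNames(phy$values[tx, ], colnames(phy$values))
    for (m in methods) {
      est <- tryCatch({
        pr <- pair_by_subject(vals, design, m, variable = tx)
        icc_oneway(pr, n_bootstrap = cfg$bootstrap, seed = next_seed())
      }, error = function(e) NULL)
      if (is.null(est)) next
      taxon_icc[[length(taxon_icc) + 1L]] <- data.frame(
        taxon = tx, method = m, estimate = est$estimate,
        ci_low = est$ci_low, ci_high = est$ci_high, stringsAsFactors = FALSE)
    }
  }
  taxon_icc <- if (length(taxon_icc)) do.call(rbind, taxon_icc) else NULL

  list(dropped_samples = qc$dropped, alpha = alpha, kruskal = kruskal,
       alpha_icc = alpha_icc,
       permanova = list(statistic = perm$statistic, p_value = perm$p_value,
                        n_permutations = perm$n_permutations, seed = perm$seed),
       pcoa = list(proportion_explained = ord$proportion_explained,
                   eigenvalues = ord$eigenvalues),
       beta_icc = beta_icc, taxon_icc = taxon_icc)
}

#' Untargeted metabolomics concordance analysis
#'
#' Builds the detectability/overlap table (per method, at levels all /
#' >=50% / >=75% / 100%: total features, shared-with-gold count and
#' percentage, optionally restricted to annotated "known" features), then
#' for each method preprocesses the shared >= `icc_level` feature set
#' (half-minimum imputation, quantile normalization and log10, each within
#' method) and profiles per-metabolite ICCs against the gold standard.
#'
#' @param intensity an intensity `feature_table` (missing = not detected).
#' @param design a `sample_design`.
#' @param config named list of options; see [run_all()].
#' @return list with `detectability_table`, `icc_summary`, `icc_estimates`.
#' @export
run_metabolome_concordance <- function(intensity, design, config = list()) {
  cfg <- pipeline_config(config)
  present <- unique(design$samples$method[design$samples$sample_id %in%
                                            colnames(intensity$values)])
  gold <- design$gold_method
  if (!gold %in% present) stopf("gold method '%s' absent from intensity table", gold)
  methods <- setdiff(present, gold)

  det <- lapply(stats::setNames(present, present), function(m)
    detectability(intensity, design, m))
  known <- cfg$known_features

  levels_ <- c(0, cfg$detectability_levels)
  level_label <- function(l) if (l == 0) "all" else sprintf("%d", round(100 * l))
  rows <- list()
  for (l in levels_) {
    sets <- lapply(det, function(fr) {
      if (l == 0) names(fr)[fr > 0] else names(fr)[fr >= l - 1e-12]
    })
    for (m in c(gold, methods)) {
      shared <- pct <- NA_real_
      known_n <- known_shared <- known_pct <- NA_real_
      if (m != gold) {
        shared <- length(intersect(sets[[gold]], sets[[m]]))
        # percent of gold is undefined when the gold set is empty at a level
        if (length(sets[[gold]]) > 0) {
          pct <- overlap_with_gold(sets[[gold]], sets[[m]])$percent
        }
      }
      if (!is.null(known)) {
        known_n <- length(intersect(sets[[m]], known))
        if (m != gold) {
          gold_known <- intersect(sets[[gold]], known)
          known_shared <- length(intersect(gold_known, sets[[m]]))
          if (length(gold_known) > 0) {
            known_pct <- overlap_with_gold(gold_known,
                                           intersect(sets[[m]], known))$percent
          }
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        level = level_label(l), method = m, n_features = length(sets[[m]]),
        shared_with_gold = shared, percent_of_gold = pct,
        n_known = known_n, known_shared = known_shared,
        known_percent = known_pct, stringsAsFactors = FALSE)
    }
  }
  table1 <- do.call(rbind, rows)

  icc_summary <- list(); icc_estimates <- list()
  for (m in methods) {
    shared <- intersect(names(det[[gold]])[det[[gold]] >= cfg$icc_level - 1e-12],
                        names(det[[m]])[det[[m]] >= cfg$icc_level - 1e-12])
    if (length(shared) == 0) next
    sub <- structure(list(values = intensity$values[shared, , drop = FALSE],
                          kind = "intensity"), class = "feature_table")
    prep <- function(mm) {
      t2 <- half_min_impute(sub, design, mm)
      t2 <- quantile_normalize(t2, design, mm)
      cols <- intersect(design_samples(design, mm), colnames(t2$values))
      v <- log10(t2$values[, cols, drop = FALSE])
      colnames(v) <- design_subject_of(design, mm)[cols]
      feature_table(v, kind = "log_intensity")
    }
    prof <- metabolite_icc_profile(prep(gold), prep(m), features = shared)
    icc_summary[[length(icc_summary) + 1L]] <-
      cbind(data.frame(method = m, stringsAsFactors = FALSE), prof$summary)
    est <- prof$estimates; est$method <- m
    icc_estimates[[length(icc_estimates) + 1L]] <- est
  }
  list(detectability_table = table1,
       icc_summary = if (length(icc_summary)) do.call(rbind, icc_summary) else NULL,
       icc_estimates = if (length(icc_estimates)) do.call(rbind, icc_estimates) else NULL)
}

#' Targeted SCFA concordance analysis
#'
#' Per-SCFA detectability by method, then per-SCFA one-way ICC with
#' bootstrap CI against the gold standard, restricted to SCFAs with
#' >= `icc_level` detectability in both the gold standard and the method.
#' Configured SCFAs absent from the table are skipped and listed.
#'
#' @param scfa an intensity `feature_table` of SCFA concentrations.
#' @param design a `sample_design`.
#' @param config named list; `scfas` names the panel (default: all rows).
#' @return list with `detectability`, `icc`, `skipped`.
#' @export
run_targeted_concordance <- function(scfa, design, config = list()) {
  cfg <- pipeline_config(config)
  next_seed <- seed_stream(cfg$seed + 104729L)
  panel <- cfg$scfas %||% rownames(scfa$values)
  skipped <- setdiff(panel, rownames(scfa$values))
  panel <- intersect(panel, rownames(scfa$values))
  present <- unique(design$samples$method[design$samples$sample_id %in%
                                            colnames(scfa$values)])
  gold <- design$gold_method
  methods <- setdiff(present, gold)
  det <- lapply(stats::setNames(present, present), function(m)
    detectability(scfa, design, m)[panel])
  det_df <- do.call(rbind, lapply(present, function(m)
    data.frame(scfa = panel, method = m, detectability = unname(det[[m]]),
               stringsAsFactors = FALSE)))
  icc <- list()
  for (m in methods) {
    for (f in panel) {
      if (det[[gold]][f] < cfg$icc_level - 1e-12 ||
          det[[m]][f] < cfg$icc_level - 1e-12) next
      vals <- stats::setNames(scfa$values[f, ], colnames(scfa$values))
      est <- tryCatch({
        pr <- pair_by_subject(vals, design, m, variable = f)
        icc_oneway(pr, n_bootstrap = cfg$bootstrap, seed = next_seed())
      }, error = function(e) NULL)
      if (is.null(est)) next
      icc[[length(icc) + 1L]] <- data.frame(
        scfa = f, method = m, estimate = est$estimate, ci_low = est$ci_low,
        ci_high = est$ci_high, n_subjects = est$n_subjects,
        stringsAsFactors = FALSE)
    }
  }
  list(detectability = det_df,
       icc = if (length(icc)) do.call(rbind, icc) else NULL,
       skipped = skipped)
}

#' Genus-SCFA correlation screen across methods
#'
#' Aggregates counts to genus, converts to square-root relative abundances
#' and screens Spearman correlations against the configured SCFA panel
#' within each method present in both assays.
#'
#' @param counts a counts `feature_table`.
#' @param taxonomy a `taxonomy_map`.
#' @param scfa an intensity `feature_table` of SCFA concentrations.
#' @param design a `sample_design`.
#' @param config named list; `scfas`, `alpha`, `bonferroni_m`,
#'   `correlation_methods` are honoured.
#' @return data.frame of correlation results across methods (possibly with
#'   zero rows when the SCFA panel is empty).
#' @export
run_correlation_screen <- function(counts, taxonomy, scfa, design,
                                   config = list()) {
  cfg <- pipeline_config(config)
  genus <- sqrt_transform(relative_abundance(aggregate_by_rank(counts, taxonomy,
                                                               "genus")))
  panel <- cfg$scfas %||% rownames(scfa$values)
  panel <- intersect(panel, rownames(scfa$values))
  if (length(panel) == 0) {
    return(data.frame(taxon = character(0), metabolite = character(0),
                      method = character(0), rho = numeric(0),
                      p_value = numeric(0), n = integer(0),
                      significant_nominal = logical(0),
                      significant_bonferroni = logical(0)))
  }
  scfa_panel <- structure(list(values = scfa$values[panel, , drop = FALSE],
                               kind = scfa$kind), class = "feature_table")
  in_micro <- unique(design$samples$method[design$samples$sample_id %in%
                                             colnames(counts$values)])
  in_scfa <- unique(design$samples$method[design$samples$sample_id %in%
                                            colnames(scfa$values)])
  methods <- cfg$correlation_methods %||% intersect(in_micro, in_scfa)
  res <- lapply(methods, function(m) {
    tryCatch(correlation_screen(genus, scfa_panel, design, m,
                                alpha = cfg$alpha, m = cfg$bonferroni_m),
             error = function(e) NULL)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0) stopf("no method produced a correlation screen")
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Run the full concordance study from a config file
#'
#' Reads a YAML configuration, obtains inputs (either file paths or a
#' `simulate:` block with generator parameters), runs the microbiome,
#' untargeted-metabolome, targeted-SCFA and correlation sections, and
#' writes a JSON report plus TSV tables and a run log into `out_dir`.
#' Identical config + inputs give byte-identical outputs.
#'
#' Recognized config keys: `seed`, `gold_method`, `min_reads`,
#' `n_permutations`, `bootstrap`, `detectability_levels`, `icc_level`,
#' `taxa`, `scfas`, `known_features`, `alpha`, `bonferroni_m`,
#' `use_relative`, `correlation_methods`; inputs under `inputs:` (paths
#' `counts`, `taxonomy`, `metadata`, `intensity`, `scfa`) or `simulate:`
#' (`community:`, `metabolome:`, `scfa:` blocks of generator arguments).
#'
#' @param config a YAML file path or an equivalent named list.
#' @param out_dir output directory (created if needed); `NULL` skips
#'   writing.
#' @return the report, invisibly (a nested list).
#' @export
run_all <- function(config, out_dir = NULL) {
  cfg_raw <- if (is.character(config)) yaml::read_yaml(config) else config
  cfg <- pipeline_config(cfg_raw)
  if (is.null(cfg_raw$gold_method) && is.null(cfg_raw$simulate)) {
    stopf("config must name gold_method (or use a simulate block)")
  }
  log_lines <- c(sprintf("fecalconcord run; base seed %s", cfg$seed))

  if (!is.null(cfg_raw$simulate)) {
    sim <- cfg_raw$simulate
    com_args <- sim$community %||% list()
    com_args$seed <- com_args$seed %||% (cfg$seed + 11L)
    com <- do.call(generate_community, com_args)
    taxonomy <- simulate_taxonomy(feature_ids(com$table),
                                  seed = cfg$seed + 13L)
    met_args <- sim$metabolome %||% list()
    met_args$seed <- met_args$seed %||% (cfg$seed + 17L)
    met <- do.call(generate_metabolome, met_args)
    scfa_args <- sim$scfa %||% list(n_features = 10, censor_quantile = 0.1)
    scfa_args$seed <- scfa_args$seed %||% (cfg$seed + 19L)
    scfa <- do.call(generate_metabolome, scfa_args)
    rownames(scfa$table$values) <- scfa_names(nrow(scfa$table$values))
    counts <- com$table; design_micro <- com$design
    intensity <- met$table; design_met <- met$design
    scfa_tab <- scfa$table; design_scfa <- scfa$design
    log_lines <- c(log_lines, "inputs: simulated (community, metabolome, scfa)")
  } else {
    inp <- cfg_raw$inputs
    counts <- read_feature_table(inp$counts, kind = "counts")
    taxonomy <- read_taxonomy(inp$taxonomy)
    design_micro <- read_sample_design(inp$metadata, cfg_raw$gold_method)
    design_met <- design_scfa <- design_micro
    intensity <- read_feature_table(inp$intensity, kind = "intensity")
    scfa_tab <- read_feature_table(inp$scfa, kind = "intensity")
    log_lines <- c(log_lines, sprintf("inputs: %s", paste(unlist(inp), collapse = ", ")))
  }

  micro <- run_microbiome_concordance(counts, taxonomy, design_micro, cfg)
  metab <- run_metabolome_concordance(intensity, design_met, cfg)
  targ <- run_targeted_concordance(scfa_tab, design_scfa, cfg)
  # correlation needs the microbiome and SCFA assays on the same design
  corr <- if (identical(design_micro$samples, design_scfa$samples) ||
              is.null(cfg_raw$simulate)) {
    run_correlation_screen(counts, taxonomy, scfa_tab, design_micro, cfg)
  } else {
    # simulated assays have separate sample ids; align SCFA columns to the
    # microbiome design through subject x method
    sc2 <- scfa_tab
    map <- design_scfa$samples
    micro_map <- design_micro$samples
    key <- paste(map$subject_id, map$method)
    mkey <- paste(micro_map$subject_id, micro_map$method)
    idx <- match(key, mkey)
    keep <- !is.na(idx)
    sc2$values <- sc2$values[, map$sample_id[keep], drop = FALSE]
    colnames(sc2$values) <- micro_map$sample_id[idx[keep]]
    run_correlation_screen(counts, taxonomy, sc2, design_micro, cfg)
  }

  report <- list(
    metadata = list(seed = cfg$seed, bootstrap = cfg$bootstrap,
                    n_permutations = cfg$n_permutations,
                    icc_level = cfg$icc_level,
                    gold_method = design_micro$gold_method),
    microbiome = micro, metabolome = metab, targeted = targ,
    correlation = corr)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE,
                         na = "null", dataframe = "rows")
    wt <- function(df, f) if (!is.null(df) && nrow(df))
      utils::write.table(df, file.path(out_dir, f), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    wt(micro$alpha, "alpha_diversity.tsv")
    wt(micro$alpha_icc, "alpha_icc.tsv")
    wt(micro$beta_icc, "beta_icc.tsv")
    wt(micro$taxon_icc, "taxon_icc.tsv")
    wt(metab$detectability_table, "detectability_table.tsv")
    wt(metab$icc_summary, "metabolite_icc_summary.tsv")
    wt(metab$icc_estimates, "metabolite_icc.tsv")
    wt(targ$detectability, "scfa_detectability.tsv")
    wt(targ$icc, "scfa_icc.tsv")
    wt(corr, "correlation.tsv")
    log_lines <- c(log_lines,
                   sprintf("sections: microbiome, metabolome, targeted, correlation"),
                   sprintf("bootstrap B = %d; permutations = %d",
                           cfg$bootstrap, cfg$n_permutations))
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  invisible(report)
}

#' Names for a simulated short-chain fatty acid panel
#' @param n panel size (up to 10).
#' @return character vector of SCFA names, predominant first.
#' @export
scfa_names <- function(n) {
  nm <- c("butyric_acid", "propionic_acid", "acetic_acid", "valeric_acid",
          "isovaleric_acid", "isobutyric_acid", "hexanoic_acid",
          "2-methylbutyric_acid", "heptanoic_acid", "caproic_acid")
  if (n > length(nm)) nm <- c(nm, paste0("scfa_", seq_len(n - length(nm))))
  nm[seq_len(n)]
}

#' Simulate a taxonomy map for generated OTU ids
#'
#' Assigns each feature a random genus nested in a family and one of four
#' common gut phyla; a fraction of features lack a genus annotation so the
#' unclassified-placeholder path is exercised.
#'
#' @param feature_ids character vector of OTU ids.
#' @param seed RNG seed.
#' @param n_genera number of distinct genera to draw from.
#' @param frac_unclassified fraction of features with no genus annotation.
#' @return a `taxonomy_map`.
#' @export
simulate_taxonomy <- function(feature_ids, seed, n_genera = 30,
                              frac_unclassified = 0.1) {
  with_seed(seed, {
    phyla <- c("Firmicutes", "Bacteroidetes", "Actinobacteria", "Proteobacteria")
    genus_pool <- paste0("Genus", seq_len(n_genera))
    genus_phylum <- sample(phyla, n_genera, replace = TRUE,
                           prob = c(0.5, 0.3, 0.1, 0.1))
    gi <- sample.int(n_genera, length(feature_ids), replace = TRUE)
    unc <- stats::runif(length(feature_ids)) < frac_unclassified
    lineage <- vapply(seq_along(feature_ids), function(i) {
      ph <- genus_phylum[gi[i]]
      fam <- paste0("Family", ((gi[i] - 1) %/% 3) + 1)
      gen <- if (unc[i]) "" else genus_pool[gi[i]]
      paste0("k__Bacteria;p__", ph, ";c__C1;o__O1;f__", fam, ";g__", gen)
    }, character(1))
    taxonomy_map(feature_ids, lineage)
  })
}
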
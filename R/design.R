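#' Paired sample design: subject x collection method
#'
#' Maps each sample to its subject and collection method and designates one
#' method as the gold standard (immediate freezing in the motivating study).
#' Each (subject, method) pair may map to at most one sample.
#'
#' @param sample_id,subject_id,method aligned character vectors.
#' @param gold_method the reference method label.
#' @return a `sample_design` object.
#' @export
sample_design <- function(sample_id, subject_id, method, gold_method) {
  df <- data.frame(sample_id = as.character(sample_id),
                   subject_id = as.character(subject_id),
                   method = as.character(method),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample_id)) stopf("duplicate sample ids in design")
  if (!gold_method %in% df$method) {
    stopf("gold method '%s' has no samples in the design", gold_method)
  }
  key <- paste(df$subject_id, df$method, sep = "\r")
  if (anyDuplicated(key)) {
    stopf("design maps more than one sample to the same (subject, method) pair")
  }
  structure(list(samples = df, gold_method = gold_method),
            class = "sample_design")
}

#' @export
print.sample_design <- function(x, ...) {
  cat(sprintf("<sample_design> %d samples, %d subjects, %d methods (gold: %s)\n",
              nrow(x$samples), length(unique(x$samples$subject_id)),
              length(unique(x$samples$method)), x$gold_method))
  invisible(x)
}

#' Read a sample design from a metadata TSV
#'
#' Requires columns `sample_id`, `subject_id`, `method`.
#'
#' @param path TSV path.
#' @param gold_method the reference method label.
#' @return a `sample_design`.
#' @export
read_sample_design <- function(path, gold_method) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  need <- c("sample_id", "subject_id", "method")
  if (!all(need %in% names(df))) {
    stopf("metadata must have columns %s", paste(need, collapse = ", "))
  }
  sample_design(df$sample_id, df$subject_id, df$method, gold_method)
}

#' Write a sample design's metadata TSV
#' @param x a `sample_design`.
#' @param path output path.
#' @export
write_sample_design <- function(x, path) {
  utils::write.table(x$samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

design_samples <- function(design, method) {
  design$samples$sample_id[design$samples$method == method]
}

design_methods <- function(design) unique(design$samples$method)

# sample_id -> subject_id lookup restricted to one method
design_subject_of <- function(design, method) {
  s <- design$samples[design$samples$method == method, ]
  stats::setNames(s$subject_id, s$sample_id)
}

#' Pair per-sample values by subject against the gold standard
#'
#' For a scalar measured on every sample (an alpha-diversity index, a phylum
#' relative abundance, a metabolite level), pull out the subjects that have
#' both a gold-standard sample and a sample from `method` with non-missing
#' values, aligned in the same subject order.
#'
#' @param values named numeric vector, names = sample ids.
#' @param design a `sample_design`.
#' @param method the alternate method to pair against the gold standard.
#' @param variable optional variable name carried along for reporting.
#' @return a `paired_measurements` object with fields `subject_id`, `gold`,
#'   `alt`, `variable`, `method`.
#' @export
pair_by_subject <- function(values, design, method, variable = NA_character_) {
  stopifnot(inherits(design, "sample_design"))
  if (method == design$gold_method) {
    stopf("method must differ from the gold standard '%s'", design$gold_method)
  }
  gmap <- design_subject_of(design, design$gold_method)
  mmap <- design_subject_of(design, method)
  if (length(mmap) == 0) stopf("no samples for method '%s'", method)
  gmap <- gmap[names(gmap) %in% names(values)]
  mmap <- mmap[names(mmap) %in% names(values)]
  gv <- stats::setNames(values[names(gmap)], gmap)
  mv <- stats::setNames(values[names(mmap)], mmap)
  subjects <- intersect(names(gv)[!is.na(gv)], names(mv)[!is.na(mv)])
  if (length(subjects) < 2) {
    stopf("fewer than 2 subjects have complete (gold, %s) pairs", method)
  }
  structure(list(subject_id = subjects,
                 gold = unname(gv[subjects]),
                 alt = unname(mv[subjects]),
                 variable = variable, method = method),
            class = "paired_measurements")
}

#' @export
print.paired_measurements <- function(x, ...) {
  cat(sprintf("<paired_measurements> %s vs gold, %d subjects%s\n", x$method,
              length(x$subject_id),
              if (is.na(x$variable)) "" else paste0(" [", x$variable, "]")))
  invisible(x)
}
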
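#' Feature tables (features x samples)
#'
#' A `feature_table` holds a nonnegative numeric matrix with features in rows
#' and samples in columns, plus a `kind` tag describing what the numbers are:
#'
#' * `"counts"` — integer sequence/read counts; missing values are not
#'   allowed (absence of a taxon is a zero, not an NA).
#' * `"intensity"` — mass-spectrometry style intensities; `NA` encodes a
#'   value below the detection limit.
#' * `"proportion"` — columns sum to one (relative abundances).
#' * `"sqrt_proportion"` — square-root transformed relative abundances.
#' * `"log_intensity"` — log10-transformed intensities (may be negative).
#'
#' @param values numeric matrix, features in rows, samples in columns.
#' @param kind one of `"counts"`, `"intensity"`, `"proportion"`,
#'   `"sqrt_proportion"`, `"log_intensity"`.
#' @param feature_ids,sample_ids optional identifier vectors; default to the
#'   matrix dimnames.
#' @return A validated `feature_table` object.
#' @export
feature_table <- function(values, kind = c("counts", "intensity", "proportion",
                                           "sqrt_proportion", "log_intensity"),
                          feature_ids = rownames(values),
                          sample_ids = colnames(values)) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(feature_ids)) feature_ids <- paste0("feature_", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(ncol(values)))
  dimnames(values) <- list(as.character(feature_ids), as.character(sample_ids))
  x <- structure(list(values = values, kind = kind), class = "feature_table")
  validate_feature_table(x)
}

#' Validate a feature table against its kind's invariants
#'
#' @param x a `feature_table`.
#' @return `x`, invisibly on success; otherwise an error.
#' @export
validate_feature_table <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  v <- x$values
  if (anyDuplicated(rownames(v))) stopf("duplicate feature identifiers")
  if (anyDuplicated(colnames(v))) stopf("duplicate sample identifiers")
  if (anyNA(v) && x$kind != "intensity") {
    stopf("missing values are only allowed in intensity tables (kind = '%s')",
          x$kind)
  }
  finite <- v[!is.na(v)]
  if (x$kind != "log_intensity" && any(finite < 0)) {
    stopf("negative entries are not allowed in a %s table", x$kind)
  }
  if (x$kind == "counts" && any(finite != round(finite))) {
    stopf("count tables must contain integers")
  }
  if (x$kind == "proportion") {
    cs <- colSums(v)
    if (any(abs(cs - 1) > 1e-9)) {
      stopf("proportion table columns must sum to 1 (found %s)",
            paste(format(cs[abs(cs - 1) > 1e-9]), collapse = ", "))
    }
  }
  invisible(x)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d features x %d samples, kind = %s\n",
              nrow(x$values), ncol(x$values), x$kind))
  if (anyNA(x$values)) {
    cat(sprintf("  missing cells: %d\n", sum(is.na(x$values))))
  }
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Feature and sample identifiers
#' @param x a `feature_table`.
#' @return character vector of identifiers.
#' @export
feature_ids <- function(x) rownames(x$values) %||% character(0)

#' @rdname feature_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Subset a feature table's samples, keeping the kind tag
#' @noRd
ft_select_samples <- function(x, samples) {
  keep <- x$values[, samples, drop = FALSE]
  structure(list(values = keep, kind = x$kind), class = "feature_table")
}

#' Read a feature table from delimited text or BIOM
#'
#' Delimited files must have feature identifiers in the first column and one
#' header row of sample identifiers; the separator is taken from the file
#' extension (`.csv` = comma, anything else = tab). Files ending in `.biom`
#' are parsed with the biomformat package (JSON BIOM).
#'
#' For `kind = "intensity"`, blank cells and the strings `NA`/`NaN` become
#' missing values; for `kind = "counts"` any missing cell is an error.
#'
#' @param path file path.
#' @param kind table kind, see [feature_table()].
#' @return a `feature_table`.
#' @export
read_feature_table <- function(path, kind = "counts") {
  if (grepl("\\.biom$", path, ignore.case = TRUE)) {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stopf("reading BIOM files requires the biomformat package")
    }
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    return(feature_table(m, kind = kind))
  }
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, na.strings = c("NA", "NaN", ""),
                          quote = "\"", comment.char = "")
  m <- as.matrix(df)
  if (kind == "counts" && anyNA(m)) {
    stopf("count table '%s' contains blank or NA cells", basename(path))
  }
  feature_table(m, kind = kind)
}

#' Write a feature table as TSV (features x samples)
#'
#' Round-trips exactly through [read_feature_table()]: identifiers, values
#' and missingness are preserved.
#'
#' @param x a `feature_table`.
#' @param path output path.
#' @export
write_feature_table <- function(x, path) {
  df <- data.frame(feature_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop samples with low sequencing depth
#'
#' Samples whose total read count falls below `min_reads` are excluded, the
#' standard QC step for amplicon libraries that failed on the sequencer.
#'
#' @param x a counts `feature_table`.
#' @param min_reads minimum column sum to retain a sample (default 1000).
#' @return list with `table` (the filtered `feature_table`) and `dropped`
#'   (character vector of removed sample ids).
#' @export
filter_low_depth <- function(x, min_reads = 1000) {
  stopifnot(inherits(x, "feature_table"))
  if (x$kind != "counts") stopf("depth filtering applies to count tables")
  depths <- colSums(x$values)
  drop <- names(depths)[depths < min_reads]
  if (length(drop) == ncol(x$values)) {
    stopf("all %d samples fall below min_reads = %d", length(drop), min_reads)
  }
  keep <- setdiff(colnames(x$values), drop)
  list(table = ft_select_samples(x, keep), dropped = drop)
}

.TAXON_RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus")

#' Read a taxonomy map
#'
#' Expects a TSV with a `feature_id` column and a lineage column of
#' semicolon-delimited ranks from kingdom to genus. Greengenes-style rank
#' prefixes (`k__`, `p__`, ...) are stripped; empty ranks become `NA`.
#'
#' @param path TSV path.
#' @return a `taxonomy_map`: data.frame with columns `feature_id`,
#'   `kingdom` ... `genus`.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  lineage_col <- setdiff(names(df), "feature_id")[1]
  taxonomy_map(df$feature_id, df[[lineage_col]])
}

#' Build a taxonomy map from lineage strings
#'
#' @param feature_ids character vector.
#' @param lineages semicolon-delimited lineage strings aligned with
#'   `feature_ids`.
#' @return a `taxonomy_map` data.frame.
#' @export
taxonomy_map <- function(feature_ids, lineages) {
  parts <- strsplit(as.character(lineages), ";")
  m <- t(vapply(parts, function(p) {
    p <- trimws(p)
    p <- sub("^[a-z]__", "", p)
    p[p == ""] <- NA_character_
    length(p) <- length(.TAXON_RANKS)
    p
  }, character(length(.TAXON_RANKS))))
  out <- data.frame(feature_id = as.character(feature_ids), m,
                    stringsAsFactors = FALSE)
  names(out) <- c("feature_id", .TAXON_RANKS)
  class(out) <- c("taxonomy_map", "data.frame")
  out
}

#' Aggregate a feature table to a taxonomic rank
#'
#' Rows sharing the same lineage down to `rank` are summed. Features lacking
#' an annotation at `rank` are kept under a placeholder naming the deepest
#' annotated rank, e.g. an unannotated genus within family Rikenellaceae
#' becomes `Rikenellaceae_UCG` ("unclassified genus"); features with no
#' annotation at all aggregate under `Unassigned_UC<r>`. Column totals are
#' conserved exactly.
#'
#' @param x a `feature_table`.
#' @param taxonomy a `taxonomy_map` covering (at least) the table's features.
#' @param rank one of `"kingdom"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`.
#' @return a `feature_table` of the same kind with taxon rows.
#' @export
aggregate_by_rank <- function(x, taxonomy, rank) {
  stopifnot(inherits(x, "feature_table"))
  if (!rank %in% .TAXON_RANKS) {
    stopf("unknown rank '%s' (supported: %s)", rank,
          paste(.TAXON_RANKS, collapse = ", "))
  }
  ri <- match(rank, .TAXON_RANKS)
  idx <- match(rownames(x$values), taxonomy$feature_id)
  suffix <- paste0("_UC", toupper(substr(rank, 1, 1)))
  labels <- vapply(seq_along(idx), function(i) {
    if (is.na(idx[i])) return(paste0("Unassigned", suffix))
    lin <- as.character(taxonomy[idx[i], .TAXON_RANKS])[seq_len(ri)]
    if (!is.na(lin[ri])) return(lin[ri])
    deepest <- rev(lin[!is.na(lin)])[1]
    if (is.null(deepest) || is.na(deepest)) deepest <- "Unassigned"
    paste0(deepest, suffix)
  }, character(1))
  groups <- factor(labels, levels = unique(labels))
  agg <- rowsum(x$values, groups)  # keeps factor level order
  feature_table(agg, kind = x$kind)
}
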
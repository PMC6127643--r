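# Shared fixture builders. Everything is generated in code; nothing binary.

# Tiny fixed count table: 3 features x 4 samples, 2 subjects x 2 methods.
tiny_counts <- function() {
  m <- matrix(c(3, 1, 0,
                4, 2, 0,
                1, 5, 2,
                2, 6, 1), nrow = 3,
              dimnames = list(c("OTU1", "OTU2", "OTU3"),
                              c("S1.gold", "S1.alt", "S2.gold", "S2.alt")))
  feature_table(m, kind = "counts")
}

tiny_design <- function() {
  sample_design(c("S1.gold", "S1.alt", "S2.gold", "S2.alt"),
                c("S1", "S1", "S2", "S2"),
                c("gold", "alt", "gold", "alt"), gold_method = "gold")
}

# Paired design over n subjects and the given methods (first = gold),
# sample ids "S<i>.<method>".
paired_design <- function(n, methods = c("gold", "alt")) {
  ids <- as.vector(outer(methods, paste0("S", seq_len(n)),
                         function(m, s) paste0(s, ".", m)))
  sample_design(ids, rep(paste0("S", seq_len(n)), each = length(methods)),
                rep(methods, times = n), gold_method = methods[1])
}

# Euclidean distance matrix from named 1-D values.
euclid_dist <- function(values) {
  D <- as.matrix(stats::dist(values))
  dimnames(D) <- list(names(values), names(values))
  D
}

# Distance matrix + design embedding paired scalar values (gold/alt per
# subject) as 1-D points; the bridge between the scalar and distance ICC.
paired_1d_geometry <- function(gold, alt) {
  n <- length(gold)
  ids <- c(paste0("S", seq_len(n), ".gold"), paste0("S", seq_len(n), ".alt"))
  vals <- stats::setNames(c(gold, alt), ids)
  design <- sample_design(ids, rep(paste0("S", seq_len(n)), 2),
                          rep(c("gold", "alt"), each = n), "gold")
  list(D = euclid_dist(vals), design = design)
}

write_tsv_fixture <- function(df, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  utils::write.table(df, path, sep = if (ext == ".csv") "," else "\t",
                     quote = FALSE, row.names = FALSE)
  path
}
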
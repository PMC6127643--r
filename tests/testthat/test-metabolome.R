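# 2 features x 8 subjects x 2 methods with hand-placed missingness.
met_fixture <- function() {
  n <- 8
  ids <- c(paste0("S", 1:n, ".gold"), paste0("S", 1:n, ".alt"))
  design <- sample_design(ids, rep(paste0("S", 1:n), 2),
                          rep(c("gold", "alt"), each = n), "gold")
  v <- matrix(seq(2, by = 2, length.out = 2 * 2 * n), nrow = 2)
  dimnames(v) <- list(c("m1", "m2"), ids)
  list(table = feature_table(v, "intensity"), design = design)
}

test_that("detectability counts non-missing participants per method", {
  fx <- met_fixture()
  v <- fx$table$values
  v["m1", paste0("S", 1:2, ".gold")] <- NA   # 6 of 8 detected
  v["m2", paste0("S", 1:8, ".alt")] <- NA    # all missing
  tb <- feature_table(v, "intensity")
  expect_equal(unname(detectability(tb, fx$design, "gold")["m1"]), 0.75)
  expect_equal(unname(detectability(tb, fx$design, "gold")["m2"]), 1)
  expect_equal(unname(detectability(tb, fx$design, "alt")["m2"]), 0)
  expect_error(detectability(tb, fx$design, "nope"), "no samples")
})

test_that("min_detected_count is the ceiling rule", {
  expect_identical(min_detected_count(0.75, 8), 6L)
  expect_identical(min_detected_count(1, 8), 8L)
  expect_identical(min_detected_count(0.5, 7), 4L)
  expect_error(min_detected_count(0, 8), "level")
  expect_error(min_detected_count(1.2, 8), "level")
})

test_that("filter_by_detectability matches a brute-force recount", {
  sim <- generate_metabolome(n_subjects = 8, methods = c("gold", "alt"),
                             n_features = 60, censor_quantile = 0.3, seed = 17)
  for (lvl in c(0, 0.5, 0.75, 1)) {
    kept <- feature_ids(filter_by_detectability(sim$table, sim$design, "alt", lvl))
    cols <- paste0("S", 1:8, ".alt")
    brute <- rownames(sim$table$values)[
      rowSums(!is.na(sim$table$values[, cols])) >= lvl * 8]
    expect_setequal(kept, brute)
  }
  expect_length(feature_ids(filter_by_detectability(sim$table, sim$design,
                                                    "alt", 0)), 60)
})

test_that("overlap_with_gold reproduces the published percentage arithmetic", {
  gold <- paste0("m", 1:621)
  ov <- overlap_with_gold(gold, paste0("m", 1:213))
  expect_identical(ov$shared, 213L)
  expect_equal(ov$percent, 34.3)
  expect_equal(overlap_with_gold(gold, gold)$percent, 100.0)
  expect_equal(overlap_with_gold(gold, "zzz")$percent, 0.0)
  expect_error(overlap_with_gold(character(0), gold), "empty gold")
})

test_that("half_min_impute fills from each method's own minimum", {
  fx <- met_fixture()
  v <- fx$table$values
  v["m1", "S3.gold"] <- NA
  v["m1", "S2.alt"] <- NA
  tb <- feature_table(v, "intensity")
  imp <- half_min_impute(tb, fx$design)
  gold_min <- min(v["m1", paste0("S", 1:8, ".gold")], na.rm = TRUE)
  alt_min <- min(v["m1", paste0("S", 1:8, ".alt")], na.rm = TRUE)
  expect_equal(imp$values["m1", "S3.gold"], gold_min / 2)
  expect_equal(imp$values["m1", "S2.alt"], alt_min / 2)
  # detected cells untouched; no-missing table unchanged
  detected <- !is.na(v)
  expect_equal(imp$values[detected], v[detected])
  expect_equal(half_min_impute(fx$table, fx$design)$values, fx$table$values)
  # a feature with nothing detected in-method errors
  v2 <- fx$table$values
  v2["m1", paste0("S", 1:8, ".alt")] <- NA
  expect_error(half_min_impute(feature_table(v2, "intensity"), fx$design),
               "no detected value")
  # worked example: (2, 4, NA) -> 1
  d3 <- sample_design(c("a", "b", "c"), c("s1", "s2", "s3"),
                      rep("gold", 3), "gold")
  t3 <- feature_table(matrix(c(2, 4, NA), 1, 3,
                             dimnames = list("m", c("a", "b", "c"))),
                      "intensity")
  expect_equal(half_min_impute(t3, d3)$values["m", "c"], 1)
})

test_that("imputation is pure and leaves raw detectability recoverable", {
  sim <- generate_metabolome(n_subjects = 8, methods = c("gold", "alt"),
                             n_features = 40, censor_quantile = 0.2, seed = 23)
  before <- detectability(sim$table, sim$design, "alt")
  snapshot <- sim$table$values
  imp <- half_min_impute(sim$table, sim$design)
  expect_false(anyNA(imp$values))
  # the input table is untouched, so detectability on raw data is unchanged
  expect_identical(sim$table$values, snapshot)
  expect_identical(detectability(sim$table, sim$design, "alt"), before)
})

test_that("quantile_normalize matches the worked example and limma", {
  tb <- feature_table(matrix(c(1, 2, 3, 4, 5, 6), 3,
                             dimnames = list(paste0("m", 1:3), c("a", "b"))),
                      "intensity")
  qn <- quantile_normalize(tb)
  expect_equal(unname(qn$values[, "a"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn$values[, "b"]), c(2.5, 3.5, 4.5))

  # fixed point: identical samples unchanged
  same <- feature_table(matrix(c(5, 1, 9, 5, 1, 9), 3), "intensity")
  expect_equal(quantile_normalize(same)$values, same$values)

  # post-condition on tie-free data: every sample gets the same multiset
  set.seed(31)
  m <- matrix(rlnorm(60), 15,
              dimnames = list(paste0("m", 1:15), paste0("s", 1:4)))
  qn2 <- quantile_normalize(feature_table(m, "intensity"))
  sorted <- apply(qn2$values, 2, sort)
  for (j in 2:4) expect_equal(unname(sorted[, j]), unname(sorted[, 1]))
  # tied data follow the averaged-reference rule; limma is the oracle
  skip_if_not_installed("limma")
  mt <- matrix(sample(1:40, 60, replace = TRUE), 15,
               dimnames = list(paste0("m", 1:15), paste0("s", 1:4)))
  qn3 <- quantile_normalize(feature_table(mt, "intensity"))
  ref <- limma::normalizeQuantiles(mt, ties = TRUE)
  expect_equal(unname(qn3$values), unname(ref), tolerance = 1e-12)
  ref2 <- limma::normalizeQuantiles(m, ties = TRUE)
  expect_equal(unname(qn2$values), unname(ref2), tolerance = 1e-12)
})

test_that("quantile_normalize preconditions", {
  with_na <- feature_table(matrix(c(1, NA, 3, 4), 2), "intensity")
  expect_error(quantile_normalize(with_na), "complete")
  single <- feature_table(matrix(c(1, 2), 2, 1), "intensity")
  expect_warning(quantile_normalize(single), "identity")
})

test_that("log10_transform requires positive complete values", {
  tb <- feature_table(matrix(c(100, 1, 10, 1000), 2), "intensity")
  lt <- log10_transform(tb)
  expect_equal(unname(lt$values), matrix(c(2, 0, 1, 3), 2))
  expect_identical(lt$kind, "log_intensity")
  expect_error(log10_transform(feature_table(matrix(c(0, 1), 1, 2),
                                             "intensity")), "positive")
})

test_that("metabolite_icc_profile matches componentwise icc_oneway", {
  sim <- generate_metabolome(n_subjects = 12, methods = c("gold", "alt"),
                             n_features = 30, censor_quantile = 0, seed = 41)
  v <- log10(sim$table$values)
  gold_cols <- paste0("S", 1:12, ".gold"); alt_cols <- paste0("S", 1:12, ".alt")
  gt <- feature_table(`colnames<-`(v[, gold_cols], paste0("S", 1:12)),
                      "log_intensity")
  mt <- feature_table(`colnames<-`(v[, alt_cols], paste0("S", 1:12)),
                      "log_intensity")
  prof <- metabolite_icc_profile(gt, mt)
  for (f in c("MET1", "MET7", "MET30")) {
    direct <- icc_oneway(list(gold = gt$values[f, ], alt = mt$values[f, ]))
    expect_equal(prof$estimates$estimate[prof$estimates$feature_id == f],
                 direct$estimate, tolerance = 1e-12)
  }
  expect_equal(prof$summary$median,
               median(prof$estimates$estimate), tolerance = 1e-12)
  expect_lte(prof$summary$q1, prof$summary$median)
  expect_lte(prof$summary$median, prof$summary$q3)

  # duplicated tables -> median 1, IQR width 0
  dup <- metabolite_icc_profile(gt, gt)
  expect_equal(dup$summary$median, 1)
  expect_equal(dup$summary$q3 - dup$summary$q1, 0)
})

test_that("detectability-level feature counts are monotone down the levels", {
  sim <- generate_metabolome(n_subjects = 8, methods = c("gold", "alt"),
                             n_features = 80, censor_quantile = 0.35, seed = 53)
  counts <- vapply(c(0, 0.5, 0.75, 1), function(l)
    length(feature_ids(filter_by_detectability(sim$table, sim$design,
                                               "alt", l))), numeric(1))
  expect_true(all(diff(counts) <= 0))
})
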
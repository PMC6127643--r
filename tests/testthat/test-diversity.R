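test_that("alpha indices match closed forms and hand-derived values", {
  expect_equal(shannon(rep(5, 4)), log(4))
  expect_equal(shannon(c(0, 7, 0)), 0)
  # p = (0.25, 0.25, 0.5): -sum p ln p = 1.5 ln 2
  expect_equal(shannon(c(1, 1, 2)), 1.5 * log(2), tolerance = 1e-12)
  expect_equal(round(shannon(c(1, 1, 2)), 4), 1.0397)

  expect_equal(simpson(rep(1, 4)), 0.75)
  expect_equal(simpson(c(0, 3)), 0)
  expect_equal(simpson(c(1, 1, 2)), 1 - (0.0625 + 0.0625 + 0.25))

  # no singletons -> S_obs; worked singleton/doubleton cases
  expect_equal(chao1(c(3, 2, 5)), 3)
  expect_equal(chao1(c(1, 1, 2, 2, 5)), 5 + 2 * 1 / (2 * 3))
  expect_equal(chao1(c(1, 1, 1)), 3 + 3 * 2 / 2)
  expect_error(chao1(c(0.5, 1)), "integer")
  expect_error(shannon(c(0, 0)), "all-zero")
})

test_that("shannon/simpson are scale-invariant, chao1 bounds richness", {
  set.seed(101)
  for (i in 1:20) {
    x <- rpois(30, 3)
    if (sum(x) == 0) x[1] <- 1
    expect_equal(shannon(x), shannon(x * 17), tolerance = 1e-12)
    expect_equal(simpson(x), simpson(x / sum(x)), tolerance = 1e-12)
    expect_gte(chao1(x), sum(x > 0))
  }
})

test_that("alpha indices agree with vegan on random count vectors", {
  set.seed(77)
  m <- matrix(rpois(200, 5), nrow = 20)
  m[1, ] <- m[1, ] + 1  # no all-zero columns
  for (j in seq_len(ncol(m))) {
    expect_equal(shannon(m[, j]), unname(vegan::diversity(m[, j])),
                 tolerance = 1e-12)
    expect_equal(simpson(m[, j]),
                 unname(vegan::diversity(m[, j], index = "simpson")),
                 tolerance = 1e-12)
    veg <- suppressWarnings(vegan::estimateR(m[, j]))  # warns on its own SE
    expect_equal(chao1(m[, j]), unname(veg["S.chao1"]), tolerance = 1e-10)
  }
})

test_that("relative_abundance and sqrt_transform behave as stated", {
  ft <- feature_table(matrix(c(2, 2, 4), 3, 1,
                             dimnames = list(letters[1:3], "s")), "counts")
  ra <- relative_abundance(ft)
  expect_equal(unname(ra$values[, 1]), c(0.25, 0.25, 0.5))
  expect_identical(ra$kind, "proportion")
  st <- sqrt_transform(ra)
  expect_equal(unname(st$values[, 1]), sqrt(c(0.25, 0.25, 0.5)))
  expect_identical(st$kind, "sqrt_proportion")
  expect_equal(sqrt_transform(relative_abundance(
    feature_table(matrix(5, 1, 1), "counts")))$values[1, 1], 1)

  z <- feature_table(matrix(c(1, 0), 1, 2), "counts")
  expect_error(relative_abundance(z), "zero-total")
  expect_error(sqrt_transform(ft), "proportion")
})

test_that("bray_curtis matches worked examples and its invariants", {
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(1, 0, 2), c(0, 3, 0)), 1)
  expect_equal(bray_curtis(c(1, 0, 3), c(0, 2, 2)), 0.5)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  expect_error(bray_curtis(1:3, 1:2), "length")
  set.seed(5)
  for (i in 1:25) {
    x <- runif(10); y <- runif(10)
    d <- bray_curtis(x, y)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(d, bray_curtis(y, x))
  }
})

test_that("distance_matrix equals elementwise bray_curtis and vegdist", {
  set.seed(11)
  m <- matrix(rpois(60, 8), nrow = 10,
              dimnames = list(paste0("f", 1:10), paste0("s", 1:6)))
  ft <- feature_table(m, "counts")
  D <- distance_matrix(ft)
  expect_identical(dim(D), c(6L, 6L))
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 6))
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(D[i, j], bray_curtis(m[, i], m[, j]), tolerance = 1e-12)
  }
  # identical samples at distance zero
  ft2 <- feature_table(cbind(m, s7 = m[, 1]), "counts")
  expect_equal(distance_matrix(ft2)["s1", "s7"], 0)
  expect_error(distance_matrix(feature_table(matrix(1, 1, 1), "counts")),
               "2 samples")
})

test_that("pcoa reproduces forced geometries and Euclidean input", {
  # two samples at distance d -> single axis at +/- d/2
  D2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  ord <- pcoa(D2, 1)
  expect_equal(unname(sort(abs(ord$coordinates[, 1]))), c(1.5, 1.5))

  # equilateral triangle -> two equal positive eigenvalues
  D3 <- matrix(1, 3, 3) - diag(3)
  dimnames(D3) <- list(letters[1:3], letters[1:3])
  ord3 <- pcoa(D3, 2)
  pos <- ord3$eigenvalues[ord3$eigenvalues > 1e-12]
  expect_length(pos, 2)
  expect_equal(pos[1], pos[2], tolerance = 1e-10)

  # Euclidean distances from random 2-D points are reconstructed
  set.seed(42)
  pts <- matrix(rnorm(20), ncol = 2)
  D <- as.matrix(dist(pts))
  ordE <- pcoa(D, 2)
  rec <- as.matrix(dist(ordE$coordinates))
  expect_lt(max(abs(rec - D)), 1e-8)
  expect_true(all(diff(ordE$eigenvalues) <= 1e-10))
  expect_lte(sum(ordE$proportion_explained), 1 + 1e-12)
  expect_error(pcoa(D, 10), "n_axes")
})
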
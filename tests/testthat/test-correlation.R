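test_that("spearman handles monotone extremes and preconditions", {
  x <- c(2, 5, 1, 9, 4, 7, 3, 8)
  expect_equal(spearman(x, exp(x))$rho, 1)
  expect_equal(spearman(x, -x^3)$rho, -1)
  expect_error(spearman(1:3, 3:1), "4 complete pairs")
  expect_error(spearman(1:5, rep(2, 5)), "constant")
  # missing pairs dropped listwise
  res <- spearman(c(x, NA), c(exp(x), 1))
  expect_identical(res$n, 8L)
})

test_that("exact permutation p matches cor.test on tie-free data", {
  set.seed(19)
  for (n in c(5, 7, 8)) {
    for (rep in 1:5) {
      x <- sample(100, n); y <- sample(100, n)
      mine <- spearman(x, y)
      ref <- suppressWarnings(cor.test(x, y, method = "spearman", exact = TRUE))
      expect_equal(mine$rho, unname(ref$estimate), tolerance = 1e-12)
      expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    }
  }
  # and the t-approximation above the exact cutoff
  x <- rnorm(30); y <- x + rnorm(30)
  mine <- spearman(x, y)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("n = 8 with rho near 0.83 gives p near 0.010", {
  # rank permutation (2,4,1,3,6,5,8,7): sum d^2 = 14, rho = 1 - 84/504
  y <- c(2, 4, 1, 3, 6, 5, 8, 7)
  res <- spearman(1:8, y)
  expect_equal(res$rho, 1 - 6 * 14 / 504, tolerance = 1e-12)
  # frozen from the enumeration oracle (= cor.test exact)
  expect_equal(res$p_value, 0.015376984127, tolerance = 1e-9)
  # the published table's convention is the t-approximation: p ~ 0.010
  approx <- spearman(1:8, y, exact_max_n = 0)
  expect_lt(abs(approx$p_value - 0.010), 0.005)
})

test_that("rho is invariant under strictly monotone transforms", {
  set.seed(4)
  x <- runif(12); y <- runif(12)
  base <- spearman(x, y)
  expect_equal(spearman(exp(x), y)$rho, base$rho)
  expect_equal(spearman(x, y^3 + 2)$rho, base$rho)
  expect_equal(spearman(x, y)$p_value, spearman(exp(x), y)$p_value)
})

test_that("bonferroni_threshold arithmetic", {
  expect_equal(bonferroni_threshold(0.05, 25), 0.002)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 100), 5e-4)
  expect_error(bonferroni_threshold(0.05, 0), "m must be")
})

screen_fixture <- function(seed = 2, n = 8) {
  set.seed(seed)
  subjects <- paste0("S", seq_len(n))
  taxa <- feature_table(matrix(runif(3 * n), 3,
                               dimnames = list(paste0("g", 1:3), subjects)),
                        "intensity")
  mets <- feature_table(matrix(runif(2 * n), 2,
                               dimnames = list(c("but", "prop"), subjects)),
                        "intensity")
  list(taxa = taxa, mets = mets)
}

test_that("correlation_screen reduces to spearman and sets coherent flags", {
  fx <- screen_fixture()
  one_t <- feature_table(fx$taxa$values[1, , drop = FALSE], "intensity")
  one_m <- feature_table(fx$mets$values[1, , drop = FALSE], "intensity")
  res <- correlation_screen(one_t, one_m)
  direct <- spearman(fx$taxa$values[1, ], fx$mets$values[1, ])
  expect_identical(nrow(res), 1L)
  expect_equal(res$rho, direct$rho)
  expect_equal(res$p_value, direct$p_value)

  full <- correlation_screen(fx$taxa, fx$mets, alpha = 0.05)
  expect_identical(nrow(full), 6L)
  expect_identical(attr(full, "m_tests"), 6L)
  expect_true(all(full$p_value == sort(full$p_value)))
  expect_identical(full$significant_nominal, full$p_value < 0.05)
  expect_identical(full$significant_bonferroni, full$p_value < 0.05 / 6)
  expect_true(all(full$significant_nominal[full$significant_bonferroni]))
  # m override
  ov <- correlation_screen(fx$taxa, fx$mets, m = 25)
  expect_equal(attr(ov, "bonferroni_critical"), 0.002)
})

test_that("screen results are invariant to row/column reordering", {
  fx <- screen_fixture(seed = 6)
  base <- correlation_screen(fx$taxa, fx$mets)
  shuf_t <- feature_table(fx$taxa$values[c(3, 1, 2), sample(8)], "intensity")
  shuf_m <- feature_table(fx$mets$values[2:1, sample(8)], "intensity")
  redo <- correlation_screen(shuf_t, shuf_m)
  key <- function(d) d[order(d$taxon, d$metabolite),
                       c("taxon", "metabolite", "rho", "p_value")]
  expect_equal(key(base), key(redo), ignore_attr = TRUE)
})

test_that("a coupled genus/SCFA pair is detected with high power at n = 8", {
  hits <- 0
  for (r in 1:200) {
    set.seed(1000 + r)
    u <- rnorm(8)
    taxon <- u + rnorm(8, 0, 0.35)       # subject-driven coupling, rho ~ 0.85
    scfa <- u + rnorm(8, 0, 0.35)
    p <- spearman(taxon, scfa)$p_value
    if (p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.8)
})

test_that("null screens hold the nominal false-positive rate", {
  # 200 replicate 5x3 screens of independent data: per-test FP rate ~ 0.05
  fp <- 0; total <- 0
  for (r in 1:200) {
    set.seed(3000 + r)
    tx <- feature_table(matrix(rlnorm(5 * 10), 5,
                               dimnames = list(paste0("g", 1:5),
                                               paste0("S", 1:10))), "intensity")
    mt <- feature_table(matrix(rlnorm(3 * 10), 3,
                               dimnames = list(paste0("m", 1:3),
                                               paste0("S", 1:10))), "intensity")
    res <- correlation_screen(tx, mt)
    fp <- fp + sum(res$significant_nominal)
    total <- total + nrow(res)
  }
  expect_lt(abs(fp / total - 0.05), 0.02)
})
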
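test_that("simple coefficient statistics match direct evaluation", {
  expect_equal(mav(c(1, -2, 3, -4)), 2.5)
  expect_equal(mav(rep(0, 5)), 0)
  expect_equal(mav(rep(3.7, 9)), 3.7)
  expect_error(mav(numeric(0)), "empty")

  expect_identical(extrema(c(3, -1, 7)), c(min = -1, max = 7))
  expect_identical(extrema(5), c(min = 5, max = 5))

  expect_equal(coef_std(1:4), 1.2909944487358056)
  expect_equal(coef_std(rep(2, 10)), 0)
  x <- rnorm(50)
  expect_equal(coef_std(-3 * x), 3 * coef_std(x))
  expect_error(coef_std(1), "at least 2")

  expect_equal(avg_power(c(1, 2, 3, 4)), 7.5)
  expect_equal(avg_power(rep(1, 8)), 1)
  expect_equal(avg_power(rep(0, 8)), 0)
})

test_that("Shannon entropy matches direct summation and respects its bounds", {
  # single-bin mass and uniform mass
  expect_equal(shannon_entropy(c(0, 0, 2, 0)), 0)
  expect_equal(shannon_entropy(c(1, 1, 1, 1)), 2)           # log2(4)
  # p = (0.5, 0.25, 0.25) via energies (sqrt(2), 1, 1)
  expect_equal(shannon_entropy(c(sqrt(2), 1, 1)), 1.5)
  expect_equal(shannon_entropy(numeric(3)), 0)              # no energy

  set.seed(3)
  for (i in 1:25) {
    x <- rnorm(sample(10:200, 1))
    h <- shannon_entropy(x)
    expect_gte(h, 0)
    expect_lte(h, log2(length(x)) + 1e-12)
    expect_equal(h, entropy_oracle(x^2 / sum(x^2)), tolerance = 1e-12)
    # scale invariance of the energy estimator
    expect_equal(shannon_entropy(5 * x), h, tolerance = 1e-10)
  }

  # histogram estimator
  xh <- c(rep(0, 50), rep(1, 25), rep(2, 25)) # quarters: p = (.5,.25,.25)
  expect_equal(shannon_entropy(xh, estimator = "histogram", n_bins = 3), 1.5)
  expect_equal(shannon_entropy(rep(4, 10), estimator = "histogram"), 0)
  expect_error(shannon_entropy(1:5, estimator = "histogram", n_bins = 1),
               "n_bins")
})

test_that("approximate entropy matches the brute-force counting oracle", {
  set.seed(17)
  for (i in 1:30) {
    n <- sample(30:150, 1)
    x <- switch(1 + i %% 3,
                runif(n), rnorm(n), sin(seq_len(n) / sample(2:9, 1)) + rnorm(n, sd = 0.2))
    m <- sample(1:3, 1)
    r <- 0.2 * sd(x)
    expect_equal(apen(x, m = m, r = r, relative_r = FALSE),
                 apen_oracle(x, m, r), tolerance = 1e-12)
  }
})

test_that("approximate entropy behaves like a regularity statistic", {
  expect_equal(apen(rep(2, 60)), 0)
  # strict alternation is near-perfectly regular (small O(1/N) edge effect)
  expect_lt(apen(rep(c(1, 5), 40), m = 2, r = 0.2), 1e-3)
  set.seed(23)
  for (i in 1:10) {
    periodic <- sin(2 * pi * (1:200) / 20)
    random <- runif(200, -1, 1)
    expect_lt(apen(periodic), apen(random))
    expect_gte(apen(random), 0)
  }
  expect_error(apen(1:3, m = 2), "too short")
  expect_error(apen(rnorm(50), r = 0), "r must be")
})

test_that("MAV is bounded by the root of average power (Cauchy-Schwarz)", {
  set.seed(9)
  for (i in 1:50) {
    x <- rnorm(sample(5:500, 1), sd = runif(1, 0.1, 100))
    expect_lte(mav(x), sqrt(avg_power(x)) + 1e-12)
  }
})

test_that("feature table has the documented shape and column order", {
  ds <- generate_dataset(tiny_spec(n = 3, len = 512))
  tab <- build_feature_table(ds)
  expect_s3_class(tab, "feature_table")
  expect_equal(nrow(tab), 6)
  expect_equal(ncol(tab), 2 + 28)
  expect_identical(names(tab)[1:2], c("source_id", "set_label"))
  # subband-major with fixed feature order
  expect_identical(
    names(tab)[3:9],
    paste0("D3_", c("MAV", "MAXC", "MINC", "STD", "AVP", "SHEN", "APEN")))
  expect_identical(names(tab)[10], "D4_MAV")
  expect_true(all(is.finite(as.matrix(tab[, -(1:2)]))))

  one <- build_feature_table(ds, subbands = "D5")
  expect_equal(ncol(one), 2 + 7)

  expect_error(build_feature_table(ds, subbands = "D9"), "D9")
})

test_that("feature rows are deterministic and order-invariant", {
  ds <- generate_dataset(tiny_spec(n = 2, len = 256))
  tab <- build_feature_table(ds, subbands = c("D4", "D5"))
  # identical segments give identical rows
  dup <- labeled_dataset(list(ds$signals[[1]], ds$signals[[1]]))
  tdup <- build_feature_table(dup, subbands = c("D4", "D5"))
  expect_identical(tdup[1, -(1:2)], tdup[2, -(1:2)], ignore_attr = TRUE)
  # permuting segment order permutes rows without changing values
  perm <- rev(seq_along(ds$signals))
  tperm <- build_feature_table(labeled_dataset(ds$signals[perm]),
                               subbands = c("D4", "D5"))
  expect_equal(as.matrix(tperm[perm, -(1:2)]), as.matrix(tab[, -(1:2)]),
               ignore_attr = TRUE)
})

test_that("feature_columns selects single cells or everything", {
  ds <- generate_dataset(tiny_spec(n = 2, len = 256))
  tab <- build_feature_table(ds)
  expect_identical(feature_columns(tab, "D5", "MAV"), "D5_MAV")
  expect_length(feature_columns(tab, "all", "all"), 28)
  expect_error(feature_columns(tab, "D5", "XYZ"), "not present")
})
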
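test_that("peaks_to_composition aggregates family areas to percentages", {
  pk <- data.frame(peak_id = c("p1", "p2", "p3"),
                   family = c("A", "A", "B"), area = c(2, 1, 1))
  expect_equal(peaks_to_composition(pk), c(A = 75, B = 25))
  expect_equal(peaks_to_composition(
    data.frame(peak_id = "p", family = "X", area = 5)), c(X = 100))
  expect_error(peaks_to_composition(
    data.frame(peak_id = "p", family = "X", area = 0)), "zero")

  set.seed(17)
  pk <- data.frame(peak_id = paste0("p", 1:50),
                   family = sample(LETTERS[1:5], 50, TRUE),
                   area = runif(50))
  got <- peaks_to_composition(pk)
  want <- sapply(split(pk$area, factor(pk$family, unique(pk$family))), sum)
  want <- 100 * want / sum(pk$area)
  expect_equal(got, want[names(got)], tolerance = 1e-12)
  expect_equal(sum(got), 100, tolerance = 1e-12)
})

test_that("filter_families reproduces the 7-family set and is idempotent", {
  fx <- load_fixture()
  kept <- filter_families(fx$composition)
  expect_identical(colnames(kept),
                   c("DISI", "LAO", "CRISP", "PLA2", "SP", "SVMP", "PEP"))
  expect_identical(filter_families(kept), kept)

  withzero <- cbind(fx$composition, ZERO = 0)
  expect_false("ZERO" %in% colnames(filter_families(withzero)))
  expect_identical(colnames(filter_families(fx$composition, 0, 0)),
                   colnames(fx$composition))
  expect_error(filter_families(fx$composition, min_presence = 9),
               "exceeds number of taxa")
})

test_that("arcsin_sqrt transforms correctly and reports offending cells", {
  expect_equal(arcsin_sqrt(c(0, 100), "percent"), c(0, pi / 2))
  expect_equal(arcsin_sqrt(0.5, "proportion"), pi / 4)
  expect_equal(arcsin_sqrt(0.85, "proportion"), 1.1730969, tolerance = 1e-6)
  m <- matrix(c(0.2, 1.4), 1, dimnames = list("Sca", c("ok", "bad")))
  expect_error(arcsin_sqrt(m, "proportion"), "Sca.*bad")
  expect_error(arcsin_sqrt(-1, "percent"), "out of range")

  p <- seq(0, 1, by = 0.05)
  th <- arcsin_sqrt(p, "proportion")
  expect_true(all(diff(th) > 0))
  expect_equal(arcsin_sqrt(1 - p, "proportion"), pi / 2 - th)
})

test_that("pearson_cor matches the fixture value and a cov/sd oracle", {
  fx <- load_fixture()
  expect_equal(round(pearson_cor(fx$diet[, "mam"], fx$diet[, "liz"]), 2),
               -0.68)
  x <- rnorm(10)
  expect_equal(pearson_cor(x, x), 1)
  set.seed(5)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(pearson_cor(a, b), cov(a, b) / (sd(a) * sd(b)),
               tolerance = 1e-12)
  expect_error(pearson_cor(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(pearson_cor(1:2, 1:2), "at least 3")
})

test_that("covariance PCA of transformed diet matches published loadings", {
  fx <- load_fixture()
  p <- pca_traits(arcsin_sqrt(fx$diet, "proportion"), "covariance")
  expect_equal(round(p$variance_fractions[1], 2), 0.87)
  p <- orient_component(p, 1, "liz")
  expect_equal(round(p$scaled_loadings["mam", 1], 2), -0.95)
  expect_equal(round(p$scaled_loadings["liz", 1], 2), 0.91)
})

test_that("pca_traits agrees with a brute-force eigen oracle", {
  set.seed(31)
  X <- matrix(rnorm(32), 8, 4, dimnames = list(paste0("t", 1:8), LETTERS[1:4]))
  p <- pca_traits(X)
  e <- eigen(cov(X), symmetric = TRUE)
  expect_equal(p$eigenvalues, pmax(e$values, 0), tolerance = 1e-9)
  for (j in 1:4) {
    expect_equal(unname(abs(p$eigenvectors[, j])), abs(e$vectors[, j]),
                 tolerance = 1e-9)
    if (p$eigenvalues[j] > 1e-12)
      expect_equal(unname(p$scaled_loadings[, j]),
                   unname(cor(X, p$scores[, j])[, 1]), tolerance = 1e-9)
  }
  # reconstruction of the decomposed matrix
  R <- p$eigenvectors %*% diag(p$eigenvalues) %*% t(p$eigenvectors)
  expect_lt(max(abs(R - cov(X))), 1e-10)
  # variance fractions invariant to a global scale change
  p2 <- pca_traits(1000 * X)
  expect_equal(p2$variance_fractions, p$variance_fractions, tolerance = 1e-12)
  # scaled loadings invariant to the covariance divisor convention:
  # divisor cancels between sqrt(lambda) and the variable sd, so princomp
  # (divisor n) gives the same correlations
  pc <- princomp(X)
  L <- unclass(pc$loadings) %*% diag(pc$sdev)
  L <- sweep(L, 1, apply(X, 2, function(v) sqrt(mean((v - mean(v))^2))), "/")
  expect_equal(abs(unname(L)), abs(unname(p$scaled_loadings)),
               tolerance = 1e-9)
})

test_that("two independent equal-variance variables split variance evenly", {
  set.seed(7)
  a <- scale(rnorm(40))[, 1]
  b <- scale(residuals(lm(rnorm(40) ~ a)))[, 1]  # force orthogonality
  p <- pca_traits(cbind(a = a, b = b))
  expect_equal(p$variance_fractions, c(0.5, 0.5), tolerance = 1e-10)
})

test_that("per-variable squared scaled loadings are bounded by 1", {
  fx <- load_fixture()
  v <- arcsin_sqrt(filter_families(fx$composition), "percent")
  p <- pca_traits(v)
  expect_true(all(rowSums(p$scaled_loadings^2) <= 1 + 1e-9))
  expect_equal(sum(p$variance_fractions), 1, tolerance = 1e-10)
})

test_that("trait CSV round-trips through disk", {
  fx <- load_fixture()
  f <- tempfile(fileext = ".csv")
  write_trait_csv(fx$composition, f)
  expect_equal(read_trait_csv(f), fx$composition)
  unlink(f)
})
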
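test_that("gls_mean reduces to the arithmetic mean on a star tree", {
  V <- 2.5 * diag(6)
  x <- rnorm(6)
  expect_equal(gls_mean(V, x), mean(x), tolerance = 1e-12)
  Vy <- phylo_vcv(yule_tree(7, seed = 4))
  expect_equal(gls_mean(Vy, rep(3.2, 7)), 3.2, tolerance = 1e-12)
})

test_that("gls_mean matches the explicit matrix formula", {
  V <- matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3)
  x <- c(1, 2, 3)
  iV <- solve(V)
  want <- drop((t(rep(1, 3)) %*% iV %*% x) / (t(rep(1, 3)) %*% iV %*% rep(1, 3)))
  expect_equal(gls_mean(V, x), want, tolerance = 1e-12)
})

test_that("gls_mean reports taxa mismatches and singular V", {
  V <- phylo_vcv(parse_newick("((A:1,B:1):1,C:2);"))
  expect_error(gls_mean(V, c(A = 1, B = 2, D = 3)), "unmatched.*D|D.*unmatched")
  Vs <- matrix(1, 3, 3) + diag(1e-15, 3)
  expect_error(gls_mean(Vs, 1:3), "singular|ill-conditioned")
})

test_that("K is exactly 1 on star phylogenies and affine-invariant", {
  for (n in c(5, 20)) {
    V <- 1.7 * diag(n)
    x <- rnorm(n)
    expect_equal(blomberg_k(V, x)$K, 1, tolerance = 1e-12)
  }
  tr <- yule_tree(16, seed = 9)
  x <- simulate_bm(tr, seed = 21)
  k0 <- blomberg_k(phylo_vcv(tr), x)$K
  expect_equal(blomberg_k(phylo_vcv(tr), 5 - 3 * x)$K, k0, tolerance = 1e-10)
})

test_that("K matches a brute-force oracle and orders clade structure", {
  tr <- balanced4()
  V <- phylo_vcv(tr)
  conc <- setNames(c(0, 0, 1, 1), c("A", "B", "C", "D"))
  disc <- setNames(c(0, 1, 0, 1), c("A", "B", "C", "D"))
  k_conc <- blomberg_k(V, conc)
  k_disc <- blomberg_k(V, disc)
  expect_equal(k_conc$K, oracle_k(V, as.numeric(conc)), tolerance = 1e-12)
  expect_equal(k_disc$K, oracle_k(V, as.numeric(disc)), tolerance = 1e-12)
  expect_gt(k_conc$K, k_disc$K)
  expect_equal(k_conc$K, k_conc$ratio_obs / k_conc$ratio_exp,
               tolerance = 1e-12)

  for (i in 1:10) {
    trr <- yule_tree(sample(6:12, 1), seed = 300 + i)
    x <- simulate_bm(trr, seed = 600 + i)
    expect_equal(blomberg_k(phylo_vcv(trr), x)$K,
                 oracle_k(phylo_vcv(trr), as.numeric(x[trr$tip.label])),
                 tolerance = 1e-10)
  }
})

test_that("K agrees with picante's implementation", {
  skip_if_not_installed("picante")
  for (i in 1:5) {
    tr <- yule_tree(10, seed = 40 + i)
    x <- simulate_bm(tr, seed = 50 + i)
    expect_equal(blomberg_k(phylo_vcv(tr), x)$K,
                 as.numeric(picante::Kcalc(x[tr$tip.label], tr)),
                 tolerance = 1e-8)
  }
})

test_that("K is invariant under branch-length rescaling", {
  tr <- yule_tree(14, seed = 77)
  V <- phylo_vcv(tr)
  x <- simulate_bm(tr, seed = 78)
  expect_equal(blomberg_k(7.3 * V, x)$K, blomberg_k(V, x)$K,
               tolerance = 1e-10)
})

test_that("K rejects constant traits and tiny trees warn", {
  V <- phylo_vcv(yule_tree(6, seed = 1))
  expect_error(blomberg_k(V, rep(2, 6)), "constant")
  V3 <- phylo_vcv(parse_newick("((A:1,B:1):1,C:2);"))
  expect_warning(blomberg_k(V3, c(1, 2, 4)), "fewer than 4")
})

test_that("permutation test: star-tree p is 1, bounds and reproducibility", {
  star <- parse_newick("(A:1,B:1,C:1,D:1,E:1);")
  r <- signal_test(star, setNames(rnorm(5), LETTERS[1:5]),
                   n_perm = 99, seed = 2)
  expect_equal(r$p_value, 1)

  tr <- yule_tree(12, seed = 12)
  x <- simulate_bm(tr, seed = 13)
  r1 <- signal_test(tr, x, n_perm = 199, seed = 7)
  r2 <- signal_test(tr, x, n_perm = 199, seed = 7)
  expect_identical(r1$p_value, r2$p_value)
  expect_gte(r1$p_value, 1 / 200)
  expect_lte(r1$p_value, 1)
  r3 <- signal_test(tr, x, n_perm = 199, seed = 8)
  expect_true(is.numeric(r3$p_value))  # different stream still valid
  expect_error(signal_test(tr, x, n_perm = 199), "seed")
})

test_that("permutation test keeps nominal size and detects BM signal", {
  # size: i.i.d. traits should reject at ~alpha (reduced replication here;
  # the full-size calibration lives in the acceptance tests)
  tr <- yule_tree(16, seed = 900)
  hits <- 0
  nrep <- 200
  for (i in seq_len(nrep)) {
    x <- setNames(with_seed_test(9000 + i, rnorm(16)), tr$tip.label)
    p <- signal_test(tr, x, n_perm = 99, seed = 100 + i)$p_value
    if (p <= 0.05) hits <- hits + 1
  }
  expect_gte(hits / nrep, 0.01)
  expect_lte(hits / nrep, 0.10)

  # power: strong-signal BM traits on a larger tree give small median p
  tr32 <- yule_tree(32, seed = 901)
  ps <- vapply(1:50, function(i) {
    x <- simulate_bm(tr32, seed = 700 + i)
    signal_test(tr32, x, n_perm = 99, seed = 800 + i)$p_value
  }, numeric(1))
  expect_lte(median(ps), 0.05)
})

test_that("signal_screen is column-wise consistent and error-isolating", {
  tr <- yule_tree(10, seed = 55)
  x <- simulate_bm(tr, seed = 56)
  traits <- cbind(a = x, a_copy = x, const = rep(1, 10))
  rownames(traits) <- names(x)
  scr <- signal_screen(tr, traits, n_perm = 99, seed = 5)
  expect_equal(scr$K[1], scr$K[2])
  expect_true(is.na(scr$K[3]))
  expect_match(scr$error[3], "constant")

  # each row equals a standalone run with the same derived seed
  for (j in 1:2) {
    solo <- signal_test(tr, traits[, j], n_perm = 99,
                        seed = venomcomp:::derive_seed(5, j))
    expect_identical(scr$K[j], solo$K)
    expect_identical(scr$p_value[j], solo$p_value)
  }
})
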
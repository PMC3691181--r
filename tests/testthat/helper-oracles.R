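# Independent oracles, deliberately naive and separate from the package's
# code paths.

# Brute-force phylogenetic covariance: walk the root-to-tip path of every
# tip as an explicit node sequence, then sum lengths on the shared prefix.
oracle_vcv <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  parent_of <- function(node) tree$edge[tree$edge[, 2] == node, 1]
  len_of <- function(node) tree$edge.length[tree$edge[, 2] == node]
  paths <- lapply(seq_len(n), function(tip) {
    nodes <- tip
    while (nodes[1] != root) nodes <- c(parent_of(nodes[1]), nodes)
    nodes
  })
  V <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    shared <- intersect(paths[[i]], paths[[j]])
    shared <- setdiff(shared, root)
    V[i, j] <- sum(vapply(shared, len_of, numeric(1)))
  }
  V
}

# Brute-force Blomberg K: the four defining quantities with explicit
# solve() inverses, no factorization sharing.
oracle_k <- function(V, x) {
  n <- length(x)
  one <- rep(1, n)
  iV <- solve(V)
  ahat <- drop(solve(t(one) %*% iV %*% one) %*% (t(one) %*% iV %*% x))
  r <- x - ahat
  mse0 <- drop(t(r) %*% r) / (n - 1)
  mse <- drop(t(r) %*% iV %*% r) / (n - 1)
  expected <- (sum(diag(V)) - n / drop(t(one) %*% iV %*% one)) / (n - 1)
  (mse0 / mse) / expected
}

# Whitened-OLS PGLS oracle: premultiply by inv(chol(V)') and run lm().
oracle_pgls <- function(V, y, x) {
  L <- t(chol(V))
  Li <- solve(L)
  Xw <- Li %*% cbind(1, x)   # whiten design including the intercept column
  yw <- drop(Li %*% y)
  fit <- stats::lm(yw ~ Xw - 1)
  sm <- summary(fit)
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
       se_slope = sm$coefficients[2, 2],
       t = sm$coefficients[2, 3])
}

# Independent transcription of the published composition/diet table,
# entered column-by-column (the package fixture was entered row-by-row).
oracle_fixture <- function() {
  taxa <- c("Sms", "Smm", "Smb", "Sca", "Sct", "Sce", "Catrox", "Agc")
  comp <- cbind(
    DISI   = c(1.4, 1.8, 7.5, 2.4, 4.1, 0.8, 6.2, 1.3),
    LAO    = c(0, 0, 2.0, 4.0, 1.4, 2.4, 8.0, 0.4),
    CRISP  = c(1.6, 1.6, 2.8, 0.6, 1.2, 10.1, 4.3, 3.7),
    PLA2   = c(21.3, 18.1, 31.8, 28.9, 30.3, 13.1, 7.3, 31.7),
    SP     = c(17.8, 13.1, 16.8, 17.5, 19.6, 23.3, 19.8, 14.3),
    SVMP   = c(51.1, 62.7, 35.3, 42.2, 38.9, 45.6, 49.8, 32.5),
    svNGF  = c(0.7, 0, 0.1, 0.1, 0.1, 0.1, 0.0, 0.3),
    CTL    = c(1.8, 0, 0.1, 0.1, 0.1, 0.1, 1.6, 2.4),
    MYO    = c(0, 0, 0, 0.4, 0.1, 0, 0.0, 0.0),
    DC     = c(0, 0, 1.3, 0.1, 0.1, 0.1, 0.0, 0.0),
    PEP    = c(4.3, 2.7, 2.1, 3.7, 4.1, 4.2, 3.0, 0.7),
    Kunitz = c(0, 0, 0.1, 0, 0, 0.1, 0.0, 0.0))
  diet <- cbind(
    mam = c(0.20, 0.17, 0.17, 0.85, 0.73, 0.32, 0.87, 0.37),
    liz = c(0.20, 0.50, 0.32, 0.00, 0.14, 0.60, 0.05, 0.06))
  rownames(comp) <- rownames(diet) <- taxa
  list(composition = comp, diet = diet)
}

with_seed_test <- function(seed, expr) {
  set.seed(seed)
  expr
}

# Small fixed ultrametric test tree used across files.
balanced4 <- function() parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
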
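# Simulators for trees and traits with known ground truth. Every generator
# takes an explicit seed, derives an independent stream per operation via
# derive_seed(), restores the caller's RNG state on exit, and is
# bit-reproducible given (arguments, seed).

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as_seed(seed))
  expr
}

#' Simulate a Yule (pure-birth) tree
#'
#' Forward simulation of the pure-birth process: while j lineages exist the
#' waiting time to the next speciation is exponential with rate
#' `j * birth_rate`; a uniformly chosen lineage then splits. Simulation
#' starts from the root split (2 lineages) and stops when `n_tips` lineages
#' exist, at which point every pendant branch is extended to the present, so
#' the tree is exactly ultrametric. By default the tree is rescaled to unit
#' depth so that trait-rate parameters are comparable across `n_tips`.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Speciation rate per lineage per unit time (> 0).
#' @param seed Integer seed (required).
#' @param unit_depth Rescale total depth to 1 (default TRUE). Set FALSE to
#'   keep raw waiting times (e.g. to inspect the exponential waiting-time
#'   property).
#' @return A \code{"phylo"} tree with tips `t1..tn`.
#' @export
yule_tree <- function(n_tips, birth_rate = 1, seed, unit_depth = TRUE) {
  if (missing(seed)) stop("seed must be given explicitly", call. = FALSE)
  stopifnot(n_tips >= 2, birth_rate > 0)
  with_seed(derive_seed(seed, 101L), {
    # Lineages carry provisional ids; id 0 is the root. An edge is closed
    # (recorded with its start/end time) when its lineage splits or when
    # the simulation stops.
    t_now <- 0
    active_id <- c(1L, 2L)     # the two lineages born at the root split
    active_parent <- c(0L, 0L)
    active_born <- c(0, 0)
    next_id <- 3L
    rec <- list()              # closed edges: (id, parent, t0, t1, tip)
    while (length(active_id) < n_tips) {
      j <- length(active_id)
      t_now <- t_now + stats::rexp(1, rate = j * birth_rate)
      i <- sample.int(j, 1)
      rec[[length(rec) + 1L]] <- c(active_id[i], active_parent[i],
                                   active_born[i], t_now, 0)
      kids <- c(next_id, next_id + 1L); next_id <- next_id + 2L
      active_parent <- c(active_parent[-i], rep(active_id[i], 2L))
      active_id <- c(active_id[-i], kids)
      active_born <- c(active_born[-i], t_now, t_now)
    }
    t_end <- t_now + stats::rexp(1, rate = n_tips * birth_rate)
    for (i in seq_along(active_id)) {
      rec[[length(rec) + 1L]] <- c(active_id[i], active_parent[i],
                                   active_born[i], t_end, 1)
    }
    E <- do.call(rbind, rec)
    colnames(E) <- c("id", "parent", "t0", "t1", "tip")
    # Relabel to ape convention: tips 1..n, internals n+1..2n-1, root n+1.
    new_id <- integer(next_id)               # indexed by provisional id + 1
    new_id[1L] <- n_tips + 1L                # root (provisional id 0)
    tip_rows <- E[, "tip"] == 1
    new_id[E[tip_rows, "id"] + 1L] <- seq_len(n_tips)
    new_id[E[!tip_rows, "id"] + 1L] <- n_tips + 1L + seq_len(sum(!tip_rows))
    edge <- cbind(new_id[E[, "parent"] + 1L], new_id[E[, "id"] + 1L])
    storage.mode(edge) <- "integer"
    len <- E[, "t1"] - E[, "t0"]
    if (unit_depth && t_end > 0) len <- len / t_end
    tr <- list(edge = edge, edge.length = len,
               tip.label = paste0("t", seq_len(n_tips)),
               Nnode = n_tips - 1L)
    class(tr) <- "phylo"
    tr <- ape::reorder.phylo(tr, "cladewise")
    validate_phylo(tr)
  })
}

#' Simulate a Brownian-motion trait on a tree
#'
#' Tip values are generated by independent Gaussian increments along each
#' branch with variance `sigma2 * branch length`, started at `root_state`.
#' The tip vector is multivariate normal with mean `root_state` and
#' covariance `sigma2 * phylo_vcv(tree)`.
#'
#' @param tree A \code{"phylo"} tree.
#' @param sigma2 Brownian rate (trait^2 per unit branch length, > 0).
#' @param root_state Trait value at the root (default 0).
#' @param seed Integer seed (required).
#' @return Named numeric vector of tip values (tree tip order).
#' @export
simulate_bm <- function(tree, sigma2 = 1, root_state = 0, seed) {
  if (missing(seed)) stop("seed must be given explicitly", call. = FALSE)
  validate_phylo(tree)
  stopifnot(sigma2 > 0)
  with_seed(derive_seed(seed, 202L), {
    tr <- ape::reorder.phylo(tree, "cladewise")
    n <- length(tr$tip.label)
    state <- numeric(n + tr$Nnode)
    state[n + 1L] <- root_state
    inc <- stats::rnorm(nrow(tr$edge), mean = 0,
                        sd = sqrt(sigma2 * tr$edge.length))
    for (e in seq_len(nrow(tr$edge))) {   # cladewise: parents precede children
      state[tr$edge[e, 2]] <- state[tr$edge[e, 1]] + inc[e]
    }
    stats::setNames(state[seq_len(n)], tr$tip.label)
  })
}

#' Simulate a trait with tunable phylogenetic signal
#'
#' Draws the tip vector from a multivariate normal with covariance
#' `sigma2 * lambda_transform(phylo_vcv(tree), lambda)`. `lambda = 1`
#' matches [simulate_bm()] in law; `lambda = 0` gives independent tips
#' (heteroscedastic only through tip depths; i.i.d. on an ultrametric
#' tree).
#'
#' @param tree A \code{"phylo"} tree.
#' @param lambda Signal strength in \[0, 1\].
#' @param sigma2 Rate parameter (> 0).
#' @param root_state Mean of every tip (default 0).
#' @param seed Integer seed (required).
#' @return Named numeric vector of tip values.
#' @export
simulate_signal <- function(tree, lambda, sigma2 = 1, root_state = 0, seed) {
  if (missing(seed)) stop("seed must be given explicitly", call. = FALSE)
  stopifnot(sigma2 > 0)
  C <- sigma2 * lambda_transform(phylo_vcv(tree), lambda)
  L <- tryCatch(chol(C), error = function(e)
    stop("transformed covariance is singular", call. = FALSE))
  with_seed(derive_seed(seed, 303L), {
    z <- stats::rnorm(nrow(C))
    stats::setNames(root_state + drop(crossprod(L, z)), rownames(C))
  })
}

#' Simulate a venom-like compositional table on a tree
#'
#' One latent Brownian trait per protein family evolves on the tree; each
#' taxon's composition is the softmax of its latent values times 100, so
#' rows lie on the simplex (sum exactly 100) while phylogenetic structure
#' is preserved in the log-ratios (a logistic-normal construction).
#'
#' @param tree A \code{"phylo"} tree.
#' @param n_families Number of protein families (>= 2).
#' @param sigma2 Brownian rate of the latent traits.
#' @param seed Integer seed (required).
#' @param latent_offset Optional numeric matrix (taxa x families) added to
#'   the latent values before the softmax, e.g. to suppress a family in
#'   chosen taxa.
#' @return Matrix taxa x families of percentages, columns `F1..Fk`.
#' @export
simulate_composition <- function(tree, n_families, sigma2 = 1, seed,
                                 latent_offset = NULL) {
  if (missing(seed)) stop("seed must be given explicitly", call. = FALSE)
  stopifnot(n_families >= 2)
  lat <- sapply(seq_len(n_families), function(j)
    simulate_bm(tree, sigma2 = sigma2, root_state = 0,
                seed = derive_seed(seed, 400L + j)))
  colnames(lat) <- paste0("F", seq_len(n_families))
  if (!is.null(latent_offset)) lat <- lat + latent_offset
  ex <- exp(lat - apply(lat, 1, max))
  100 * ex / rowSums(ex)
}

#' Simulate a phylogenetically coupled diet-venom pair
#'
#' Ground truth for PGLS recovery: the diet trait evolves by Brownian
#' motion on the tree, and the venom trait is
#' `true_slope * diet + intercept + noise`, where the noise is an
#' independent Brownian trait with rate `sigma2_noise` - i.e. exactly the
#' generating model PGLS assumes.
#'
#' @param tree A \code{"phylo"} tree.
#' @param true_slope Generating slope.
#' @param sigma2_noise Brownian rate of the residual trait (> 0).
#' @param sigma2_diet Brownian rate of the diet trait (default 1).
#' @param intercept Generating intercept (default 0).
#' @param seed Integer seed (required).
#' @return List with `diet`, `venom` (named vectors) and `params`.
#' @export
simulate_diet_venom <- function(tree, true_slope = 0.5, sigma2_noise = 1,
                                sigma2_diet = 1, intercept = 0, seed) {
  if (missing(seed)) stop("seed must be given explicitly", call. = FALSE)
  diet <- simulate_bm(tree, sigma2 = sigma2_diet, seed = derive_seed(seed, 501L))
  noise <- simulate_bm(tree, sigma2 = sigma2_noise, seed = derive_seed(seed, 502L))
  venom <- intercept + true_slope * diet + noise
  list(diet = diet, venom = venom,
       params = list(true_slope = true_slope, intercept = intercept,
                     sigma2_noise = sigma2_noise, sigma2_diet = sigma2_diet,
                     seed = as_seed(seed)))
}
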
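#' Parse a Newick string into a validated phylogeny
#'
#' Thin validating wrapper around [ape::read.tree()]. The returned object is
#' an ordinary \code{"phylo"} tree that satisfies the contracts every
#' downstream statistic relies on: at least two uniquely labelled tips, and a
#' finite non-negative branch length on every edge. Internal node labels are
#' ignored; the dialect is unquoted labels, no comments, semicolon-terminated.
#'
#' @param text A Newick string (semicolon-terminated).
#' @return An object of class \code{"phylo"} (rooted, with branch lengths).
#' @seealso [write_newick()], [read_newick_file()]
#' @export
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' tr$tip.label
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tr <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("malformed Newick string: ", conditionMessage(e),
                             call. = FALSE),
    warning = function(w) stop("malformed Newick string: ", conditionMessage(w),
                               call. = FALSE)
  )
  if (is.null(tr)) stop("malformed Newick string: parser returned no tree",
                        call. = FALSE)
  validate_phylo(tr)
}

#' Read and validate a Newick file
#'
#' @param path Path to a Newick file containing a single tree.
#' @return A validated \code{"phylo"} object.
#' @export
read_newick_file <- function(path) {
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

# Contract checks shared by every entry point that accepts a tree.
validate_phylo <- function(tr) {
  if (!inherits(tr, "phylo")) stop("not a 'phylo' object", call. = FALSE)
  n <- length(tr$tip.label)
  if (n < 2L) stop("tree must have at least 2 tips (found ", n, ")",
                   call. = FALSE)
  if (anyDuplicated(tr$tip.label)) {
    dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
    stop("duplicate tip labels: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(tr$tip.label))) stop("empty tip label", call. = FALSE)
  if (is.null(tr$edge.length)) stop("missing branch lengths", call. = FALSE)
  bad <- !is.finite(tr$edge.length) | tr$edge.length < 0
  if (any(bad)) {
    stop("missing, non-finite or negative branch length on edge(s) ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  tr
}

#' Serialize a phylogeny to Newick
#'
#' Branch lengths are printed with enough digits (>= 10 significant) that
#' \code{parse_newick(write_newick(tree))} reproduces the topology and lengths.
#'
#' @param tree A \code{"phylo"} object.
#' @param file Optional path; when given the string is also written to disk.
#' @param digits Significant digits for branch lengths (default 12).
#' @return The Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL, digits = 12) {
  validate_phylo(tree)
  s <- ape::write.tree(tree, digits = digits)
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

#' Root-to-tip depths of all tips
#'
#' @param tree A \code{"phylo"} object.
#' @return Named numeric vector of tip depths, in tree time units.
#' @export
tip_depths <- function(tree) {
  validate_phylo(tree)
  nt <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  names(nt) <- tree$tip.label
  nt
}

#' Test ultrametricity within a relative tolerance
#'
#' @param tree A \code{"phylo"} object.
#' @param tol Relative tolerance as a fraction of tree depth (default 1e-6).
#' @return Logical scalar.
#' @export
is_ultrametric_tree <- function(tree, tol = 1e-6) {
  d <- tip_depths(tree)
  depth <- max(d)
  if (depth == 0) return(TRUE)
  (max(d) - min(d)) <= tol * depth
}

#' Brownian-motion variance-covariance matrix of a tree
#'
#' Entry \eqn{v_{ij}} is the shared root-to-tip path length of tips i and j
#' (the depth of their most recent common ancestor); the diagonal holds tip
#' depths. Under Brownian motion with rate \eqn{\sigma^2} the tip states are
#' multivariate normal with covariance \eqn{\sigma^2 V}. This matrix is the
#' engine of both Blomberg's K and PGLS.
#'
#' @param tree A \code{"phylo"} object.
#' @return A symmetric n x n matrix with tip labels as dimnames, in the
#'   tree's tip-label order.
#' @export
#' @examples
#' phylo_vcv(parse_newick("((A:1,B:1):1,C:2);"))
phylo_vcv <- function(tree) {
  validate_phylo(tree)
  V <- ape::vcv.phylo(tree)
  V[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Graft an outgroup tip above the root of an ultrametric tree
#'
#' Creates a new root with two children: the existing tree on a stem of
#' length `divergence_time - depth(tree)`, and the new tip on a pendant
#' branch of length `divergence_time`. The result is again ultrametric with
#' depth `divergence_time`. This is how a precomputed outgroup divergence
#' date (e.g. from an external sequence-distance estimate) is attached to a
#' calibrated ingroup tree.
#'
#' @param tree An ultrametric \code{"phylo"} object.
#' @param label Tip label for the outgroup (must not collide with existing
#'   labels).
#' @param divergence_time Age of the new root; must exceed the current tree
#'   depth.
#' @param tol Ultrametricity tolerance passed to [is_ultrametric_tree()].
#' @return A \code{"phylo"} object with one more tip.
#' @export
#' @examples
#' write_newick(graft_outgroup(parse_newick("(A:1,B:1);"), "C", 2))
graft_outgroup <- function(tree, label, divergence_time, tol = 1e-6) {
  validate_phylo(tree)
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  if (label %in% tree$tip.label)
    stop("label '", label, "' already present in tree", call. = FALSE)
  if (!is_ultrametric_tree(tree, tol))
    stop("tree is not ultrametric within tolerance", call. = FALSE)
  depth <- max(tip_depths(tree))
  if (!is.finite(divergence_time) || divergence_time <= depth)
    stop("divergence_time (", divergence_time,
         ") must exceed current tree depth (", signif(depth, 10), ")",
         call. = FALSE)
  stem <- divergence_time - depth
  inner <- sub(";\\s*$", "", ape::write.tree(tree, digits = 15))
  s <- sprintf("(%s:%.15g,%s:%.15g);", inner, stem, label, divergence_time)
  parse_newick(s)
}

#' Pagel-lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies the off-diagonal entries of V by `lambda`, leaving the diagonal
#' untouched. `lambda = 1` returns V (full Brownian structure); `lambda = 0`
#' gives a diagonal matrix, i.e. the star-phylogeny limit with no shared
#' history. Used as the signal-strength dial of the trait simulators.
#'
#' @param V Phylogenetic covariance matrix (from [phylo_vcv()]).
#' @param lambda Number in \[0, 1\].
#' @return Transformed covariance matrix (same dimnames).
#' @export
lambda_transform <- function(V, lambda) {
  V <- validate_vcv(V)
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda < 0 || lambda > 1)
    stop("lambda must be a single number in [0, 1]", call. = FALSE)
  W <- V * lambda
  diag(W) <- diag(V)
  W
}

# Covariance-matrix contract shared by the statistics layer.
validate_vcv <- function(V) {
  if (!is.matrix(V) || nrow(V) != ncol(V))
    stop("V must be a square matrix", call. = FALSE)
  if (any(!is.finite(V))) stop("V has non-finite entries", call. = FALSE)
  if (any(V < -1e-12)) stop("V has negative entries", call. = FALSE)
  if (max(abs(V - t(V))) > 1e-8 * max(abs(V), 1))
    stop("V is not symmetric", call. = FALSE)
  V
}
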
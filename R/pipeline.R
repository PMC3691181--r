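#' Load the packaged Sistrurus venom/diet dataset
#'
#' Returns the comparative dataset for the eight-taxon rattlesnake study
#' system: venom-proteome composition (12 protein families, percent of
#' total venom proteome per taxon), diet (proportion of mammals and lizards
#' among prey), published phylogenetic-signal and PGLS result tables for
#' cross-reference, and a time-calibrated tree.
#'
#' The tree deserves a caveat: the multilocus species-tree branch lengths
#' underlying the original analyses were never published. The packaged tree
#' is a synthetic stand-in - correct topology
#' `(((Sca,(Sct,Sce)),(Smb,(Sms,Smm))),Catrox),Agc` and the two published
#' calibrations (0.49 Myr for the Sms-Smm split, 0.77 Myr for the Smb
#' split), with all other node ages plausible placeholders. Statistics that
#' depend on branch lengths (K, PGLS) computed from it are therefore
#' illustrative, and [run_full_analysis()] stamps them as such.
#'
#' Note the `Agc` composition row sums to 87.3, not 100: the remaining
#' fraction of that venom proteome is unassigned material excluded from the
#' published family table.
#'
#' @return List with elements `composition` (matrix, taxa x 12 families),
#'   `diet` (matrix, taxa x \{mam, liz\}, proportions), `tree`
#'   (\code{"phylo"}), `tree_approximate` (TRUE), `published_signal` and
#'   `published_pgls` (data.frames of the published K and PGLS tables).
#' @export
#' @examples
#' fx <- load_fixture()
#' dim(fx$composition)   # 8 x 12
load_fixture <- function() {
  path <- function(f) system.file("extdata", f, package = "venomcomp",
                                  mustWork = TRUE)
  comp <- read_trait_csv(path("sistrurus_composition.csv"))
  diet <- read_trait_csv(path("sistrurus_diet.csv"))
  tree <- read_newick_file(path("sistrurus_tree_synthetic.nwk"))
  # Agc carries an unassigned fraction; allow its short row sum.
  comp <- validate_composition(comp, row_sum_tol = 15)
  stopifnot(setequal(rownames(comp), tree$tip.label),
            setequal(rownames(diet), tree$tip.label))
  list(
    composition = comp,
    diet = diet[rownames(comp), , drop = FALSE],
    tree = tree,
    tree_approximate = TRUE,
    published_signal = utils::read.csv(path("sistrurus_published_signal.csv"),
                                       stringsAsFactors = FALSE),
    published_pgls = utils::read.csv(path("sistrurus_published_pgls.csv"),
                                     stringsAsFactors = FALSE)
  )
}

#' Run the full phylogenetic comparative analysis
#'
#' Executes the complete pipeline on a tree, a venom composition table and
#' a diet table: (1) family filtering by mean abundance and prevalence;
#' (2) arcsine-square-root transform of venom percentages and diet
#' proportions; (3) covariance-matrix PCA of each; (4) diet-diet Pearson
#' correlation; (5) a phylogenetic-signal screen (Blomberg's K with tip
#' randomization) over the retained venom families, venom PC1/PC2, the two
#' diet variables and diet PC1; (6) a PGLS screen of the venom traits
#' (retained families + venom PC1/PC2) on the diet PC1 score; (7) the
#' Benjamini-Yekutieli critical p-value at the screen's test count.
#'
#' @param tree A \code{"phylo"} tree whose tips match the table rows.
#' @param composition Venom composition table (taxa x families, percent).
#' @param diet Diet table (taxa x variables, proportions in \[0, 1\]).
#' @param n_perm Permutations per signal test (default 1000).
#' @param seed Integer master seed (required).
#' @param alpha FDR level for the B-Y adjustment (default 0.05).
#' @param min_mean_pct,min_presence Family filter thresholds (defaults 1, 6).
#' @param tree_approximate Provenance flag copied into the report.
#' @return Object of class `"venom_report"`; see [report_json()].
#' @export
run_full_analysis <- function(tree, composition, diet, n_perm = 1000, seed,
                              alpha = 0.05, min_mean_pct = 1,
                              min_presence = 6, tree_approximate = FALSE) {
  if (missing(seed)) stop("seed must be given explicitly", call. = FALSE)
  validate_phylo(tree)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  comp <- stage("composition validation",
                validate_composition(composition, row_sum_tol = Inf))
  diet <- as.matrix(diet)
  taxa <- tree$tip.label
  if (!setequal(rownames(comp), taxa) || !setequal(rownames(diet), taxa))
    stop("stage 'alignment': taxa of tree, composition and diet differ",
         call. = FALSE)
  comp <- comp[taxa, , drop = FALSE]
  diet <- diet[taxa, , drop = FALSE]

  retained <- stage("filter_families",
                    filter_families(comp, min_mean_pct, min_presence))
  venom_t <- stage("arcsin_sqrt venom", arcsin_sqrt(retained, "percent"))
  diet_t <- stage("arcsin_sqrt diet", arcsin_sqrt(diet, "proportion"))
  venom_pca <- stage("venom PCA", pca_traits(venom_t, "covariance"))
  diet_pca <- stage("diet PCA", pca_traits(diet_t, "covariance"))
  diet_cor <- if (ncol(diet) >= 2)
    stage("diet correlation", pearson_cor(diet[, 1], diet[, 2])) else NA_real_

  venom_traits <- cbind(venom_t,
                        PC1_venom = venom_pca$scores[, 1],
                        PC2_venom = venom_pca$scores[, 2])
  signal_traits <- cbind(venom_traits, diet_t,
                         PC1_diet = diet_pca$scores[, 1])
  signal_tab <- stage("signal screen",
                      signal_screen(tree, signal_traits, n_perm = n_perm,
                                    seed = seed))
  V <- phylo_vcv(tree)
  pgls_tab <- stage("PGLS screen",
                    pgls_screen(V, venom_traits, diet_pca$scores[, 1],
                                predictor_name = "PC1_diet"))
  k <- sum(is.na(pgls_tab$error))
  crit <- by_critical(alpha, max(k, 1))
  pgls_tab$significant_after_BY <- !is.na(pgls_tab$p_value) &
    pgls_tab$p_value <= crit

  structure(list(
    retained_families = colnames(retained),
    venom_pca = list(variance_fractions = venom_pca$variance_fractions,
                     scaled_loadings = venom_pca$scaled_loadings),
    diet_pca = list(variance_fractions = diet_pca$variance_fractions,
                    scaled_loadings = diet_pca$scaled_loadings),
    diet_correlation = diet_cor,
    signal = signal_tab,
    pgls = pgls_tab,
    by_critical = crit,
    provenance = list(
      seed = as_seed(seed), n_perm = as.integer(n_perm), alpha = alpha,
      min_mean_pct = min_mean_pct, min_presence = min_presence,
      n_taxa = length(taxa),
      tree_approximate = isTRUE(tree_approximate),
      tree_note = if (isTRUE(tree_approximate))
        "illustrative - tree approximate" else "as supplied")
  ), class = "venom_report")
}

#' Run the full analysis on the packaged Sistrurus dataset
#'
#' @inheritParams run_full_analysis
#' @return A `"venom_report"` (with the approximate-tree provenance flag
#'   set; see [load_fixture()]).
#' @export
run_fixture_analysis <- function(n_perm = 1000, seed, alpha = 0.05) {
  fx <- load_fixture()
  run_full_analysis(fx$tree, fx$composition, fx$diet, n_perm = n_perm,
                    seed = seed, alpha = alpha,
                    tree_approximate = fx$tree_approximate)
}

#' @export
print.venom_report <- function(x, ...) {
  cat("Phylogenetic comparative analysis of venom composition\n")
  cat("  retained families:", paste(x$retained_families, collapse = ", "), "\n")
  cat(sprintf("  venom PCA: PC1 %.0f%%, PC2 %.0f%% of variance\n",
              100 * x$venom_pca$variance_fractions[1],
              100 * x$venom_pca$variance_fractions[2]))
  cat(sprintf("  diet PCA: PC1 %.0f%%; diet correlation r = %.2f\n",
              100 * x$diet_pca$variance_fractions[1], x$diet_correlation))
  cat(sprintf("  signal screen: %d traits, %d permutations each\n",
              nrow(x$signal), x$provenance$n_perm))
  cat(sprintf("  PGLS screen: %d traits, B-Y critical p = %.4f (alpha = %g)\n",
              nrow(x$pgls), x$by_critical, x$provenance$alpha))
  if (x$provenance$tree_approximate)
    cat("  note: K and PGLS values are", x$provenance$tree_note, "\n")
  invisible(x)
}

#' Serialize an analysis report to JSON
#'
#' Full numeric precision is retained; the JSON re-loads to the same values.
#'
#' @param report A `"venom_report"`.
#' @param path Output path; when NULL the JSON string is returned.
#' @return The path (invisibly) or the JSON string.
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "venom_report"))
  ser <- list(
    retained_families = report$retained_families,
    venom_pca = list(
      variance_fractions = report$venom_pca$variance_fractions,
      scaled_loadings = as.data.frame(report$venom_pca$scaled_loadings)),
    diet_pca = list(
      variance_fractions = report$diet_pca$variance_fractions,
      scaled_loadings = as.data.frame(report$diet_pca$scaled_loadings)),
    diet_correlation = report$diet_correlation,
    signal = report$signal,
    pgls = report$pgls,
    by_critical = report$by_critical,
    provenance = report$provenance
  )
  js <- jsonlite::toJSON(ser, auto_unbox = TRUE, digits = NA, na = "null",
                         dataframe = "columns")
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' Venom-proteome divergence rate
#'
#' Converts a shared-proteome percentage and an elapsed divergence time into
#' percent divergence per 100,000 years:
#' \eqn{(100 - shared) / (10\, t_{Myr})}. Total elapsed time since the
#' split is used (not per-lineage time).
#'
#' @param shared_pct Percent of the venom proteome shared (0-100).
#' @param time_myr Time since divergence in Myr (> 0).
#' @return Divergence rate in percent per 100 kyr.
#' @export
#' @examples
#' divergence_rate(95, 0.49)   # ~1% per 100,000 years
divergence_rate <- function(shared_pct, time_myr) {
  if (!is.numeric(shared_pct) || any(shared_pct < 0) || any(shared_pct > 100))
    stop("shared_pct must be in [0, 100]", call. = FALSE)
  if (!is.numeric(time_myr) || any(time_myr <= 0))
    stop("time_myr must be > 0", call. = FALSE)
  (100 - shared_pct) / (time_myr * 10)
}
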
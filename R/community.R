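# OTU-table community statistics: rarefying normalization, diversity
# indices, Bray-Curtis distances, UPGMA dendrograms, constrained
# ordination and FDR adjustment. Distance, ordination and subsampling
# primitives are delegated to vegan/stats/ape; this module provides the
# validated, pipeline-facing surface.

as_count_matrix <- function(counts) {
  m <- as.matrix(counts)
  if (is.null(rownames(m))) rownames(m) <- paste0("S", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("OTU", seq_len(ncol(m)))
  if (any(m < 0) || any(!is.finite(m))) {
    stop_rusitecr("counts must be finite and non-negative",
                  "rusitecr_validation_error")
  }
  m
}

#' Rarefy an OTU table to its minimum sample depth
#'
#' Normalizes sequencing depth by subsampling each sample's reads
#' without replacement down to the smallest sample total, the common
#' practice for amplicon OTU tables. Seeded and reproducible.
#'
#' @param counts samples x OTUs count matrix (or data.frame).
#' @param seed RNG seed; `NULL` uses the current stream.
#' @param depth target depth; defaults to the minimum sample total.
#' @return integer count matrix with every row summing to `depth`.
#' @export
rarefy_to_min <- function(counts, seed = NULL, depth = NULL) {
  m <- as_count_matrix(counts)
  totals <- rowSums(m)
  if (any(totals <= 0)) {
    stop_rusitecr("every sample must have at least one read",
                  "rusitecr_validation_error")
  }
  if (is.null(depth)) depth <- min(totals)
  if (depth > min(totals)) {
    stop_rusitecr("depth exceeds the smallest sample total",
                  "rusitecr_validation_error")
  }
  # rrarefy's "observed counts" heuristic misfires on small tables
  # whose rarest OTU count exceeds 1; validity is already checked here
  out <- with_seed(seed, withCallingHandlers(
    vegan::rrarefy(m, depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }))
  storage.mode(out) <- "integer"
  out
}

#' Per-sample diversity indices
#'
#' Richness (observed OTUs), classic Chao1 richness
#' S + F1 (F1 - 1) / (2 (F2 + 1)), Shannon H (natural log), Pielou
#' evenness H / ln(richness), Gini-Simpson 1 - sum(p^2), and Good's
#' coverage 1 - F1/N (F1, F2 = singleton and doubleton counts). Compute
#' on a rarefied table so depths are comparable.
#'
#' @param counts samples x OTUs count matrix.
#' @return data.frame with one row per sample: `sample_id`, `richness`,
#'   `chao1`, `shannon`, `evenness`, `simpson`, `goods_coverage`.
#' @export
diversity_indices <- function(counts) {
  m <- as_count_matrix(counts)
  if (any(rowSums(m) <= 0)) {
    stop_rusitecr("every sample must have at least one read",
                  "rusitecr_validation_error")
  }
  rich <- vegan::specnumber(m)
  shan <- vegan::diversity(m, index = "shannon")
  simp <- vegan::diversity(m, index = "simpson")
  f1 <- rowSums(m == 1)
  f2 <- rowSums(m == 2)
  data.frame(
    sample_id = rownames(m),
    richness = rich,
    chao1 = rich + f1 * (f1 - 1) / (2 * (f2 + 1)),
    shannon = shan,
    evenness = ifelse(rich > 1, shan / log(rich), NA_real_),
    simpson = simp,
    goods_coverage = 1 - f1 / rowSums(m),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Bray-Curtis dissimilarity matrix
#'
#' BC(a, b) = sum|a_i - b_i| / sum(a_i + b_i) on transformed
#' abundances. The default log(x + 1) transform damps the influence of
#' dominant OTUs while remaining defined at zero.
#'
#' @param counts samples x OTUs count matrix.
#' @param transform abundance transform applied before the distance;
#'   default [log1p]; use [identity] for raw counts.
#' @return a [stats::dist] of Bray-Curtis dissimilarities.
#' @export
bray_curtis <- function(counts, transform = log1p) {
  m <- as_count_matrix(counts)
  if (any(rowSums(m) == 0)) {
    stop_rusitecr("Bray-Curtis undefined for all-zero samples",
                  "rusitecr_validation_error")
  }
  vegan::vegdist(transform(m), method = "bray")
}

#' UPGMA dendrogram from a distance matrix
#'
#' Average-linkage agglomerative clustering. Ties are broken towards
#' the lowest-index pair (the behaviour of [stats::hclust]),
#' deterministically.
#'
#' @param d a [stats::dist] or square symmetric matrix.
#' @return an [ape::as.phylo] tree; leaf labels are the sample ids.
#' @export
upgma <- function(d) {
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d))) {
      stop_rusitecr("distance matrix must be symmetric",
                    "rusitecr_validation_error")
    }
    d <- as.dist(d)
  }
  ape::as.phylo(hclust(d, method = "average"))
}

#' UPGMA dendrogram as newick text
#'
#' @inheritParams upgma
#' @return single newick string (with branch lengths; internal heights
#'   follow the average-linkage merge heights).
#' @export
upgma_newick <- function(d) {
  ape::write.tree(upgma(d))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment controlling the false discovery rate; a validated
#' wrapper over [stats::p.adjust].
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop_rusitecr("p-values must lie in [0, 1]", "rusitecr_validation_error")
  }
  p.adjust(pvalues, method = "BH")
}

#' Canonical correspondence analysis with permutation tests
#'
#' Constrained correspondence analysis (ter Braak) of a community table
#' on explanatory fermentation variables, with marginal (one variable
#' at a time) permutation significance. Ordination is delegated to
#' [vegan::cca]; significance to [vegan::anova.cca] with
#' `by = "margin"`.
#'
#' @param counts samples x OTUs count matrix (typically rarefied).
#' @param env data.frame of explanatory variables, rows matching
#'   samples; constant columns are rejected.
#' @param n_perm permutations for the significance tests (default 999).
#' @param seed RNG seed for the permutations.
#' @return list of class `cca_result`: `eigenvalues` (constrained),
#'   `total_inertia`, `constrained_inertia`, `site_scores`,
#'   `species_scores`, `biplot_scores`, `variable_p` (named, one per
#'   explanatory variable), `rank_deficient` flag, and the underlying
#'   vegan `ordination` object.
#' @export
cca_ordination <- function(counts, env, n_perm = 999, seed = NULL) {
  m <- as_count_matrix(counts)
  env <- as.data.frame(env)
  if (nrow(env) != nrow(m)) {
    stop_rusitecr("env rows must match samples", "rusitecr_validation_error")
  }
  constant <- vapply(env, function(x) length(unique(x)) < 2, logical(1))
  if (any(constant)) {
    stop_rusitecr(paste("constant explanatory variable(s):",
                        paste(names(env)[constant], collapse = ", ")),
                  "rusitecr_validation_error")
  }
  if (nrow(m) < ncol(env) + 2) {
    stop_rusitecr("need at least (number of variables + 2) samples",
                  "rusitecr_validation_error")
  }
  ord <- vegan::cca(m ~ ., data = env)
  rank_def <- !is.null(ord$CCA$alias) ||
    ord$CCA$qrank < sum(vapply(env, function(x)
      if (is.numeric(x)) 1L else length(unique(x)) - 1L, integer(1)))
  pvals <- with_seed(seed, {
    an <- vegan::anova.cca(ord, by = "margin", permutations = n_perm)
    setNames(an[["Pr(>F)"]][seq_len(nrow(an) - 1)],
             rownames(an)[seq_len(nrow(an) - 1)])
  })
  structure(list(
    eigenvalues = unname(ord$CCA$eig),
    total_inertia = ord$tot.chi,
    constrained_inertia = sum(ord$CCA$eig),
    site_scores = vegan::scores(ord, display = "sites",
                                choices = seq_along(ord$CCA$eig)),
    species_scores = vegan::scores(ord, display = "species",
                                   choices = seq_along(ord$CCA$eig)),
    biplot_scores = ord$CCA$biplot,
    variable_p = pvals,
    rank_deficient = rank_def,
    ordination = ord
  ), class = "cca_result")
}
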
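# OTU-table statistics: rarefaction, diversity, distances, clustering,
# ordination, FDR.

test_that("rarefying normalization conserves depth and composition", {
  m <- rbind(a = c(8, 2), b = c(50, 50), c = c(30, 10))
  r <- rarefy_to_min(m, seed = 1)
  expect_true(all(rowSums(r) == 10))
  expect_true(all(r <= m))
  # depth equal to the total returns the sample unchanged
  same <- rarefy_to_min(rbind(x = c(8, 2), y = c(6, 4)), seed = 1)
  expect_equal(rowSums(same), c(x = 10, y = 10))
  expect_equal(unname(rarefy_to_min(matrix(c(8, 2), 1), seed = 1)[1, ]),
               c(8, 2))
  # hypergeometric expectation: (8, 2) rarefied to 5 averages (4, 1)
  draws <- vapply(1:300, function(s)
    rarefy_to_min(rbind(c(8, 2), c(4, 1)), seed = s)[1, 1], numeric(1))
  se <- sqrt(5 * 0.8 * 0.2 * (10 - 5) / (10 - 1)) / sqrt(300)
  expect_lt(abs(mean(draws) - 4), 4 * se)
  expect_error(rarefy_to_min(rbind(c(0, 0), c(1, 1))),
               class = "rusitecr_validation_error")
  # seeded and reproducible
  big <- matrix(rpois(200, 20), 10)
  expect_identical(rarefy_to_min(big, seed = 42), rarefy_to_min(big, seed = 42))
})

test_that("diversity indices match their closed forms", {
  uniform <- matrix(rep(10, 8), nrow = 1)
  d <- diversity_indices(uniform)
  expect_equal(d$richness, 8)
  expect_equal(d$shannon, log(8))
  expect_equal(d$evenness, 1)
  single <- matrix(c(25, 0, 0), nrow = 1)
  ds <- diversity_indices(single)
  expect_equal(ds$shannon, 0)
  expect_equal(ds$simpson, 0)
  hand <- diversity_indices(matrix(c(5, 3, 2), nrow = 1))
  expect_equal(hand$shannon, 1.0297, tolerance = 1e-4)
  expect_equal(hand$simpson, 0.62)
  # chao1 collapses to richness without singletons; Good's counts them
  no_single <- matrix(c(5, 3, 2), nrow = 1)
  expect_equal(diversity_indices(no_single)$chao1,
               diversity_indices(no_single)$richness)
  with_single <- matrix(c(10, 1, 1, 2), nrow = 1)
  expect_equal(diversity_indices(with_single)$chao1, 4 + 2 * 1 / (2 * 2))
  expect_equal(diversity_indices(with_single)$goods_coverage, 1 - 2 / 14)
  # permutation-invariance over OTU labels
  set.seed(2)
  x <- matrix(rpois(30, 5), nrow = 1)
  p <- sample(ncol(x))
  expect_equal(diversity_indices(x)$shannon,
               diversity_indices(x[, p, drop = FALSE])$shannon)
  expect_equal(diversity_indices(x)$simpson,
               diversity_indices(x[, p, drop = FALSE])$simpson)
})

test_that("Bray-Curtis distances are bounded, symmetric and exact by hand", {
  ident <- rbind(a = c(3, 4, 1), b = c(3, 4, 1))
  expect_equal(as.matrix(bray_curtis(ident))[1, 2], 0)
  disjoint <- rbind(a = c(5, 0), b = c(0, 9))
  expect_equal(as.matrix(bray_curtis(disjoint))[1, 2], 1)
  hand <- rbind(a = c(1, 1, 0), b = c(0, 1, 1))
  expect_equal(as.matrix(bray_curtis(hand, transform = identity))[1, 2], 0.5)
  set.seed(9)
  for (i in 1:10) {
    m <- matrix(rpois(60, 3), nrow = 6)
    m[rowSums(m) == 0, 1] <- 1
    D <- as.matrix(bray_curtis(m))
    expect_true(all(D >= 0 & D <= 1))
    expect_equal(D, t(D))
    expect_true(all(diag(D) == 0))
  }
  expect_error(bray_curtis(rbind(c(0, 0), c(1, 1))),
               class = "rusitecr_validation_error")
})

test_that("UPGMA matches a naive average-linkage oracle", {
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  tr <- upgma(d2)
  expect_setequal(tr$tip.label, c("A", "B"))
  expect_equal(sum(tr$edge.length), 0.4)
  d3 <- matrix(c(0, 0.1, 0.9,
                 0.1, 0, 0.9,
                 0.9, 0.9, 0), 3,
               dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  nwk <- upgma_newick(d3)
  expect_match(nwk, "\\(A[:0-9.]*,B[:0-9.]*\\)|\\(B[:0-9.]*,A[:0-9.]*\\)")
  set.seed(13)
  for (i in 1:5) {
    m <- matrix(runif(16, 0.1, 1), 4)
    D <- (m + t(m)) / 2
    diag(D) <- 0
    dimnames(D) <- list(paste0("s", 1:4), paste0("s", 1:4))
    tree <- upgma(D)
    coph <- as.matrix(ape::cophenetic.phylo(tree))[rownames(D), rownames(D)]
    expect_equal(unname(coph), oracle_cophenetic(D), tolerance = 1e-9)
  }
  asym <- matrix(c(0, 1, 2, 0), 2)
  expect_error(upgma(asym), class = "rusitecr_validation_error")
})

test_that("Benjamini-Hochberg adjustment is the step-up procedure", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.27, 0.6)
  adj <- bh_adjust(p)
  expect_true(all(diff(adj[order(p)]) >= 0))
  expect_true(all(adj <= 1 & adj >= p))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "rusitecr_validation_error")
})

test_that("CCA conserves inertia and separates constructed groups", {
  set.seed(21)
  cfg <- simulation_config(otu = list(n_samples = 16, n_otus = 60,
                                      fold_change = 8,
                                      depth_range = c(2000, 2500)))
  sim <- simulate_otu_table(cfg, seed = 31)
  env <- data.frame(forage = sim$metadata$forage,
                    covar = rnorm(16))
  res <- cca_ordination(sim$counts, env, n_perm = 199, seed = 1)
  # conservation identity: constrained + unconstrained = CA total inertia
  ca <- vegan::cca(sim$counts)
  expect_equal(res$total_inertia, ca$tot.chi, tolerance = 1e-9)
  expect_lte(res$constrained_inertia, res$total_inertia)
  expect_true(all(diff(res$eigenvalues) <= 1e-12))
  # a binary variable aligned with a strong compositional split
  # separates the groups on axis 1
  ax1 <- res$site_scores[, 1]
  gra <- sim$metadata$forage == "GRA"
  expect_true(max(ax1[gra]) < min(ax1[!gra]) ||
                min(ax1[gra]) > max(ax1[!gra]))
  expect_lt(res$variable_p[["forage"]], 0.05)
  expect_error(cca_ordination(sim$counts,
                              data.frame(k = rep(1, 16))),
               class = "rusitecr_validation_error")
})
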
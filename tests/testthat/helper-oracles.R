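# Independent oracles used to cross-check the package's numerics.
# Each is a deliberately naive reimplementation (grid search, brute
# force, direct enumeration) kept free of package internals.

# Exhaustive grid search for the single-pool exponential fit.
oracle_france_grid <- function(time_h, volume_ml,
                               a_range, c_range, n_grid = 201) {
  a_grid <- seq(a_range[1], a_range[2], length.out = n_grid)
  c_grid <- seq(c_range[1], c_range[2], length.out = n_grid)
  best <- c(A = NA, c = NA, rss = Inf)
  for (a in a_grid) {
    for (cc in c_grid) {
      rss <- sum((volume_ml - a * (1 - exp(-cc * time_h)))^2)
      if (rss < best["rss"]) best <- c(A = a, c = cc, rss = rss)
    }
  }
  list(A = unname(best["A"]), c = unname(best["c"]),
       res_a = diff(a_range) / (n_grid - 1),
       res_c = diff(c_range) / (n_grid - 1))
}

# Naive average-linkage agglomeration returning merge heights and the
# sets merged at each step.
oracle_average_linkage <- function(D) {
  D <- as.matrix(D)
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric(0)
  avg_d <- function(a, b) mean(D[a, b])
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        d <- avg_d(clusters[[i]], clusters[[j]])
        if (d < best[1]) best <- c(d, j, i)
      }
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- c(clusters[-c(best[2], best[3])], list(merged))
  }
  heights
}

# Cophenetic distances from naive average linkage (for topology
# checks): distance at which two leaves first share a cluster.
oracle_cophenetic <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  out <- matrix(0, n, n)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        d <- mean(D[clusters[[i]], clusters[[j]]])
        if (d < best[1]) best <- c(d, j, i)
      }
    }
    for (a in clusters[[best[2]]]) for (b in clusters[[best[3]]]) {
      out[a, b] <- out[b, a] <- best[1]
    }
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- c(clusters[-c(best[2], best[3])], list(merged))
  }
  out
}

# One-way PERMANOVA pseudo-F straight from the sums-of-squared-
# distances identities (no Gower centering, no projections).
oracle_oneway_pseudo_f <- function(D, groups) {
  D <- as.matrix(D)
  n <- nrow(D)
  ss_total <- sum(D[upper.tri(D)]^2) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    Dg <- D[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(Dg[upper.tri(Dg)]^2) / length(idx)
  }
  a <- length(unique(groups))
  ((ss_total - ss_within) / (a - 1)) / (ss_within / (n - a))
}

# Exact one-way permutation p-value by enumerating all n! orderings.
oracle_oneway_exact_p <- function(D, groups) {
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
    }
    out
  }
  f_obs <- oracle_oneway_pseudo_f(D, groups)
  f_all <- vapply(perms(seq_along(groups)), function(p)
    oracle_oneway_pseudo_f(D, groups[p]), numeric(1))
  mean(f_all >= f_obs - 1e-12)
}

# Brute-force OLS line by direct minimization of the SSE.
oracle_ols_slope <- function(x, y) {
  fit <- optim(c(0, 0), function(par) sum((y - par[1] - par[2] * x)^2),
               method = "BFGS", control = list(reltol = 1e-14))
  fit$par[2]
}

random_vfa_profile <- function() {
  vfa_profile(acetate = runif(1, 5, 20), propionate = runif(1, 2, 12),
              butyrate = runif(1, 1, 8), valerate = runif(1, 0.2, 2),
              isobutyrate = runif(1, 0, 1), isovalerate = runif(1, 0, 2))
}
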
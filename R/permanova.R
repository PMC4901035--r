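# Permutational multivariate analysis of variance (PERMANOVA) on a
# dissimilarity matrix, per McArdle & Anderson's partitioning of the
# Gower-centered distance matrix. Implemented here (rather than
# delegated) because the pipeline needs both the reduced-model
# (Freedman-Lane) residual-permutation scheme and an exhaustive
# enumeration mode for exact small-sample p-values.

# Gower-centered inner-product matrix of a distance matrix:
# G = (I - 11'/n) (-D^2/2) (I - 11'/n).
gower_center <- function(D) {
  A <- -0.5 * D^2
  n <- nrow(A)
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

# Symmetric projection ("hat") matrix onto the column space of X.
hat_matrix <- function(X) {
  q <- qr(X)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(Q)
}

# All n! permutations of 1..n as rows (small n only).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[as.vector(sub)], nrow(sub)))
  }))
}

#' PERMANOVA with reduced-model residual permutation
#'
#' Partitions the total sum of squares of a dissimilarity matrix among
#' the terms of a factorial design and tests each term with a
#' permutation pseudo-F. Each term is adjusted for all other terms
#' (marginal sums of squares; for balanced factorial designs these
#' coincide with sequential ones). Significance uses permutation of
#' residuals under the reduced model (Freedman-Lane): for term k the
#' residuals of the model without k are permuted, the fitted part is
#' retained, and the pseudo-F for k is recomputed;
#' p = (1 + #\{F* >= F\}) / (1 + n_perm). With `exhaustive = TRUE` all
#' n! sample relabellings are enumerated instead and
#' p = #\{F* >= F\} / n!.
#'
#' @param d a [stats::dist] or square symmetric dissimilarity matrix.
#' @param data data.frame of design factors, rows matching samples.
#' @param terms character vector of column names of `data` to test
#'   (default all columns). Interactions are not expanded; pass
#'   precomputed interaction factors if needed.
#' @param n_perm number of random permutations (default 999); ignored
#'   when `exhaustive = TRUE`.
#' @param seed RNG seed for the permutations.
#' @param exhaustive enumerate all permutations (requires n <= 8).
#' @return data.frame of class `permanova_result`, one row per term:
#'   `term`, `df`, `ss`, `pseudo_f`, `p_value`, `n_perm`; attributes
#'   `ss_residual`, `df_residual`, `ss_total`.
#' @export
permanova <- function(d, data, terms = names(data), n_perm = 999,
                      seed = NULL, exhaustive = FALSE) {
  D <- as.matrix(d)
  if (!isSymmetric(unname(D))) {
    stop_rusitecr("dissimilarity matrix must be symmetric",
                  "rusitecr_validation_error")
  }
  n <- nrow(D)
  data <- as.data.frame(data)
  if (nrow(data) != n) {
    stop_rusitecr("design rows must match samples", "rusitecr_validation_error")
  }
  for (tm in terms) {
    if (!tm %in% names(data)) {
      stop_rusitecr(sprintf("term `%s` not in design data", tm),
                    "rusitecr_validation_error")
    }
    if (length(unique(data[[tm]])) < 2) {
      stop_rusitecr(sprintf("term `%s` has a single level", tm),
                    "rusitecr_validation_error")
    }
  }
  G <- gower_center(D)
  term_cols <- lapply(terms, function(tm) {
    x <- data[[tm]]
    if (is.numeric(x)) matrix(x, ncol = 1)
    else model.matrix(~ f, data.frame(f = factor(x)))[, -1, drop = FALSE]
  })
  intercept <- matrix(1, n, 1)
  X_full <- do.call(cbind, c(list(intercept), term_cols))
  H_full <- hat_matrix(X_full)
  rank_full <- qr(X_full)$rank
  M_res <- diag(n) - H_full
  ss_res <- sum(M_res * G)
  df_res <- n - rank_full
  ss_total <- sum(diag(G))

  perms <- if (exhaustive) {
    if (n > 8) {
      stop_rusitecr("exhaustive enumeration limited to n <= 8",
                    "rusitecr_validation_error")
    }
    all_permutations(n)
  } else {
    with_seed(seed, t(replicate(n_perm, sample.int(n))))
  }

  rows <- lapply(seq_along(terms), function(k) {
    X_red <- do.call(cbind, c(list(intercept), term_cols[-k]))
    H_red <- hat_matrix(X_red)
    df_k <- rank_full - qr(X_red)$rank
    H_diff <- H_full - H_red
    ss_k <- sum(H_diff * G)
    f_obs <- (ss_k / df_k) / (ss_res / df_res)
    Fit <- H_red %*% G %*% H_red
    M_red <- diag(n) - H_red
    E <- M_red %*% G %*% M_red
    f_perm <- apply(perms, 1, function(p) {
      G_star <- Fit + E[p, p]
      ssk <- sum(H_diff * G_star)
      ssr <- sum(M_res * G_star)
      (ssk / df_k) / (ssr / df_res)
    })
    p_val <- if (exhaustive) mean(f_perm >= f_obs - 1e-12)
    else (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + nrow(perms))
    data.frame(term = terms[k], df = df_k, ss = ss_k, pseudo_f = f_obs,
               p_value = p_val, n_perm = nrow(perms),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "ss_residual") <- ss_res
  attr(out, "df_residual") <- df_res
  attr(out, "ss_total") <- ss_total
  class(out) <- c("permanova_result", "data.frame")
  out
}
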
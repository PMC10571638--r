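## Group-conditional structure of the behavior battery: Spearman correlation
## matrices, PCA of the correlation matrix, and the binomial independence
## null for the fraction of animals meeting >= k criteria.

#' Pairwise Spearman correlation matrix with p-values
#'
#' Spearman rank correlations (average ranks for ties) between the behavior
#' columns, restricted to `group_mask` when given. Two-sided p-values use the
#' large-sample t approximation `t = r * sqrt((n - 2) / (1 - r^2))` on
#' `n - 2` degrees of freedom by default; `exact = TRUE` switches to the
#' exact permutation null of [stats::cor.test()], advisable for groups of
#' fewer than ~10 animals.
#'
#' @param x a `"behavior_matrix"` or data.frame/matrix of behavior columns.
#' @param group_mask optional logical/integer subset of rows.
#' @param behaviors columns to correlate (default the five scored
#'   behaviors).
#' @param exact logical; exact p-values for small groups.
#' @return List with `r` (symmetric, unit diagonal), `p` (NA diagonal) and
#'   `n`.
#' @export
spearman_matrix <- function(x, group_mask = NULL, behaviors = .behaviors,
                            exact = FALSE) {
  m <- .behavior_values(x, behaviors)
  if (!is.null(group_mask)) m <- m[group_mask, , drop = FALSE]
  n <- nrow(m)
  if (n < 4) {
    stop_audcage(sprintf("group has %d animal(s); Spearman matrix needs at least 4", n),
                 "audcage_group_error")
  }
  r <- stats::cor(m, method = "spearman")
  p <- matrix(NA_real_, ncol(m), ncol(m), dimnames = dimnames(r))
  for (i in seq_len(ncol(m) - 1)) {
    for (j in (i + 1):ncol(m)) {
      if (exact) {
        pv <- suppressWarnings(
          stats::cor.test(m[, i], m[, j], method = "spearman", exact = TRUE)$p.value
        )
      } else {
        rij <- r[i, j]
        if (abs(rij) >= 1) {
          pv <- 0
        } else {
          tstat <- rij * sqrt((n - 2) / (1 - rij^2))
          pv <- 2 * stats::pt(-abs(tstat), df = n - 2)
        }
      }
      p[i, j] <- p[j, i] <- pv
    }
  }
  list(r = r, p = p, n = n)
}

#' PCA of the behavior battery
#'
#' Eigendecomposition of the group's behavior correlation matrix (columns are
#' z-scored within the group, so PCA is on correlations — the behaviors have
#' incommensurable units). Components are ordered by decreasing eigenvalue
#' and each component's sign is oriented so its largest-magnitude loading is
#' positive.
#'
#' @param x a `"behavior_matrix"` or data.frame/matrix of behavior columns.
#' @param group_mask optional logical/integer subset of rows.
#' @param n_components how many components to return (default all).
#' @param behaviors columns to use (default the five scored behaviors).
#' @return List with `loadings` (behaviors x components eigenvector matrix),
#'   `eigenvalues`, `explained_variance` (fractions summing to 1 over all
#'   components) and `n`.
#' @export
pca_loadings <- function(x, group_mask = NULL, n_components = NULL,
                         behaviors = .behaviors) {
  m <- .behavior_values(x, behaviors)
  if (!is.null(group_mask)) m <- m[group_mask, , drop = FALSE]
  n <- nrow(m)
  if (n < 4) {
    stop_audcage(sprintf("group has %d animal(s); PCA needs at least 4", n),
                 "audcage_group_error")
  }
  sdv <- apply(m, 2, stats::sd)
  if (any(sdv == 0)) {
    stop_audcage(paste0("zero-variance behavior column(s) within group: ",
                        paste(behaviors[sdv == 0], collapse = ", ")),
                 "audcage_group_error")
  }
  C <- stats::cor(m)
  eig <- eigen(C, symmetric = TRUE)
  V <- eig$vectors
  ## orient: largest-|loading| entry of each component positive
  for (j in seq_len(ncol(V))) {
    piv <- which.max(abs(V[, j]))
    if (V[piv, j] < 0) V[, j] <- -V[, j]
  }
  dimnames(V) <- list(behaviors, paste0("PC", seq_len(ncol(V))))
  ncomp <- n_components %||% ncol(V)
  list(loadings = V[, seq_len(ncomp), drop = FALSE],
       eigenvalues = eig$values,
       explained_variance = eig$values / sum(eig$values),
       n = n)
}

#' Expected fraction of animals meeting >= k independent criteria
#'
#' Under the null that the per-behavior criteria are independent, each with
#' positivity probability `q`, the fraction of animals fulfilling at least
#' `k` of `m` criteria is the binomial upper tail
#' `sum_{j >= k} C(m, j) q^j (1 - q)^(m - j)`. Comparing this null with an
#' observed prone fraction quantifies how far the criteria are from
#' independence.
#'
#' @param q per-criterion positivity probability in `[0, 1]`.
#' @param m number of criteria (default 5).
#' @param k criterion-count threshold (default 2).
#' @return The expected fraction in `[0, 1]`.
#' @examples
#' independence_null(0.35, 5, 2)  # 0.5716 to 4 decimals
#' @export
independence_null <- function(q, m = 5L, k = 2L) {
  if (q < 0 || q > 1) stop_audcage("q must lie in [0, 1]", "audcage_config_error")
  if (k < 0 || k > m) stop_audcage("k must lie in 0..m", "audcage_config_error")
  if (k == 0) return(1)
  stats::pbinom(k - 1, size = m, prob = q, lower.tail = FALSE)
}

#' Group-conditional structure report
#'
#' For each group (`prone`, `resistant`, and `all`) computes the Spearman
#' correlation matrix with p-values and the correlation-matrix PCA of the
#' behavior battery.
#'
#' @param x a `"behavior_matrix"` (or data.frame with the behavior columns).
#' @param class character vector (`"prone"`/`"resistant"`) aligned with the
#'   rows of `x`, e.g. from an [aud_phenotype()] fit.
#' @param behaviors columns analyzed (default the five scored behaviors).
#' @param exact passed to [spearman_matrix()].
#' @param on_small `"omit"` (default) records `n` and skips the matrices for
#'   groups of fewer than 4 animals; `"error"` raises instead.
#' @return An object of class `"structure_report"`: per group, a list with
#'   `n`, `spearman` and `pca` (the latter two `NULL` when omitted).
#' @export
phenotype_structure <- function(x, class, behaviors = .behaviors,
                                exact = FALSE, on_small = c("omit", "error")) {
  on_small <- match.arg(on_small)
  stopifnot(length(class) == nrow(as.data.frame(x)))
  groups <- list(prone = class == "prone",
                 resistant = class == "resistant",
                 all = rep(TRUE, length(class)))
  rep_out <- lapply(names(groups), function(g) {
    mask <- groups[[g]]
    n <- sum(mask)
    if (n < 4) {
      if (on_small == "error") {
        stop_audcage(sprintf("group '%s' has %d animal(s); need at least 4", g, n),
                     "audcage_group_error")
      }
      return(list(n = n, spearman = NULL, pca = NULL))
    }
    list(n = n,
         spearman = spearman_matrix(x, mask, behaviors, exact = exact),
         pca = pca_loadings(x, mask, behaviors = behaviors))
  })
  names(rep_out) <- names(groups)
  structure(rep_out, class = "structure_report", behaviors = behaviors)
}

#' @export
print.structure_report <- function(x, ...) {
  cat("Group-conditional behavior structure\n")
  for (g in names(x)) {
    el <- x[[g]]
    if (is.null(el$spearman)) {
      cat(sprintf("  %s: n = %d (too small, omitted)\n", g, el$n))
      next
    }
    off <- el$spearman$r[upper.tri(el$spearman$r)]
    cat(sprintf("  %s: n = %d, mean off-diagonal Spearman r = %.3f, PC1 explains %.1f%%\n",
                g, el$n, mean(off), 100 * el$pca$explained_variance[1]))
  }
  invisible(x)
}

#' Mean off-diagonal Spearman correlation of a group
#'
#' Convenience summary used when contrasting prone vs resistant structure.
#'
#' @param report a `"structure_report"`.
#' @param group `"prone"`, `"resistant"` or `"all"`.
#' @return Mean of the 10 off-diagonal correlations (NA if omitted).
#' @export
mean_offdiag_spearman <- function(report, group) {
  el <- report[[group]]
  if (is.null(el$spearman)) return(NA_real_)
  mean(el$spearman$r[upper.tri(el$spearman$r)])
}
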
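#' Per-electrode dependent-samples t statistics
#'
#' Paired t-test per electrode between two participant x electrode matrices:
#' with differences `d = a - b`, `t = mean(d) / (sd(d) / sqrt(n))`. If the
#' differences at an electrode have zero variance and a nonzero mean, the
#' statistic is reported as +/-Inf with a warning (and is treated as
#' significant downstream); a zero mean with zero variance gives t = 0.
#'
#' @param a,b numeric matrices, participants x electrodes, same participants
#'   in the same row order and identical electrode columns.
#' @return named numeric vector of t values, one per electrode.
#' @export
dependent_t_map <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!identical(dim(a), dim(b))) stopf("a and b must have identical dimensions")
  n <- nrow(a)
  if (n < 2L) stopf("need at least 2 participants")
  d <- a - b
  m <- colMeans(d)
  s <- sqrt(colSums((d - rep(m, each = n))^2) / (n - 1))
  t <- m / (s / sqrt(n))
  degenerate <- s == 0
  if (any(degenerate)) {
    t[degenerate & m == 0] <- 0
    if (any(degenerate & m != 0)) {
      warning("zero variance of paired differences at some electrode(s): t reported as +/-Inf",
              call. = FALSE)
      t[degenerate & m > 0] <- Inf
      t[degenerate & m < 0] <- -Inf
    }
  }
  names(t) <- colnames(a)
  t
}

# Clusters from a logical significance vector and a t map: connected
# components of the adjacency graph within same-sign significant electrodes;
# only components of size >= 2 count. Returns a list of
# list(electrodes, sign, mass), sorted by |mass| descending.
clusters_from_sig <- function(tmap, sig, adj, channels) {
  out <- list()
  for (sgn in c(1, -1)) {
    idx <- which(sig & sign(tmap) == sgn)
    for (comp in connected_components(adj, idx)) {
      if (length(comp) >= 2L) {
        out[[length(out) + 1L]] <- list(electrodes = channels[comp],
                                        sign = sgn,
                                        mass = sum(tmap[comp]))
      }
    }
  }
  if (length(out) > 1L) {
    out <- out[order(vapply(out, function(cl) abs(cl$mass), 0),
                     decreasing = TRUE)]
  }
  out
}

#' Form spatial clusters of significant electrodes
#'
#' Electrodes whose two-tailed paired-t p value falls below `alpha_form`
#' (reference distribution: t with `df` degrees of freedom) are marked
#' significant. Within the significant set, connected components of the
#' montage adjacency graph are computed separately for positive-t and
#' negative-t electrodes; components of two or more electrodes form
#' clusters, each with mass = sum of its member t values. Isolated
#' significant electrodes never form a cluster.
#'
#' @param tmap named t-value vector from [dependent_t_map()] (names must
#'   match the montage channels).
#' @param montage a [rift_montage].
#' @param df degrees of freedom of the paired t (participants - 1).
#' @param alpha_form cluster-forming two-tailed alpha (default 0.05).
#' @return list of clusters, each `list(electrodes, sign, mass)`, sorted by
#'   absolute mass (electrodes in montage order within each cluster).
#' @export
form_clusters <- function(tmap, montage, df, alpha_form = 0.05) {
  stopifnot(inherits(montage, "rift_montage"))
  if (!(alpha_form > 0 && alpha_form < 1)) stopf("alpha_form must lie in (0, 1)")
  if (!identical(names(tmap), montage$channels)) {
    stopf("tmap names must match the montage channels")
  }
  tcrit <- stats::qt(1 - alpha_form / 2, df)
  clusters_from_sig(tmap, abs(tmap) > tcrit, montage$adjacency,
                    montage$channels)
}

all_sign_matrix <- function(n) {
  if (n > 20L) stopf("exhaustive enumeration limited to 20 participants")
  m <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  dimnames(m) <- NULL
  m
}

# Vectorized paired-t over many sign-flip permutations.
# d: participants x electrodes; signs: n_perm x participants.
perm_t_matrix <- function(d, signs) {
  n <- nrow(d)
  ssq <- colSums(d^2)
  means <- (signs %*% d) / n                     # n_perm x electrodes
  vars <- sweep(-n * means^2, 2L, ssq, `+`) / (n - 1)
  vars[vars < 0] <- 0                            # numeric guard
  t <- means / sqrt(vars / n)
  t[is.nan(t)] <- 0                              # 0/0: all-zero differences
  t
}

#' Permutation null distribution of the maximum cluster mass
#'
#' Under the paired-exchangeability null, each participant's condition
#' labels can be flipped independently; a flip negates that participant's
#' difference. For each permutation the full t-map and cluster formation are
#' recomputed and the permutation statistic is the maximum absolute cluster
#' mass (0 when no cluster forms). With `exhaustive = TRUE` all `2^n` sign
#' patterns are enumerated instead of sampled (including the identity), so
#' downstream p values equal the exact enumeration p.
#'
#' @param a,b participant x electrode matrices (as in [dependent_t_map()]).
#' @param montage a [rift_montage] whose channels match the columns.
#' @param n_perm number of random permutations (default 5000).
#' @param alpha_form cluster-forming two-tailed alpha (default 0.05).
#' @param exhaustive enumerate all sign flips instead of sampling.
#' @return numeric vector of max-|mass| null statistics (length `n_perm`,
#'   or `2^n` when exhaustive).
#' @export
permutation_null <- function(a, b, montage, n_perm = 5000, alpha_form = 0.05,
                             exhaustive = FALSE) {
  stopifnot(inherits(montage, "rift_montage"))
  a <- as.matrix(a); b <- as.matrix(b)
  if (!identical(dim(a), dim(b))) stopf("a and b must have identical dimensions")
  if (ncol(a) != length(montage$channels)) {
    stopf("electrode columns (%d) must match the montage (%d channels)",
          ncol(a), length(montage$channels))
  }
  n <- nrow(a)
  if (n < 2L) stopf("need at least 2 participants")
  if (!exhaustive && (!is_count(n_perm))) stopf("n_perm must be a positive integer")
  d <- a - b
  signs <- if (exhaustive) all_sign_matrix(n) else {
    matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), ncol = n)
  }
  tmat <- perm_t_matrix(d, signs)
  tcrit <- stats::qt(1 - alpha_form / 2, n - 1)
  adj <- montage$adjacency
  channels <- montage$channels
  sigmat <- abs(tmat) > tcrit
  null <- numeric(nrow(tmat))
  candidates <- which(rowSums(sigmat) >= 2L)
  for (i in candidates) {
    cl <- clusters_from_sig(tmat[i, ], sigmat[i, ], adj, channels)
    if (length(cl) > 0L) null[i] <- abs(cl[[1L]]$mass)
  }
  null
}

#' Two-tailed cluster-based permutation test over electrodes
#'
#' Assembles the observed t map and clusters, the permutation null of the
#' maximum absolute cluster mass, and per-cluster Monte Carlo p values with
#' the finite-sample correction `p = (1 + #(null >= |mass|)) / (1 + n_perm)`
#' (exact enumeration p when `exhaustive = TRUE`). Both tails share a single
#' max-|mass| null; a cluster is flagged significant when `p < alpha`.
#'
#' @inheritParams permutation_null
#' @param alpha significance threshold for cluster p values (default 0.05).
#' @param seed optional integer seed for the permutation RNG (local to the
#'   call).
#' @return an object of class `rift_cluster_test`: clusters (electrodes,
#'   sign, mass, p, significant), the observed `tmap`, `null` distribution,
#'   `n_perm`, `alpha`, `alpha_form`, `df` and `exhaustive`.
#' @export
cluster_test <- function(a, b, montage, n_perm = 5000, alpha = 0.05,
                         alpha_form = 0.05, exhaustive = FALSE, seed = NULL) {
  a <- as.matrix(a); b <- as.matrix(b)
  tmap <- suppressWarnings(dependent_t_map(a, b))
  names(tmap) <- montage$channels
  n <- nrow(a)
  observed <- form_clusters(tmap, montage, df = n - 1, alpha_form = alpha_form)
  null <- with_seed(seed,
                    permutation_null(a, b, montage, n_perm = n_perm,
                                     alpha_form = alpha_form,
                                     exhaustive = exhaustive))
  n_eff <- length(null)
  clusters <- lapply(observed, function(cl) {
    p <- if (exhaustive) mean(null >= abs(cl$mass)) else {
      (1 + sum(null >= abs(cl$mass))) / (1 + n_eff)
    }
    c(cl, list(p = p, significant = p < alpha))
  })
  structure(list(clusters = clusters, tmap = tmap, null = null,
                 n_perm = n_eff, alpha = alpha, alpha_form = alpha_form,
                 df = n - 1, exhaustive = exhaustive),
            class = "rift_cluster_test")
}

#' Does a cluster test contain any significant cluster?
#'
#' @param x a `rift_cluster_test`.
#' @return `TRUE` if any cluster's Monte Carlo p is below the test's alpha.
#' @export
any_significant <- function(x) {
  stopifnot(inherits(x, "rift_cluster_test"))
  any(vapply(x$clusters, `[[`, TRUE, "significant"))
}

#' @export
print.rift_cluster_test <- function(x, ...) {
  cat(sprintf("<rift_cluster_test> %s permutations (df = %d, cluster-forming alpha = %g)\n",
              if (x$exhaustive) sprintf("exhaustive %d", x$n_perm)
              else format(x$n_perm, big.mark = ","),
              x$df, x$alpha_form))
  if (length(x$clusters) == 0L) {
    cat("  no clusters formed\n")
  } else {
    for (cl in x$clusters) {
      cat(sprintf("  %s cluster: mass %.2f, p = %.4f%s [%s]\n",
                  if (cl$sign > 0) "positive" else "negative",
                  cl$mass, cl$p, if (cl$significant) " *" else "",
                  paste(cl$electrodes, collapse = ", ")))
    }
  }
  invisible(x)
}

#' Export a cluster test result as JSON
#'
#' @param x a `rift_cluster_test`.
#' @param path output path.
#' @param frequency_hz,contrast,seed optional metadata recorded in the JSON.
#' @return `path`, invisibly.
#' @export
export_cluster_json <- function(x, path, frequency_hz = NULL, contrast = NULL,
                                seed = NULL) {
  stopifnot(inherits(x, "rift_cluster_test"))
  obj <- list(frequency_hz = frequency_hz, contrast = contrast,
              clusters = lapply(x$clusters, function(cl) {
                list(electrodes = cl$electrodes, sign = cl$sign,
                     mass = cl$mass, p = cl$p, significant = cl$significant)
              }),
              n_permutations = x$n_perm, alpha = x$alpha,
              alpha_form = x$alpha_form, df = x$df, seed = seed)
  jsonlite::write_json(obj[!vapply(obj, is.null, TRUE)], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
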
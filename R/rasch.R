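#' Discordant pairwise response counts
#'
#' For every ordered item pair (i, j), counts the child-rounds that
#' observed both items and passed i while failing j. Under the Rasch model
#' these discordant counts are conditionally sufficient for difficulty
#' differences: given that exactly one of two items is passed, the
#' probability that it is item i depends only on the difficulty difference,
#' and the person's ability cancels. Concordant pairs contribute nothing.
#'
#' @param rm A \code{dscale_matrix}.
#' @return An integer matrix \code{n} with \code{n[i, j]} the count of
#'   child-rounds passing i and failing j; zero diagonal.
#' @export
pairwise_counts <- function(rm) {
  stopifnot(inherits(rm, "dscale_matrix"))
  m <- rm$scores
  p <- (!is.na(m)) & m == 1L
  f <- (!is.na(m)) & m == 0L
  storage.mode(p) <- "numeric"
  storage.mode(f) <- "numeric"
  n <- crossprod(p, f)
  diag(n) <- 0
  n
}

# Pool item-level discordant counts to constraint-cluster level.
# Within-cluster pairs are excluded (the diagonal of the pooled table).
collapse_counts <- function(counts, cluster) {
  g <- t(rowsum(t(rowsum(counts, cluster)), cluster))
  diag(g) <- 0
  g
}

#' Estimate Rasch item difficulties by constrained pairwise likelihood
#'
#' Maximises the pairwise conditional (Bradley-Terry) pseudo-likelihood
#' \deqn{\sum_{i<j} n_{ij} \log \pi_{ij} + n_{ji} \log(1 - \pi_{ij}),
#'   \quad \pi_{ij} = \frac{e^{\delta_j - \delta_i}}{1 + e^{\delta_j -
#'   \delta_i}},}
#' where all members of a constraint cluster (an active equate group, or a
#' cross-country same-instrument pool) share a single difficulty: their
#' discordant counts against outside items are pooled and within-cluster
#' pairs are excluded. Solved by minorise-maximise (MM) fixed-point
#' iterations on the cluster-level counts. When exactly one of a pair's two
#' counts is zero, a small smoothing constant is added to both so the
#' finite maximiser exists. The solution is normalised to mean-zero
#' difficulty over clusters (each cluster counted once, so large
#' instruments do not dominate the origin).
#'
#' @param counts Matrix from \code{\link{pairwise_counts}}.
#' @param clusters Named character vector mapping item code to constraint
#'   cluster id; items not named get a singleton cluster. \code{NULL} means
#'   no constraints.
#' @param tol Convergence tolerance on the max absolute difficulty change
#'   (logits), default \code{1e-8}.
#' @param max_iter Maximum MM iterations, default 2000.
#' @param eps Smoothing added to both counts of a pair when exactly one is
#'   zero, default 0.05.
#' @return Named numeric vector of difficulties (logits, mean zero over
#'   clusters) with attributes \code{clusters} (item -> cluster id),
#'   \code{iterations} and \code{converged}.
#' @export
estimate_difficulties <- function(counts, clusters = NULL, tol = 1e-8,
                                  max_iter = 2000, eps = 0.05) {
  items <- rownames(counts)
  if (is.null(items)) stop("`counts` must have item dimnames")
  cl <- setNames(items, items)
  if (!is.null(clusters)) {
    hit <- intersect(items, names(clusters))
    cl[hit] <- clusters[hit]
  }
  cc <- collapse_counts(counts, cl)
  ids <- rownames(cc)
  k <- length(ids)
  if (k < 2) stop("need at least two constraint clusters to estimate")

  # smooth one-sided zeros so every observed comparison is two-sided
  one_sided <- (cc > 0) != (t(cc) > 0)
  smooth <- one_sided | t(one_sided)
  cc[smooth] <- cc[smooth] + eps

  # the cluster comparison graph must be strongly connected
  adj <- cc > 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  if (comp$no > 1)
    stop(sprintf(
      "pairwise comparison graph is not strongly connected (%d components); %s",
      comp$no, "link the instruments with active equate groups or drop isolated items"))

  N <- cc + t(cc)
  W <- rowSums(cc)
  p <- rep(1, k)
  delta <- -log(p)
  converged <- FALSE
  it <- 0
  # MM warm start: monotone but slow near the optimum
  mm_tol <- max(tol, 1e-2)
  while (it < max_iter) {
    it <- it + 1
    denom <- 1 / outer(p, p, "+")
    diag(denom) <- 0
    p_new <- W / rowSums(N * denom)
    p_new <- p_new / exp(mean(log(p_new)))
    delta_new <- -log(p_new)
    step <- max(abs(delta_new - delta))
    p <- p_new
    delta <- delta_new
    if (step < mm_tol) break
  }
  # damped Newton polish on the concave pairwise log-likelihood; the
  # Hessian is a weighted graph Laplacian (singular along translations),
  # regularised on the direction of constant shifts
  pos <- cc > 0
  loglik <- function(delta) {
    logA <- plogis(outer(-delta, delta, "+"), log.p = TRUE)
    sum(cc[pos] * logA[pos])
  }
  ll <- loglik(delta)
  while (it < max_iter) {
    it <- it + 1
    A <- plogis(outer(-delta, delta, "+"))   # A[i, j] = pi_ij
    G <- cc * (1 - A)
    grad <- colSums(G) - rowSums(G)
    Wt <- N * A * (1 - A)
    L <- diag(rowSums(Wt)) - Wt
    x <- solve(L + 1 / k, grad)
    x <- x - mean(x)
    damp <- 1
    repeat {
      cand <- delta + damp * x
      ll_new <- loglik(cand)
      if (ll_new >= ll - 1e-12 || damp < 1e-4) break
      damp <- damp / 2
    }
    step <- max(abs(damp * x))
    delta <- delta + damp * x
    delta <- delta - mean(delta)
    ll <- ll_new
    if (step < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf(
      "pairwise estimation did not converge in %d iterations (last step %.3g logits)",
      max_iter, step))
  delta <- delta - mean(delta)          # mean zero over clusters
  out <- setNames(delta[match(cl, ids)], items)
  attr(out, "clusters") <- cl
  attr(out, "iterations") <- it
  attr(out, "converged") <- converged
  out
}
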
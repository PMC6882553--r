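# Independent oracles used to freeze expected values. These deliberately
# avoid the package's estimation code paths.

# Conditional maximum likelihood for complete binary data: eliminates the
# person parameters by conditioning on raw scores, with elementary
# symmetric functions computed by direct polynomial expansion and the
# likelihood maximised numerically.
oracle_cml <- function(x) {
  k <- ncol(x)
  s <- colSums(x)
  r_tab <- table(factor(rowSums(x), levels = 0:k))
  esf <- function(eps) {
    g <- 1
    for (e in eps) g <- c(g, 0) + c(0, g * e)
    g
  }
  negcl <- function(v) {
    delta <- c(v, -sum(v))
    gam <- esf(exp(-delta))
    sum(delta * s) + sum(as.numeric(r_tab) * log(gam))
  }
  fit <- optim(rep(0, k - 1), negcl, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  delta <- c(fit$par, -sum(fit$par))
  setNames(delta - mean(delta), colnames(x))
}

# Dense-grid numerical integration for the EAP posterior mean/SD.
oracle_eap <- function(x, delta_d, a, prior_mean, prior_sd, step = 0.001,
                       span = 40) {
  g <- seq(prior_mean - span, prior_mean + span, by = step)
  ll <- rep(0, length(g))
  for (it in names(x)) {
    p <- plogis((g - delta_d[[it]]) / a)
    ll <- ll + if (x[[it]] == 1) log(p) else log(1 - p)
  }
  lp <- ll + dnorm(g, prior_mean, prior_sd, log = TRUE)
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  m <- sum(w * g)
  c(mean = m, sd = sqrt(sum(w * (g - m)^2)))
}

# Union-find connected components over an explicit edge list.
oracle_components <- function(nodes, edges) {
  parent <- setNames(nodes, nodes)
  find <- function(i) {
    while (parent[[i]] != i) i <- parent[[i]]
    i
  }
  for (e in edges) parent[[find(e[1])]] <- find(e[2])
  roots <- vapply(nodes, find, "")
  split(nodes, roots)
}

# Exhaustive pairwise-count enumeration over every person and item pair.
oracle_pairwise_counts <- function(x) {
  k <- ncol(x)
  n <- matrix(0, k, k, dimnames = list(colnames(x), colnames(x)))
  for (p in seq_len(nrow(x))) for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    xi <- x[p, i]; xj <- x[p, j]
    if (!is.na(xi) && !is.na(xj) && xi == 1 && xj == 0)
      n[i, j] <- n[i, j] + 1
  }
  n
}

# Grid search of the pooled pairwise objective for three items with items
# 1 and 2 sharing one difficulty (mean-zero over the two clusters).
oracle_cluster_grid <- function(counts, step = 1e-3, lim = 5) {
  obj <- function(t) {
    # cluster at t, free item at -t; within-cluster pairs excluded
    n_c3 <- counts[1, 3] + counts[2, 3]
    n_3c <- counts[3, 1] + counts[3, 2]
    p <- plogis(-t - t)   # pi_{c,3} = logistic(delta_3 - delta_c)
    n_c3 * log(p) + n_3c * log(1 - p)
  }
  ts <- seq(-lim, lim, by = step)
  t_hat <- ts[which.max(vapply(ts, obj, 1))]
  c(cluster = t_hat, free = -t_hat)
}
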
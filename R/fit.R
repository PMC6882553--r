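#' Infit and outfit item-fit statistics
#'
#' With \eqn{P_{ni} = \mathrm{logistic}(\theta_n - \delta_i)} and
#' standardised residual \eqn{z_{ni} = (x_{ni} - P_{ni}) /
#' \sqrt{P_{ni}(1-P_{ni})}}, outfit is the unweighted mean of
#' \eqn{z_{ni}^2} over observed responses to item i, and infit is the
#' information-weighted version \eqn{\sum (x_{ni}-P_{ni})^2 / \sum
#' P_{ni}(1-P_{ni})}. Both have expectation near 1 when the model holds;
#' values well below 1 indicate overfitting (e.g. higher discrimination
#' than the Rasch slope), values above 1 underfitting.
#'
#' @param rm A \code{dscale_matrix}.
#' @param delta_logit Named difficulties in logits covering the matrix
#'   columns.
#' @param theta Numeric vector of abilities (logits), one per child-round
#'   row (typically EAP estimates).
#' @return Data frame \code{item, infit, outfit, n_obs}; items with no
#'   observed responses get \code{NA} statistics.
#' @export
infit_outfit <- function(rm, delta_logit, theta) {
  stopifnot(inherits(rm, "dscale_matrix"),
            length(theta) == nrow(rm$scores))
  m <- rm$scores[, names(delta_logit)[names(delta_logit) %in%
                                        colnames(rm$scores)], drop = FALSE]
  delta <- delta_logit[colnames(m)]
  P <- plogis(outer(theta, delta, "-"))
  obs <- !is.na(m)
  R2 <- (m - P)^2
  V <- P * (1 - P)
  R2[!obs] <- 0
  Vo <- V
  Vo[!obs] <- 0
  n_obs <- colSums(obs)
  outfit <- ifelse(n_obs > 0, colSums(R2 / pmax(V, 1e-12) * obs) / n_obs, NA_real_)
  infit <- ifelse(n_obs > 0, colSums(R2) / colSums(Vo), NA_real_)
  data.frame(item = colnames(m), infit = unname(infit),
             outfit = unname(outfit), n_obs = unname(n_obs),
             stringsAsFactors = FALSE)
}

#' Apply the item retention rule
#'
#' An item is retained when it belongs to an active equate group, or, as an
#' independent item, when both its infit and outfit are strictly below 1.
#' The strict sub-1 rule keeps only independent items that discriminate at
#' least as sharply as the Rasch slope, favouring scale coherence over item
#' count.
#'
#' @param fit Data frame from \code{\link{infit_outfit}}.
#' @param bank An \code{\link{item_bank}}.
#' @param active_groups Character vector of equate-group ids currently
#'   active.
#' @return List with \code{retained} (item codes) and \code{removed}
#'   (data frame \code{item, reason}).
#' @export
retention_pass <- function(fit, bank, active_groups = character()) {
  eg <- bank$equate_group[match(fit$item, bank$item_code)]
  in_active <- !is.na(eg) & eg %in% active_groups
  fit_ok <- !is.na(fit$infit) & !is.na(fit$outfit) &
    fit$infit < 1 & fit$outfit < 1
  keep <- in_active | fit_ok
  reason <- rep(NA_character_, nrow(fit))
  reason[!keep & is.na(fit$infit)] <- "no observed responses"
  bad <- !keep & !is.na(fit$infit)
  reason[bad] <- sprintf("independent item with infit %.2f / outfit %.2f (rule: both < 1)",
                         fit$infit[bad], fit$outfit[bad])
  list(retained = fit$item[keep],
       removed = data.frame(item = fit$item[!keep], reason = reason[!keep],
                            stringsAsFactors = FALSE))
}

# One-dimensional pairwise refit of a single item's difficulty, all other
# difficulties held fixed. Newton on the pairwise log-likelihood; returns
# the estimate and its standard error from the observed information.
refit_one <- function(counts, delta, item, tol = 1e-10, max_iter = 100) {
  others <- setdiff(names(delta), item)
  n_ij <- counts[item, others]
  n_ji <- counts[others, item]
  use <- (n_ij + n_ji) > 0
  if (!any(use)) return(c(est = NA_real_, se = NA_real_, n = 0))
  n_ij <- n_ij[use]; n_ji <- n_ji[use]
  dj <- delta[others][use]
  d <- unname(delta[item])
  if (is.na(d)) d <- 0
  for (k in seq_len(max_iter)) {
    pij <- plogis(dj - d)
    score <- sum(-n_ij * (1 - pij) + n_ji * pij)
    info <- sum((n_ij + n_ji) * pij * (1 - pij))
    if (info <= 0) break
    step <- score / info
    # score is decreasing in d, so Newton ascends with d <- d - score/(-info)
    d <- d + step
    if (abs(step) < tol) break
  }
  pij <- plogis(dj - d)
  info <- sum((n_ij + n_ji) * pij * (1 - pij))
  c(est = d, se = 1 / sqrt(info), n = unname(sum(n_ij + n_ji)))
}

# Sandwich standard error for the one-item pairwise refit: pairwise
# contributions sharing a child-round are correlated, so the naive
# information understates the variance. Clusters the pseudo-likelihood
# score by child-round.
refit_se_robust <- function(m, delta, item, est) {
  others <- intersect(setdiff(names(delta), item), colnames(m))
  xi <- m[, item]
  xo <- m[, others, drop = FALSE]
  pij <- plogis(delta[others] - est)
  wins <- (xi == 1) * (xo == 0)
  losses <- (xi == 0) * (xo == 1)
  wins[is.na(wins)] <- 0
  losses[is.na(losses)] <- 0
  u <- -wins %*% (1 - pij) + losses %*% pij
  info <- sum((colSums(wins) + colSums(losses)) * pij * (1 - pij))
  if (info <= 0) return(NA_real_)
  sqrt(sum(u^2)) / info
}

#' Flag differential item functioning across groups
#'
#' For each item, re-estimates its difficulty separately within each group
#' (e.g. country), holding every other item's difficulty fixed at the
#' pooled estimate, and compares the group-specific estimates. An item is
#' flagged when the largest pairwise difference exceeds
#' \code{threshold} logits and a Wald test on that difference is
#' significant at \code{alpha}. A group contributes only when the item has
#' at least \code{min_n} pairwise wins and \code{min_n} pairwise losses
#' there (raw response counts are not enough: with almost no discordances
#' the refit is skewed and its Wald interval invalid); items testable in
#' fewer than two groups are "untestable". Flagged items should not be
#' pooled across groups (kept group-specific or excluded, per caller
#' policy).
#'
#' @param rm A \code{dscale_matrix}.
#' @param delta_logit Named pooled difficulties (logits).
#' @param grouping Vector (length = rows of the matrix) of group labels,
#'   e.g. country of the cohort.
#' @param items Items to test; default all columns.
#' @param min_n Minimum pairwise wins and losses per group (default 30).
#' @param threshold Minimum difficulty gap (logits) to flag, default 0.5.
#' @param alpha Wald significance level, default 0.05.
#' @return Data frame \code{item, n_groups, max_diff, se_diff, p, verdict}
#'   with verdict in \code{flagged / ok / untestable}.
#' @export
dif_flag <- function(rm, delta_logit, grouping, items = NULL,
                     min_n = 30, threshold = 0.5, alpha = 0.05) {
  stopifnot(inherits(rm, "dscale_matrix"),
            length(grouping) == nrow(rm$scores))
  if (is.null(items)) items <- colnames(rm$scores)
  groups <- unique(as.character(grouping))
  counts_g <- lapply(groups, function(g)
    pairwise_counts(structure(list(
      scores = rm$scores[grouping == g, , drop = FALSE]),
      class = "dscale_matrix")))
  names(counts_g) <- groups
  wins <- sapply(counts_g, rowSums)
  losses <- sapply(counts_g, colSums)
  res <- lapply(items, function(it) {
    ok_g <- groups[wins[it, ] >= min_n & losses[it, ] >= min_n]
    if (length(ok_g) < 2)
      return(data.frame(item = it, n_groups = length(ok_g),
                        max_diff = NA_real_, se_diff = NA_real_,
                        p = NA_real_, verdict = "untestable",
                        stringsAsFactors = FALSE))
    est <- t(vapply(ok_g, function(g) {
      r <- refit_one(counts_g[[g]], delta_logit, it)
      if (!is.na(r[["est"]]))
        r[["se"]] <- refit_se_robust(
          rm$scores[grouping == g, , drop = FALSE], delta_logit, it,
          r[["est"]])
      r
    }, numeric(3)))
    est <- est[!is.na(est[, "est"]) & !is.na(est[, "se"]), ,
               drop = FALSE]
    if (nrow(est) < 2)
      return(data.frame(item = it, n_groups = nrow(est),
                        max_diff = NA_real_, se_diff = NA_real_,
                        p = NA_real_, verdict = "untestable",
                        stringsAsFactors = FALSE))
    i <- which.max(est[, "est"]); j <- which.min(est[, "est"])
    diff <- est[i, "est"] - est[j, "est"]
    se <- sqrt(est[i, "se"]^2 + est[j, "se"]^2)
    p <- 2 * pnorm(-abs(diff) / se)
    data.frame(item = it, n_groups = nrow(est), max_diff = diff,
               se_diff = se, p = p,
               verdict = if (diff > threshold && p < alpha) "flagged" else "ok",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
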
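#' Anchor specification for the D-score metric
#'
#' The D-score unit and origin are defined by fixing the difficulties of
#' two widely measured, culturally robust motor milestones: lifting the
#' head to 45 degrees in prone position at 20 D-score units, and sitting
#' stably without support at 40 D-score units.
#'
#' @param item_lo,item_hi Item codes of the two anchor milestones.
#' @param value_lo,value_hi Their fixed difficulties in D-score units
#'   (defaults 20 and 40).
#' @return An object of class \code{anchor_spec}.
#' @export
anchor_spec <- function(item_lo = "lifts head to 45 degrees in prone position",
                        item_hi = "sits in stable position without support",
                        value_lo = 20, value_hi = 40) {
  stopifnot(value_hi > value_lo, item_lo != item_hi)
  structure(list(item_lo = item_lo, item_hi = item_hi,
                 value_lo = value_lo, value_hi = value_hi),
            class = "anchor_spec")
}

#' Map logit difficulties to the anchored D-score metric
#'
#' Finds the unique increasing linear map placing the two anchor items at
#' their fixed D-score values: slope \eqn{a = (v_{hi} - v_{lo}) /
#' (\delta_{hi} - \delta_{lo})} (D units per logit) and offset
#' \eqn{b = v_{lo} - a\,\delta_{lo}}. All difficulties transform as
#' \eqn{\delta_D = a\delta + b}; on the D metric the pass probability is
#' \code{logistic((theta_D - delta_D) / a)}, so the fitted model is
#' preserved exactly under the change of units.
#'
#' @param delta_logit Named difficulties in logits, containing both anchor
#'   items.
#' @param anchors An \code{\link{anchor_spec}}.
#' @return List with \code{a} (slope, > 0), \code{b} (offset),
#'   \code{delta_d} (named difficulties in D units) and \code{anchors}.
#' @export
anchor_transform <- function(delta_logit, anchors = anchor_spec()) {
  stopifnot(inherits(anchors, "anchor_spec"))
  miss <- setdiff(c(anchors$item_lo, anchors$item_hi), names(delta_logit))
  if (length(miss) > 0)
    stop("anchor item(s) missing from the fitted difficulties: ",
         paste(miss, collapse = "; "))
  d_lo <- delta_logit[[anchors$item_lo]]
  d_hi <- delta_logit[[anchors$item_hi]]
  if (!(d_hi > d_lo))
    stop(sprintf(
      "anchor difficulties are inverted or equal on the logit scale (%.3f vs %.3f)",
      d_lo, d_hi))
  a <- (anchors$value_hi - anchors$value_lo) / (d_hi - d_lo)
  b <- anchors$value_lo - a * d_lo
  delta_d <- a * as.numeric(delta_logit) + b
  names(delta_d) <- names(delta_logit)
  list(a = a, b = b, delta_d = delta_d, anchors = anchors)
}

#' Rasch pass probability on the D-score metric
#'
#' \code{logistic((theta_d - delta_d) / a)}: exactly 0.5 when ability
#' equals difficulty, strictly increasing in ability. The anchoring slope
#' \code{a} (D units per logit) carries the unit change, so probabilities
#' agree with the fitted logit-scale model.
#'
#' @param theta_d Ability in D-score units.
#' @param delta_d Item difficulty in D-score units.
#' @param a Anchoring slope in D units per logit (> 0); 1 gives the plain
#'   logit-scale model.
#' @return Probability of passing.
#' @export
rasch_probability <- function(theta_d, delta_d, a = 1) {
  stopifnot(a > 0)
  plogis((theta_d - delta_d) / a)
}

#' Equally spaced quadrature grid with normal prior weights
#'
#' @param mean,sd Prior mean and SD (same units as the difficulties).
#' @param span Half-width of the grid around the mean (default 15).
#' @param n_nodes Number of nodes (default 601).
#' @return List with \code{nodes} (increasing) and \code{weights}
#'   (non-negative, summing to 1).
#' @export
quadrature_grid <- function(mean = 0, sd = 5, span = 15, n_nodes = 601) {
  nodes <- seq(mean - span, mean + span, length.out = n_nodes)
  w <- dnorm(nodes, mean, sd)
  list(nodes = nodes, weights = w / sum(w))
}

#' Expected a posteriori (EAP) ability for one child-round
#'
#' The posterior over ability is the normal prior times the Rasch
#' likelihood of the observed responses, evaluated on an equally spaced
#' grid; the D-score is the posterior mean and its standard error of
#' measurement the posterior SD. With no observed responses the prior mean
#' and SD are returned unchanged.
#'
#' @param x Named 0/1 response vector (names are item codes; NAs dropped).
#' @param delta_d Named item difficulties (D units) covering the responded
#'   items.
#' @param a Anchoring slope (D units per logit).
#' @param prior_mean,prior_sd Normal prior in D units.
#' @param grid Optional \code{\link{quadrature_grid}}; default 601 nodes
#'   spanning \code{prior_mean +/- 15}.
#' @return List with \code{d_score}, \code{sem}, \code{n_items_used}.
#' @export
eap_score <- function(x, delta_d, a = 1, prior_mean = 0, prior_sd = 5,
                      grid = NULL) {
  x <- x[!is.na(x)]
  miss <- setdiff(names(x), names(delta_d))
  if (length(miss) > 0)
    stop("response(s) to item(s) absent from the model: ",
         paste(head(miss, 5), collapse = ", "))
  if (length(x) == 0)
    return(list(d_score = prior_mean, sem = prior_sd, n_items_used = 0L))
  if (is.null(grid))
    grid <- quadrature_grid(prior_mean, prior_sd)
  d <- delta_d[names(x)]
  eta <- outer(grid$nodes, d, "-") / a
  ll <- as.vector(plogis(eta, log.p = TRUE) %*% x +
                    plogis(-eta, log.p = TRUE) %*% (1 - x))
  lp <- ll + log(pmax(grid$weights, 1e-300))
  post <- exp(lp - max(lp))
  post <- post / sum(post)
  m <- sum(post * grid$nodes)
  v <- sum(post * (grid$nodes - m)^2)
  list(d_score = m, sem = sqrt(v), n_items_used = length(x))
}

# Vectorised EAP over all child-rounds of a response matrix, on a shared
# grid with the single-child node spacing (0.05 units). prior_mean may be
# scalar or per-row; prior weights are evaluated per child on the shared
# grid, which is numerically equivalent to per-child grids at equal node
# density. Children are processed in chunks to bound memory.
eap_batch <- function(m, delta_d, a = 1, prior_mean = 0, prior_sd = 5,
                      span = 15, step = 0.05, chunk = 1000L) {
  stopifnot(all(colnames(m) %in% names(delta_d)))
  n <- nrow(m)
  prior_mean <- rep_len(prior_mean, n)
  d <- delta_d[colnames(m)]
  lo <- min(prior_mean) - span
  hi <- max(prior_mean) + span
  nodes <- seq(lo, hi, by = step)
  eta <- outer(nodes, d, "-") / a
  logP <- plogis(eta, log.p = TRUE)
  logQ <- plogis(-eta, log.p = TRUE)
  est <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("d_score", "sem")))
  n_used <- rowSums(!is.na(m))
  for (s in seq(1, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    xs <- m[idx, , drop = FALSE]
    obs <- !is.na(xs)
    xp <- xs; xp[!obs] <- 0L
    xf <- (1L - xs); xf[!obs] <- 0L
    ll <- logP %*% t(xp) + logQ %*% t(xf)          # nodes x children
    lpr <- dnorm(outer(nodes, prior_mean[idx], "-"), sd = prior_sd,
                 log = TRUE)
    lp <- ll + lpr
    lp <- sweep(lp, 2, apply(lp, 2, max))
    w <- exp(lp)
    w <- sweep(w, 2, colSums(w), "/")
    mu <- colSums(w * nodes)
    v <- colSums(w * nodes^2) - mu^2
    est[idx, 1] <- mu
    est[idx, 2] <- sqrt(pmax(v, 0))
  }
  # zero-response rows carry the prior unchanged (no grid truncation)
  none <- n_used == 0
  est[none, 1] <- prior_mean[none]
  est[none, 2] <- prior_sd
  data.frame(d_score = est[, 1], sem = est[, 2], n_items_used = n_used)
}

#' EAP D-scores for every child-round of a response matrix
#'
#' Two prior policies are supported. \code{"flat"} uses an effectively
#' uninformative normal prior (SD 50) on a grid spanning the difficulty
#' range; scores are then driven by the responses alone. \code{"auto"}
#' (default) first scores with the flat prior, smooths the resulting
#' D-scores against the square root of age to obtain a preliminary median
#' curve, and rescores with a normal prior centred on that curve with SD 5
#' D units, stabilising estimates for children with few items.
#'
#' @param rm A \code{dscale_matrix}.
#' @param model A \code{dscale_model} from \code{\link{build_model}}, or a
#'   list with \code{delta_d} (named, D units) and \code{anchor$a}.
#' @param prior \code{"auto"} or \code{"flat"}.
#' @param prior_sd Prior SD (D units) for the informative pass, default 5.
#' @return Data frame \code{child_id, cohort, round, age_months, d_score,
#'   sem, n_items_used}.
#' @export
score_children <- function(rm, model, prior = c("auto", "flat"),
                           prior_sd = 5) {
  prior <- match.arg(prior)
  stopifnot(inherits(rm, "dscale_matrix"))
  delta_d <- model$delta_d
  a <- if (!is.null(model$anchor)) model$anchor$a else 1
  m <- rm$scores[, intersect(colnames(rm$scores), names(delta_d)),
                 drop = FALSE]
  if (ncol(m) == 0) stop("no matrix items overlap the model")
  mid <- mean(range(delta_d))
  span_flat <- diff(range(delta_d)) / 2 + 15
  flat <- eap_batch(m, delta_d, a, prior_mean = mid, prior_sd = 50,
                    span = span_flat)
  if (prior == "flat") {
    out <- flat
  } else {
    age <- rm$meta$age_months
    if (length(unique(age)) >= 4) {
      fit <- smooth.spline(sqrt(age), flat$d_score,
                           df = min(5, length(unique(age)) - 1))
      mu <- predict(fit, sqrt(age))$y
    } else {
      mu <- ave(flat$d_score, age)   # too few distinct ages to smooth
    }
    out <- eap_batch(m, delta_d, a, prior_mean = mu, prior_sd = prior_sd)
  }
  cbind(rm$meta, out)
}
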
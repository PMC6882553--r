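#' Fit an LMS (Box-Cox) age-conditional reference for D-scores
#'
#' Models the age-conditional distribution of D-scores with the LMS
#' method: at each age the distribution is Box-Cox normal with power
#' \eqn{L(t)}, median \eqn{M(t)} and coefficient of variation \eqn{S(t)},
#' so that \eqn{z = ((y/M)^L - 1)/(L S)} (or \eqn{\log(y/M)/S} when
#' \eqn{L = 0}) is standard normal. The three curves are estimated by
#' penalized maximum likelihood via iterative backfitting: each cycle takes
#' a Fisher-scoring step per observation in one curve's parameter and
#' smooths the working variate against transformed age with a fixed-df
#' smoothing spline. Age is smoothed on a power-transformed axis (default
#' square root) to stabilise infancy curvature, and a small positive
#' offset is added to the D-scores before fitting (the Box-Cox form needs
#' positive values near age zero) and removed on inversion.
#'
#' @param d_score Numeric D-scores.
#' @param age_months Ages in decimal months, same length.
#' @param df Effective degrees of freedom for the L, M, S curves; default
#'   \code{c(L = 3, M = 5, S = 3)}.
#' @param age_power Power transform applied to age before smoothing
#'   (default 0.5).
#' @param offset Positive constant added to D-scores before the Box-Cox
#'   fit (default 1) and subtracted by \code{\link{daz_inverse}}.
#' @param L_fixed Fix the power curve at a constant (e.g. 1 for a normal
#'   heteroscedastic model); \code{NULL} (default) estimates it.
#' @param min_obs Minimum score-age pairs required (default 50).
#' @param age_grid Ages (months) at which the curves are returned; default
#'   a monthly grid over the observed range.
#' @param max_cycles,tol Backfitting control.
#' @return An object of class \code{lms_reference}: \code{age_grid},
#'   \code{L}, \code{M}, \code{S} vectors plus the fitting configuration.
#' @export
fit_lms <- function(d_score, age_months, df = c(L = 3, M = 5, S = 3),
                    age_power = 0.5, offset = 1, L_fixed = NULL,
                    min_obs = 50, age_grid = NULL, max_cycles = 50,
                    tol = 1e-7) {
  ok <- is.finite(d_score) & is.finite(age_months)
  d_score <- d_score[ok]; age_months <- age_months[ok]
  if (length(d_score) < min_obs)
    stop(sprintf("need at least %d score-age pairs (got %d)", min_obs,
                 length(d_score)))
  y <- d_score + offset
  if (any(y <= 0))
    stop("non-positive D-scores after offset; increase `offset`")
  t <- age_months^age_power
  if (is.null(age_grid))
    age_grid <- seq(floor(min(age_months)), ceiling(max(age_months)), by = 1)
  gaps <- diff(sort(unique(round(age_months))))
  if (length(gaps) > 0 && max(gaps) > diff(range(age_months)) / df[["M"]])
    warning("age coverage has a gap larger than the smoothing span; curves are extrapolated across it")

  smooth_c <- function(x, w, dfc) {
    if (length(unique(t)) < 4 || dfc <= 1) return(rep(weighted.mean(x, w), length(t)))
    fit <- smooth.spline(t, x, w = w, df = min(dfc, length(unique(t)) - 1))
    predict(fit, t)$y
  }

  mu <- smooth_c(y, rep(1, length(y)), df[["M"]])
  mu <- pmax(mu, 1e-3)
  sig <- rep(max(sd(y / mu - 1), 0.01), length(y))
  nu <- rep(if (is.null(L_fixed)) 1 else L_fixed, length(y))

  zfun <- function(y, mu, sig, nu) {
    z <- ifelse(abs(nu) < 1e-8, log(y / mu) / sig,
                ((y / mu)^nu - 1) / (nu * sig))
    z
  }
  loglik <- function(mu, sig, nu) {
    z <- zfun(y, mu, sig, nu)
    sum(nu * log(y / mu) - log(sig) - z^2 / 2)
  }

  ll <- loglik(mu, sig, nu)
  for (cyc in seq_len(max_cycles)) {
    # M curve: step in log(mu)
    z <- zfun(y, mu, sig, nu)
    u <- z / sig + nu * (z^2 - 1)
    info <- 1 / sig^2 + 2 * nu^2
    work <- log(mu) + u / info
    mu <- pmax(exp(smooth_c(work, info, df[["M"]])), 1e-3)
    # S curve: step in log(sigma)
    z <- zfun(y, mu, sig, nu)
    u <- z^2 - 1
    work <- log(sig) + u / 2
    sig <- pmin(pmax(exp(smooth_c(work, rep(2, length(y)), df[["S"]])),
                     1e-4), 2)
    # L curve
    if (is.null(L_fixed)) {
      z <- zfun(y, mu, sig, nu)
      w_ <- log(y / mu)
      u <- ifelse(abs(nu) < 1e-4,
                  w_ - w_^3 / (2 * sig^2),   # limit of the score as L -> 0
                  w_ - z * w_ / (nu * sig) - z^2 * w_ + z^2 / nu)
      info <- pmax(7 * sig^2 / 4, 1e-6)
      work <- nu + u / info
      nu <- pmin(pmax(smooth_c(work, info, df[["L"]]), -5), 5)
    }
    ll_new <- loglik(mu, sig, nu)
    if (!is.finite(ll_new)) stop("LMS likelihood diverged; check inputs")
    if (abs(ll_new - ll) < tol * (abs(ll) + 1)) { ll <- ll_new; break }
    ll <- ll_new
  }

  tg <- age_grid^age_power
  on_grid <- function(vals, dfc) {
    if (length(unique(t)) < 4) return(rep(mean(vals), length(tg)))
    predict(smooth.spline(t, vals, df = min(dfc, length(unique(t)) - 1)),
            tg)$y
  }
  M <- pmax(on_grid(mu, df[["M"]]), 1e-3)
  S <- pmin(pmax(on_grid(sig, df[["S"]]), 1e-4), 2)
  L <- if (is.null(L_fixed)) on_grid(nu, df[["L"]]) else rep(L_fixed, length(tg))
  structure(list(age_grid = age_grid, L = L, M = M, S = S,
                 offset = offset, age_power = age_power, df = df,
                 loglik = ll, n = length(y), cycles = cyc),
            class = "lms_reference")
}

#' Construct an LMS reference from explicit curves
#'
#' Useful for externally supplied or closed-form references. Curves are
#' recycled to the grid length and validated (\code{M > 0}, \code{S > 0},
#' increasing grid); a non-monotone median curve triggers a warning since
#' development should increase with age on average.
#'
#' @param age_grid Increasing ages in months.
#' @param L,M,S Curve values on the grid (scalars are recycled).
#' @param offset D-score offset used with the transform (default 0).
#' @return An \code{lms_reference}.
#' @export
lms_reference <- function(age_grid, L, M, S, offset = 0) {
  stopifnot(all(diff(age_grid) > 0))
  L <- rep_len(L, length(age_grid))
  M <- rep_len(M, length(age_grid))
  S <- rep_len(S, length(age_grid))
  if (any(M <= 0) || any(S <= 0)) stop("M and S must be positive")
  if (any(diff(M) < 0))
    warning("median curve is not non-decreasing over the age grid")
  structure(list(age_grid = age_grid, L = L, M = M, S = S,
                 offset = offset, age_power = NA_real_, df = NULL,
                 loglik = NA_real_, n = 0L, cycles = 0L),
            class = "lms_reference")
}

#' @export
print.lms_reference <- function(x, ...) {
  cat(sprintf(
    "<lms_reference> ages %g-%g months (%d grid points), fitted on %d scores\n",
    min(x$age_grid), max(x$age_grid), length(x$age_grid), x$n))
  cat(sprintf("  M range %.1f-%.1f, S range %.3f-%.3f, L range %.2f-%.2f (offset %g)\n",
              min(x$M), max(x$M), min(x$S), max(x$S), min(x$L), max(x$L),
              x$offset))
  invisible(x)
}

# Interpolate the L, M, S curves at arbitrary ages within support.
lms_at <- function(ref, age_months) {
  rng <- range(ref$age_grid)
  if (any(age_months < rng[1] - 1e-9 | age_months > rng[2] + 1e-9))
    stop(sprintf("age outside the reference support [%g, %g] months",
                 rng[1], rng[2]))
  list(L = approx(ref$age_grid, ref$L, age_months, rule = 2)$y,
       M = approx(ref$age_grid, ref$M, age_months, rule = 2)$y,
       S = approx(ref$age_grid, ref$S, age_months, rule = 2)$y)
}

#' D-score-for-age z-score (DAZ)
#'
#' Transforms a D-score to a z-score under the age-conditional LMS
#' reference: \eqn{z = ((y/M)^L - 1)/(L S)} for \eqn{L \ne 0} and
#' \eqn{z = \log(y/M)/S} for \eqn{L = 0}, where \eqn{y} is the D-score
#' plus the reference's fitting offset. Strictly increasing in the D-score
#' at fixed age.
#'
#' @param d_score D-scores.
#' @param age_months Ages in months (within the reference support).
#' @param ref An \code{\link{fit_lms}} reference.
#' @return Numeric z-scores.
#' @export
daz <- function(d_score, age_months, ref) {
  stopifnot(inherits(ref, "lms_reference"))
  p <- lms_at(ref, age_months)
  y <- d_score + ref$offset
  if (any(y <= 0, na.rm = TRUE))
    stop("non-positive D-score after offset: Box-Cox transform undefined")
  ifelse(abs(p$L) < 1e-8, log(y / p$M) / p$S,
         ((y / p$M)^p$L - 1) / (p$L * p$S))
}

#' Inverse DAZ transform
#'
#' Maps a z-score back to the D-score at a given age; exact inverse of
#' \code{\link{daz}} (round trips to numerical precision).
#'
#' @param z z-scores.
#' @param age_months Ages in months.
#' @param ref An \code{\link{fit_lms}} reference.
#' @return D-scores.
#' @export
daz_inverse <- function(z, age_months, ref) {
  stopifnot(inherits(ref, "lms_reference"))
  p <- lms_at(ref, age_months)
  y <- ifelse(abs(p$L) < 1e-8, p$M * exp(p$S * z),
              p$M * (1 + p$L * p$S * z)^(1 / p$L))
  y - ref$offset
}

#' Write an LMS reference to JSON
#' @param ref An \code{lms_reference}.
#' @param path Output path.
#' @export
write_reference <- function(ref, path) {
  jsonlite::write_json(unclass(ref)[c("age_grid", "L", "M", "S", "offset",
                                      "age_power", "df", "n")],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an LMS reference written by \code{\link{write_reference}}
#' @param path JSON path.
#' @return An \code{lms_reference}.
#' @export
read_reference <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(j, class = "lms_reference")
}
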
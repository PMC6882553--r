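#' Classify a correlation by conventional strength bands
#'
#' Bands on |r|, closed on the left: below-low [0, 0.20), low
#' [0.20, 0.40), moderate [0.40, 0.60), strong [0.60, 0.80), very strong
#' [0.80, 1].
#'
#' @param r Correlations in [-1, 1] (absolute value is classified).
#' @param bounds Lower bounds of the four named bands.
#' @return Factor with levels below-low, low, moderate, strong,
#'   very strong.
#' @export
classify_r <- function(r, bounds = c(0.20, 0.40, 0.60, 0.80)) {
  stopifnot(all(abs(r) <= 1 + 1e-12, na.rm = TRUE))
  labs <- c("below-low", "low", "moderate", "strong", "very strong")
  cut(abs(r), breaks = c(0, bounds, 1 + 1e-12), labels = labs,
      right = FALSE, include.lowest = TRUE)
}

#' Discriminant validity: DAZ differences across known risk factors
#'
#' Per cohort-round, compares mean DAZ across groups defined by three
#' established predictors of early development: low birth weight
#' (< 2.5 kg) and stunting (height-for-age z < -2) with two-sample
#' t-tests (Welch by default), and maternal education (four ordered
#' categories) with a one-way ANOVA F-test. Categories with fewer than
#' \code{min_n} observations are excluded from the tests and marked in the
#' cell table.
#'
#' @param daz_df Data frame with \code{child_id, cohort, round, daz}.
#' @param covariates Data frame with \code{child_id} and any of
#'   \code{birth_weight_kg}, \code{haz}, \code{mat_edu} (levels none /
#'   primary / secondary / above).
#' @param min_n Minimum group size retained in a test, default 10.
#' @param alpha Significance level recorded in the output, default 0.05.
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return List of class \code{dscale_discriminant} with \code{cells}
#'   (mean (SD) n per cohort-round-factor-level, exclusion marks) and
#'   \code{tests} (statistic, p, significance per cohort-round-factor;
#'   factors without data are marked \code{"no data"}).
#' @export
discriminant_tests <- function(daz_df, covariates, min_n = 10,
                               alpha = 0.05, var_equal = FALSE) {
  d <- merge(daz_df, covariates, by = "child_id")
  edu_levels <- c("none", "primary", "secondary", "above")
  factors <- list(
    low_birth_weight = function(x)
      factor(ifelse(x$birth_weight_kg < 2.5, "low", "normal"),
             levels = c("low", "normal")),
    stunting = function(x)
      factor(ifelse(x$haz < -2, "stunted", "non-stunted"),
             levels = c("stunted", "non-stunted")),
    maternal_education = function(x) factor(x$mat_edu, levels = edu_levels))
  cells <- list(); tests <- list()
  for (cr in split(d, list(d$cohort, d$round), drop = TRUE)) {
    for (fname in names(factors)) {
      src <- switch(fname, low_birth_weight = "birth_weight_kg",
                    stunting = "haz", maternal_education = "mat_edu")
      if (is.null(cr[[src]]) || all(is.na(cr[[src]]))) {
        tests[[length(tests) + 1]] <- data.frame(
          cohort = cr$cohort[1], round = cr$round[1], factor = fname,
          statistic = NA_real_, df1 = NA_real_, df2 = NA_real_,
          p = NA_real_, significant = NA, note = "no data",
          stringsAsFactors = FALSE)
        next
      }
      g <- factors[[fname]](cr)
      ok <- !is.na(g) & !is.na(cr$daz)
      tab <- table(g[ok])
      lev <- names(tab)
      cell <- data.frame(
        cohort = cr$cohort[1], round = cr$round[1], factor = fname,
        level = lev,
        mean = as.numeric(tapply(cr$daz[ok], g[ok], mean)[lev]),
        sd = as.numeric(tapply(cr$daz[ok], g[ok], sd)[lev]),
        n = as.integer(tab[lev]),
        excluded = as.integer(tab[lev]) < min_n,
        stringsAsFactors = FALSE)
      cells[[length(cells) + 1]] <- cell
      keep_lev <- lev[tab[lev] >= min_n]
      sel <- ok & g %in% keep_lev
      res <- data.frame(cohort = cr$cohort[1], round = cr$round[1],
                        factor = fname, statistic = NA_real_,
                        df1 = NA_real_, df2 = NA_real_, p = NA_real_,
                        significant = NA, note = NA_character_,
                        stringsAsFactors = FALSE)
      if (length(keep_lev) < 2) {
        res$note <- "fewer than 2 groups with >= min_n observations"
      } else if (fname == "maternal_education") {
        fitaov <- aov(daz ~ droplevels(g[sel]), data = data.frame(
          daz = cr$daz[sel]))
        an <- anova(fitaov)
        res$statistic <- an[["F value"]][1]
        res$df1 <- an$Df[1]; res$df2 <- an$Df[2]
        res$p <- an[["Pr(>F)"]][1]
      } else {
        tt <- t.test(cr$daz[sel] ~ droplevels(g[sel]),
                     var.equal = var_equal)
        res$statistic <- unname(tt$statistic)
        res$df2 <- unname(tt$parameter)
        res$p <- tt$p.value
      }
      res$significant <- !is.na(res$p) & res$p < alpha
      tests[[length(tests) + 1]] <- res
    }
  }
  structure(list(cells = do.call(rbind, cells),
                 tests = do.call(rbind, tests), min_n = min_n,
                 alpha = alpha),
            class = "dscale_discriminant")
}

#' @export
print.dscale_discriminant <- function(x, ...) {
  tt <- x$tests[!is.na(x$tests$p), ]
  cat(sprintf(
    "<dscale_discriminant> %d cohort-round-factor tests (%d significant at p < %g), %d excluded cells\n",
    nrow(x$tests), sum(tt$significant), x$alpha,
    sum(x$cells$excluded)))
  invisible(x)
}

#' Age-adjusted z-scores by internal standardisation
#'
#' Rank-based inverse-normal transform within sliding age windows: for
#' each observation, the scores of all children within half a window width
#' in age form the reference sample; the observation's z-score is
#' \code{qnorm((rank - 3/8) / (n + 1/4))} (Blom offset). Windows with too
#' few observations are widened (with a warning). The transform is
#' invariant to any monotone rescoring of the instrument.
#'
#' @param score Raw instrument scores.
#' @param age_months Ages, same length.
#' @param window Window width in months, default 3.
#' @param min_n Minimum reference-sample size per window, default 20.
#' @return Numeric z-scores (mean ~ 0, SD ~ 1 within windows).
#' @export
internal_standardize <- function(score, age_months, window = 3,
                                 min_n = 20) {
  ok <- !is.na(score) & !is.na(age_months)
  if (sd(score[ok]) == 0)
    stop("scores are constant: ranks are degenerate, cannot standardise")
  z <- rep(NA_real_, length(score))
  widened <- FALSE
  idx <- which(ok)
  ages <- age_months[idx]
  scs <- score[idx]
  span <- diff(range(ages))
  for (j in seq_along(idx)) {
    w <- window
    repeat {
      sel <- abs(ages - ages[j]) <= w / 2
      if (sum(sel) >= min(min_n, length(idx)) || w > 2 * span + window)
        break
      w <- w * 1.5
      widened <- TRUE
    }
    s <- scs[sel]
    pos <- match(j, which(sel))
    ri <- rank(s, ties.method = "average")[pos]
    z[idx[j]] <- qnorm((ri - 3 / 8) / (length(s) + 1 / 4))
  }
  if (widened)
    warning("some age windows were widened to reach the minimum sample size")
  z
}

#' Concurrent validity: Pearson correlation of DAZ with instrument scores
#'
#' @param daz_df Data frame \code{child_id, cohort, round, daz}.
#' @param instrument_scores Data frame \code{child_id, round, instrument,
#'   score} of age-standardised instrument scores (external norms or
#'   \code{\link{internal_standardize}}).
#' @param usage Optional data frame \code{instrument, pct_items} (share of
#'   the instrument's administered items used in the D-score), merged into
#'   the output.
#' @return Data frame \code{cohort, round, instrument, r, n, note}; cells
#'   with fewer than 3 matched children get \code{NA} and a note.
#' @export
concurrent_corr <- function(daz_df, instrument_scores, usage = NULL) {
  d <- merge(daz_df, instrument_scores, by = c("child_id", "round"))
  if (nrow(d) == 0)
    return(data.frame(cohort = character(), round = character(),
                      instrument = character(), r = numeric(),
                      n = integer(), note = character(),
                      class = classify_r(numeric()),
                      stringsAsFactors = FALSE))
  out <- lapply(split(d, list(d$cohort, d$round, d$instrument),
                      drop = TRUE), function(g) {
    ok <- complete.cases(g$daz, g$score)
    data.frame(cohort = g$cohort[1], round = g$round[1],
               instrument = g$instrument[1],
               r = if (sum(ok) >= 3 && sd(g$daz[ok]) > 0 &&
                       sd(g$score[ok]) > 0)
                 cor(g$daz[ok], g$score[ok]) else NA_real_,
               n = sum(ok),
               note = if (sum(ok) < 3) "fewer than 3 matched children"
               else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if (!is.null(usage)) out <- merge(out, usage, by = "instrument",
                                    all.x = TRUE, sort = FALSE)
  out$class <- classify_r(out$r)
  out
}

#' Predictive validity: correlation of early DAZ with later outcomes
#'
#' Pairs each early-childhood (Time 1) DAZ record with later (Time 2)
#' outcome scores collected at least \code{min_gap_years} later, groups
#' Time 1 records into 12-month age bins, splits Time 2 into middle
#' childhood (> 4-9 years) and adolescence (> 9-18 years), and reports the
#' Pearson correlation per cohort, age bin, outcome and period. Bins with
#' fewer than \code{min_n} pairs are suppressed (r set to \code{NA},
#' marked). A child assessed in several rounds contributes once per bin.
#'
#' @param daz_df Data frame \code{child_id, cohort, round, age_months,
#'   daz}.
#' @param outcomes Data frame \code{child_id, age_years, outcome_name,
#'   score}.
#' @param min_gap_years Minimum years between Time 1 and Time 2, default 2.
#' @param min_n Minimum pairs per bin, default 10.
#' @param bin_months Width of the Time 1 age bins, default 12.
#' @return Data frame \code{cohort, age_bin, outcome_name, period, r, n,
#'   suppressed}.
#' @export
predictive_corr <- function(daz_df, outcomes, min_gap_years = 2,
                            min_n = 10, bin_months = 12) {
  d <- merge(daz_df, outcomes, by = "child_id")
  d <- d[d$age_years - d$age_months / 12 >= min_gap_years, , drop = FALSE]
  if (nrow(d) == 0)
    return(data.frame(cohort = character(), age_bin = character(),
                      outcome_name = character(), period = character(),
                      r = numeric(), n = integer(), suppressed = logical(),
                      stringsAsFactors = FALSE))
  lo <- floor(d$age_months / bin_months) * bin_months
  d$age_bin <- sprintf("%d-%d mo", lo, lo + bin_months - 1)
  d$period <- ifelse(d$age_years > 9, "adolescence", "middle childhood")
  d <- d[d$age_years > 4 & d$age_years <= 18, , drop = FALSE]
  out <- lapply(split(d, list(d$cohort, d$age_bin, d$outcome_name,
                              d$period), drop = TRUE), function(g) {
    ok <- complete.cases(g$daz, g$score)
    n <- sum(ok)
    data.frame(cohort = g$cohort[1], age_bin = g$age_bin[1],
               outcome_name = g$outcome_name[1], period = g$period[1],
               r = if (n >= min_n) cor(g$daz[ok], g$score[ok]) else NA_real_,
               n = n, suppressed = n < min_n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$cohort, out$age_bin, out$outcome_name), ]
}

#' Correlation of D-scores from an item subset with the full model
#'
#' Emulates administering a shorter instrument: every child-round is
#' scored twice, once with the full retained item pool and once with only
#' the responses to the given subset, and the two D-score vectors are
#' correlated. Child-rounds left without any subset item are excluded from
#' the correlation and counted.
#'
#' @param rm A \code{dscale_matrix}.
#' @param model A \code{dscale_model}.
#' @param subset Item codes (must be retained model items).
#' @param prior Prior policy passed to \code{\link{score_children}}.
#' @return List with \code{r}, \code{n_used}, \code{n_excluded},
#'   \code{mean_abs_diff}, \code{sem_ratio} (mean subset sem / full sem)
#'   and the per-child \code{scores} data frame.
#' @export
item_subset_sim <- function(rm, model, subset, prior = "auto") {
  bad <- setdiff(subset, model$retained)
  if (length(bad) > 0)
    stop("subset contains items outside the retained model: ",
         paste(head(bad, 5), collapse = ", "))
  full <- score_children(rm, model, prior = prior)
  rm_sub <- subset_items(rm, subset)
  sub <- score_children(rm_sub, model, prior = prior)
  use <- sub$n_items_used > 0
  scores <- data.frame(rm$meta,
                       d_full = full$d_score, sem_full = full$sem,
                       d_subset = sub$d_score, sem_subset = sub$sem,
                       n_items_subset = sub$n_items_used,
                       stringsAsFactors = FALSE)
  list(r = cor(full$d_score[use], sub$d_score[use]),
       n_used = sum(use), n_excluded = sum(!use),
       mean_abs_diff = mean(abs(full$d_score[use] - sub$d_score[use])),
       sem_ratio = mean(sub$sem[use]) / mean(full$sem[use]),
       scores = scores)
}
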
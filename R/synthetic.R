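#' Median developmental trajectory used by the synthetic generator
#'
#' A monotone median D-score curve, \code{coef * age^power}. With the
#' defaults the median rises from about 11 D at 1 month to about 76 D at
#' 48 months, placing the head-lift milestone (20 D) near 3 months and
#' stable sitting (40 D) near 13 months.
#'
#' @param age_months Ages in months.
#' @param coef,power Curve parameters (defaults 11 and 0.5).
#' @return Median D-scores.
#' @export
d_median_curve <- function(age_months, coef = 11, power = 0.5) {
  coef * age_months^power
}

#' Multi-cohort synthetic study design
#'
#' Describes instruments (item counts, difficulty ranges, native scoring
#' schemes), cohorts with measurement rounds (sample size, age
#' distribution, instrument per round), cross-instrument equate groups
#' sharing a true difficulty, covariate effects and the latent-outcome
#' link. The default emulates a miniature multi-country study: 5 cohorts,
#' 4 instruments of 40 items spanning staggered difficulty ranges, 6
#' equate groups (two of which are the anchor milestones), 500 children
#' per cohort, 1-3 rounds per cohort, and a Time 2 outcome per cohort.
#'
#' @param n_per_cohort Children per cohort, default 500.
#' @param rho Target correlation between the standardised latent ability
#'   and the Time 2 outcome, default 0.3.
#' @param sd_individual SD of stable individual ability effects in D
#'   units, default 5.
#' @param covariate_effects DAZ-unit shifts for low birth weight,
#'   stunting, and each maternal-education step.
#' @param a_true True scale slope in D units per logit, default 2 (a 10 D
#'   gap then moves the pass probability from about 8 to about 92 percent).
#' @return A list of class \code{cohort_design}.
#' @export
cohort_design <- function(n_per_cohort = 500, rho = 0.3,
                          sd_individual = 5,
                          covariate_effects = c(lbw = -0.4,
                                                stunting = -0.3,
                                                edu_step = 0.15),
                          a_true = 2) {
  stopifnot(abs(rho) < 1, a_true > 0, sd_individual > 0)
  instruments <- list(
    inst_a = list(n_items = 40, range = c(8, 40), scoring = "notyet10"),
    inst_b = list(n_items = 40, range = c(24, 54), scoring = "binary"),
    inst_c = list(n_items = 40, range = c(40, 70), scoring = "pass2"),
    inst_d = list(n_items = 40, range = c(58, 82), scoring = "binary"))
  # group difficulties sit inside the informative window of both member
  # instruments given the ages at which the cohorts administer them
  equate <- list(
    eq_headlift = list(delta = 20, instruments = c("inst_a", "inst_b"),
                       domain = "gross motor", anchor = 20),
    eq_stack = list(delta = 34, instruments = c("inst_a", "inst_b"),
                    domain = "fine motor", anchor = NA),
    eq_sit = list(delta = 40, instruments = c("inst_b", "inst_c"),
                  domain = "gross motor", anchor = 40),
    eq_words = list(delta = 50, instruments = c("inst_b", "inst_c"),
                    domain = "expressive language", anchor = NA),
    eq_tower = list(delta = 62, instruments = c("inst_c", "inst_d"),
                    domain = "fine motor", anchor = NA),
    eq_point = list(delta = 66, instruments = c("inst_c", "inst_d"),
                    domain = "receptive language", anchor = NA))
  cohorts <- list(
    bd = list(rounds = list(list(mean_age = 18, sd_age = 2,
                                 instrument = "inst_b")),
              outcome = list(age_years = 6, name = "iq")),
    br = list(rounds = list(
      list(mean_age = 3, sd_age = 1, instrument = "inst_a"),
      list(mean_age = 12, sd_age = 1.5, instrument = "inst_b"),
      list(mean_age = 24, sd_age = 2, instrument = "inst_c")),
      outcome = list(age_years = 18, name = "iq")),
    et = list(rounds = list(
      list(mean_age = 12, sd_age = 1.5, instrument = "inst_b"),
      list(mean_age = 30, sd_age = 2, instrument = "inst_c"),
      list(mean_age = 36, sd_age = 2, instrument = "inst_d")),
      outcome = list(age_years = 10, name = "vocabulary")),
    nl = list(rounds = list(
      list(mean_age = 2, sd_age = 0.5, instrument = "inst_a"),
      list(mean_age = 9, sd_age = 1, instrument = "inst_a"),
      list(mean_age = 18, sd_age = 2, instrument = "inst_c")),
      outcome = list(age_years = 5.5, name = "iq")),
    za = list(rounds = list(
      list(mean_age = 6, sd_age = 1, instrument = "inst_a"),
      list(mean_age = 9, sd_age = 1, instrument = "inst_b"),
      list(mean_age = 48, sd_age = 2, instrument = "inst_d")),
      outcome = list(age_years = 7, name = "vocabulary")))
  structure(list(instruments = instruments, equate = equate,
                 cohorts = cohorts, n_per_cohort = n_per_cohort,
                 rho = rho, sd_individual = sd_individual,
                 covariate_effects = covariate_effects, a_true = a_true,
                 median = list(coef = 11, power = 0.5)),
            class = "cohort_design")
}

# Build the item bank and true D-unit difficulties implied by a design.
design_bank <- function(design) {
  domains <- DSCALE_DOMAINS
  rows <- list()
  delta <- numeric(0)
  for (ins in names(design$instruments)) {
    sp <- design$instruments[[ins]]
    codes <- sprintf("%s_%02d", ins, seq_len(sp$n_items))
    d <- seq(sp$range[1], sp$range[2], length.out = sp$n_items)
    rows[[ins]] <- data.frame(
      item_code = codes, instrument = ins,
      domain = domains[(seq_len(sp$n_items) - 1) %% 5 + 1],
      equate_group = NA_character_, active = FALSE,
      anchor_value = NA_real_, recode_rule = sp$scoring,
      stringsAsFactors = FALSE)
    delta[codes] <- d
  }
  bank <- do.call(rbind, rows)
  anchors <- anchor_spec()
  for (g in names(design$equate)) {
    eq <- design$equate[[g]]
    for (ins in eq$instruments) {
      codes <- bank$item_code[bank$instrument == ins &
                                is.na(bank$equate_group)]
      slot <- codes[which.min(abs(delta[codes] - eq$delta))]
      code <- slot
      if (!is.na(eq$anchor) && ins == eq$instruments[1])
        code <- if (eq$anchor == anchors$value_lo) anchors$item_lo
        else anchors$item_hi
      i <- match(slot, bank$item_code)
      bank$item_code[i] <- code
      bank$equate_group[i] <- g
      bank$active[i] <- TRUE
      bank$domain[i] <- eq$domain
      bank$anchor_value[i] <- if (!is.na(eq$anchor) &&
                                    ins == eq$instruments[1]) eq$anchor
      else NA_real_
      names(delta)[match(slot, names(delta))] <- code
      delta[code] <- eq$delta
    }
  }
  rownames(bank) <- NULL
  list(bank = item_bank(bank), delta_d = delta)
}

# Raw-score layer: re-express a binary pass/fail in the instrument's
# native scheme (passes split over the scheme's passing levels).
rawify <- function(x, scheme) {
  n <- length(x)
  switch(scheme,
         binary = x,
         notyet10 = ifelse(x == 1, sample(c(5, 10), n, replace = TRUE), 0),
         pass2 = ifelse(x == 1, sample(c(1, 2), n, replace = TRUE), 0),
         stop("unknown scoring scheme: ", scheme))
}

#' Generate a synthetic multi-cohort item-response dataset with known truth
#'
#' Draws, per child, a stable individual ability effect (normal, SD
#' \code{sd_individual} D units) and covariates (birth weight,
#' height-for-age, maternal education) whose effects shift ability by the
#' configured amounts; per round, an age around the round's target and the
#' latent ability \eqn{\theta =} median-curve(age) + individual effect +
#' covariate shifts; responses to every item of the round's instrument as
#' Bernoulli(logistic((\eqn{\theta} - \eqn{\delta}) / a)). Each child only
#' sees their cohort-round's instrument, reproducing planned missingness.
#' Time 2 outcomes are the cohort-standardised latent ability at the last
#' round mixed with noise to hit the target correlation \code{rho}.
#'
#' @param design A \code{\link{cohort_design}}.
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return List with \code{bank} (\code{\link{item_bank}}),
#'   \code{responses} (long data frame with instrument-native raw scores),
#'   \code{covariates}, \code{outcomes}, and \code{truth} (true
#'   difficulties in D units, true slope, per-child-round abilities,
#'   median-curve parameters, covariate assignments, design and seed).
#' @export
generate_cohorts <- function(design = cohort_design(), seed = 1) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(seed)
  db <- design_bank(design)
  bank <- db$bank
  delta_d <- db$delta_d
  a <- design$a_true
  eff <- design$covariate_effects * design$sd_individual  # DAZ -> D units

  responses <- list(); covariates <- list(); outcomes <- list()
  abilities <- list()
  edu_levels <- c("none", "primary", "secondary", "above")
  for (co in names(design$cohorts)) {
    cd <- design$cohorts[[co]]
    n <- design$n_per_cohort
    ids <- sprintf("%s_%04d", co, seq_len(n))
    u <- rnorm(n, 0, design$sd_individual)
    bw <- rnorm(n, 3.2, 0.5)
    haz <- rnorm(n, -0.6, 1.1)
    edu <- sample(edu_levels, n, replace = TRUE,
                  prob = c(0.15, 0.35, 0.35, 0.15))
    shift <- eff[["lbw"]] * (bw < 2.5) + eff[["stunting"]] * (haz < -2) +
      eff[["edu_step"]] * (match(edu, edu_levels) - 1)
    # centre the shifts so the cohort's median child sits on the median
    # curve; group gaps are unaffected
    shift <- shift - mean(shift)
    covariates[[co]] <- data.frame(child_id = ids, birth_weight_kg = bw,
                                   haz = haz, mat_edu = edu,
                                   stringsAsFactors = FALSE)
    theta_last <- NULL
    for (r in seq_along(cd$rounds)) {
      rd <- cd$rounds[[r]]
      age <- pmax(rnorm(n, rd$mean_age, rd$sd_age), 0.25)
      theta <- d_median_curve(age, design$median$coef,
                              design$median$power) + u + shift
      items <- bank$item_code[bank$instrument == rd$instrument]
      scheme <- design$instruments[[rd$instrument]]$scoring
      p <- plogis(outer(theta, delta_d[items], "-") / a)
      x <- matrix(rbinom(length(p), 1, p), nrow(p), ncol(p))
      responses[[paste(co, r)]] <- data.frame(
        child_id = rep(ids, times = length(items)),
        cohort = co, round = r,
        age_months = rep(age, times = length(items)),
        item_code = rep(items, each = n),
        raw_score = rawify(as.vector(x), scheme),
        stringsAsFactors = FALSE)
      abilities[[paste(co, r)]] <- data.frame(
        child_id = ids, cohort = co, round = r, age_months = age,
        theta_d = theta, stringsAsFactors = FALSE)
      theta_last <- theta
    }
    z <- as.vector(scale(theta_last))
    outcomes[[co]] <- data.frame(
      child_id = ids, age_years = cd$outcome$age_years,
      outcome_name = cd$outcome$name,
      score = design$rho * z + sqrt(1 - design$rho^2) * rnorm(n),
      stringsAsFactors = FALSE)
  }
  list(bank = bank,
       responses = do.call(rbind, c(responses, make.row.names = FALSE)),
       covariates = do.call(rbind, c(covariates, make.row.names = FALSE)),
       outcomes = do.call(rbind, c(outcomes, make.row.names = FALSE)),
       truth = list(delta_d = delta_d, a = a,
                    abilities = do.call(rbind, c(abilities,
                                                 make.row.names = FALSE)),
                    median = design$median,
                    covariate_effects_d = eff, design = design,
                    seed = seed))
}

#' Inject differential item functioning into a synthetic dataset
#'
#' Regenerates one group's responses to one item with the item's true
#' difficulty shifted, so the item behaves differently for that group at
#' equal ability. A shift of zero leaves the response distribution
#' unchanged; the same shift applied to every group is a pure difficulty
#' change, not DIF.
#'
#' @param sim A \code{\link{generate_cohorts}} result.
#' @param item Item code present in the bank.
#' @param group Cohort name whose responses are regenerated.
#' @param shift Difficulty shift in logits.
#' @param seed Seed for the regeneration.
#' @return The modified simulation object.
#' @export
inject_dif <- function(sim, item, group, shift, seed = 1) {
  stopifnot(item %in% sim$bank$item_code)
  sel <- sim$responses$item_code == item & sim$responses$cohort == group
  if (!any(sel)) stop(sprintf("item '%s' not observed in group '%s'",
                              item, group))
  set.seed(seed)
  ab <- sim$truth$abilities
  key <- paste(sim$responses$child_id[sel], sim$responses$round[sel])
  theta <- ab$theta_d[match(key, paste(ab$child_id, ab$round))]
  delta <- sim$truth$delta_d[[item]] + shift * sim$truth$a
  p <- plogis((theta - delta) / sim$truth$a)
  scheme <- sim$bank$recode_rule[match(item, sim$bank$item_code)]
  scheme <- c(binary = "binary", notyet10 = "notyet10",
              pass2 = "pass2")[scheme]
  sim$responses$raw_score[sel] <- rawify(rbinom(length(p), 1, p), scheme)
  sim
}

#' Write a simulated dataset to CSV/JSON files
#'
#' Writes \code{bank.csv}, \code{responses.csv}, \code{covariates.csv},
#' \code{outcomes.csv} and \code{truth.json} into a directory.
#'
#' @param sim A \code{\link{generate_cohorts}} result.
#' @param dir Output directory (created if absent).
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(sim$bank, file.path(dir, "bank.csv"), row.names = FALSE)
  write.csv(sim$responses, file.path(dir, "responses.csv"),
            row.names = FALSE)
  write.csv(sim$covariates, file.path(dir, "covariates.csv"),
            row.names = FALSE)
  write.csv(sim$outcomes, file.path(dir, "outcomes.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(delta_d = as.list(sim$truth$delta_d), a = sim$truth$a,
         median = sim$truth$median, seed = sim$truth$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
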
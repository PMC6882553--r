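# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# Default-design fit at n = 500 per cohort, used by the end-to-end checks.
acceptance_fit <- function() {
  if (is.null(.fixture_cache$acc)) {
    sim <- generate_cohorts(cohort_design(), seed = 42)
    rm <- assemble_matrix(sim$responses, sim$bank)
    model <- suppressWarnings(build_model(rm, sim$bank))
    .fixture_cache$acc <- list(sim = sim, rm = rm, model = model)
  }
  .fixture_cache$acc
}

# A moderately sized end-to-end fit used by several test files.
fitted_sim <- function() {
  if (is.null(.fixture_cache$fit)) {
    sim <- generate_cohorts(cohort_design(n_per_cohort = 200), seed = 11)
    rm <- assemble_matrix(sim$responses, sim$bank)
    model <- suppressWarnings(build_model(rm, sim$bank))
    scores <- score_children(rm, model)
    .fixture_cache$fit <- list(sim = sim, rm = rm, model = model,
                               scores = scores)
  }
  .fixture_cache$fit
}

# Build a dscale_matrix directly from a dense score matrix (rows =
# child-rounds), bypassing the long-format path.
matrix_fixture <- function(scores, cohort = "c1", age = 12) {
  n <- nrow(scores)
  structure(list(
    scores = scores,
    meta = data.frame(child_id = sprintf("ch%03d", seq_len(n)),
                      cohort = rep_len(cohort, n),
                      round = 1L, age_months = rep_len(age, n),
                      stringsAsFactors = FALSE),
    log = list(n_child_rounds = n, n_items = ncol(scores),
               n_observed = sum(!is.na(scores)), n_children = n)),
    class = "dscale_matrix")
}

# Complete Rasch data simulated at given true difficulties/abilities.
rasch_matrix <- function(theta, delta, seed = 1) {
  set.seed(seed)
  p <- plogis(outer(theta, delta, "-"))
  x <- matrix(rbinom(length(p), 1, p), length(theta), length(delta),
              dimnames = list(NULL, names(delta)))
  x
}

# A minimal two-instrument bank for harmonisation tests.
small_bank <- function() {
  item_bank(data.frame(
    item_code = c("x1", "x2", "x3", "y1", "y2", "y3"),
    instrument = rep(c("instX", "instY"), each = 3),
    domain = rep(c("fine motor", "cognition", "gross motor"), 2),
    equate_group = c(NA, NA, "g1", NA, NA, "g1"),
    active = c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE),
    anchor_value = NA_real_,
    recode_rule = "binary",
    stringsAsFactors = FALSE))
}

long_records <- function(child_id, round, item_code, raw_score,
                         cohort = "c1", age_months = 12) {
  data.frame(child_id = child_id, cohort = cohort, round = round,
             age_months = age_months, item_code = item_code,
             raw_score = raw_score, stringsAsFactors = FALSE)
}
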
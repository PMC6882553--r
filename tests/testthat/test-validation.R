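test_that("correlation classes reproduce the printed boundaries", {
  expect_equal(as.character(classify_r(0.71)), "strong")
  expect_equal(as.character(classify_r(0.40)), "moderate")
  expect_equal(as.character(classify_r(0.19)), "below-low")
  expect_equal(as.character(classify_r(0.39)), "low")
  expect_false(as.character(classify_r(0.39)) ==
                 as.character(classify_r(0.40)))
  expect_equal(as.character(classify_r(c(0.20, 0.60, 0.80, 1))),
               c("low", "strong", "very strong", "very strong"))
  expect_equal(as.character(classify_r(-0.65)), "strong")  # on |r|
})

test_that("discriminant tests detect an injected group gap", {
  set.seed(101)
  n <- 800
  bw <- c(rep(2.0, n), rep(3.4, n))
  daz_df <- data.frame(child_id = sprintf("k%04d", 1:(2 * n)),
                       cohort = "c1", round = 1,
                       daz = rnorm(2 * n) + ifelse(bw < 2.5, -0.3, 0))
  cov <- data.frame(child_id = daz_df$child_id, birth_weight_kg = bw,
                    haz = 0, mat_edu = "primary")
  res <- discriminant_tests(daz_df, cov)
  tt <- res$tests[res$tests$factor == "low_birth_weight", ]
  expect_lt(tt$p, 0.05)
  expect_true(tt$significant)
  lows <- res$cells[res$cells$factor == "low_birth_weight" &
                      res$cells$level == "low", ]
  expect_equal(lows$n, n)
  expect_lt(lows$mean, 0)
})

test_that("categories below the minimum size are excluded and marked", {
  set.seed(102)
  edu <- c(rep("none", 9), rep("primary", 50), rep("secondary", 50))
  daz_df <- data.frame(child_id = sprintf("k%03d", seq_along(edu)),
                       cohort = "c1", round = 1, daz = rnorm(109))
  cov <- data.frame(child_id = daz_df$child_id, birth_weight_kg = 3.4,
                    haz = 0, mat_edu = edu)
  res <- discriminant_tests(daz_df, cov, min_n = 10)
  cells <- res$cells[res$cells$factor == "maternal_education", ]
  expect_true(cells$excluded[cells$level == "none"])
  expect_false(any(cells$excluded[cells$level %in%
                                    c("primary", "secondary")]))
  tt <- res$tests[res$tests$factor == "maternal_education", ]
  expect_equal(tt$df1, 1)  # two groups survive the cut
})

test_that("absent covariates are reported as missing sections", {
  daz_df <- data.frame(child_id = c("a", "b"), cohort = "c1", round = 1,
                       daz = c(0, 1))
  cov <- data.frame(child_id = c("a", "b"), birth_weight_kg = NA_real_,
                    haz = c(-1, 0), mat_edu = NA_character_)
  res <- discriminant_tests(daz_df, cov)
  tt <- res$tests
  expect_equal(tt$note[tt$factor == "low_birth_weight"], "no data")
  expect_equal(tt$note[tt$factor == "maternal_education"], "no data")
})

test_that("internal standardisation reproduces standard normal scores", {
  set.seed(103)
  n <- 1000
  score <- rnorm(n)
  z <- internal_standardize(score, age_months = rep(12, n),
                            window = 1000)
  expect_gt(cor(z, score), 0.99)
  expect_lt(abs(mean(z)), 0.01)
  expect_lt(abs(sd(z) - 1), 0.05)
})

test_that("internal standardisation is invariant to monotone rescoring", {
  set.seed(104)
  n <- 300
  age <- runif(n, 6, 30)
  score <- rnorm(n, age, 2)
  z1 <- internal_standardize(score, age)
  z2 <- internal_standardize(exp(score / 4), age)
  expect_equal(z1, z2)
})

test_that("degenerate constant scores are rejected", {
  expect_error(internal_standardize(rep(3, 50), runif(50, 0, 10)),
               "constant")
})

test_that("concurrent correlation recovers designed overlap", {
  set.seed(105)
  n <- 500
  latent <- rnorm(n)
  target <- 0.7
  daz_df <- data.frame(child_id = sprintf("k%03d", 1:n), cohort = "c1",
                       round = 1, daz = latent)
  inst <- data.frame(child_id = daz_df$child_id, round = 1,
                     instrument = "instX",
                     score = target * latent +
                       sqrt(1 - target^2) * rnorm(n))
  out <- concurrent_corr(daz_df, inst)
  expect_equal(out$r, target, tolerance = 0.05)
  expect_equal(out$n, n)

  self <- concurrent_corr(daz_df,
                          data.frame(child_id = daz_df$child_id,
                                     round = 1, instrument = "self",
                                     score = daz_df$daz))
  expect_equal(self$r, 1)
  expect_equal(as.character(self$class), "very strong")
})

test_that("unmatched children leave the correlation undefined but marked", {
  daz_df <- data.frame(child_id = c("a", "b"), cohort = "c1", round = 1,
                       daz = c(0, 1))
  inst <- data.frame(child_id = c("c", "d"), round = 1,
                     instrument = "instX", score = c(0, 1))
  out <- concurrent_corr(daz_df, inst)
  expect_equal(nrow(out), 0)

  one <- concurrent_corr(daz_df,
                         data.frame(child_id = "a", round = 1,
                                    instrument = "instX", score = 0.2))
  expect_true(is.na(one$r))
  expect_match(one$note, "fewer than 3")
})

test_that("predictive correlations follow the age-bin and gap rules", {
  set.seed(106)
  n <- 800
  latent <- rnorm(n)
  daz_df <- data.frame(child_id = sprintf("k%04d", 1:n), cohort = "c1",
                       round = 1, age_months = runif(n, 0, 24),
                       daz = latent)
  outcomes <- data.frame(child_id = daz_df$child_id, age_years = 7,
                         outcome_name = "iq",
                         score = 0.3 * latent + sqrt(1 - 0.09) * rnorm(n))
  out <- predictive_corr(daz_df, outcomes)
  expect_setequal(unique(out$age_bin), c("0-11 mo", "12-23 mo"))
  expect_true(all(out$period == "middle childhood"))
  pooled_r <- sum(out$r * out$n) / sum(out$n)
  expect_equal(pooled_r, 0.3, tolerance = 0.06)

  # a Time 2 round only 1 year later is excluded entirely
  soon <- outcomes
  soon$age_years <- daz_df$age_months / 12 + 1
  expect_equal(nrow(predictive_corr(daz_df, soon)), 0)
})

test_that("a child assessed in two rounds appears once per age bin", {
  daz_df <- data.frame(child_id = "kid", cohort = "c1", round = c(1, 2),
                       age_months = c(6, 18), daz = c(0.2, 0.4))
  filler <- data.frame(child_id = sprintf("f%02d", 1:12), cohort = "c1",
                       round = 1, age_months = rep(c(5, 17), 6),
                       daz = rnorm(12))
  outcomes <- data.frame(child_id = c("kid", filler$child_id),
                         age_years = 8, outcome_name = "iq",
                         score = rnorm(13))
  out <- predictive_corr(rbind(daz_df, filler), outcomes, min_n = 5)
  expect_equal(sort(unique(out$age_bin)), c("0-11 mo", "12-23 mo"))
  expect_equal(out$n[out$age_bin == "0-11 mo"], 7)
  expect_equal(out$n[out$age_bin == "12-23 mo"], 7)
})

test_that("scoring on an item subset tracks the full model", {
  fx <- fitted_sim()
  full <- item_subset_sim(fx$rm, fx$model, fx$model$retained,
                          prior = "flat")
  expect_equal(full$r, 1)
  expect_equal(full$n_excluded, 0)

  half <- fx$model$retained[seq(1, length(fx$model$retained), by = 2)]
  sub <- item_subset_sim(fx$rm, fx$model, half, prior = "flat")
  expect_gt(sub$r, 0.95)
  expect_gt(sub$sem_ratio, 1)

  single <- item_subset_sim(fx$rm, fx$model, fx$model$retained[1],
                            prior = "flat")
  expect_lt(single$r, sub$r)
  expect_gt(single$sem_ratio, sub$sem_ratio)

  expect_error(item_subset_sim(fx$rm, fx$model, "not_an_item"),
               "outside the retained model")
})
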
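test_that("recode rules map native scores to binary, with exceptions", {
  rules <- default_recode_rules(pass2_exceptions = "bat_06")
  expect_identical(recode(2, rules$pass2, "bat_01"), 1L)
  expect_identical(recode(1, rules$pass2, "bat_01"), 1L)
  expect_identical(recode(1, rules$pass2, "bat_06"), 0L)
  expect_identical(recode(2, rules$pass2, "bat_06"), 1L)
  expect_identical(recode(c(0, 5, 10), rules$notyet10, "asq_01"),
                   c(0L, 1L, 1L))
  expect_identical(recode(NA, rules$binary), NA_integer_)
  expect_error(recode(3, rules$pass2, "bat_01"), "raw score")
  expect_error(recode(7, rules$notyet10, "asq_01"), "'notyet10'")
})

test_that("recoding already-binary scores is idempotent across rules", {
  rules <- default_recode_rules()
  for (rule in rules[c("binary", "pass2")]) {
    x <- c(0L, 1L, NA_integer_, 1L, 0L)
    expect_identical(recode(x, rule, "item"), x)
    expect_identical(recode(recode(x, rule, "item"), rule, "item"),
                     recode(x, rule, "item"))
  }
})

test_that("item bank validation enforces structural invariants", {
  ok <- data.frame(item_code = c("a", "b"), instrument = c("i1", "i2"),
                   domain = "cognition", equate_group = "g",
                   active = TRUE, stringsAsFactors = FALSE)
  expect_s3_class(item_bank(ok), "dscale_bank")
  dup <- ok; dup$item_code <- c("a", "a")
  expect_error(item_bank(dup), "duplicated")
  bad_dom <- ok; bad_dom$domain <- "personal-social"
  expect_error(item_bank(bad_dom), "domain")
  solo <- ok[1, ]
  expect_error(item_bank(solo), "fewer than 2 members")
  mono <- ok; mono$instrument <- "i1"
  expect_error(item_bank(mono), "span 2 instruments")
  bad_anchor <- ok; bad_anchor$anchor_value <- c(25, NA)
  expect_error(item_bank(bad_anchor), "anchor_value")
})

test_that("assemble_matrix builds the child-round by item matrix", {
  bank <- small_bank()
  rec <- long_records(rep(c("c1", "c2"), each = 2), 1,
                      rep(c("x1", "x2"), 2), c(1, 0, 0, 1))
  rm <- assemble_matrix(rec, bank)
  expect_equal(dim(rm$scores), c(2, 2))
  expect_equal(rm$scores[1, ], c(x1 = 1L, x2 = 0L))
  expect_equal(rm$log$n_observed, 4)
  expect_equal(rm$log$n_children, 2)
})

test_that("never co-administered instruments yield block missingness", {
  bank <- small_bank()
  rec <- rbind(long_records("c1", 1, c("x1", "x2"), c(1, 0)),
               long_records("c2", 1, c("y1", "y2"), c(0, 1),
                            cohort = "c2"))
  rm <- assemble_matrix(rec, bank)
  expect_true(all(is.na(rm$scores[1, c("y1", "y2")])))
  expect_true(all(is.na(rm$scores[2, c("x1", "x2")])))
})

test_that("assemble_matrix rejects duplicates, unknown items, bad ages", {
  bank <- small_bank()
  dup <- long_records(c("c1", "c1"), 1, c("x1", "x1"), c(1, 1))
  expect_error(assemble_matrix(dup, bank), "duplicate")
  alien <- long_records("c1", 1, "zz", 1)
  expect_error(assemble_matrix(alien, bank), "not in bank")
  neg <- long_records("c1", 1, "x1", 1); neg$age_months <- -2
  expect_error(assemble_matrix(neg, bank), "age_months")
})

test_that("sparse-item filter removes by least populated category", {
  m <- cbind(rare = c(rep(1L, 9), rep(0L, 100)),
             boundary = c(rep(1L, 10), rep(0L, 10), rep(NA, 89)),
             empty = rep(NA_integer_, 109),
             common = rep(c(0L, 1L), len = 109))
  fs <- filter_sparse_items(matrix_fixture(m), min_count = 10)
  expect_setequal(fs$removed$item, c("rare", "empty"))
  expect_setequal(colnames(fs$matrix$scores), c("boundary", "common"))
})

test_that("raising min_count never revives a removed item", {
  set.seed(4)
  m <- matrix(rbinom(400, 1, runif(20, 0.02, 0.5)), 20, 20, byrow = TRUE,
              dimnames = list(NULL, paste0("i", 1:20)))
  kept <- lapply(c(1, 3, 5, 8), function(mc)
    colnames(filter_sparse_items(matrix_fixture(m), mc)$matrix$scores))
  for (i in seq_len(length(kept) - 1))
    expect_true(all(kept[[i + 1]] %in% kept[[i]]))
})

test_that("filtering is a fixed point on the surviving records", {
  set.seed(5)
  bank <- small_bank()
  rec <- long_records(rep(sprintf("c%02d", 1:30), each = 3), 1,
                      rep(c("x1", "x2", "x3"), 30),
                      rbinom(90, 1, rep(c(0.95, 0.5, 0.5), 30)))
  rm1 <- filter_sparse_items(assemble_matrix(rec, bank), 10)$matrix
  surviving <- rec[rec$item_code %in% colnames(rm1$scores), ]
  rm2 <- filter_sparse_items(assemble_matrix(surviving, bank), 10)$matrix
  expect_identical(rm1$scores, rm2$scores)
})

test_that("connectivity reflects co-observation and active equate links", {
  bank <- small_bank()
  rec <- rbind(long_records("c1", 1, c("x1", "x2"), c(1, 0)),
               long_records("c2", 1, c("y1", "y2"), c(0, 1),
                            cohort = "c2"))
  rm <- assemble_matrix(rec, bank)
  expect_warning(comps <- connectivity_check(rm, bank), "disconnected")
  expect_length(comps, 2)

  rec2 <- rbind(rec,
                long_records("c1", 1, "x3", 1),
                long_records("c2", 1, "y3", 0, cohort = "c2"))
  rm2 <- assemble_matrix(rec2, bank)
  comps2 <- connectivity_check(rm2, bank)  # g1 bridges the instruments
  expect_length(comps2, 1)
})

test_that("chained instruments form one component, matching union-find", {
  bank <- item_bank(data.frame(
    item_code = paste0("i", 1:6),
    instrument = rep(c("A", "B", "C"), each = 2),
    domain = "cognition",
    equate_group = c(NA, "ab", "ab", "bc", "bc", NA),
    active = TRUE, stringsAsFactors = FALSE))
  rec <- rbind(
    long_records("p1", 1, c("i1", "i2"), c(1, 0)),
    long_records("p2", 1, c("i3", "i4"), c(1, 0), cohort = "c2"),
    long_records("p3", 1, c("i5", "i6"), c(1, 0), cohort = "c3"))
  rm <- assemble_matrix(rec, bank)
  comps <- connectivity_check(rm, bank)
  edges <- list(c("i1", "i2"), c("i3", "i4"), c("i5", "i6"),
                c("i2", "i3"), c("i4", "i5"))
  expect_length(comps, length(oracle_components(paste0("i", 1:6), edges)))
  expect_setequal(comps[[1]], paste0("i", 1:6))
})
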
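test_that("pairwise counts tally discordant co-observations only", {
  m <- rbind(c(1L, 0L), c(1L, 0L), c(1L, 0L), c(0L, 1L),
             c(1L, 1L), c(0L, 0L))
  colnames(m) <- c("A", "B")
  n <- pairwise_counts(matrix_fixture(m))
  expect_equal(n["A", "B"], 3)
  expect_equal(n["B", "A"], 1)
  expect_equal(diag(n), c(A = 0, B = 0))
})

test_that("items never co-observed have zero counts", {
  m <- rbind(c(1L, NA), c(NA, 0L))
  colnames(m) <- c("A", "B")
  n <- pairwise_counts(matrix_fixture(m))
  expect_true(all(n == 0))
})

test_that("pairwise counts on a complete toy matrix match enumeration", {
  x <- rbind(c(1L, 0L, 0L), c(1L, 1L, 0L), c(0L, 1L, 1L), c(1L, 0L, 1L))
  colnames(x) <- c("p", "q", "r")
  expect_equal(pairwise_counts(matrix_fixture(x)),
               oracle_pairwise_counts(x))
})

test_that("two-item difficulties follow the closed-form pairwise MLE", {
  sym <- matrix(c(0, 5, 5, 0), 2, dimnames = list(c("A", "B"),
                                                  c("A", "B")))
  d <- estimate_difficulties(sym)
  expect_equal(as.numeric(d), c(0, 0), tolerance = 1e-9)

  asym <- matrix(c(0, 1, 9, 0), 2, dimnames = list(c("A", "B"),
                                                   c("A", "B")))
  d2 <- estimate_difficulties(asym)
  expect_equal(unname(d2["B"] - d2["A"]), log(9), tolerance = 1e-7)
})

test_that("cluster-constrained solution matches a grid-search oracle", {
  counts <- matrix(c(0, 2, 3,
                     4, 0, 6,
                     1, 2, 0), 3, byrow = TRUE,
                   dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  d <- estimate_difficulties(counts, clusters = c(A = "cl", B = "cl"))
  expect_identical(unname(d["A"]), unname(d["B"]))  # bitwise equality
  oracle <- oracle_cluster_grid(counts)
  expect_equal(unname(d["A"]), unname(oracle["cluster"]),
               tolerance = 2e-3)
  expect_equal(unname(d["C"]), unname(oracle["free"]), tolerance = 2e-3)
})

test_that("estimates are invariant to a shift of all abilities", {
  set.seed(21)
  delta <- setNames(seq(-2, 2, length.out = 6), paste0("i", 1:6))
  theta <- rnorm(300)
  u <- matrix(runif(300 * 6), 300, 6)
  x1 <- (u < plogis(outer(theta, delta, "-"))) + 0L
  x2 <- (u < plogis(outer(theta + 1.7, delta, "-"))) + 0L
  colnames(x1) <- colnames(x2) <- names(delta)
  d1 <- estimate_difficulties(pairwise_counts(matrix_fixture(x1)))
  d2 <- estimate_difficulties(pairwise_counts(matrix_fixture(x2)))
  # same uniform draws, shifted abilities: difficulty differences should
  # move only through the (different) realised response patterns
  expect_equal(cor(as.numeric(d1), as.numeric(d2)), 1, tolerance = 0.02)
  expect_equal(as.numeric(d1 - d1[1]), as.numeric(d2 - d2[1]),
               tolerance = 0.35)
})

test_that("pairwise estimates agree with brute-force conditional ML", {
  set.seed(31)
  delta <- setNames(seq(-1.5, 1.5, length.out = 8), paste0("i", 1:8))
  x <- rasch_matrix(rnorm(200, 0, 1.2), delta, seed = 31)
  pw <- estimate_difficulties(pairwise_counts(matrix_fixture(x)))
  cml <- oracle_cml(x)
  expect_lt(max(abs(pw - cml[names(pw)])), 0.15)
})

test_that("a disconnected comparison graph is rejected", {
  counts <- matrix(0, 4, 4, dimnames = list(paste0("i", 1:4),
                                            paste0("i", 1:4)))
  counts[1, 2] <- counts[2, 1] <- 5
  counts[3, 4] <- counts[4, 3] <- 5
  expect_error(estimate_difficulties(counts), "not strongly connected")
})

test_that("fit statistics are near 1 under the generating model", {
  set.seed(41)
  n <- 10000
  theta <- rep(0, n)
  x <- cbind(even = rbinom(n, 1, 0.5))  # ability equals difficulty
  rm <- matrix_fixture(x)
  fit <- infit_outfit(rm, c(even = 0), theta)
  expect_equal(fit$infit, 1, tolerance = 0.05)
  expect_equal(fit$outfit, 1, tolerance = 0.05)
})

test_that("a single response at P = 0.5 gives outfit exactly 1", {
  rm <- matrix_fixture(cbind(solo = 1L))
  fit <- infit_outfit(rm, c(solo = 0), theta = 0)
  expect_equal(fit$outfit, 1)
  expect_equal(fit$n_obs, 1)
})

test_that("over-discriminating items show infit below 1 under Rasch", {
  set.seed(42)
  n <- 4000
  theta <- rnorm(n)
  steep <- rbinom(n, 1, plogis(3 * theta))   # 2PL, slope 3
  rasch <- rbinom(n, 1, plogis(theta))
  rm <- matrix_fixture(cbind(steep = steep, rasch = rasch))
  fit <- infit_outfit(rm, c(steep = 0, rasch = 0), theta)
  expect_lt(fit$infit[fit$item == "steep"], 1)
  expect_lt(fit$infit[fit$item == "steep"],
            fit$infit[fit$item == "rasch"])
})

test_that("retention keeps active-equate members and sharp independents", {
  bank <- small_bank()  # x3, y3 in group g1
  fit <- data.frame(
    item = c("x1", "x2", "x3"),
    infit = c(0.95, 0.95, 1.40),
    outfit = c(0.99, 1.01, 1.40),
    n_obs = 100, stringsAsFactors = FALSE)
  ret <- retention_pass(fit, bank, active_groups = "g1")
  expect_true("x1" %in% ret$retained)    # both < 1
  expect_false("x2" %in% ret$retained)   # outfit 1.01
  expect_true("x3" %in% ret$retained)    # active equate member
  expect_match(ret$removed$reason[ret$removed$item == "x2"], "outfit 1.01")
})

test_that("DIF screen calibrates under no DIF and detects a 1-logit shift", {
  set.seed(51)
  k <- 20
  delta <- setNames(seq(-2, 2, length.out = k), paste0("i", 1:k))
  n <- 2000
  x_g1 <- rasch_matrix(rnorm(n, 0, 1.5), delta, seed = 52)
  x_g2 <- rasch_matrix(rnorm(n, 0.3, 1.5), delta, seed = 53)
  # group 2 harder on item i10 by 1 logit
  shift <- delta; shift["i10"] <- shift["i10"] + 1
  x_g2s <- rasch_matrix(rnorm(n, 0.3, 1.5), shift, seed = 53)

  rm_null <- matrix_fixture(rbind(x_g1, x_g2))
  grouping <- rep(c("g1", "g2"), each = n)
  d0 <- estimate_difficulties(pairwise_counts(rm_null))
  verdicts_null <- dif_flag(rm_null, d0, grouping)
  expect_lte(mean(verdicts_null$verdict == "flagged"), 0.1)

  rm_dif <- matrix_fixture(rbind(x_g1, x_g2s))
  d1 <- estimate_difficulties(pairwise_counts(rm_dif))
  verdicts <- dif_flag(rm_dif, d1, grouping)
  expect_identical(verdicts$verdict[verdicts$item == "i10"], "flagged")
})

test_that("an item observed in a single group is untestable", {
  set.seed(61)
  delta <- setNames(c(-0.5, 0, 0.5), c("a", "b", "solo"))
  x <- rasch_matrix(rnorm(400), delta, seed = 61)
  x[201:400, "solo"] <- NA
  rm <- matrix_fixture(x)
  d <- estimate_difficulties(pairwise_counts(rm))
  v <- dif_flag(rm, d, rep(c("g1", "g2"), each = 200))
  expect_identical(v$verdict[v$item == "solo"], "untestable")
})
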
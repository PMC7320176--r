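test_that("ranked binning splits patients into contiguous near-equal cohorts", {
  set.seed(90)
  v <- rnorm(1898)
  bins <- rank_and_bin(v, 10)
  sizes <- as.integer(table(bins))
  # 1898 = 8 x 190 + 2 x 189, remainder to the low-expression cohorts
  expect_equal(sizes, c(190, 190, 190, 190, 190, 190, 190, 190, 189, 189))
  expect_equal(as.integer(table(rank_and_bin(rnorm(12), 6))), rep(2L, 6))
  expect_error(rank_and_bin(rnorm(5), 6), "n < k")
})

test_that("binning is a rank partition", {
  set.seed(91)
  for (r in 1:10) {
    n <- sample(20:200, 1); k <- sample(2:10, 1)
    v <- rnorm(n)
    bins <- rank_and_bin(v, k)
    sizes <- tabulate(bins, k)
    expect_equal(sum(sizes), n)
    expect_lte(max(sizes) - min(sizes), 1)
    # expression in cohort j never exceeds expression in cohort j+1
    for (j in seq_len(k - 1)) expect_lte(max(v[bins == j]), min(v[bins == j + 1]))
  }
})

test_that("cohort incidence reproduces reported contingency proportions", {
  expect_equal(cohort_incidence(rep(1, 66), c(rep(TRUE, 49), rep(FALSE, 17))),
               49 / 66)
  expect_equal(cohort_incidence(rep(1:2, each = 5), rep(TRUE, 10)), c(1, 1))
  expect_equal(cohort_incidence(rep(1:2, each = 5), rep(FALSE, 10)), c(0, 0))
  expect_error(cohort_incidence(c(1, 1, 3, 3), rep(TRUE, 4)), "empty cohort")
  expect_error(cohort_incidence(1:4, c(TRUE, NA, TRUE, FALSE)), "labelled")
})

test_that("monotone proportion profiles give |R| = 1 with the enumerated permutation p", {
  up <- correlate_expression_incidence(seq(0.05, 0.5, length.out = 10))
  expect_equal(up$R, 1)
  expect_equal(up$direction, "positive")
  down <- correlate_expression_incidence(seq(0.5, 0.05, length.out = 10))
  expect_equal(down$R, -1)
  expect_equal(down$direction, "negative")
  k6 <- correlate_expression_incidence(c(0.1, 0.15, 0.2, 0.3, 0.4, 0.45))
  expect_equal(k6$p, 2 / 720)
})

test_that("exact permutation p-values match full enumeration for k <= 7", {
  set.seed(92)
  for (k in 4:7) {
    for (r in 1:3) {
      pi <- round(runif(k), 2)   # rounding induces occasional ties
      if (sd(pi) == 0) pi[1] <- pi[1] + 0.05
      got <- correlate_expression_incidence(pi)
      expect_equal(got$p, spearman_perm_oracle(pi), tolerance = 1e-12)
    }
  }
})

test_that("degenerate and transformed inputs behave as documented", {
  const <- correlate_expression_incidence(rep(0.2, 8))
  expect_equal(const$R, 0)
  expect_equal(const$p, 1)
  expect_equal(const$direction, "none")
  expect_error(correlate_expression_incidence(c(0.1, 0.2, 0.3)), "at least 4")
  # Spearman R is invariant under strictly monotone transforms of expression
  set.seed(93)
  expr <- rlnorm(200); tnbc <- runif(200) < 0.3
  r1 <- correlate_expression_incidence(
    cohort_incidence(rank_and_bin(expr, 10), tnbc))
  r2 <- correlate_expression_incidence(
    cohort_incidence(rank_and_bin(log(expr), 10), tnbc))
  expect_equal(r1$R, r2$R)
  expect_equal(r1$p, r2$p)
})

test_that("orthologue mapping keeps strict one-to-one pairs and logs the rest", {
  map <- data.frame(
    mouse = c("Notch1", "Jup", "Jup", "Met", "Lipc", "Hdac4"),
    human = c("NOTCH1", "JUP", "JUPL", "MET", "SHARED", "SHARED"))
  got <- map_orthologues(c("Notch1", "Jup", "Met", "Lipc", "Hdac4", "Cntn5"), map)
  expect_equal(got$human[got$mouse == "Notch1"], "NOTCH1")
  expect_setequal(got$mouse, c("Notch1", "Met"))
  dropped <- attr(got, "dropped")
  expect_equal(dropped$unmapped, "Cntn5")
  expect_equal(dropped$one_to_many, "Jup")
  expect_setequal(dropped$many_to_one, c("Lipc", "Hdac4"))
  expect_error(map_orthologues("x", map[0, ]), "empty")
})

test_that("two-database consensus requires significance and matching direction in both", {
  r1 <- data.frame(gene = c("A", "B", "C", "D"),
                   R = c(0.9, 0.9, 0.9, -0.9),
                   p = c(0.01, 0.01, 0.40, 0.01))
  r2 <- data.frame(gene = c("A", "B", "C", "D"),
                   R = c(0.8, -0.8, 0.8, -0.7),
                   p = c(0.02, 0.02, 0.01, 0.03))
  cons <- cross_db_consensus(r1, r2)
  expect_equal(sort(cons$gene[cons$consensus]), c("A", "D"))
  expect_equal(cons$direction[cons$gene == "A"], "positive")
  expect_equal(cons$direction[cons$gene == "D"], "negative")
  expect_equal(cons$direction[cons$gene == "B"], "none")  # opposite signs
  expect_equal(cons$direction[cons$gene == "C"], "none")  # one database only
})

test_that("incidence summaries carry Wilson intervals with sane bounds", {
  s <- incidence_summary(0, 10)
  expect_equal(s$percent, 0)
  expect_equal(s$ci_low, 0)
  expect_gt(s$ci_high, 0)
  s2 <- incidence_summary(18, 48)
  expect_equal(s2$percent, 37.5)
  expect_true(s2$ci_low < 37.5 && 37.5 < s2$ci_high)
  expect_error(incidence_summary(5, 0), "n_total")
})

test_that("simulated cohorts keep the receptor triple consistent with the TNBC flag", {
  co <- simulate_patient_cohort(500, c(eff = 2, null = 0), seed = 94)
  cl <- co$clinical
  allneg <- cl$er == "neg" & cl$pr == "neg" & cl$her2 == "neg"
  expect_equal(cl$tnbc, allneg)
  expect_identical(co, simulate_patient_cohort(500, c(eff = 2, null = 0), seed = 94))
  # zero base rate with null genes: every cohort proportion is zero
  co0 <- simulate_patient_cohort(200, c(null = 0), base_tnbc_rate = 0, seed = 95)
  pi0 <- cohort_incidence(rank_and_bin(co0$expression[, 1], 10), co0$clinical$tnbc)
  expect_equal(pi0, rep(0, 10))
})

test_that("the BRCA1-mutant sub-screen runs on the flagged subset with k = 6", {
  co <- simulate_patient_cohort(800, c(eff = 2.5, null = 0), seed = 96)
  res <- tnbc_screen(co, k = 6, brca1_only = TRUE)
  expect_equal(nrow(res), 2)
  expect_true(all(is.finite(res$R)))
})
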
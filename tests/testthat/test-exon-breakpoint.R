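test_that("exon normalization removes depth and length bias", {
  counts <- matrix(c(10, 40, 5, 20, 80, 10), nrow = 3)
  lens <- c(100, 400, 50)
  norm1 <- normalize_exon_counts(counts, lib_sizes = c(1e6, 2e6), exon_lengths = lens)
  # doubling all counts and the library size changes nothing
  norm2 <- normalize_exon_counts(2 * counts, lib_sizes = 2 * c(1e6, 2e6),
                                 exon_lengths = lens)
  expect_equal(norm1, norm2)
  # doubling an exon's length together with its counts changes nothing
  c3 <- counts; c3[2, ] <- 2 * c3[2, ]
  l3 <- lens; l3[2] <- 2 * l3[2]
  expect_equal(normalize_exon_counts(c3, c(1e6, 2e6), l3), norm1)
  # zero counts normalize to zero; zero library sizes are refused
  expect_equal(normalize_exon_counts(matrix(0, 2, 1), 10, c(5, 5)),
               matrix(0, 2, 1))
  expect_error(normalize_exon_counts(counts, c(0, 1e6), lens), "library size")
})

test_that("a noise-free step at exon 25 is recovered exactly", {
  n <- 34
  base <- runif(n, 1, 3)
  trapped <- cbind(base * c(rep(1, 24), rep(8, n - 24)))
  control <- cbind(base)
  bp <- detect_breakpoint(trapped, control)
  expect_equal(bp$b, 25)
  expect_equal(bp$fold, 8, tolerance = 1e-6)  # up to the eps pseudocount
})

test_that("flat profiles yield no breakpoint under the fold gate", {
  prof <- cbind(runif(20, 1, 2))
  bp <- detect_breakpoint(prof * 1.05, prof)
  expect_true(is.na(bp$b))
  expect_lt(bp$fold, 2)
})

test_that("the breakpoint scan matches an independent re-implementation", {
  scan_oracle <- function(tr, ct, eps = 1e-8) {
    r <- log((rowMeans(tr) + eps) / (rowMeans(ct) + eps))
    n <- length(r)
    best_b <- NA; best_sep <- -Inf
    for (b in 2:n) {
      up <- mean(r[1:(b - 1)]); down <- mean(r[b:n])
      if (down - up > best_sep) { best_sep <- down - up; best_b <- b }
    }
    list(b = best_b, fold = exp(best_sep))
  }
  set.seed(55)
  for (r in 1:20) {
    n <- sample(6:40, 1)
    tr <- matrix(rexp(n * 3), n)
    ct <- matrix(rexp(n * 3), n)
    got <- detect_breakpoint(tr, ct, min_fold = 0)
    want <- scan_oracle(tr, ct)
    expect_equal(got$b, want$b)
    expect_equal(got$fold, want$fold)
  }
})

test_that("the call is invariant to sample order within groups", {
  ec <- simulate_exon_counts(rep(150, 30), breakpoint_exon = 12, fold = 8,
                             depth = 0.5, n_trapped = 4, n_control = 4, seed = 61)
  nm <- normalize_exon_counts(ec$counts, ec$lib_sizes, ec$exon_lengths)
  tr <- nm[, ec$group == "trapped"]; ct <- nm[, ec$group == "control"]
  a <- detect_breakpoint(tr, ct)
  b <- detect_breakpoint(tr[, c(3, 1, 4, 2)], ct[, c(2, 4, 1, 3)])
  expect_equal(a$b, b$b)
  expect_equal(a$fold, b$fold)
})

test_that("simulated exon counts are reproducible and exchangeable under the null", {
  a <- simulate_exon_counts(rep(200, 20), 10, fold = 8, depth = 0.3, seed = 71)
  b <- simulate_exon_counts(rep(200, 20), 10, fold = 8, depth = 0.3, seed = 71)
  expect_identical(a, b)
  expect_error(simulate_exon_counts(rep(200, 20), 10), "seed")
  # fold 1: trapped and control exchangeable (location test at alpha = 0.01)
  rejections <- 0L; n_seeds <- 20
  for (s in seq_len(n_seeds)) {
    ec <- simulate_exon_counts(rep(200, 25), 10, fold = 1, depth = 0.3,
                               n_trapped = 3, n_control = 3, seed = 600 + s)
    nm <- normalize_exon_counts(ec$counts, ec$lib_sizes, ec$exon_lengths)
    p <- t.test(colMeans(nm[, ec$group == "trapped"]),
                colMeans(nm[, ec$group == "control"]))$p.value
    rejections <- rejections + (p < 0.01)
  }
  expect_lte(rejections, 2)
})

test_that("a strong step with high depth shows the constructed fold", {
  ec <- simulate_exon_counts(rep(500, 30), breakpoint_exon = 16, fold = 8,
                             depth = 20, seed = 81)
  nm <- normalize_exon_counts(ec$counts, ec$lib_sizes, ec$exon_lengths)
  tr <- rowMeans(nm[, ec$group == "trapped"])
  ct <- rowMeans(nm[, ec$group == "control"])
  ratio <- mean(tr[16:30] / ct[16:30]) / mean(tr[1:15] / ct[1:15])
  expect_equal(ratio, 8, tolerance = 0.05)
})
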
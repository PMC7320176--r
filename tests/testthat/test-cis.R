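test_that("the Poisson CIS tail matches its closed form and direct summation", {
  expect_equal(poisson_cis_pvalue(0, w = 1e4, N = 100, L = 1e6), 1)
  # lambda = 1, k = 8: closed-form tail 1 - e^{-1} sum_{j<8} 1/j!
  closed <- 1 - exp(-1) * sum(1 / factorial(0:7))
  expect_lt(abs(poisson_cis_pvalue(8, w = 1e4, N = 100, L = 1e6) - closed), 1e-12)
  # strictly decreasing in k at fixed lambda
  p <- poisson_cis_pvalue(0:30, w = 1e4, N = 500, L = 1e6)
  expect_true(all(diff(p[-1]) < 0))
  expect_true(all(p > 0 & p <= 1))
})

test_that("invalid Poisson arguments are refused", {
  expect_error(poisson_cis_pvalue(1, w = 2e6, N = 10, L = 1e6), "exceed")
  expect_error(poisson_cis_pvalue(-1, w = 10, N = 10, L = 1e6), "non-negative")
  expect_error(poisson_cis_pvalue(1, w = -5, N = 10, L = 1e6), "positive")
})

test_that("the gene scan scores the gene body plus the 3 kb upstream window", {
  d <- default_screen(seed = 301)
  cis <- gene_cis_scan(d$insertions, d$catalog)
  all_tab <- attr(cis, "all")
  g <- d$catalog$genes[match(all_tab$gene_id, d$catalog$genes$gene_id), ]
  expect_equal(all_tab$w, g$end - g$start + 1 + 3000)
  # genes with zero insertions never appear among retained CIS genes
  expect_true(all(cis$k > 0))
  expect_true(all(cis$p < 0.05))
})

test_that("an empty insertion table yields an empty result, not an error", {
  d <- default_screen(seed = 305)
  empty <- d$insertions[0, ]
  class(empty) <- class(d$insertions)
  expect_equal(nrow(gene_cis_scan(empty, d$catalog)), 0)
})

test_that("the recurrence filter applies the two-strain 5% rule with an inclusive boundary", {
  cis <- fake_cis(f40 = c(0.06, 0.10, 0.05, 0.03),
                  f75 = c(0.07, 0.03, 0.05, 0.08))
  kept <- recurrence_filter(cis, theta = 0.05)
  expect_setequal(kept$gene_id, c("g01", "g03"))  # (.06,.07) and boundary (.05,.05)
})

test_that("a group with a tumour-less strain makes recurrence fractions undefined", {
  cis <- fake_cis(f40 = 0.5, f75 = 0.5)
  attr(cis, "strain_totals") <- c(`12740` = 100, `12775` = 0)
  expect_error(recurrence_filter(cis), "zero tumours")
})

test_that("group combination obeys set arithmetic", {
  ov <- combine_groups(paste0("g", 1:10), paste0("g", 11:20))
  expect_equal(ov$sizes[["union"]], 20)
  expect_equal(ov$sizes[["intersection"]], 0)
  same <- combine_groups(paste0("g", 1:5), paste0("g", 1:5))
  expect_setequal(same$union, paste0("g", 1:5))
  expect_setequal(same$intersection, paste0("g", 1:5))
  ab <- combine_groups(paste0("g", 1:7), paste0("g", 5:12))
  expect_equal(ab$sizes[["union"]],
               ab$sizes[["a"]] + ab$sizes[["b"]] - ab$sizes[["intersection"]])
  expect_setequal(c(ab$only_a, ab$only_b, ab$intersection), ab$union)
})

test_that("the oncoplot matrix conserves per-gene tumour counts and frequencies", {
  drv <- list(driver_spec("gene010", "ONCOGENE", penetrance = 0.25, hotspot = c(3, 5)),
              driver_spec("gene030", "TSG", penetrance = 0.15))
  d <- default_screen(seed = 311, drivers = drv)
  cis <- gene_cis_scan(d$insertions, d$catalog)
  mat <- oncoplot_matrix(cis$gene_id, d$insertions, d$catalog)
  expect_true(all(mat %in% 0:1))
  expect_equal(unname(rowSums(mat)),
               unname(cis$t[match(rownames(mat), cis$gene_id)]))
  freq <- attr(mat, "frequency")
  expect_false(is.unsorted(rev(freq)))
  expect_equal(unname(freq), unname(rowSums(mat) / ncol(mat)))
  # permuting tumours leaves frequencies unchanged
  perm <- mat[, sample(ncol(mat)), drop = FALSE]
  expect_equal(rowSums(perm), rowSums(mat))
})

test_that("a fully null screen is calibrated and the recurrence filter empties it", {
  n_rep <- 10
  frac <- numeric(n_rep); nonempty <- 0L
  for (r in seq_len(n_rep)) {
    d <- default_screen(seed = 320 + 7 * r)
    cis <- gene_cis_scan(d$insertions, d$catalog)
    frac[r] <- nrow(cis) / nrow(d$catalog$genes)
    nonempty <- nonempty + (nrow(recurrence_filter(cis)) > 0)
  }
  n_tests <- n_rep * 60
  se <- sqrt(0.05 * 0.95 / n_tests)
  expect_lt(abs(mean(frac) - 0.05), 3 * se)
  expect_gte(mean(nonempty == 0), 0.95)
})

test_that("donor-chromosome exclusion drops the strain-matched donor insertions", {
  d <- default_screen(seed = 331)
  donor <- attr(d$insertions, "donor_chrom")
  cis <- gene_cis_scan(d$insertions, d$catalog, exclude_donor = TRUE)
  N_excl <- attr(cis, "params")$N
  ins <- as.data.frame(d$insertions)
  expect_equal(N_excl, sum(ins$chrom != donor[ins$strain]))
})
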
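# shared fixture builders: small, fast synthetic inputs built in code

# sequence-backed test world: 4 x 500 kb chromosomes, 8 compact genes
small_world <- function(seed = 101, n_tumours = 10L, background_rate = 20,
                        drivers = list()) {
  ctl <- make_gene_catalog(
    n_genes = 8, chrom_lengths = setNames(rep(5e5, 4), paste0("chr", 1:4)),
    gene_length = c(4e3, 8e3), seed = seed)
  gen <- make_genome(ctl$chrom_lengths, seed = seed + 1L)
  cfg <- screen_config(
    n_tumours = data.frame(strain = c("12740", "12775"), cre = "WAP",
                           n = n_tumours),
    background_rate = background_rate, drivers = drivers, seed = seed + 2L)
  list(catalog = ctl, genome = gen, config = cfg)
}

# default coordinate-only screen conditions (genome-scale catalog)
default_screen <- function(seed, drivers = list(), n = 100L) {
  ctl <- make_gene_catalog(n_genes = 60, seed = seed)
  ins <- simulate_screen(ctl, screen_config(
    n_tumours = data.frame(strain = c("12740", "12775"), cre = "WAP", n = n),
    drivers = drivers, seed = seed + 1L))
  list(catalog = ctl, insertions = ins)
}

site_key <- function(d) paste(d$chrom, d$pos, d$transposon_orient, d$tumour_id)

# hand-assembled gene_cis table for filter tests
fake_cis <- function(f40, f75, n_tumours = 200L) {
  df <- data.frame(gene_id = sprintf("g%02d", seq_along(f40)),
                   chrom = "chr1", start = 1L, end = 1000L, w = 1000L,
                   k = 10L, t = 10L, f_12740 = f40, f_12775 = f75,
                   p = 1e-6, q = 1e-5, stringsAsFactors = FALSE)
  structure(df, class = c("gene_cis", "data.frame"),
            strain_totals = c(`12740` = n_tumours / 2, `12775` = n_tumours / 2),
            n_tumours = n_tumours)
}

# independent Poisson upper-tail oracle: direct mass summation, no ppois
poisson_tail_oracle <- function(k, lambda) {
  if (k == 0) return(1)
  m <- exp(-lambda + k * log(lambda) - lgamma(k + 1))
  tot <- 0; j <- k
  while (m > 1e-300 && (j <= lambda || m > tot * 1e-18)) {
    tot <- tot + m
    j <- j + 1
    m <- m * lambda / j
  }
  min(1, tot)
}

# independent exact two-sided binomial oracle at p0 = 0.5: Pascal's triangle
binom_oracle <- function(k, n) {
  counts <- 1
  for (i in seq_len(n)) counts <- c(0, counts) + c(counts, 0)
  sum(counts[counts <= counts[k + 1]]) / 2^n
}

# independent exact Spearman permutation oracle: cor() on every permutation
spearman_perm_oracle <- function(pi) {
  k <- length(pi)
  idx <- seq_len(k)
  r_obs <- cor(idx, pi, method = "spearman")
  perms <- .perm_all(k)
  r_all <- apply(perms, 1, function(o) cor(idx, pi[o], method = "spearman"))
  mean(abs(r_all) >= abs(r_obs) - 1e-9)
}
.perm_all <- function(k) {
  if (k == 1) return(matrix(1L))
  sub <- .perm_all(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i)
    cbind(i, matrix(seq_len(k)[-i][sub], nrow(sub)))))
}
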
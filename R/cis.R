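#' Poisson upper-tail p-value for insertion enrichment in a region
#'
#' Under a uniform-insertion null, the number of insertions falling in a
#' region of width `w` out of `N` insertions over an effective genome of
#' length `L` is Poisson with mean `lambda = N * w / L`. The common
#' insertion site (CIS) p-value is the upper tail `P(X >= k)`.
#'
#' @param k observed insertion count (vectorized).
#' @param w region width in bp.
#' @param N total insertions genome-wide.
#' @param L effective genome length in bp.
#' @return p-value(s) in (0, 1]; `p = 1` when `k = 0`.
#' @examples
#' poisson_cis_pvalue(8, w = 1e4, N = 100, L = 1e6)  # lambda = 1
#' @export
poisson_cis_pvalue <- function(k, w, N, L) {
  if (length(w) != 1 || length(N) != 1 || length(L) != 1)
    stop("w, N and L must be scalars")
  if (is.na(w) || is.na(N) || is.na(L) || w <= 0 || L <= 0 || N < 0)
    stop("w and L must be positive and N non-negative")
  if (w > L) stop("region width w cannot exceed genome length L")
  if (any(is.na(k)) || any(k < 0) || any(k != floor(k)))
    stop("k must be non-negative integers")
  lambda <- N * w / L
  p <- stats::ppois(k - 1, lambda, lower.tail = FALSE)
  p[k == 0] <- 1
  pmin(p, 1)
}

#' Scan all genes for common insertion sites
#'
#' Scores every gene of the catalog over its gene body extended 3 kb upstream
#' (strand-aware) against the uniform-insertion Poisson null, and retains
#' genes with `p < alpha`. A site overlapping two genes' extended regions
#' counts for both. Per-strain tumour fractions (the share of that strain's
#' tumours carrying at least one insertion in the region) are attached for
#' the downstream recurrence filter. Benjamini-Hochberg q-values are reported
#' alongside the raw p-values; the retention filter itself uses raw p.
#'
#' @param insertions a deduplicated `insertion_table`.
#' @param catalog a `gene_catalog`.
#' @param alpha retention threshold on the raw Poisson p-value (default 0.05).
#' @param upstream upstream window in bp (default 3000).
#' @param exclude_donor drop insertions on each strain's donor chromosome
#'   before scoring (off by default: with two strains the recurrence filter
#'   already controls local-hopping artifacts).
#' @param donor_chrom named strain-to-chromosome map; defaults to the
#'   `donor_chrom` attribute of the insertion table.
#' @param genome_length effective genome length; defaults to the sum of the
#'   catalog's chromosome lengths.
#' @return a `gene_cis` data.frame (one row per retained gene): gene_id,
#'   chrom, start, end (extended region), w, k (insertions), t (tumours),
#'   f_12740, f_12775, p, q. The full all-genes table is attached as
#'   attribute `all`, the per-strain tumour totals as attribute
#'   `strain_totals`.
#' @export
gene_cis_scan <- function(insertions, catalog, alpha = 0.05, upstream = 3000,
                          exclude_donor = FALSE, donor_chrom = NULL,
                          genome_length = NULL) {
  stopifnot(inherits(catalog, "gene_catalog"), is.data.frame(insertions))
  ins <- as.data.frame(insertions)
  roster <- attr(insertions, "tumours")
  if (exclude_donor) {
    if (is.null(donor_chrom)) donor_chrom <- attr(insertions, "donor_chrom")
    if (is.null(donor_chrom)) stop("exclude_donor requires a donor_chrom map")
    keep <- ins$chrom != donor_chrom[ins$strain]
    ins <- ins[keep, , drop = FALSE]
  }
  L <- if (is.null(genome_length)) sum(catalog$chrom_lengths) else genome_length
  N <- nrow(ins)
  reg <- gene_regions(catalog, upstream = upstream)

  if (nrow(reg) == 0 || N == 0) {
    empty <- data.frame(gene_id = character(), chrom = character(),
                        start = integer(), end = integer(), w = integer(),
                        k = integer(), t = integer(), f_12740 = numeric(),
                        f_12775 = numeric(), p = numeric(), q = numeric())
    class(empty) <- c("gene_cis", "data.frame")
    attr(empty, "all") <- empty
    return(empty)
  }

  gr_genes <- GenomicRanges::GRanges(reg$chrom,
                                     IRanges::IRanges(reg$start, reg$end))
  gr_ins <- GenomicRanges::GRanges(ins$chrom, IRanges::IRanges(ins$pos, ins$pos))
  ov <- GenomicRanges::findOverlaps(gr_genes, gr_ins)
  gi <- S4Vectors::queryHits(ov)
  ii <- S4Vectors::subjectHits(ov)

  # tumour totals per strain (roster if available, else observed tumours)
  if (is.null(roster))
    roster <- unique(ins[, intersect(c("tumour_id", "strain", "cre"), names(ins))])
  strain_totals <- table(factor(roster$strain, levels = c("12740", "12775")))

  k <- tabulate(gi, nbins = nrow(reg))
  t_cnt <- integer(nrow(reg))
  f40 <- f75 <- numeric(nrow(reg))
  hit_split <- split(ii, gi)
  for (nm in names(hit_split)) {
    g <- as.integer(nm)
    tum <- unique(ins$tumour_id[hit_split[[nm]]])
    t_cnt[g] <- length(tum)
    str <- roster$strain[match(tum, roster$tumour_id)]
    f40[g] <- if (strain_totals[["12740"]] > 0)
      sum(str == "12740") / strain_totals[["12740"]] else NA_real_
    f75[g] <- if (strain_totals[["12775"]] > 0)
      sum(str == "12775") / strain_totals[["12775"]] else NA_real_
  }

  all_tab <- data.frame(gene_id = reg$gene_id, chrom = reg$chrom,
                        start = reg$start, end = reg$end, w = reg$width,
                        k = k, t = t_cnt, f_12740 = f40, f_12775 = f75,
                        stringsAsFactors = FALSE)
  all_tab$p <- vapply(seq_len(nrow(all_tab)), function(i)
    poisson_cis_pvalue(all_tab$k[i], all_tab$w[i], N, L), numeric(1))
  all_tab$q <- stats::p.adjust(all_tab$p, method = "BH")

  out <- all_tab[all_tab$p < alpha & all_tab$k > 0, , drop = FALSE]
  out <- out[order(out$p, -out$k), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gene_cis", "data.frame")
  attr(out, "all") <- all_tab
  attr(out, "strain_totals") <- strain_totals
  attr(out, "n_tumours") <- nrow(roster)
  attr(out, "params") <- list(alpha = alpha, upstream = upstream, N = N, L = L,
                              exclude_donor = exclude_donor)
  out
}

#' Two-strain recurrence filter for CIS genes
#'
#' Keeps genes whose insertion recurrence reaches `theta` (default 5%) of the
#' tumours in *both* transposon strains. Local hopping inflates insertion
#' density on a strain's donor chromosome only, so requiring recurrence in
#' both strains — whose donor chromosomes differ — filters out hopping
#' artifacts. The boundary is inclusive (fractions equal to `theta` pass).
#'
#' @param cis a [gene_cis_scan()] result.
#' @param theta per-strain tumour-fraction threshold (default 0.05).
#' @param group optional group label (e.g. `"BrWSB"`) carried on the result.
#' @return a `candidate_set` data.frame: gene_id, frequency (fraction of all
#'   tumours), f_12740, f_12775, k, t, p, q.
#' @export
recurrence_filter <- function(cis, theta = 0.05, group = NULL) {
  stopifnot(inherits(cis, "gene_cis"))
  totals <- attr(cis, "strain_totals")
  if (is.null(totals) || any(totals == 0))
    stop("recurrence fraction undefined: a strain has zero tumours in this group")
  keep <- !is.na(cis$f_12740) & !is.na(cis$f_12775) &
    cis$f_12740 >= theta & cis$f_12775 >= theta
  out <- as.data.frame(cis)[keep, , drop = FALSE]
  out$frequency <- out$t / attr(cis, "n_tumours")
  out <- out[order(-out$frequency, out$p),
             c("gene_id", "frequency", "f_12740", "f_12775", "k", "t", "p", "q")]
  rownames(out) <- NULL
  structure(out, class = c("candidate_set", "data.frame"),
            group = group, theta = theta,
            n_tumours = attr(cis, "n_tumours"))
}

#' Combine two candidate gene sets
#'
#' Set arithmetic over two candidate lists (e.g. the WAP-Cre and MMTV-Cre
#' screen groups): union, intersection and group-exclusive genes, with the
#' identity |A u B| = |A| + |B| - |A n B|.
#'
#' @param a,b `candidate_set` objects or character vectors of gene ids.
#' @return a `group_overlap` list: union, intersection, only_a, only_b, sizes.
#' @examples
#' combine_groups(paste0("g", 1:119), paste0("g", 80:169))$sizes
#' @export
combine_groups <- function(a, b) {
  ga <- if (is.data.frame(a)) a$gene_id else as.character(a)
  gb <- if (is.data.frame(b)) b$gene_id else as.character(b)
  ga <- unique(ga); gb <- unique(gb)
  res <- list(union = union(ga, gb), intersection = intersect(ga, gb),
              only_a = setdiff(ga, gb), only_b = setdiff(gb, ga))
  res$sizes <- c(a = length(ga), b = length(gb),
                 union = length(res$union), intersection = length(res$intersection))
  structure(res, class = "group_overlap")
}

#' @export
print.group_overlap <- function(x, ...) {
  s <- x$sizes
  cat(sprintf("Candidate groups: |A| = %d, |B| = %d, overlap = %d, union = %d\n",
              s[["a"]], s[["b"]], s[["intersection"]], s[["union"]]))
  invisible(x)
}

#' Gene-by-tumour presence matrix (oncoplot layout)
#'
#' Binary matrix indicating which tumours carry at least one insertion in
#' each candidate gene's extended region, with rows ordered by descending
#' recurrence frequency. Row sums equal per-gene tumour counts.
#'
#' @param candidates a `candidate_set` (or character vector of gene ids).
#' @param insertions an `insertion_table`.
#' @param catalog the `gene_catalog`.
#' @param upstream upstream window in bp (default 3000).
#' @return an `oncoplot_matrix`: integer 0/1 matrix genes x tumours with a
#'   `frequency` attribute (per-gene fraction of all tumours).
#' @export
oncoplot_matrix <- function(candidates, insertions, catalog, upstream = 3000) {
  genes <- if (is.data.frame(candidates)) candidates$gene_id else as.character(candidates)
  ins <- as.data.frame(insertions)
  roster <- attr(insertions, "tumours")
  tumours <- if (!is.null(roster)) roster$tumour_id else unique(ins$tumour_id)
  reg <- gene_regions(catalog, upstream = upstream)
  reg <- reg[match(genes, reg$gene_id), , drop = FALSE]
  if (anyNA(reg$gene_id)) stop("candidate gene missing from catalog")
  mat <- matrix(0L, nrow = length(genes), ncol = length(tumours),
                dimnames = list(genes, tumours))
  gr_genes <- GenomicRanges::GRanges(reg$chrom, IRanges::IRanges(reg$start, reg$end))
  gr_ins <- GenomicRanges::GRanges(ins$chrom, IRanges::IRanges(ins$pos, ins$pos))
  ov <- GenomicRanges::findOverlaps(gr_genes, gr_ins)
  gi <- S4Vectors::queryHits(ov); ii <- S4Vectors::subjectHits(ov)
  mat[cbind(gi, match(ins$tumour_id[ii], tumours))] <- 1L
  freq <- rowSums(mat) / length(tumours)
  o <- order(-freq)
  mat <- mat[o, , drop = FALSE]
  structure(mat, frequency = freq[o], class = c("oncoplot_matrix", class(mat)))
}

#' Plot an oncoplot presence matrix
#'
#' @param x an [oncoplot_matrix()].
#' @param ... passed to [graphics::image()].
#' @return invisibly `x`.
#' @export
plot.oncoplot_matrix <- function(x, ...) {
  m <- unclass(x)[rev(seq_len(nrow(x))), , drop = FALSE]
  graphics::image(t(m), axes = FALSE, col = c("grey92", "firebrick"),
                  xlab = "tumours", ylab = "", ...)
  graphics::axis(2, at = seq(0, 1, length.out = nrow(m)), labels = rownames(m),
                 las = 2, cex.axis = 0.6, tick = FALSE)
  invisible(x)
}
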
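#' Sense fraction and orientation-bias test for a gene's insertions
#'
#' A transposon insertion is "sense" when its internal (CAG) promoter points
#' in the gene's transcriptional direction — the configuration that drives an
#' activated, truncated transcript. A strong sense bias therefore marks
#' candidate oncogenes, while disrupting (tumour-suppressor) insertions show
#' no orientation preference. The bias is tested with an exact two-sided
#' binomial test against 0.5: the p-value sums the probabilities of all
#' outcomes no more likely than the observed one (the minimum-likelihood
#' two-sided rule).
#'
#' @param n_sense number of sense-oriented insertions.
#' @param n_total total insertions (must be >= 1).
#' @return list with `f_sense = n_sense / n_total` and `p_binom`.
#' @examples
#' sense_fraction(100, 136)  # f = 0.735
#' @export
sense_fraction <- function(n_sense, n_total) {
  stopifnot(length(n_sense) == 1, length(n_total) == 1)
  if (is.na(n_total) || n_total < 1) stop("n_total must be >= 1")
  if (is.na(n_sense) || n_sense < 0 || n_sense > n_total)
    stop("n_sense must lie in [0, n_total]")
  list(f_sense = n_sense / n_total,
       p_binom = binom_twosided(n_sense, n_total))
}

#' Exact two-sided binomial p-value at p0 = 0.5
#'
#' Minimum-likelihood two-sided rule: sums the point probabilities of every
#' outcome whose probability does not exceed that of the observed count
#' (within a small relative tolerance to absorb floating-point ties).
#'
#' @param k observed successes.
#' @param n trials.
#' @param p0 null success probability (default 0.5).
#' @return two-sided p-value in (0, 1].
#' @export
binom_twosided <- function(k, n, p0 = 0.5) {
  stopifnot(n >= 1, k >= 0, k <= n)
  d <- stats::dbinom(0:n, n, p0)
  min(1, sum(d[d <= d[k + 1] * (1 + 1e-7)]))
}

#' Positional clustering score for insertions in a gene region
#'
#' Measures whether insertions pile into a hotspot or spread over the gene:
#' the score is the largest fraction of insertions contained in any sliding
#' window of width `window_frac` x region length. The maximum over all
#' windows is attained by a window whose left edge sits on an insertion, so
#' the scan is exhaustive over insertion-anchored windows. A score of 1 means
#' all insertions fall inside one window; uniformly spread insertions score
#' about `window_frac`.
#'
#' @param positions insertion positions (>= 1 required), all within the region.
#' @param region_start,region_end region bounds (the extended gene region).
#' @param window_frac window width as a fraction of region length (default 0.2).
#' @return clustering score in (0, 1].
#' @export
cluster_score <- function(positions, region_start, region_end, window_frac = 0.2) {
  if (length(positions) == 0) stop("cluster_score requires at least one position")
  stopifnot(region_end >= region_start, window_frac > 0, window_frac <= 1)
  if (any(positions < region_start | positions > region_end))
    stop("positions outside the region")
  W <- window_frac * (region_end - region_start + 1)
  p <- sort(positions)
  best <- 0L
  for (i in seq_along(p)) {
    best <- max(best, sum(p >= p[i] & p < p[i] + W))
  }
  best / length(p)
}

#' Classify a candidate gene as oncogene-like or tumour-suppressor-like
#'
#' Decision rule on the orientation and clustering evidence:
#' `ONCOGENE` when the insertions are significantly sense-biased
#' (`f_sense > 0.5` and `p_binom < alpha`) *and* clustered
#' (`cluster_score >= cluster_min`); `TSG` when there is no sense bias
#' (`p_binom >= alpha` or `f_sense < 0.5`) and at least `min_insertions`
#' insertions support the call; `AMBIGUOUS` otherwise (too few insertions, or
#' sense-biased but dispersed).
#'
#' @param f_sense,p_binom from [sense_fraction()].
#' @param cluster from [cluster_score()].
#' @param n_total total insertions for the gene.
#' @param alpha significance level for the orientation test (default 0.05).
#' @param cluster_min clustering threshold for an oncogene call (default 0.5).
#' @param min_insertions minimum insertions for a confident call (default 5).
#' @return a `driver_call` list: class, evidence.
#' @export
classify_driver <- function(f_sense, p_binom, cluster, n_total,
                            alpha = 0.05, cluster_min = 0.5, min_insertions = 5L) {
  stopifnot(f_sense >= 0, f_sense <= 1, p_binom > 0, p_binom <= 1 + 1e-12,
            cluster > 0, cluster <= 1, n_total >= 1)
  if (n_total < min_insertions) {
    cls <- "AMBIGUOUS"
    ev <- sprintf("only %d insertions (< %d)", n_total, min_insertions)
  } else if (f_sense > 0.5 && p_binom < alpha && cluster >= cluster_min) {
    cls <- "ONCOGENE"
    ev <- sprintf("sense-biased (f = %.2f, p = %.3g) and clustered (%.2f)",
                  f_sense, p_binom, cluster)
  } else if (p_binom >= alpha || f_sense < 0.5) {
    cls <- "TSG"
    ev <- sprintf("no sense bias (f = %.2f, p = %.3g); dispersed or unoriented",
                  f_sense, p_binom)
  } else {
    cls <- "AMBIGUOUS"
    ev <- sprintf("sense-biased (f = %.2f, p = %.3g) but dispersed (%.2f < %.2f)",
                  f_sense, p_binom, cluster, cluster_min)
  }
  structure(list(class = cls, evidence = ev), class = "driver_call")
}

#' Orientation-and-clustering classification of candidate genes
#'
#' Computes, for each candidate gene, the orientation profile (sense counts
#' over all insertions in the gene's extended region), the positional
#' clustering score, and the resulting oncogene/TSG call.
#'
#' @param candidates a `candidate_set` or character vector of gene ids.
#' @param insertions an `insertion_table`.
#' @param catalog the `gene_catalog`.
#' @param upstream upstream window in bp (default 3000).
#' @param window_frac,alpha,cluster_min,min_insertions see [cluster_score()]
#'   and [classify_driver()].
#' @return a `driver_calls` data.frame: gene_id, n_total, n_sense, f_sense,
#'   p_binom, cluster_score, class, evidence.
#' @export
classify_candidates <- function(candidates, insertions, catalog, upstream = 3000,
                                window_frac = 0.2, alpha = 0.05,
                                cluster_min = 0.5, min_insertions = 5L) {
  genes <- if (is.data.frame(candidates)) candidates$gene_id else as.character(candidates)
  ins <- as.data.frame(insertions)
  reg <- gene_regions(catalog, upstream = upstream)
  rows <- lapply(genes, function(g) {
    r <- reg[reg$gene_id == g, ]
    if (nrow(r) != 1) stop("gene missing from catalog: ", g)
    sel <- ins$chrom == r$chrom & ins$pos >= r$start & ins$pos <= r$end
    sub <- ins[sel, , drop = FALSE]
    if (nrow(sub) == 0) return(NULL)
    n_sense <- sum(sub$transposon_orient == r$strand)
    sf <- sense_fraction(n_sense, nrow(sub))
    cs <- cluster_score(sub$pos, r$start, r$end, window_frac = window_frac)
    call <- classify_driver(sf$f_sense, sf$p_binom, cs, nrow(sub),
                            alpha = alpha, cluster_min = cluster_min,
                            min_insertions = min_insertions)
    data.frame(gene_id = g, n_total = nrow(sub), n_sense = n_sense,
               f_sense = sf$f_sense, p_binom = sf$p_binom, cluster_score = cs,
               class = call$class, evidence = call$evidence,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(), n_total = integer(),
                      n_sense = integer(), f_sense = numeric(),
                      p_binom = numeric(), cluster_score = numeric(),
                      class = character(), evidence = character())
  rownames(out) <- NULL
  class(out) <- c("driver_calls", "data.frame")
  out
}

#' Plot sense fractions of classified genes
#'
#' One point per gene: sense fraction against insertion count, coloured by
#' call, with the equal-ratio line at 0.5 dashed.
#'
#' @param x a `driver_calls` data.frame.
#' @param ... passed to [graphics::plot()].
#' @return invisibly `x`.
#' @export
plot.driver_calls <- function(x, ...) {
  col <- c(ONCOGENE = "firebrick", TSG = "steelblue", AMBIGUOUS = "grey60")
  graphics::plot(x$n_total, x$f_sense, log = "x", ylim = c(0, 1),
                 pch = 19, col = col[x$class],
                 xlab = "insertions in gene region", ylab = "sense fraction", ...)
  graphics::abline(h = 0.5, lty = 2)
  graphics::legend("bottomright", legend = names(col), col = col, pch = 19,
                   bty = "n", cex = 0.8)
  invisible(x)
}
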
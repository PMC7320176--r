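#' Map mouse candidate genes to human orthologues
#'
#' Restricts an orthologue table to the query genes and keeps only strict
#' one-to-one pairs: mouse genes mapping to several human genes, and human
#' genes targeted by several mouse genes, are dropped (and reported in the
#' `dropped` attribute together with unmapped queries).
#'
#' @param genes character vector of mouse gene ids.
#' @param mapping data.frame with columns `mouse` and `human`.
#' @return data.frame of retained (mouse, human) pairs, with attribute
#'   `dropped` (named list: unmapped, one_to_many, many_to_one).
#' @export
map_orthologues <- function(genes, mapping) {
  stopifnot(is.data.frame(mapping), all(c("mouse", "human") %in% names(mapping)))
  if (nrow(mapping) == 0) stop("empty orthologue mapping table")
  genes <- unique(as.character(genes))
  m <- unique(mapping[mapping$mouse %in% genes, c("mouse", "human")])
  unmapped <- setdiff(genes, m$mouse)
  multi_h <- unique(m$mouse[m$mouse %in% m$mouse[duplicated(m$mouse)]])
  m <- m[!m$mouse %in% multi_h, , drop = FALSE]
  multi_m <- unique(m$human[m$human %in% m$human[duplicated(m$human)]])
  many_to_one <- m$mouse[m$human %in% multi_m]
  m <- m[!m$human %in% multi_m, , drop = FALSE]
  rownames(m) <- NULL
  attr(m, "dropped") <- list(unmapped = unmapped, one_to_many = multi_h,
                             many_to_one = many_to_one)
  m
}

#' Rank patients by expression and split them into equal cohorts
#'
#' Patients are sorted by ascending expression (ties broken by stable patient
#' order) and cut into `k` contiguous rank cohorts whose sizes differ by at
#' most one; the first `n mod k` cohorts (lowest expression) receive the
#' extra patient.
#'
#' @param values expression values, one per patient.
#' @param k number of cohorts (2 <= k <= n).
#' @param ids optional patient ids used as the stable tie-break; defaults to
#'   input order.
#' @return integer cohort assignment (1 = lowest expression), aligned to the
#'   input order.
#' @examples
#' table(rank_and_bin(rnorm(1898), 10))  # eight cohorts of 190, two of 189
#' @export
rank_and_bin <- function(values, k, ids = NULL) {
  n <- length(values)
  k <- as.integer(k)
  if (k < 2) stop("k must be >= 2")
  if (n < k) stop("fewer patients than cohorts (n < k)")
  if (is.null(ids)) ids <- seq_len(n)
  ord <- order(values, ids)
  sizes <- rep(n %/% k, k)
  rem <- n %% k
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  cohort <- integer(n)
  cohort[ord] <- rep(seq_len(k), sizes)
  cohort
}

#' Per-cohort TNBC proportion
#'
#' @param cohort integer cohort assignment from [rank_and_bin()].
#' @param labels logical (or 0/1) TNBC status per patient.
#' @return numeric vector `pi_1..pi_k` of per-cohort proportions.
#' @export
cohort_incidence <- function(cohort, labels) {
  if (length(cohort) != length(labels)) stop("cohort and labels differ in length")
  if (anyNA(labels)) stop("every patient must be labelled")
  k <- max(cohort)
  sizes <- tabulate(cohort, nbins = k)
  if (any(sizes == 0)) stop("empty cohort")
  as.numeric(tapply(as.logical(labels), factor(cohort, levels = seq_len(k)), mean))
}

# all permutations of 1..k as a k! x k matrix (row-wise)
.perm_matrix <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- .perm_matrix(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    m <- sub
    m[m >= i] <- m[m >= i] + 1L
    cbind(rep(i, nrow(m)), m)
  }))
}

#' Correlate cohort rank with subtype incidence
#'
#' Spearman rank correlation between the cohort index (1 = lowest
#' expression) and the per-cohort TNBC proportions, with a two-sided p-value
#' by full permutation enumeration when `k <= exact_max_k` (all `k!`
#' orderings of the observed proportions) and the t approximation otherwise.
#' Tied proportions receive average ranks. A constant proportion vector is
#' degenerate: `R = 0`, `p = 1`, direction `"none"`.
#'
#' @param pi per-cohort proportions from [cohort_incidence()].
#' @param alpha significance level used to set the direction (default 0.05).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param exact_max_k largest k for exact permutation enumeration (default 8).
#' @return a `cohort_correlation` list: R, p, direction
#'   (`"positive"`/`"negative"`/`"none"`), k, pi.
#' @export
correlate_expression_incidence <- function(pi, alpha = 0.05,
                                           method = c("spearman", "pearson"),
                                           exact_max_k = 8L) {
  method <- match.arg(method)
  k <- length(pi)
  if (k < 4) stop("need at least 4 cohorts")
  if (anyNA(pi) || any(pi < 0) || any(pi > 1)) stop("proportions must lie in [0,1]")
  idx <- seq_len(k)
  if (stats::sd(pi) == 0) {
    out <- list(R = 0, p = 1, direction = "none", k = k, pi = pi, method = method)
    class(out) <- "cohort_correlation"
    return(out)
  }
  R <- stats::cor(idx, pi, method = method)
  if (method == "spearman" && k <= exact_max_k) {
    y <- rank(pi, ties.method = "average")
    perms <- .perm_matrix(k)
    # R is monotone in sum(idx * y_perm): compare the centered cross-products
    y_perm <- matrix(y[perms], nrow = nrow(perms))
    s <- as.numeric(y_perm %*% idx)
    stat <- abs(s - k * mean(idx) * mean(y))
    s_obs <- sum(idx * y)
    p <- mean(stat >= abs(s_obs - k * mean(idx) * mean(y)) - 1e-9)
  } else {
    tt <- R * sqrt((k - 2) / max(1 - R^2, .Machine$double.eps))
    p <- 2 * stats::pt(abs(tt), df = k - 2, lower.tail = FALSE)
  }
  p <- min(1, max(0, p))
  direction <- if (p < alpha) { if (R > 0) "positive" else "negative" } else "none"
  structure(list(R = R, p = p, direction = direction, k = k, pi = pi,
                 method = method),
            class = "cohort_correlation")
}

#' @export
print.cohort_correlation <- function(x, ...) {
  cat(sprintf("%s R = %.3f, p = %.4g (%d cohorts, %s)\n",
              if (x$method == "spearman") "Spearman" else "Pearson",
              x$R, x$p, x$k, x$direction))
  invisible(x)
}

#' Expression-binned TNBC-incidence screen over many genes
#'
#' For each gene: rank patients by that gene's expression, split into `k`
#' equal cohorts, compute per-cohort TNBC proportions, and correlate cohort
#' rank with incidence. This is the per-database half of the cross-species
#' screen; run it once per database and feed the results to
#' [cross_db_consensus()]. For the BRCA1-mutant sub-analysis, subset the
#' patients first and use `k = 6`.
#'
#' @param expression numeric matrix, patients x genes (column names are gene
#'   ids), or a `patient_cohort` from [simulate_patient_cohort()].
#' @param tnbc logical TNBC status per patient (ignored when `expression` is
#'   a `patient_cohort`).
#' @param k number of cohorts (default 10; 6 for BRCA1-mutant subsets).
#' @param alpha significance level (default 0.05).
#' @param method correlation method, see [correlate_expression_incidence()].
#' @param brca1_only restrict to BRCA1-mutant patients (requires a
#'   `patient_cohort` input).
#' @return a `tnbc_screen` data.frame: gene, R, p, direction.
#' @export
tnbc_screen <- function(expression, tnbc = NULL, k = 10L, alpha = 0.05,
                        method = "spearman", brca1_only = FALSE) {
  if (inherits(expression, "patient_cohort")) {
    clin <- expression$clinical
    expr <- expression$expression
    if (brca1_only) {
      keep <- clin$brca1_mutant
      clin <- clin[keep, , drop = FALSE]
      expr <- expr[keep, , drop = FALSE]
    }
    tnbc <- clin$tnbc
  } else {
    if (brca1_only) stop("brca1_only requires a patient_cohort input")
    expr <- as.matrix(expression)
    if (is.null(tnbc)) stop("tnbc labels required")
  }
  if (is.null(colnames(expr))) colnames(expr) <- paste0("g", seq_len(ncol(expr)))
  res <- lapply(seq_len(ncol(expr)), function(j) {
    bins <- rank_and_bin(expr[, j], k)
    cc <- correlate_expression_incidence(cohort_incidence(bins, tnbc),
                                         alpha = alpha, method = method)
    data.frame(gene = colnames(expr)[j], R = cc$R, p = cc$p,
               direction = cc$direction, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, class = c("tnbc_screen", "data.frame"), k = k, alpha = alpha)
}

#' Consensus of two database screens
#'
#' Flags genes significant at `alpha` in both databases with the same
#' direction of correlation; genes significant in only one database, or with
#' opposite signs, are excluded from the consensus.
#'
#' @param res1,res2 `tnbc_screen` results sharing gene identifiers.
#' @param alpha significance level (default 0.05).
#' @return data.frame: gene, R_db1, p_db1, R_db2, p_db2, consensus (logical),
#'   direction (`"none"` unless consensus).
#' @export
cross_db_consensus <- function(res1, res2, alpha = 0.05) {
  m <- merge(as.data.frame(res1)[, c("gene", "R", "p")],
             as.data.frame(res2)[, c("gene", "R", "p")],
             by = "gene", suffixes = c("_db1", "_db2"))
  sig <- m$p_db1 < alpha & m$p_db2 < alpha
  same <- sign(m$R_db1) == sign(m$R_db2) & sign(m$R_db1) != 0
  m$consensus <- sig & same
  m$direction <- ifelse(m$consensus & m$R_db1 > 0, "positive",
                        ifelse(m$consensus, "negative", "none"))
  m[order(-m$consensus, m$p_db1), ]
}

#' Proportion with Wilson 95% confidence interval
#'
#' Incidence summary for reported contingency counts, e.g. 85 TNBC of 149
#' tumours -> 57.0%.
#'
#' @param n_pos positive count.
#' @param n_total total count (>= 1).
#' @param conf confidence level (default 0.95).
#' @return an `incidence_summary` list: percent, ci_low, ci_high (percent
#'   scale), n_pos, n_total.
#' @examples
#' incidence_summary(85, 149)
#' @export
incidence_summary <- function(n_pos, n_total, conf = 0.95) {
  if (n_total < 1) stop("n_total must be >= 1")
  if (n_pos < 0 || n_pos > n_total) stop("n_pos must lie in [0, n_total]")
  phat <- n_pos / n_total
  z <- stats::qnorm(1 - (1 - conf) / 2)
  denom <- 1 + z^2 / n_total
  centre <- (phat + z^2 / (2 * n_total)) / denom
  half <- z * sqrt(phat * (1 - phat) / n_total + z^2 / (4 * n_total^2)) / denom
  structure(list(percent = 100 * phat,
                 ci_low = 100 * max(0, centre - half),
                 ci_high = 100 * min(1, centre + half),
                 n_pos = n_pos, n_total = n_total, conf = conf),
            class = "incidence_summary")
}

#' @export
print.incidence_summary <- function(x, ...) {
  cat(sprintf("%.1f%% (%d/%d), %d%% CI [%.1f, %.1f]\n", x$percent, x$n_pos,
              x$n_total, round(100 * x$conf), x$ci_low, x$ci_high))
  invisible(x)
}

#' Simulate a patient cohort with expression-linked TNBC labels
#'
#' Per-gene log-normal expression for `n` patients. For an effect gene with
#' slope `s`, the TNBC probability follows a logit-linear link in the gene's
#' expression percentile:
#' `logit P(TNBC) = logit(base_tnbc_rate) + s * (percentile - 0.5)`;
#' null genes (slope 0) are independent of the labels. Receptor statuses are
#' consistent with the TNBC flag (TNBC = ER, PR and HER2 all negative), a
#' basal-type flag co-occurs with TNBC, and a BRCA1-mutant flag is drawn
#' independently.
#'
#' @param n number of patients.
#' @param gene_effects named numeric vector of logit slopes (0 = null gene).
#' @param base_tnbc_rate baseline TNBC probability (default 0.15).
#' @param brca1_rate probability of the BRCA1-mutant flag (default 0.1).
#' @param seed integer seed; required.
#' @return a `patient_cohort` list: `expression` (patients x genes matrix)
#'   and `clinical` (data.frame: patient_id, er, pr, her2, tnbc, basal,
#'   brca1_mutant).
#' @export
simulate_patient_cohort <- function(n, gene_effects, base_tnbc_rate = 0.15,
                                    brca1_rate = 0.1, seed) {
  if (missing(seed)) stop("'seed' is required: generators must be reproducible")
  stopifnot(n >= 1, base_tnbc_rate >= 0, base_tnbc_rate <= 1,
            length(gene_effects) >= 1)
  if (is.null(names(gene_effects)))
    names(gene_effects) <- paste0("g", seq_along(gene_effects))
  set.seed(seed)
  G <- length(gene_effects)
  expr <- matrix(stats::rlnorm(n * G), nrow = n,
                 dimnames = list(sprintf("P%05d", seq_len(n)), names(gene_effects)))
  eta <- rep(stats::qlogis(base_tnbc_rate), n)
  if (base_tnbc_rate > 0 && base_tnbc_rate < 1) {
    for (j in which(gene_effects != 0)) {
      pct <- (rank(expr[, j], ties.method = "first") - 0.5) / n
      eta <- eta + gene_effects[j] * (pct - 0.5)
    }
    tnbc <- stats::runif(n) < stats::plogis(eta)
  } else {
    tnbc <- rep(base_tnbc_rate == 1, n)
  }
  # receptor triple consistent with the TNBC flag
  er <- ifelse(tnbc, "neg", NA)
  pr <- ifelse(tnbc, "neg", NA)
  her2 <- ifelse(tnbc, "neg", NA)
  non <- which(!tnbc)
  if (length(non)) {
    er[non] <- sample(c("pos", "neg"), length(non), replace = TRUE, prob = c(0.7, 0.3))
    pr[non] <- sample(c("pos", "neg"), length(non), replace = TRUE, prob = c(0.6, 0.4))
    her2[non] <- sample(c("pos", "neg"), length(non), replace = TRUE, prob = c(0.2, 0.8))
    allneg <- non[er[non] == "neg" & pr[non] == "neg" & her2[non] == "neg"]
    if (length(allneg)) {
      flip <- sample(c("er", "pr", "her2"), length(allneg), replace = TRUE)
      er[allneg[flip == "er"]] <- "pos"
      pr[allneg[flip == "pr"]] <- "pos"
      her2[allneg[flip == "her2"]] <- "pos"
    }
  }
  basal <- stats::runif(n) < ifelse(tnbc, 0.75, 0.08)
  clinical <- data.frame(patient_id = rownames(expr), er = er, pr = pr,
                         her2 = her2, tnbc = tnbc, basal = basal,
                         brca1_mutant = stats::runif(n) < brca1_rate,
                         stringsAsFactors = FALSE)
  structure(list(expression = expr, clinical = clinical),
            class = "patient_cohort")
}
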
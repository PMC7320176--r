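#' Generate a synthetic gene catalog
#'
#' Builds a set of non-overlapping gene models (span, strand, exon structure)
#' laid out on a small set of chromosomes. The catalog is the annotation
#' backbone for the insertion-site analysis: every gene is later scored over
#' its gene body extended by an upstream promoter window (3 kb by default),
#' mirroring how SB screen hits are annotated to genes.
#'
#' Genes are spread over chromosomes proportionally to chromosome length and
#' placed in disjoint slots so that gene spans plus their upstream windows
#' never overlap chromosome ends. Exons are numbered in transcription order:
#' exon 1 is leftmost for `+` genes and rightmost for `-` genes.
#'
#' @param n_genes number of genes to generate.
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param gene_length length-2 numeric range (min, max) of gene spans in bp.
#' @param n_exons length-2 integer range of exons per gene.
#' @param seed integer seed; required for reproducibility.
#' @return an object of class `gene_catalog`: a list with elements `genes`
#'   (data.frame: gene_id, chrom, strand, start, end), `exons` (data.frame:
#'   gene_id, exon, start, end — `exon` in transcription order) and
#'   `chrom_lengths`.
#' @examples
#' cat <- make_gene_catalog(n_genes = 10, seed = 1)
#' head(cat$genes)
#' @export
make_gene_catalog <- function(n_genes = 60,
                              chrom_lengths = stats::setNames(rep(25e6, 5), paste0("chr", 1:5)),
                              gene_length = c(10e3, 30e3),
                              n_exons = c(8L, 12L),
                              seed) {
  if (missing(seed)) stop("'seed' is required: generators must be reproducible")
  stopifnot(length(chrom_lengths) >= 1, all(chrom_lengths > 0),
            length(gene_length) == 2, gene_length[1] <= gene_length[2],
            gene_length[1] >= 50,
            length(n_exons) == 2, n_exons[1] >= 1, n_exons[1] <= n_exons[2])
  if (is.null(names(chrom_lengths)) || anyDuplicated(names(chrom_lengths)))
    stop("chrom_lengths must have unique names")
  n_genes <- as.integer(n_genes)
  if (n_genes < 0) stop("n_genes must be >= 0")
  set.seed(seed)

  empty <- function() {
    structure(list(
      genes = data.frame(gene_id = character(), chrom = character(),
                         strand = character(), start = integer(), end = integer(),
                         stringsAsFactors = FALSE),
      exons = data.frame(gene_id = character(), exon = integer(),
                         start = integer(), end = integer(), stringsAsFactors = FALSE),
      chrom_lengths = chrom_lengths
    ), class = "gene_catalog")
  }
  if (n_genes == 0L) return(empty())

  # genes per chromosome, proportional to length (largest-remainder rounding)
  share <- chrom_lengths / sum(chrom_lengths) * n_genes
  n_per <- floor(share)
  rem <- n_genes - sum(n_per)
  if (rem > 0) {
    top <- order(share - n_per, decreasing = TRUE)[seq_len(rem)]
    n_per[top] <- n_per[top] + 1
  }

  margin <- 3000  # keep upstream windows on-chromosome
  genes <- list(); exons <- list(); gid <- 0L
  for (ci in seq_along(chrom_lengths)) {
    m <- n_per[ci]
    if (m == 0) next
    len <- chrom_lengths[ci]
    if (m * (gene_length[2] + 2 * margin) > len)
      stop("infeasible packing: total gene span exceeds chromosome length on ",
           names(chrom_lengths)[ci])
    slot <- floor(len / m)
    for (j in seq_len(m)) {
      gid <- gid + 1L
      glen <- round(stats::runif(1, gene_length[1], gene_length[2]))
      lo <- (j - 1L) * slot + margin + 1
      hi <- j * slot - margin - glen
      start <- floor(stats::runif(1, lo, hi + 1))
      end <- start + glen - 1L
      strand <- sample(c("+", "-"), 1L)
      nx_range <- seq(n_exons[1], n_exons[2])
      nx <- nx_range[sample.int(length(nx_range), 1L)]
      ex <- .make_exons(start, end, nx, strand)
      id <- sprintf("gene%03d", gid)
      genes[[gid]] <- data.frame(gene_id = id, chrom = names(chrom_lengths)[ci],
                                 strand = strand, start = start, end = end,
                                 stringsAsFactors = FALSE)
      ex$gene_id <- id
      exons[[gid]] <- ex[, c("gene_id", "exon", "start", "end")]
    }
  }
  out <- structure(list(genes = do.call(rbind, genes),
                        exons = do.call(rbind, exons),
                        chrom_lengths = chrom_lengths),
                   class = "gene_catalog")
  rownames(out$genes) <- rownames(out$exons) <- NULL
  validate_gene_catalog(out)
  out
}

# Split [start, end] into nx exons separated by introns; exon 1 is the
# 5'-most exon in transcription order (rightmost for '-' genes).
.make_exons <- function(start, end, nx, strand) {
  glen <- end - start + 1
  nseg <- 2L * nx - 1L
  w <- stats::runif(nseg, 0.5, 1.5)
  seg <- pmax(1L, floor(w / sum(w) * (glen - nseg)) + 1L)
  seg[nseg] <- glen - sum(seg[-nseg])
  stopifnot(seg[nseg] >= 1)
  ends <- start - 1L + cumsum(seg)
  starts <- c(start, ends[-nseg] + 1L)
  is_exon <- seq_len(nseg) %% 2L == 1L
  ex <- data.frame(start = starts[is_exon], end = ends[is_exon])
  ex$exon <- if (strand == "+") seq_len(nx) else rev(seq_len(nx))
  ex
}

#' Validate a gene catalog
#'
#' Checks the structural invariants of a `gene_catalog`: gene spans within
#' chromosome bounds, start <= end, exons strictly ordered and non-overlapping
#' inside the gene span, positive exon lengths, and exon numbering that is
#' consecutive 1..n in transcription order.
#'
#' @param catalog a `gene_catalog`.
#' @return invisibly `TRUE`; stops with a message on the first violation.
#' @export
validate_gene_catalog <- function(catalog) {
  stopifnot(inherits(catalog, "gene_catalog"))
  g <- catalog$genes; e <- catalog$exons
  if (nrow(g) == 0) return(invisible(TRUE))
  if (anyDuplicated(g$gene_id)) stop("duplicate gene_id")
  if (!all(g$chrom %in% names(catalog$chrom_lengths))) stop("gene on unknown chromosome")
  if (!all(g$start >= 1 & g$start <= g$end)) stop("invalid gene span")
  if (!all(g$end <= catalog$chrom_lengths[g$chrom])) stop("gene exceeds chromosome length")
  if (!all(g$strand %in% c("+", "-"))) stop("invalid strand")
  for (i in seq_len(nrow(g))) {
    ex <- e[e$gene_id == g$gene_id[i], ]
    ex <- ex[order(ex$start), ]
    if (nrow(ex) == 0) stop("gene without exons: ", g$gene_id[i])
    if (!all(ex$end >= ex$start)) stop("exon with non-positive length: ", g$gene_id[i])
    if (ex$start[1] < g$start[i] || ex$end[nrow(ex)] > g$end[i])
      stop("exon outside gene span: ", g$gene_id[i])
    if (nrow(ex) > 1 && any(ex$start[-1] <= ex$end[-nrow(ex)]))
      stop("overlapping exons: ", g$gene_id[i])
    expected <- if (g$strand[i] == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
    if (!identical(as.integer(ex$exon), as.integer(expected)))
      stop("exon numbering not in transcription order: ", g$gene_id[i])
  }
  # genes non-overlapping within chromosome
  for (chr in unique(g$chrom)) {
    gg <- g[g$chrom == chr, ]
    gg <- gg[order(gg$start), ]
    if (nrow(gg) > 1 && any(gg$start[-1] <= gg$end[-nrow(gg)]))
      stop("overlapping genes on ", chr)
  }
  invisible(TRUE)
}

#' Gene regions extended by an upstream window
#'
#' Returns the annotation window used throughout the CIS analysis: the gene
#' body extended by `upstream` bp on the promoter side (before `start` for
#' `+` genes, after `end` for `-` genes), clipped to chromosome bounds.
#'
#' @param catalog a `gene_catalog`, or a data.frame with columns
#'   gene_id, chrom, strand, start, end.
#' @param upstream upstream extension in bp (default 3000).
#' @return data.frame: gene_id, chrom, strand, start, end (extended), width.
#' @export
gene_regions <- function(catalog, upstream = 3000) {
  g <- if (inherits(catalog, "gene_catalog")) catalog$genes else catalog
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end") %in% names(g)),
            upstream >= 0)
  start <- ifelse(g$strand == "+", g$start - upstream, g$start)
  end <- ifelse(g$strand == "+", g$end, g$end + upstream)
  start <- pmax(1, start)
  if (inherits(catalog, "gene_catalog"))
    end <- pmin(end, unname(catalog$chrom_lengths[g$chrom]))
  data.frame(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
             start = start, end = end, width = end - start + 1,
             stringsAsFactors = FALSE)
}

#' @export
print.gene_catalog <- function(x, ...) {
  cat("Gene catalog:", nrow(x$genes), "genes on",
      length(x$chrom_lengths), "chromosomes (",
      format(sum(x$chrom_lengths), big.mark = ","), "bp )\n")
  invisible(x)
}

#' Generate a random genome sequence
#'
#' Uniform-composition random chromosomes for sequence-backed simulations
#' (junction-read emission and read mapping). SB insertions require TA
#' dinucleotides; random sequence provides them at roughly 1/16 density.
#'
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param seed integer seed; required.
#' @return a [Biostrings::DNAStringSet] named by chromosome.
#' @export
make_genome <- function(chrom_lengths, seed) {
  if (missing(seed)) stop("'seed' is required: generators must be reproducible")
  stopifnot(all(chrom_lengths > 0), !is.null(names(chrom_lengths)))
  set.seed(seed)
  seqs <- vapply(chrom_lengths, function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  }, character(1))
  Biostrings::DNAStringSet(stats::setNames(seqs, names(chrom_lengths)))
}

# 1-based positions of the T of every TA dinucleotide on a chromosome
ta_positions <- function(genome, chrom) {
  BiocGenerics::start(Biostrings::matchPattern("TA", genome[[chrom]]))
}

#' Write / read a gene catalog as plain TSV files
#'
#' Serializes a catalog to `<prefix>.genes.tsv`, `<prefix>.exons.tsv` and
#' `<prefix>.chroms.tsv` (a GTF-lite representation usable as the external
#' gene-model interface).
#'
#' @param catalog a `gene_catalog`.
#' @param prefix file path prefix.
#' @return invisibly `prefix`.
#' @export
write_catalog <- function(catalog, prefix) {
  stopifnot(inherits(catalog, "gene_catalog"))
  utils::write.table(catalog$genes, paste0(prefix, ".genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(catalog$exons, paste0(prefix, ".exons.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(chrom = names(catalog$chrom_lengths),
                                length = unname(catalog$chrom_lengths)),
                     paste0(prefix, ".chroms.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(prefix) {
  for (suf in c(".genes.tsv", ".exons.tsv", ".chroms.tsv"))
    if (!file.exists(paste0(prefix, suf)))
      stop("input file not found: ", paste0(prefix, suf))
  chroms <- utils::read.table(paste0(prefix, ".chroms.tsv"), sep = "\t",
                              header = TRUE, stringsAsFactors = FALSE)
  out <- structure(list(
    genes = utils::read.table(paste0(prefix, ".genes.tsv"), sep = "\t",
                              header = TRUE, stringsAsFactors = FALSE),
    exons = utils::read.table(paste0(prefix, ".exons.tsv"), sep = "\t",
                              header = TRUE, stringsAsFactors = FALSE),
    chrom_lengths = stats::setNames(chroms$length, chroms$chrom)),
    class = "gene_catalog")
  validate_gene_catalog(out)
  out
}
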
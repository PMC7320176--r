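#' Configure junction-read emission
#'
#' @param adapters an [adapter_config()] providing the IRDR ends and linker.
#' @param read_length read length in nt (default 150, single-end).
#' @param flank length-2 range of the genomic flank in nt; the flank must be
#'   short enough that the linker still falls inside the read.
#' @param error_rate per-base substitution error probability.
#' @param contaminant_fraction fraction of reads replaced by random sequence
#'   lacking the transposon end (library contaminants).
#' @param reads_per_site number of reads emitted per insertion site.
#' @param seed integer seed; required.
#' @return a `read_config` list.
#' @export
read_config <- function(adapters = adapter_config(), read_length = 150L,
                        flank = c(40L, 90L), error_rate = 0,
                        contaminant_fraction = 0, reads_per_site = 1L, seed) {
  if (missing(seed)) stop("'seed' is required: generators must be reproducible")
  stopifnot(inherits(adapters, "adapter_config"),
            flank[1] >= 20, flank[1] <= flank[2],
            error_rate >= 0, error_rate < 1,
            contaminant_fraction >= 0, contaminant_fraction <= 1,
            reads_per_site >= 1)
  max_irdr <- max(nchar(adapters$irdr_l), nchar(adapters$irdr_r))
  if (max_irdr + flank[2] + nchar(adapters$linker) > read_length)
    stop("read_length too short for IRDR + flank + linker")
  structure(list(adapters = adapters, read_length = as.integer(read_length),
                 flank = as.integer(flank), error_rate = error_rate,
                 contaminant_fraction = contaminant_fraction,
                 reads_per_site = as.integer(reads_per_site),
                 seed = as.integer(seed)),
            class = "read_config")
}

#' Emit splinkerette junction reads for simulated insertions
#'
#' Each read is the transposon IRDR end (left or right, chosen at random),
#' followed by the genomic flank starting at the TA junction, followed by the
#' splinkerette linker and random filler up to the read length. The strand
#' the flank is read from follows the fixed orientation convention shared
#' with [locate_insertions()]: the flank runs rightward on the plus strand
#' when (IRDR end is `R`) equals (transposon orientation is `+`), leftward on
#' the minus strand otherwise. Substitution errors and transposon-less
#' contaminant reads are added at the configured rates.
#'
#' Every insertion must sit at a TA dinucleotide of the reference (`pos` at
#' the T); a non-TA position is a model violation and raises an error.
#'
#' @param insertions an `insertion_table` (chrom, pos, transposon_orient,
#'   tumour_id, ...).
#' @param genome reference [Biostrings::DNAStringSet].
#' @param config a [read_config()].
#' @return a `junction_reads` data.frame: read_id, seq, tumour_id, strain,
#'   cre; attribute `truth` holds the per-read planted site (chrom, pos,
#'   orientation, IRDR end, contaminant flag) for recovery scoring.
#' @export
emit_reads <- function(insertions, genome, config) {
  stopifnot(is.data.frame(insertions), inherits(config, "read_config"),
            all(insertions$chrom %in% names(genome)))
  set.seed(config$seed)
  ad <- config$adapters
  fwd <- stats::setNames(as.character(genome), names(genome))
  chrom_len <- nchar(fwd)

  idx <- rep(seq_len(nrow(insertions)), each = config$reads_per_site)
  n <- length(idx)
  ins <- insertions[idx, , drop = FALSE]

  # model check: SB integrates at TA
  ta <- substr(fwd[ins$chrom], ins$pos, ins$pos + 1L)
  if (any(ta != "TA"))
    stop("insertion not at a TA dinucleotide in the reference (first offender: ",
         ins$chrom[ta != "TA"][1], ":", ins$pos[ta != "TA"][1], ")")

  irdr_end <- sample(c("L", "R"), n, replace = TRUE)
  flank_range <- seq(config$flank[1], config$flank[2])
  flank_len <- flank_range[sample.int(length(flank_range), n, replace = TRUE)]
  read_strand <- ifelse((irdr_end == "R") == (ins$transposon_orient == "+"), "+", "-")

  lo <- ifelse(read_strand == "+", ins$pos, ins$pos - flank_len + 2L)
  hi <- ifelse(read_strand == "+", ins$pos + flank_len - 1L, ins$pos + 1L)
  if (any(lo < 1 | hi > chrom_len[ins$chrom]))
    stop("insertion too close to a chromosome end for the configured flank")
  flank <- substr(fwd[ins$chrom], lo, hi)
  rc <- read_strand == "-"
  if (any(rc))
    flank[rc] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(flank[rc])))

  irdr_seq <- ifelse(irdr_end == "R", ad$irdr_r, ad$irdr_l)
  body <- paste0(irdr_seq, flank, ad$linker)
  fill <- config$read_length - nchar(body)
  filler <- vapply(fill, function(k) {
    if (k <= 0) "" else paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                              collapse = "")
  }, character(1))
  seqs <- substr(paste0(body, filler), 1L, config$read_length)

  contaminant <- stats::runif(n) < config$contaminant_fraction
  if (any(contaminant)) {
    seqs[contaminant] <- vapply(which(contaminant), function(i) {
      paste(sample(c("A", "C", "G", "T"), config$read_length, replace = TRUE),
            collapse = "")
    }, character(1))
  }
  if (config$error_rate > 0) {
    seqs <- vapply(seqs, function(s) {
      b <- strsplit(s, "", fixed = TRUE)[[1]]
      hit <- stats::runif(length(b)) < config$error_rate
      if (any(hit)) {
        b[hit] <- vapply(b[hit], function(x)
          sample(setdiff(c("A", "C", "G", "T"), x), 1L), character(1))
      }
      paste(b, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }

  out <- data.frame(read_id = sprintf("r%06d", seq_len(n)), seq = seqs,
                    stringsAsFactors = FALSE)
  for (col in intersect(c("tumour_id", "strain", "cre"), names(ins)))
    out[[col]] <- ins[[col]]
  attr(out, "truth") <- data.frame(
    read_id = out$read_id, chrom = ins$chrom, pos = ins$pos,
    transposon_orient = ins$transposon_orient, irdr_end = irdr_end,
    read_strand = read_strand, contaminant = contaminant,
    stringsAsFactors = FALSE)
  class(out) <- c("junction_reads", "data.frame")
  out
}

#' Write reads to FASTQ
#'
#' @param reads a `junction_reads` data.frame (or any data.frame with
#'   `read_id` and `seq`).
#' @param path output FASTQ path.
#' @return invisibly `path`.
#' @export
write_fastq <- function(reads, path) {
  df <- .as_reads_df(reads)
  x <- Biostrings::DNAStringSet(stats::setNames(df$seq, df$read_id))
  q <- Biostrings::BStringSet(strrep("I", nchar(df$seq)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ path.
#' @return data.frame with columns read_id, seq.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = names(x), seq = as.character(x), stringsAsFactors = FALSE)
}

#' Write / read an insertion table as TSV
#'
#' The TSV schema is chrom, pos, transposon_orient, tumour_id, strain, cre,
#' support. When the table carries a ground-truth sidecar (simulated data),
#' `write_insertions()` writes it next to the table as `<path>.truth.tsv`.
#'
#' @param insertions an `insertion_table`.
#' @param path output TSV path.
#' @return invisibly `path`.
#' @export
write_insertions <- function(insertions, path) {
  utils::write.table(as.data.frame(insertions), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- attr(insertions, "truth")
  if (!is.null(truth))
    utils::write.table(truth, paste0(path, ".truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  roster <- attr(insertions, "tumours")
  if (!is.null(roster))
    utils::write.table(roster, paste0(path, ".tumours.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_insertions
#' @export
read_insertions <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c(tumour_id = "character",
                                         strain = "character"),
                          stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "transposon_orient", "tumour_id")
  if (!all(need %in% names(df)))
    stop("insertion table missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  rosterf <- paste0(path, ".tumours.tsv")
  if (file.exists(rosterf))
    attr(df, "tumours") <- utils::read.table(rosterf, sep = "\t", header = TRUE,
                                             colClasses = "character",
                                             stringsAsFactors = FALSE)
  class(df) <- c("insertion_table", "data.frame")
  df
}

#' Export insertion sites as BED6
#'
#' BED uses 0-based half-open intervals: start = pos - 1, end = pos + 1 (the
#' TA dinucleotide), name = tumour_id, strand = transposon orientation.
#'
#' @param insertions an `insertion_table`.
#' @param path output BED path.
#' @return invisibly `path`.
#' @export
write_bed <- function(insertions, path) {
  df <- as.data.frame(insertions)
  bed <- data.frame(chrom = df$chrom, start = df$pos - 1L, end = df$pos + 1L,
                    name = df$tumour_id,
                    score = if (is.null(df$support)) 0L else df$support,
                    strand = df$transposon_orient)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
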
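#' Adapter and transposon-end sequences for junction reads
#'
#' Junction reads from a splinkerette library have a fixed layout:
#' transposon IRDR end (5'), then the genomic flank starting at the TA
#' integration site, then the splinkerette linker (3'). The same configuration
#' object drives both the read simulator and the trimmer so the two stay
#' consistent. Matching tolerates up to `max_mismatch_frac` of the matched
#' sequence length in substitutions.
#'
#' @param irdr_l,irdr_r transposon left/right IRDR end sequences expected as
#'   the read prefix.
#' @param linker splinkerette linker sequence expected downstream of the
#'   genomic flank.
#' @param max_mismatch_frac mismatch tolerance as a fraction of the matched
#'   sequence length (default 0.1).
#' @param min_genomic minimum genomic-segment length retained after trimming
#'   (default 20 nt; shorter reads are discarded).
#' @return an `adapter_config` list.
#' @export
adapter_config <- function(irdr_l = "CTGGAATTTTCCAAGCTGTTTAAAGGCACA",
                           irdr_r = "GTGTATGTAAACTTCCGACTTCAACTGTAT",
                           linker = "GTCCCTTAAGCGGAGCCC",
                           max_mismatch_frac = 0.1,
                           min_genomic = 20L) {
  stopifnot(nchar(irdr_l) >= 10, nchar(irdr_r) >= 10, nchar(linker) >= 8,
            max_mismatch_frac >= 0, max_mismatch_frac < 1, min_genomic >= 1)
  structure(list(irdr_l = toupper(irdr_l), irdr_r = toupper(irdr_r),
                 linker = toupper(linker),
                 max_mismatch_frac = max_mismatch_frac,
                 min_genomic = as.integer(min_genomic)),
            class = "adapter_config")
}

# Hamming distance between two equal-length strings
.hamming <- function(a, b) sum(charToRaw(a) != charToRaw(b))

# leftmost occurrence of `pattern` in `x` with <= tol mismatches, or NA
.find_tolerant <- function(x, pattern, tol) {
  np <- nchar(pattern); nx <- nchar(x)
  if (nx < np) return(NA_integer_)
  hit <- regexpr(pattern, x, fixed = TRUE)
  if (hit > 0) return(as.integer(hit))
  if (tol == 0) return(NA_integer_)
  for (s in seq_len(nx - np + 1L)) {
    if (.hamming(substr(x, s, s + np - 1L), pattern) <= tol) return(s)
  }
  NA_integer_
}

#' Trim transposon and linker sequence from junction reads
#'
#' Locates a transposon IRDR end as the read prefix (within the mismatch
#' tolerance), then the splinkerette linker downstream, and returns the
#' intervening genomic segment. Reads are rejected, with a reason, when no
#' IRDR prefix matches (`no_transposon`), no linker is found (`no_adapter`),
#' or the genomic segment is shorter than `min_genomic` (`too_short`).
#'
#' @param reads a character vector of read sequences, a data.frame with
#'   columns `read_id` and `seq` (extra columns such as `tumour_id` are
#'   carried through), or a path to a FASTQ file.
#' @param adapters an [adapter_config()].
#' @return a `trimmed_reads` data.frame: read_id, genomic_seq, irdr_end
#'   (`"L"`/`"R"`), reject_reason (`NA` when accepted), plus carried columns.
#'   Rejection reasons partition all non-accepted reads.
#' @export
trim_reads <- function(reads, adapters = adapter_config()) {
  stopifnot(inherits(adapters, "adapter_config"))
  df <- .as_reads_df(reads)
  n <- nrow(df)
  seqs <- toupper(df$seq)
  nl <- nchar(adapters$irdr_l); nr <- nchar(adapters$irdr_r)
  tol_l <- floor(adapters$max_mismatch_frac * nl)
  tol_r <- floor(adapters$max_mismatch_frac * nr)
  tol_k <- floor(adapters$max_mismatch_frac * nchar(adapters$linker))

  irdr_end <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  genomic <- rep(NA_character_, n)

  pre_l <- substr(seqs, 1L, nl)
  pre_r <- substr(seqs, 1L, nr)
  exact_l <- pre_l == adapters$irdr_l
  exact_r <- pre_r == adapters$irdr_r
  for (i in seq_len(n)) {
    if (exact_r[i]) { irdr_end[i] <- "R"; next }
    if (exact_l[i]) { irdr_end[i] <- "L"; next }
    ml <- if (nchar(seqs[i]) >= nl) .hamming(pre_l[i], adapters$irdr_l) else Inf
    mr <- if (nchar(seqs[i]) >= nr) .hamming(pre_r[i], adapters$irdr_r) else Inf
    if (mr <= tol_r && mr <= ml) irdr_end[i] <- "R"
    else if (ml <= tol_l) irdr_end[i] <- "L"
    else reason[i] <- "no_transposon"
  }

  for (i in seq_len(n)) {
    if (!is.na(reason[i])) next
    off <- if (irdr_end[i] == "R") nr else nl
    rem <- substr(seqs[i], off + 1L, nchar(seqs[i]))
    hit <- .find_tolerant(rem, adapters$linker, tol_k)
    if (is.na(hit)) { reason[i] <- "no_adapter"; next }
    g <- substr(rem, 1L, hit - 1L)
    if (nchar(g) < adapters$min_genomic) { reason[i] <- "too_short"; next }
    genomic[i] <- g
  }

  out <- data.frame(read_id = df$read_id, genomic_seq = genomic,
                    irdr_end = irdr_end, reject_reason = reason,
                    stringsAsFactors = FALSE)
  extra <- setdiff(names(df), c("read_id", "seq"))
  for (col in extra) out[[col]] <- df[[col]]
  class(out) <- c("trimmed_reads", "data.frame")
  out
}

.as_reads_df <- function(reads) {
  if (is.character(reads) && length(reads) == 1 && file.exists(reads))
    return(read_fastq(reads))
  if (is.character(reads)) {
    ids <- names(reads)
    if (is.null(ids)) ids <- sprintf("r%06d", seq_along(reads))
    return(data.frame(read_id = ids, seq = unname(reads), stringsAsFactors = FALSE))
  }
  stopifnot(is.data.frame(reads), all(c("read_id", "seq") %in% names(reads)))
  as.data.frame(reads)
}

#' Map trimmed junction reads to insertion sites
#'
#' Locates each genomic segment on a reference by exact lookup of its first
#' 25-nt seed, then extends the hit and accepts it when the full segment has
#' at most `max_mismatch` substitutions. The insertion position is reported
#' at the T of the TA dinucleotide adjacent to the transposon junction
#' (1-based, plus-strand coordinates), and the transposon orientation is
#' derived from which IRDR end was read and the mapped strand via a fixed
#' convention: orientation is `+` exactly when (IRDR end is `R`) equals
#' (mapped strand is `+`).
#'
#' Seeds hitting two or more loci are rejected as `ambiguous_map`; segments
#' without an acceptable hit are rejected as `too_many_mismatches`.
#'
#' @param trimmed a [trim_reads()] result (rejected reads are carried through
#'   unchanged).
#' @param genome reference [Biostrings::DNAStringSet].
#' @param seed_length exact-match seed length (default 25).
#' @param max_mismatch maximum substitutions over the full segment (default 3).
#' @return a `located_reads` data.frame: the trimmed columns plus chrom, pos,
#'   transposon_orient, mismatches, with reject_reason updated.
#' @export
locate_insertions <- function(trimmed, genome, seed_length = 25L, max_mismatch = 3L) {
  stopifnot(is.data.frame(trimmed),
            all(c("genomic_seq", "irdr_end", "reject_reason") %in% names(trimmed)))
  n <- nrow(trimmed)
  out <- as.data.frame(trimmed)
  out$chrom <- NA_character_; out$pos <- NA_integer_
  out$transposon_orient <- NA_character_; out$mismatches <- NA_integer_
  ok <- which(is.na(out$reject_reason))
  if (length(ok) == 0) { class(out) <- c("located_reads", "data.frame"); return(out) }

  chrom_names <- names(genome)
  fwd <- stats::setNames(as.character(genome), chrom_names)
  rev <- stats::setNames(as.character(Biostrings::reverseComplement(genome)), chrom_names)
  chrom_len <- stats::setNames(nchar(fwd), chrom_names)

  segs <- out$genomic_seq[ok]
  seg_len <- nchar(segs)
  use_pdict <- seg_len >= seed_length
  seeds <- substr(segs, 1L, ifelse(use_pdict, seed_length, seg_len))

  # hits[[j]] collects (chrom, strand, start-in-strand-coords) per accepted read
  hit_chrom <- vector("list", length(ok))
  hit_strand <- vector("list", length(ok))
  hit_start <- vector("list", length(ok))
  add_hits <- function(j, ch, strand, starts) {
    if (length(starts) == 0) return()
    hit_chrom[[j]] <<- c(hit_chrom[[j]], rep(ch, length(starts)))
    hit_strand[[j]] <<- c(hit_strand[[j]], rep(strand, length(starts)))
    hit_start[[j]] <<- c(hit_start[[j]], starts)
  }

  if (any(use_pdict)) {
    jj <- which(use_pdict)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds[jj]))
    for (ch in chrom_names) {
      for (strand in c("+", "-")) {
        subj <- Biostrings::DNAString(if (strand == "+") fwd[[ch]] else rev[[ch]])
        m <- Biostrings::matchPDict(pd, subj)
        st <- BiocGenerics::start(m)
        for (q in which(lengths(st) > 0)) add_hits(jj[q], ch, strand, st[[q]])
      }
    }
  }
  for (j in which(!use_pdict)) {
    pat <- Biostrings::DNAString(seeds[j])
    for (ch in chrom_names) {
      add_hits(j, ch, "+", BiocGenerics::start(Biostrings::matchPattern(pat, Biostrings::DNAString(fwd[[ch]]))))
      add_hits(j, ch, "-", BiocGenerics::start(Biostrings::matchPattern(pat, Biostrings::DNAString(rev[[ch]]))))
    }
  }

  for (j in seq_along(ok)) {
    i <- ok[j]
    nh <- length(hit_start[[j]])
    if (nh == 0L) { out$reject_reason[i] <- "too_many_mismatches"; next }
    if (nh >= 2L) { out$reject_reason[i] <- "ambiguous_map"; next }
    ch <- hit_chrom[[j]]; strand <- hit_strand[[j]]; s <- hit_start[[j]]
    L <- seg_len[j]
    ref_str <- if (strand == "+") fwd[[ch]] else rev[[ch]]
    if (s + L - 1L > chrom_len[[ch]]) { out$reject_reason[i] <- "too_many_mismatches"; next }
    mm <- .hamming(substr(ref_str, s, s + L - 1L), segs[j])
    if (mm > max_mismatch) { out$reject_reason[i] <- "too_many_mismatches"; next }
    pos <- if (strand == "+") s else (chrom_len[[ch]] - s + 1L) - 1L
    out$chrom[i] <- ch
    out$pos[i] <- pos
    out$mismatches[i] <- mm
    out$transposon_orient[i] <-
      if ((out$irdr_end[i] == "R") == (strand == "+")) "+" else "-"
  }
  class(out) <- c("located_reads", "data.frame")
  out
}

#' Collapse redundant insertion sites
#'
#' Sites identical in (chrom, pos, transposon_orient, tumour_id) are collapsed
#' into one record whose `support` is the summed read count. Sites from
#' different tumours are never merged. An optional merge window collapses
#' sites within `merge_window` bp of each other (same chromosome, orientation
#' and tumour); the default window of 0 keeps 1-bp-apart sites distinct.
#'
#' @param sites data.frame with columns chrom, pos, transposon_orient,
#'   tumour_id (and optionally support, strain, cre).
#' @param merge_window merge distance in bp (default 0 = exact position).
#' @return a deduplicated `insertion_table` data.frame sorted by chrom, pos.
#' @export
dedupe_sites <- function(sites, merge_window = 0L) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "transposon_orient", "tumour_id") %in% names(sites)))
  df <- as.data.frame(sites)
  if (is.null(df$support)) df$support <- 1L
  if (nrow(df) == 0) { class(df) <- c("insertion_table", "data.frame"); return(df) }
  if (merge_window > 0) {
    grp <- paste(df$chrom, df$transposon_orient, df$tumour_id, sep = "\r")
    o <- order(grp, df$pos)
    df <- df[o, , drop = FALSE]
    grp <- grp[o]
    new_cluster <- c(TRUE, grp[-1] != grp[-nrow(df)] | diff(df$pos) > merge_window)
    cl <- cumsum(new_cluster)
    df$pos <- stats::ave(df$pos, cl, FUN = min)
  }
  key <- paste(df$chrom, df$pos, df$transposon_orient, df$tumour_id, sep = "\r")
  supp <- rowsum(as.numeric(df$support), key)
  first <- !duplicated(key)
  out <- df[first, , drop = FALSE]
  out$support <- as.integer(supp[match(key[first], rownames(supp)), 1])
  out <- out[order(out$chrom, out$pos, out$transposon_orient, out$tumour_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("insertion_table", "data.frame")
  out
}

#' Tabulate read-fate counts for a processing stage
#'
#' Counts accepted reads and every rejection reason; the counts always sum to
#' the number of input reads (rejection reasons partition the non-accepted
#' reads).
#'
#' @param x a `trimmed_reads` or `located_reads` data.frame.
#' @return named integer vector with `accepted` and one entry per reason.
#' @export
rejection_summary <- function(x) {
  stopifnot(is.data.frame(x), "reject_reason" %in% names(x))
  r <- x$reject_reason
  c(accepted = sum(is.na(r)), table(r[!is.na(r)]))
}
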
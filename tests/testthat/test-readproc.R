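ad <- adapter_config()
rand_dna <- function(n, seed) {
  set.seed(seed); paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                        collapse = "")
}

test_that("trimming rejects reads without a transposon end, linker, or enough genomic sequence", {
  genomic <- rand_dna(40, 1)
  good <- paste0(ad$irdr_r, genomic, ad$linker, rand_dna(30, 2))
  no_tn <- paste0(rand_dna(30, 3), genomic, ad$linker)
  no_lk <- paste0(ad$irdr_l, rand_dna(100, 4))
  short <- paste0(ad$irdr_r, substr(genomic, 1, 19), ad$linker, rand_dna(40, 5))
  just20 <- paste0(ad$irdr_r, substr(genomic, 1, 20), ad$linker, rand_dna(40, 5))
  tr <- trim_reads(c(good, no_tn, no_lk, short, just20, ""))
  expect_equal(tr$reject_reason,
               c(NA, "no_transposon", "no_adapter", "too_short", NA, "no_transposon"))
  expect_equal(tr$genomic_seq[1], genomic)
  expect_equal(tr$irdr_end[1], "R")
  expect_equal(nchar(tr$genomic_seq[5]), 20)
  # reasons partition the non-accepted reads
  s <- rejection_summary(tr)
  expect_equal(sum(s), nrow(tr))
})

test_that("adapter matching tolerates 10% mismatches and no more", {
  genomic <- rand_dna(40, 6)
  mutate <- function(s, at) {
    for (i in at) substr(s, i, i) <- c(A = "C", C = "G", G = "T", T = "A")[substr(s, i, i)]
    s
  }
  irdr3 <- mutate(ad$irdr_l, c(2, 11, 25))   # 3 of 30 = tolerance boundary
  irdr4 <- mutate(ad$irdr_l, c(2, 11, 25, 28))
  tr <- trim_reads(c(paste0(irdr3, genomic, ad$linker),
                     paste0(irdr4, genomic, ad$linker)))
  expect_equal(tr$reject_reason, c(NA, "no_transposon"))
  expect_equal(tr$irdr_end[1], "L")
})

test_that("emitted reads round-trip exactly through trim and locate at zero error", {
  w <- small_world(seed = 201, n_tumours = 5, background_rate = 25)
  ins <- simulate_screen(w$catalog, w$config, genome = w$genome)
  reads <- emit_reads(ins, w$genome, read_config(seed = 204))
  truth <- attr(reads, "truth")
  tr <- trim_reads(reads)
  expect_true(all(is.na(tr$reject_reason)))
  expect_equal(tr$irdr_end, truth$irdr_end)
  loc <- locate_insertions(tr, w$genome)
  expect_true(all(is.na(loc$reject_reason)))
  expect_equal(loc$chrom, truth$chrom)
  expect_equal(loc$pos, truth$pos)
  expect_equal(loc$transposon_orient, truth$transposon_orient)
  rec <- dedupe_sites(loc[is.na(loc$reject_reason), ])
  expect_gte(mean(site_key(rec) %in% site_key(ins)), 0.99)
  expect_equal(sum(!site_key(rec) %in% site_key(ins)), 0)
})

test_that("contaminant-free read sets pass trimming completely", {
  w <- small_world(seed = 211, n_tumours = 3, background_rate = 10)
  ins <- simulate_screen(w$catalog, w$config, genome = w$genome)
  reads <- emit_reads(ins, w$genome,
                      read_config(contaminant_fraction = 0, seed = 214))
  expect_true(all(startsWith(reads$seq, ad$irdr_l) | startsWith(reads$seq, ad$irdr_r)))
  expect_equal(unname(rejection_summary(trim_reads(reads))["accepted"]), nrow(reads))
})

test_that("contaminant reads are rejected as transposon-less", {
  w <- small_world(seed = 221, n_tumours = 3, background_rate = 20)
  ins <- simulate_screen(w$catalog, w$config, genome = w$genome)
  reads <- emit_reads(ins, w$genome,
                      read_config(contaminant_fraction = 0.3, seed = 224))
  truth <- attr(reads, "truth")
  tr <- trim_reads(reads)
  expect_true(all(tr$reject_reason[truth$contaminant] == "no_transposon"))
  expect_true(all(is.na(tr$reject_reason[!truth$contaminant])))
})

test_that("mapping rejects ambiguous seeds and reads beyond the mismatch budget", {
  # genome with an exact 60-mer repeat at two loci
  set.seed(30)
  base <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE), collapse = "")
  repeat60 <- substr(base, 1001, 1060)
  chr2 <- paste0(substr(base, 1, 1800), repeat60,
                 paste(sample(c("A", "C", "G", "T"), 1140, replace = TRUE),
                       collapse = ""))
  gen <- Biostrings::DNAStringSet(c(chr1 = base, chr2 = chr2))
  amb <- data.frame(read_id = "amb", genomic_seq = substr(repeat60, 1, 40),
                    irdr_end = "R", reject_reason = NA_character_)
  loc <- locate_insertions(amb, gen)
  expect_equal(loc$reject_reason, "ambiguous_map")

  uniq <- substr(base, 2001, 2040)
  mutate_at <- function(s, at) {
    for (i in at) substr(s, i, i) <- c(A = "C", C = "G", G = "T", T = "A")[substr(s, i, i)]
    s
  }
  # mismatches placed after the exact 25-nt seed
  mm3 <- mutate_at(uniq, c(28, 33, 38))
  mm4 <- mutate_at(uniq, c(28, 33, 38, 40))
  df <- data.frame(read_id = c("mm3", "mm4"), genomic_seq = c(mm3, mm4),
                   irdr_end = "R", reject_reason = NA_character_)
  loc <- locate_insertions(df, gen)
  expect_equal(loc$reject_reason, c(NA, "too_many_mismatches"))
  expect_equal(loc$mismatches[1], 3)
  expect_equal(loc$pos[1], 2001)
})

test_that("the orientation convention pairs IRDR end and mapped strand consistently", {
  # one insertion, forced through both transposon ends: opposite read strands
  # must decode to the same transposon orientation
  w <- small_world(seed = 231, n_tumours = 1, background_rate = 6)
  ins <- simulate_screen(w$catalog, w$config, genome = w$genome)
  reads <- emit_reads(ins, w$genome, read_config(reads_per_site = 4, seed = 234))
  truth <- attr(reads, "truth")
  loc <- locate_insertions(trim_reads(reads), w$genome)
  both <- merge(loc, truth[, c("read_id", "read_strand")], by = "read_id")
  expect_true(all(both$transposon_orient ==
                    ifelse((both$irdr_end == "R") == (both$read_strand == "+"),
                           "+", "-")))
  # reads from both strands of one site agree on the site
  per_site <- split(both$transposon_orient,
                    paste(both$chrom, both$pos, sep = ":"))
  expect_true(all(vapply(per_site, function(x) length(unique(x)) == 1, logical(1))))
})

test_that("non-TA insertions are refused by the read emitter", {
  w <- small_world(seed = 241, n_tumours = 2, background_rate = 5)
  ins <- simulate_screen(w$catalog, w$config, genome = w$genome)
  bad <- ins
  # shift one insertion forward to the first non-TA position
  chr <- as.character(w$genome)[[bad$chrom[1]]]
  off <- 1
  while (substr(chr, bad$pos[1] + off, bad$pos[1] + off + 1) == "TA") off <- off + 1
  bad$pos[1] <- bad$pos[1] + off
  expect_error(emit_reads(bad, w$genome, read_config(seed = 244)), "TA dinucleotide")
})

test_that("deduplication collapses identical sites and nothing else", {
  raw <- data.frame(
    chrom = "chr1", pos = c(100, 100, 100, 101, 100, 100),
    transposon_orient = c("+", "+", "+", "+", "+", "-"),
    tumour_id = c("T1", "T1", "T1", "T1", "T2", "T1"),
    stringsAsFactors = FALSE)
  dd <- dedupe_sites(raw)
  expect_equal(nrow(dd), 4)
  trip <- dd[dd$pos == 100 & dd$tumour_id == "T1" & dd$transposon_orient == "+", ]
  expect_equal(trip$support, 3)
  # 1 bp apart stays distinct at window 0; same position in two tumours stays split
  expect_true(any(dd$pos == 101))
  expect_equal(sum(dd$tumour_id == "T2"), 1)
  # a merge window joins nearby sites
  dd2 <- dedupe_sites(raw, merge_window = 2)
  expect_equal(nrow(dd2), 3)
  expect_equal(dd2$support[dd2$tumour_id == "T1" & dd2$transposon_orient == "+"], 4)
})
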
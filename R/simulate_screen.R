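#' Describe a planted driver gene for a simulated screen
#'
#' Encodes the two insertion archetypes the classifier is built to separate.
#' An `ONCOGENE` receives insertions tightly clustered in an exon hotspot with
#' a sense-orientation bias (the transposon's internal promoter pointing with
#' the gene, driving an activated, truncated transcript); a `TSG` receives
#' insertions dispersed over the whole gene span with no orientation bias
#' (gene disruption).
#'
#' @param gene_id gene identifier present in the catalog.
#' @param class `"ONCOGENE"` or `"TSG"`.
#' @param penetrance probability that a tumour carries a driver insertion;
#'   either a single value or a named vector per strain (`12740`, `12775`).
#' @param hotspot length-2 integer vector (exon_from, exon_to) in
#'   transcription order; required for `ONCOGENE`, must be `NULL` for `TSG`.
#' @param sense_prob probability that a driver insertion is sense-oriented;
#'   must exceed 0.5 for `ONCOGENE` and equal 0.5 for `TSG`.
#' @return a `driver_spec` list.
#' @export
driver_spec <- function(gene_id, class = c("ONCOGENE", "TSG"),
                        penetrance = 0.2, hotspot = NULL, sense_prob = NULL) {
  class <- match.arg(class)
  if (is.null(sense_prob)) sense_prob <- if (class == "ONCOGENE") 0.9 else 0.5
  stopifnot(all(penetrance >= 0), all(penetrance <= 1),
            sense_prob >= 0, sense_prob <= 1)
  if (class == "ONCOGENE") {
    if (is.null(hotspot)) stop("ONCOGENE driver requires a 'hotspot' exon range")
    if (sense_prob <= 0.5) stop("ONCOGENE driver requires sense_prob > 0.5")
    stopifnot(length(hotspot) == 2, hotspot[1] <= hotspot[2], hotspot[1] >= 1)
  } else {
    if (!is.null(hotspot)) stop("TSG driver uses the whole gene span (hotspot must be NULL)")
    if (sense_prob != 0.5) stop("TSG driver requires sense_prob = 0.5")
  }
  structure(list(gene_id = gene_id, class = class, penetrance = penetrance,
                 hotspot = hotspot, sense_prob = sense_prob),
            class = "driver_spec")
}

#' Configure a simulated SB screen
#'
#' The configuration mirrors the design of a two-strain, two-Cre SB screen:
#' tumours are generated per (strain, Cre) group, each tumour receives a
#' Poisson number of background insertions placed uniformly over the genome
#' except for a local-hopping excess on that strain's donor chromosome, plus
#' driver insertions according to [driver_spec()] penetrances.
#'
#' The two transposon strains carry their donor concatemer on different
#' chromosomes, so the local-hopping excess does not replicate across strains
#' — which is what the downstream two-strain recurrence filter exploits.
#'
#' @param n_tumours data.frame with columns `strain` (`"12740"`/`"12775"`),
#'   `cre` (`"WAP"`/`"MMTV"`) and `n`. Default: 100 tumours per strain in the
#'   WAP group.
#' @param background_rate expected background insertions per tumour.
#' @param donor_chrom named character vector mapping strain to its donor
#'   chromosome; `NULL` assigns the first two catalog chromosomes.
#' @param hopping_factor density multiplier (>= 1) on the donor chromosome.
#' @param drivers list of [driver_spec()] objects.
#' @param seed integer seed; required.
#' @return a `screen_config` list.
#' @export
screen_config <- function(n_tumours = data.frame(strain = c("12740", "12775"),
                                                 cre = "WAP", n = 100L),
                          background_rate = 50,
                          donor_chrom = NULL,
                          hopping_factor = 3,
                          drivers = list(),
                          seed) {
  if (missing(seed)) stop("'seed' is required: generators must be reproducible")
  stopifnot(is.data.frame(n_tumours),
            all(c("strain", "cre", "n") %in% names(n_tumours)),
            all(n_tumours$n >= 0),
            all(n_tumours$strain %in% c("12740", "12775")),
            all(n_tumours$cre %in% c("WAP", "MMTV")),
            background_rate >= 0, hopping_factor >= 1)
  if (length(drivers) && !all(vapply(drivers, inherits, logical(1), "driver_spec")))
    stop("'drivers' must be a list of driver_spec objects")
  structure(list(n_tumours = n_tumours, background_rate = background_rate,
                 donor_chrom = donor_chrom, hopping_factor = hopping_factor,
                 drivers = drivers, seed = as.integer(seed)),
            class = "screen_config")
}

#' Simulate a transposon insertional-mutagenesis screen
#'
#' Generates a deduplicated insertion table: per tumour,
#' `Poisson(background_rate)` background insertions placed uniformly over the
#' genome with the donor-chromosome density multiplied by `hopping_factor`
#' (renormalized), with random orientation; plus, with probability
#' `penetrance`, one driver insertion per planted driver, positioned in the
#' driver's hotspot (ONCOGENE) or whole span (TSG) and oriented sense with
#' probability `sense_prob` relative to the gene's strand.
#'
#' When `genome` is supplied, insertion positions are restricted to TA
#' dinucleotides (SB integrates at TA); in coordinate-only mode any position
#' is allowed, which keeps large-genome simulations fast.
#'
#' @param catalog a [make_gene_catalog()] catalog.
#' @param config a [screen_config()].
#' @param genome optional [Biostrings::DNAStringSet] matching the catalog's
#'   chromosomes; restricts insertions to TA sites.
#' @param edge_margin minimum distance of sequence-backed insertions from
#'   chromosome ends (leaves room for junction-read flanks).
#' @return an `insertion_table` data.frame with columns chrom, pos,
#'   transposon_orient, tumour_id, strain, cre, support, plus attributes
#'   `tumours` (the tumour roster) and `truth` (planted driver insertions) —
#'   the ground-truth sidecar for recovery scoring.
#' @export
simulate_screen <- function(catalog, config, genome = NULL, edge_margin = 200L) {
  stopifnot(inherits(catalog, "gene_catalog"), inherits(config, "screen_config"))
  if (is.null(config$seed)) stop("'seed' is required: generators must be reproducible")
  cl <- catalog$chrom_lengths
  donor <- config$donor_chrom
  if (is.null(donor)) {
    donor <- stats::setNames(names(cl)[c(1L, min(2L, length(cl)))], c("12740", "12775"))
  }
  if (!all(donor %in% names(cl))) stop("donor chromosome not in catalog")
  for (d in config$drivers)
    if (!d$gene_id %in% catalog$genes$gene_id)
      stop("driver gene not in catalog: ", d$gene_id)

  set.seed(config$seed)
  nt <- config$n_tumours[config$n_tumours$n > 0, , drop = FALSE]
  roster <- do.call(rbind, lapply(seq_len(nrow(nt)), function(i) {
    data.frame(strain = nt$strain[i], cre = nt$cre[i],
               idx = seq_len(nt$n[i]), stringsAsFactors = FALSE)
  }))
  if (is.null(roster) || nrow(roster) == 0)
    stop("screen with zero tumours")
  roster$tumour_id <- sprintf("T%04d", seq_len(nrow(roster)))
  roster$idx <- NULL

  ta <- NULL
  if (!is.null(genome)) {
    if (!all(names(cl) %in% names(genome))) stop("genome missing catalog chromosomes")
    ta <- lapply(stats::setNames(names(cl), names(cl)), function(ch) {
      p <- ta_positions(genome, ch)
      p[p >= edge_margin & p <= cl[[ch]] - edge_margin]
    })
    if (any(vapply(ta, length, integer(1)) == 0))
      stop("no usable TA sites on some chromosome")
  }
  pick_pos <- function(chroms) {
    # vectorized uniform draw per chromosome (or TA-site draw)
    pos <- integer(length(chroms))
    for (ch in unique(chroms)) {
      i <- chroms == ch
      pos[i] <- if (is.null(ta)) sample.int(cl[[ch]], sum(i), replace = TRUE)
                else ta[[ch]][sample.int(length(ta[[ch]]), sum(i), replace = TRUE)]
    }
    pos
  }

  # background insertions
  bg <- list()
  for (s in unique(roster$strain)) {
    rs <- roster[roster$strain == s, ]
    w <- cl * ifelse(names(cl) == donor[[s]], config$hopping_factor, 1)
    n_ins <- stats::rpois(nrow(rs), config$background_rate)
    tot <- sum(n_ins)
    if (tot == 0) next
    chroms <- sample(names(cl), tot, replace = TRUE, prob = w / sum(w))
    bg[[s]] <- data.frame(
      chrom = chroms,
      pos = pick_pos(chroms),
      transposon_orient = sample(c("+", "-"), tot, replace = TRUE),
      tumour_id = rep(rs$tumour_id, n_ins),
      strain = s,
      cre = rep(rs$cre, n_ins),
      stringsAsFactors = FALSE)
  }
  ins <- do.call(rbind, bg)

  # planted driver insertions
  truth <- list()
  for (d in config$drivers) {
    g <- catalog$genes[catalog$genes$gene_id == d$gene_id, ]
    span <- if (d$class == "ONCOGENE") {
      ex <- catalog$exons[catalog$exons$gene_id == d$gene_id &
                          catalog$exons$exon >= d$hotspot[1] &
                          catalog$exons$exon <= d$hotspot[2], ]
      if (nrow(ex) == 0) stop("hotspot exons not found for ", d$gene_id)
      c(min(ex$start), max(ex$end))
    } else c(g$start, g$end)
    pen <- if (length(d$penetrance) == 1) {
      stats::setNames(rep(d$penetrance, 2), c("12740", "12775"))
    } else d$penetrance
    carrier <- stats::runif(nrow(roster)) < pen[roster$strain]
    n_car <- sum(carrier)
    if (n_car == 0) next
    if (is.null(ta)) {
      pos <- sample.int(span[2] - span[1] + 1L, n_car, replace = TRUE) + span[1] - 1L
    } else {
      cand <- ta[[g$chrom]][ta[[g$chrom]] >= span[1] & ta[[g$chrom]] <= span[2]]
      if (length(cand) == 0) stop("no TA sites in driver span for ", d$gene_id)
      pos <- cand[sample.int(length(cand), n_car, replace = TRUE)]
    }
    sense <- stats::runif(n_car) < d$sense_prob
    orient <- ifelse(sense, g$strand, setdiff(c("+", "-"), g$strand))
    di <- data.frame(chrom = g$chrom, pos = pos, transposon_orient = orient,
                     tumour_id = roster$tumour_id[carrier],
                     strain = roster$strain[carrier],
                     cre = roster$cre[carrier], stringsAsFactors = FALSE)
    ins <- rbind(ins, di)
    di$gene_id <- d$gene_id
    di$class <- d$class
    truth[[d$gene_id]] <- di
  }

  ins$support <- 1L
  ins <- dedupe_sites(ins)
  attr(ins, "tumours") <- roster
  attr(ins, "truth") <- if (length(truth)) do.call(rbind, truth) else NULL
  rownames(attr(ins, "truth")) <- NULL
  attr(ins, "donor_chrom") <- donor
  class(ins) <- c("insertion_table", "data.frame")
  ins
}

#' @export
print.insertion_table <- function(x, ...) {
  ro <- attr(x, "tumours")
  cat("Insertion table:", nrow(x), "non-redundant sites in",
      if (!is.null(ro)) nrow(ro) else length(unique(x$tumour_id)), "tumours\n")
  tab <- table(x$strain, x$cre)
  print(tab)
  invisible(x)
}
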
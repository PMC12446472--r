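#' Configuration for the synthetic splicing/rG4 dataset
#'
#' Builds a validated configuration for the synthetic-data generator. The
#' generator emulates the statistical structure of a temperature-shift
#' cassette-exon experiment: a toy genome, skipped-exon trios on both
#' strands, replicate PSI values with planted cold-shock effects, G4
#' elements planted near splice sites at category-dependent rates, and
#' rG4-seq-style reverse-transcriptase-stalling (RTS) peaks concentrated on
#' cold-repressed exons.
#'
#' Replicate PSI noise is a clamped Gaussian: `psi = clamp(mean + e, 0, 1)`
#' with `e ~ N(0, psi_noise_sd)`. Cold-condition means are shifted by
#' `-delta_effect` for planted CREs and `+delta_effect` for planted CIEs.
#'
#' @param seed integer seed; every generator draw derives from it.
#' @param genome_length genome size in bases, or `NULL` to size the genome
#'   automatically from the event layout.
#' @param gc_background background GC fraction in (0, 1).
#' @param n_events_per_category named count of events for each of
#'   `CRE`, `CIE`, `NT`.
#' @param replicates_per_condition replicates per temperature condition
#'   (at least 2).
#' @param psi_base warm-condition mean PSI, in (0.05, 0.95).
#' @param delta_effect planted |delta PSI| for CRE/CIE events.
#' @param psi_noise_sd standard deviation of replicate PSI noise.
#' @param motif_rate numeric matrix of planting probabilities with rows
#'   `CRE`, `CIE`, `NT` and columns `SS3`, `SS5`: the probability that a
#'   canonical G4 element is written into the -25..+25 window of that
#'   splice site.
#' @param rts_peak_rate probability that a CRE event carries a planted RTS
#'   peak in one of its cassette splice-site flanks.
#' @param rts_background_rate expected background RTS peaks per kilobase.
#' @param rts_meanlog,rts_sdlog log-normal parameters of RTS peak values.
#' @param exon_length_range,cassette_length_range,intron_length_range
#'   integer ranges (min, max) for flanking exon, cassette exon and intron
#'   lengths. Introns must be at least `2 * flank` so that the +-`flank`
#'   windows of distinct events never collide.
#' @param event_gap gap in bases between consecutive event loci.
#' @param flank half-width of the widest splice-site window the layout must
#'   keep collision-free (default 200).
#' @return an object of class `rg4_synth_config` (a validated list).
#' @examples
#' cfg <- synth_config(seed = 1, n_events_per_category = c(CRE = 5, CIE = 5, NT = 5))
#' cfg$psi_base
#' @export
synth_config <- function(seed = 1L,
                         genome_length = NULL,
                         gc_background = 0.4,
                         n_events_per_category = c(CRE = 100L, CIE = 100L, NT = 100L),
                         replicates_per_condition = 4L,
                         psi_base = 0.5,
                         delta_effect = 0.3,
                         psi_noise_sd = 0.05,
                         motif_rate = default_motif_rate(),
                         rts_peak_rate = 0.8,
                         rts_background_rate = 0.05,
                         rts_meanlog = 1,
                         rts_sdlog = 0.5,
                         exon_length_range = c(80L, 160L),
                         cassette_length_range = c(60L, 150L),
                         intron_length_range = c(450L, 600L),
                         event_gap = 500L,
                         flank = 200L) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  seed <- as.integer(seed)
  probs <- c(gc_background = gc_background, rts_peak_rate = rts_peak_rate,
             psi_base = psi_base)
  bad <- probs < 0 | probs > 1
  if (any(bad))
    stop("configuration error: ", paste(names(probs)[bad], collapse = ", "),
         " must lie in [0, 1]", call. = FALSE)
  if (gc_background <= 0 && gc_background != 0)
    stop("configuration error: gc_background must be in (0, 1)", call. = FALSE)
  if (psi_noise_sd < 0)
    stop("configuration error: psi_noise_sd must be non-negative", call. = FALSE)
  if (delta_effect < 0 || delta_effect > 1)
    stop("configuration error: delta_effect must be in [0, 1]", call. = FALSE)
  n_events_per_category <- as.integer(n_events_per_category)
  if (is.null(names(n_events_per_category)))
    names(n_events_per_category) <- c("CRE", "CIE", "NT")
  if (!setequal(names(n_events_per_category), c("CRE", "CIE", "NT")))
    stop("configuration error: n_events_per_category needs CRE, CIE and NT entries",
         call. = FALSE)
  n_events_per_category <- n_events_per_category[c("CRE", "CIE", "NT")]
  if (any(n_events_per_category < 0))
    stop("configuration error: negative event counts", call. = FALSE)
  if (sum(n_events_per_category) == 0L)
    stop("configuration error: at least one event must be requested", call. = FALSE)
  if (replicates_per_condition < 2L)
    stop("configuration error: replicates_per_condition must be >= 2", call. = FALSE)
  motif_rate <- validate_motif_rate(motif_rate)
  for (rng in list(exon_length_range, cassette_length_range, intron_length_range)) {
    if (length(rng) != 2L || any(rng <= 0) || rng[1] > rng[2])
      stop("configuration error: length ranges must be positive (min, max) pairs",
           call. = FALSE)
  }
  if (intron_length_range[1] < 2L * flank)
    stop("configuration error: intron lengths must be >= 2 * flank (",
         2L * flank, ") so splice-site windows never collide", call. = FALSE)
  cfg <- list(seed = seed,
              genome_length = if (is.null(genome_length)) NULL else as.numeric(genome_length),
              gc_background = gc_background,
              n_events_per_category = n_events_per_category,
              replicates_per_condition = as.integer(replicates_per_condition),
              psi_base = psi_base,
              delta_effect = delta_effect,
              psi_noise_sd = psi_noise_sd,
              motif_rate = motif_rate,
              rts_peak_rate = rts_peak_rate,
              rts_background_rate = rts_background_rate,
              rts_meanlog = rts_meanlog,
              rts_sdlog = rts_sdlog,
              exon_length_range = as.integer(exon_length_range),
              cassette_length_range = as.integer(cassette_length_range),
              intron_length_range = as.integer(intron_length_range),
              event_gap = as.integer(event_gap),
              flank = as.integer(flank))
  class(cfg) <- "rg4_synth_config"
  cfg
}

#' Default category-by-region G4 planting rates
#'
#' Cold-repressed exons (CRE) get G4 elements at 60% of cassette 5' splice
#' sites and 30% of 3' splice sites; cold-induced (CIE) and
#' non-temperature-sensitive (NT) exons carry only a 5% background rate.
#'
#' @return a 3 x 2 numeric matrix (rows CRE/CIE/NT, columns SS3/SS5).
#' @export
default_motif_rate <- function() {
  m <- matrix(c(0.30, 0.05, 0.05,
                0.60, 0.05, 0.05),
              nrow = 3, dimnames = list(c("CRE", "CIE", "NT"), c("SS3", "SS5")))
  m
}

validate_motif_rate <- function(m) {
  if (!is.matrix(m) || !all(c("CRE", "CIE", "NT") %in% rownames(m)) ||
      !all(c("SS3", "SS5") %in% colnames(m)))
    stop("configuration error: motif_rate must be a matrix with rows CRE/CIE/NT ",
         "and columns SS3/SS5", call. = FALSE)
  m <- m[c("CRE", "CIE", "NT"), c("SS3", "SS5"), drop = FALSE]
  if (any(m < 0 | m > 1))
    stop("configuration error: motif_rate entries must lie in [0, 1]", call. = FALSE)
  m
}

#' @export
print.rg4_synth_config <- function(x, ...) {
  cat("Synthetic dataset configuration\n")
  cat("  events/category:", paste(names(x$n_events_per_category),
                                  x$n_events_per_category, sep = "=", collapse = " "), "\n")
  cat("  replicates/condition:", x$replicates_per_condition, "\n")
  cat(sprintf("  PSI: base %.2f, planted effect %.2f, noise sd %.3f\n",
              x$psi_base, x$delta_effect, x$psi_noise_sd))
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Per-operation sub-seed so each generator stage is reproducible on its own.
sub_seed <- function(seed, k) (as.integer(seed) * 97L + k) %% 2147483587L + 1L

# Genome size needed by the sequential event layout, with margin.
required_genome_length <- function(config) {
  n <- sum(config$n_events_per_category)
  per_event <- 2L * config$exon_length_range[2] +
    config$cassette_length_range[2] +
    2L * config$intron_length_range[2] +
    config$event_gap
  as.numeric(n) * per_event + 2L * config$event_gap + 2L * config$flank
}

#' Generate the synthetic genome
#'
#' I.i.d. bases over A/C/G/T with the configured GC fraction (G and C
#' equiprobable), deterministic given the configuration seed.
#'
#' @param config an [synth_config()] object.
#' @return a named [Biostrings::DNAStringSet] with one contig, `chrS`.
#' @export
synth_genome <- function(config) {
  stopifnot(inherits(config, "rg4_synth_config"))
  len <- config$genome_length
  if (is.null(len)) len <- required_genome_length(config)
  if (len <= 0)
    stop("configuration error: genome_length must be positive", call. = FALSE)
  gc <- config$gc_background
  bases <- with_seed(sub_seed(config$seed, 1L),
                     sample(c("A", "C", "G", "T"), size = len, replace = TRUE,
                            prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)))
  genome <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(genome) <- "chrS"
  genome
}

# One canonical G4 element: n_runs runs of min_run G separated by random
# non-G loops of loop_min..loop_max bases, on the sense strand.
random_g4_element <- function(motif = g4_motif()) {
  loops <- replicate(motif$n_runs - 1L, {
    n <- sample(seq.int(motif$loop_min, motif$loop_max), 1L)
    paste(sample(c("A", "C", "T"), n, replace = TRUE), collapse = "")
  })
  run <- strrep("G", motif$min_run)
  paste0(run, paste0(loops, run, collapse = ""))
}

#' Plant cassette-exon events and G4 elements on the genome
#'
#' Lays out non-overlapping exon trios sequentially (gap, upstream exon,
#' intron, cassette, intron, downstream exon), alternating assignment of
#' strand, then overwrites the genome with canonical G4 elements inside the
#' -25..+25 windows of the cassette splice sites (`SS3`, `SS5`) with the
#' category- and region-specific probabilities of `config$motif_rate`.
#' Elements are written in transcript (sense) orientation; for minus-strand
#' events their reverse complement is written into genome coordinates.
#'
#' @param config an [synth_config()] object.
#' @param genome genome as returned by [synth_genome()].
#' @return a list with `events` (data frame of exon trios, 0-based
#'   half-open), `truth` (per-event planted category and motif flags) and
#'   `genome` (the modified genome).
#' @export
synth_events <- function(config, genome) {
  stopifnot(inherits(config, "rg4_synth_config"))
  genome <- as_genome(genome)
  glen <- Biostrings::width(genome)[1]
  chrom <- names(genome)[1]
  counts <- config$n_events_per_category
  categories <- rep(names(counts), counts)

  with_seed(sub_seed(config$seed, 2L), {
    categories <- sample(categories)
    n <- length(categories)
    up_len <- sample(seq.int(config$exon_length_range[1], config$exon_length_range[2]),
                     n, replace = TRUE)
    dn_len <- sample(seq.int(config$exon_length_range[1], config$exon_length_range[2]),
                     n, replace = TRUE)
    cas_len <- sample(seq.int(config$cassette_length_range[1], config$cassette_length_range[2]),
                      n, replace = TRUE)
    in1 <- sample(seq.int(config$intron_length_range[1], config$intron_length_range[2]),
                  n, replace = TRUE)
    in2 <- sample(seq.int(config$intron_length_range[1], config$intron_length_range[2]),
                  n, replace = TRUE)
    strand <- sample(c("+", "-"), n, replace = TRUE)

    span <- up_len + in1 + cas_len + in2 + dn_len
    starts <- config$event_gap + c(0, cumsum(span[-n] + config$event_gap))
    if (n > 0 && starts[n] + span[n] + config$event_gap > glen)
      stop("sizing error: genome of ", glen, " bases cannot hold ", n,
           " events at the configured exon/intron/gap sizes (needs ",
           starts[n] + span[n] + config$event_gap, ")", call. = FALSE)

    # genomic-order trio; transcript-order roles depend on strand
    first_start <- starts
    first_end <- first_start + up_len
    cas_start <- first_end + in1
    cas_end <- cas_start + cas_len
    last_start <- cas_end + in2
    last_end <- last_start + dn_len

    events <- data.frame(
      event_id = sprintf("ev%04d_%s", seq_len(n), categories),
      chrom = chrom,
      strand = strand,
      up_start = ifelse(strand == "+", first_start, last_start),
      up_end = ifelse(strand == "+", first_end, last_end),
      cassette_start = cas_start,
      cassette_end = cas_end,
      down_start = ifelse(strand == "+", last_start, first_start),
      down_end = ifelse(strand == "+", last_end, first_end),
      stringsAsFactors = FALSE
    )

    truth <- data.frame(event_id = events$event_id,
                        category = categories,
                        motif_SS3 = FALSE, motif_SS5 = FALSE,
                        rts_planted = FALSE,
                        stringsAsFactors = FALSE)

    contig <- genome[[1]]
    for (i in seq_len(n)) {
      for (region in c("SS3", "SS5")) {
        rate <- config$motif_rate[categories[i], region]
        if (stats::runif(1) >= rate) next
        element <- random_g4_element()
        elen <- nchar(element)
        anchor <- splice_site_anchor(events[i, ], region)
        offset <- sample.int(50L - elen + 1L, 1L) - 1L # within -25..+25 window
        if (strand[i] == "+") {
          gstart <- anchor - 25L + offset
          piece <- Biostrings::DNAString(element)
        } else {
          gstart <- anchor + 25L - offset - elen
          piece <- Biostrings::reverseComplement(Biostrings::DNAString(element))
        }
        Biostrings::subseq(contig, gstart + 1L, gstart + elen) <- piece
        truth[i, paste0("motif_", region)] <- TRUE
      }
    }
    genome[[1]] <- contig
    list(events = events, truth = truth, genome = genome)
  })
}

#' Simulate replicate PSI tables for a cold/warm contrast
#'
#' Warm-condition means equal `psi_base` for every event; cold-condition
#' means are `psi_base - delta_effect` for CREs, `psi_base + delta_effect`
#' for CIEs and `psi_base` for NTs. Gaussian replicate noise is clamped to
#' the unit interval.
#'
#' @param config an [synth_config()] object.
#' @param truth truth table from [synth_events()].
#' @return a data frame with columns `event_id`, `condition` (`"cold"` /
#'   `"warm"`), `replicate`, `psi`.
#' @export
synth_psi <- function(config, truth) {
  stopifnot(inherits(config, "rg4_synth_config"))
  if (config$psi_noise_sd < 0)
    stop("configuration error: psi_noise_sd must be non-negative", call. = FALSE)
  nrep <- config$replicates_per_condition
  shift <- c(CRE = -config$delta_effect, CIE = config$delta_effect, NT = 0)
  mean_cold <- config$psi_base + unname(shift[truth$category])
  mean_warm <- rep(config$psi_base, nrow(truth))
  grid <- expand.grid(replicate = seq_len(nrep),
                      event = seq_len(nrow(truth)),
                      condition = c("cold", "warm"),
                      stringsAsFactors = FALSE)
  mu <- ifelse(grid$condition == "cold", mean_cold[grid$event], mean_warm[grid$event])
  psi <- with_seed(sub_seed(config$seed, 3L),
                   pmin(1, pmax(0, mu + stats::rnorm(nrow(grid), 0, config$psi_noise_sd))))
  data.frame(event_id = truth$event_id[grid$event],
             condition = grid$condition,
             replicate = grid$replicate,
             psi = psi,
             stringsAsFactors = FALSE)
}

#' Simulate rG4-seq RTS peaks
#'
#' With probability `rts_peak_rate`, each CRE event receives a 15-40 base
#' peak placed uniformly inside the +-`flank` window of its cassette SS3 or
#' SS5 (chosen at random), with a log-normal RTS value. Background peaks
#' are added uniformly along the genome at `rts_background_rate` peaks per
#' kilobase.
#'
#' @param config an [synth_config()] object.
#' @param events,truth from [synth_events()].
#' @param genome the genome (used only for its length).
#' @return a data frame with columns `chrom`, `start`, `end`, `name`,
#'   `rts` (0-based half-open intervals) plus a `planted_event` column
#'   (`NA` for background peaks); `truth` with updated `rts_planted` flags
#'   is attached as attribute `"truth"`.
#' @export
synth_rts_peaks <- function(config, events, truth, genome) {
  stopifnot(inherits(config, "rg4_synth_config"))
  genome <- as_genome(genome)
  glen <- Biostrings::width(genome)[1]
  chrom <- names(genome)[1]
  flank <- config$flank
  with_seed(sub_seed(config$seed, 4L), {
    peaks <- list()
    cre <- which(truth$category == "CRE")
    for (i in cre) {
      if (stats::runif(1) >= config$rts_peak_rate) next
      region <- sample(c("SS3", "SS5"), 1L)
      anchor <- splice_site_anchor(events[i, ], region)
      len <- sample(15:40, 1L)
      start <- anchor - flank + sample.int(2L * flank - len + 1L, 1L) - 1L
      truth$rts_planted[i] <- TRUE
      peaks[[length(peaks) + 1L]] <- data.frame(
        chrom = chrom, start = start, end = start + len,
        name = sprintf("rts_%s_%s", events$event_id[i], region),
        rts = stats::rlnorm(1, config$rts_meanlog, config$rts_sdlog),
        planted_event = events$event_id[i], stringsAsFactors = FALSE)
    }
    n_bg <- stats::rpois(1, config$rts_background_rate * glen / 1000)
    if (n_bg > 0) {
      len <- sample(15:40, n_bg, replace = TRUE)
      start <- floor(stats::runif(n_bg, 0, glen - len))
      peaks[[length(peaks) + 1L]] <- data.frame(
        chrom = chrom, start = start, end = start + len,
        name = sprintf("bg%04d", seq_len(n_bg)),
        rts = stats::rlnorm(n_bg, config$rts_meanlog, config$rts_sdlog),
        planted_event = NA_character_, stringsAsFactors = FALSE)
    }
    out <- if (length(peaks)) do.call(rbind, peaks) else
      data.frame(chrom = character(), start = integer(), end = integer(),
                 name = character(), rts = numeric(),
                 planted_event = character(), stringsAsFactors = FALSE)
    out <- out[order(out$start), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "truth") <- truth
    out
  })
}

#' Generate a complete on-disk synthetic dataset
#'
#' Runs the whole generator and writes genome FASTA (60-column wrapped),
#' events TSV, PSI TSV, RTS peaks BED and the truth table, plus the
#' resolved configuration as `key=value` text.
#'
#' @param config an [synth_config()] object.
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the in-memory pieces (`genome`, `events`,
#'   `truth`, `psi`, `peaks`) and the file `paths`.
#' @export
synth_fixture <- function(config, dir) {
  stopifnot(inherits(config, "rg4_synth_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- synth_genome(config)
  planted <- synth_events(config, genome)
  psi <- synth_psi(config, planted$truth)
  peaks <- synth_rts_peaks(config, planted$events, planted$truth, planted$genome)
  truth <- attr(peaks, "truth")

  paths <- list(genome = file.path(dir, "genome.fa"),
                events = file.path(dir, "events.tsv"),
                psi = file.path(dir, "psi.tsv"),
                peaks = file.path(dir, "peaks.bed"),
                truth = file.path(dir, "truth.tsv"),
                config = file.path(dir, "fixture.config"))
  Biostrings::writeXStringSet(planted$genome, paths$genome, width = 60L)
  write_tsv(planted$events, paths$events)
  write_tsv(psi, paths$psi)
  write_peaks_bed(peaks, paths$peaks)
  write_tsv(truth, paths$truth)
  writeLines(config_as_text(config), paths$config)
  invisible(list(genome = planted$genome, events = planted$events,
                 truth = truth, psi = psi, peaks = peaks, paths = paths))
}

config_as_text <- function(config) {
  flat <- list(
    seed = config$seed,
    genome_length = if (is.null(config$genome_length)) "auto" else config$genome_length,
    gc_background = config$gc_background,
    n_events_per_category = paste(names(config$n_events_per_category),
                                  config$n_events_per_category, sep = ":", collapse = ","),
    replicates_per_condition = config$replicates_per_condition,
    psi_base = config$psi_base,
    delta_effect = config$delta_effect,
    psi_noise_sd = config$psi_noise_sd,
    motif_rate = paste(apply(expand.grid(rownames(config$motif_rate),
                                         colnames(config$motif_rate)), 1,
                             function(z) paste0(z[1], ".", z[2], ":",
                                                config$motif_rate[z[1], z[2]])),
                       collapse = ","),
    rts_peak_rate = config$rts_peak_rate,
    rts_background_rate = config$rts_background_rate,
    rts_meanlog = config$rts_meanlog,
    rts_sdlog = config$rts_sdlog,
    exon_length_range = paste(config$exon_length_range, collapse = "-"),
    cassette_length_range = paste(config$cassette_length_range, collapse = "-"),
    intron_length_range = paste(config$intron_length_range, collapse = "-"),
    event_gap = config$event_gap,
    flank = config$flank)
  paste0(names(flat), "=", unlist(flat))
}
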
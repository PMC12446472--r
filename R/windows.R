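#' @importFrom Biostrings DNAStringSet reverseComplement subseq width
NULL

# Accept a DNAStringSet, DNAString, or named character vector as the genome.
as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  if (inherits(genome, "DNAString")) {
    g <- Biostrings::DNAStringSet(genome)
    names(g) <- "chrS"
    return(g)
  }
  if (is.character(genome)) {
    g <- Biostrings::DNAStringSet(toupper(chartr("Uu", "Tt", genome)))
    if (is.null(names(genome))) names(g) <- if (length(g) == 1L) "chrS" else
      paste0("chr", seq_along(g)) else names(g) <- names(genome)
    return(g)
  }
  stop("input error: genome must be a DNAStringSet or a named character vector",
       call. = FALSE)
}

#' Splice-site regions of a cassette-exon trio
#'
#' The four analysed regions, in transcript orientation: `USS5` (upstream
#' exon's 5' splice site, the donor), `SS3` (cassette 3' splice site, the
#' acceptor), `SS5` (cassette 5' splice site, the donor) and `DSS3`
#' (downstream exon's 3' splice site).
#'
#' @format a character vector of the four region names.
#' @export
SPLICE_REGIONS <- c("USS5", "SS3", "SS5", "DSS3")

#' Genomic anchor of a splice site
#'
#' Returns the 0-based genomic boundary coordinate of the requested splice
#' site for each event: with half-open exon intervals the anchor sits
#' exactly between the last exonic and first intronic base (or vice versa).
#' On the plus strand `USS5 = up_end`, `SS3 = cassette_start`,
#' `SS5 = cassette_end`, `DSS3 = down_start`; minus-strand events use the
#' genomically mirrored boundaries.
#'
#' @param events data frame of cassette-exon events (see
#'   [read_events_tsv()] for the column contract).
#' @param region one of `"USS5"`, `"SS3"`, `"SS5"`, `"DSS3"`.
#' @return integer vector of anchors, one per event.
#' @examples
#' ev <- data.frame(event_id = "e1", chrom = "chrS", strand = "+",
#'                  up_start = 0, up_end = 50, cassette_start = 100,
#'                  cassette_end = 150, down_start = 200, down_end = 250)
#' splice_site_anchor(ev, "SS3")
#' @export
splice_site_anchor <- function(events, region) {
  region <- match.arg(region, SPLICE_REGIONS)
  plus <- events$strand == "+"
  out <- switch(region,
    USS5 = ifelse(plus, events$up_end, events$up_start),
    SS3 = ifelse(plus, events$cassette_start, events$cassette_end),
    SS5 = ifelse(plus, events$cassette_end, events$cassette_start),
    DSS3 = ifelse(plus, events$down_start, events$down_end))
  as.integer(out)
}

#' Extract splice-site-anchored sequence windows
#'
#' For each event, extracts the `2 * half_width` bases centred on the
#' splice-site anchor, in transcript (sense) orientation: minus-strand
#' events return the reverse complement of the genomic slice. In the
#' window's relative coordinate system positions `-half_width..-1` lie 5'
#' of the junction and `+1..+half_width` 3' of it (there is no position 0).
#' Windows that would run off the contig are dropped with a message, never
#' padded, so composition statistics are not diluted; the number of drops
#' is available as `attr(, "dropped")`.
#'
#' @param genome a [Biostrings::DNAStringSet] (or named character vector).
#' @param events event data frame.
#' @param region splice-site region (see [splice_site_anchor()]).
#' @param half_width window half-width in bases (25 for composition/motif
#'   windows, 200 for scanning flanks).
#' @return data frame with columns `event_id`, `region`, `chrom`,
#'   `strand`, `start`, `end` (genomic, 0-based half-open), `anchor` and
#'   `sequence` (uppercase sense strand).
#' @examples
#' g <- Biostrings::DNAStringSet(c(chrS = strrep("ACGT", 100)))
#' ev <- data.frame(event_id = "e1", chrom = "chrS", strand = "+",
#'                  up_start = 0, up_end = 50, cassette_start = 100,
#'                  cassette_end = 150, down_start = 200, down_end = 250)
#' extract_windows(g, ev, "SS3", half_width = 5)$sequence
#' @export
extract_windows <- function(genome, events, region, half_width = 25L) {
  genome <- as_genome(genome)
  region <- match.arg(region, SPLICE_REGIONS)
  half_width <- as.integer(half_width)
  stopifnot(half_width >= 1L)
  anchor <- splice_site_anchor(events, region)
  start <- anchor - half_width
  end <- anchor + half_width
  clen <- stats::setNames(Biostrings::width(genome), names(genome))
  known <- events$chrom %in% names(genome)
  keep <- known & start >= 0L & end <= clen[events$chrom]
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message(n_drop, " ", region, " window(s) dropped (out of contig bounds ",
            "or unknown contig)")
  idx <- which(keep)
  seqs <- character(length(idx))
  if (length(idx)) {
    views <- Biostrings::subseq(genome[events$chrom[idx]],
                                start = start[idx] + 1L, end = end[idx])
    minus <- events$strand[idx] == "-"
    if (any(minus)) views[minus] <- Biostrings::reverseComplement(views[minus])
    seqs <- toupper(as.character(views))
  }
  out <- data.frame(event_id = events$event_id[idx],
                    region = rep(region, length(idx)),
                    chrom = events$chrom[idx],
                    strand = events$strand[idx],
                    start = start[idx],
                    end = end[idx],
                    anchor = anchor[idx],
                    sequence = unname(seqs),
                    stringsAsFactors = FALSE)
  attr(out, "dropped") <- n_drop
  out
}

#' Extract the wide scanning flank around a splice site
#'
#' Convenience wrapper over [extract_windows()] with the scanning
#' half-width (default 200 bases each side, a 400-base window).
#'
#' @inheritParams extract_windows
#' @param flank half-width in bases.
#' @return as [extract_windows()].
#' @export
extract_flanks <- function(genome, events, region, flank = 200L) {
  extract_windows(genome, events, region, half_width = flank)
}

# Map 1-based base index within a 2*half_width window to the junction-
# relative coordinate (-half_width..-1, +1..+half_width; no position 0).
rel_position <- function(i, half_width) {
  ifelse(i <= half_width, i - half_width - 1L, i - half_width)
}

#' Write extracted windows as FASTA
#'
#' Headers are `event_id|region|strand`.
#'
#' @param windows data frame from [extract_windows()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_windows_fasta <- function(windows, path) {
  seqs <- Biostrings::DNAStringSet(windows$sequence)
  names(seqs) <- paste(windows$event_id, windows$region, windows$strand, sep = "|")
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}
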
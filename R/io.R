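write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    comment.char = "", quote = "", ...)
}

#' Read a genome FASTA
#'
#' Index-free read of a (small) genome FASTA into a
#' [Biostrings::DNAStringSet]; contig names are trimmed at the first
#' whitespace.
#'
#' @param path FASTA file.
#' @return a named [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Read a cassette-exon event table
#'
#' Tab-separated with columns `event_id`, `chrom`, `strand`, `up_start`,
#' `up_end`, `cassette_start`, `cassette_end`, `down_start`, `down_end`
#' (0-based half-open). Validates interval sanity: non-empty exons,
#' transcript order consistent with strand, pairwise disjoint intervals.
#'
#' @param path TSV file.
#' @return validated event data frame.
#' @export
read_events_tsv <- function(path) {
  ev <- read_tsv(path)
  validate_events(ev)
}

validate_events <- function(ev) {
  need <- c("event_id", "chrom", "strand", "up_start", "up_end",
            "cassette_start", "cassette_end", "down_start", "down_end")
  if (!all(need %in% names(ev)))
    stop("input error: event table needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (any(duplicated(ev$event_id)))
    stop("input error: duplicated event ids", call. = FALSE)
  if (!all(ev$strand %in% c("+", "-")))
    stop("input error: strand must be '+' or '-'", call. = FALSE)
  nonempty <- ev$up_end > ev$up_start & ev$cassette_end > ev$cassette_start &
    ev$down_end > ev$down_start
  if (!all(nonempty))
    stop("input error: empty exon interval(s) in ",
         paste(utils::head(ev$event_id[!nonempty], 3), collapse = ", "),
         call. = FALSE)
  plus_ok <- ev$strand != "+" |
    (ev$up_end <= ev$cassette_start & ev$cassette_end <= ev$down_start)
  minus_ok <- ev$strand != "-" |
    (ev$down_end <= ev$cassette_start & ev$cassette_end <= ev$up_start)
  bad <- !(plus_ok & minus_ok)
  if (any(bad))
    stop("input error: exon trio out of order / overlapping in ",
         paste(utils::head(ev$event_id[bad], 3), collapse = ", "),
         call. = FALSE)
  ev
}

#' Read a long-format PSI table
#'
#' Tab-separated with columns `event_id`, `condition`, `replicate`,
#' `psi`; PSI values validated to lie in \[0, 1\].
#'
#' @param path TSV file.
#' @return PSI data frame.
#' @export
read_psi_tsv <- function(path) {
  psi <- read_tsv(path, colClasses = c(event_id = "character"))
  need <- c("event_id", "condition", "replicate", "psi")
  if (!all(need %in% names(psi)))
    stop("input error: PSI table needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (any(is.na(psi$psi)) || any(psi$psi < 0 | psi$psi > 1))
    stop("input error: PSI values must lie in [0, 1]", call. = FALSE)
  psi
}

#' Read RTS peaks from 5-column BED
#'
#' BED columns `chrom`, `start`, `end`, `name`, `score`, with the score
#' column holding the (non-negative) RTS value.
#'
#' @param path BED file.
#' @return data frame `chrom`, `start`, `end`, `name`, `rts`.
#' @export
read_peaks_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(bed) < 5L)
    stop("input error: peak BED needs 5 columns (chrom, start, end, name, RTS)",
         call. = FALSE)
  peaks <- stats::setNames(bed[, 1:5], c("chrom", "start", "end", "name", "rts"))
  validate_peaks(peaks)
}

#' Write RTS peaks as 5-column BED
#'
#' @param peaks peak data frame (`chrom`, `start`, `end`, `name`, `rts`).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  utils::write.table(peaks[, c("chrom", "start", "end", "name", "rts")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a skipped-exon table in the rMATS SE dialect
#'
#' Parses the tab-separated skipped-exon output dialect of the rMATS
#' splicing caller: columns `ID`, `chr`, `strand`, `exonStart_0base`,
#' `exonEnd`, `upstreamES`, `upstreamEE`, `downstreamES`, `downstreamEE`,
#' comma-separated per-replicate inclusion levels `IncLevel1` /
#' `IncLevel2`, and `PValue` / `FDR`. Group 1 is mapped to `cond1_label`
#' (e.g. the cold condition) and group 2 to `cond2_label`. rMATS
#' `exonStart_0base`/`ES` columns are already 0-based half-open.
#'
#' @param path rMATS SE.MATS-style TSV.
#' @param cond1_label,cond2_label condition labels to assign to sample
#'   groups 1 and 2.
#' @return list with `events` (event data frame), `psi` (long PSI table)
#'   and `p_values` (named vector of the caller's per-event p-values,
#'   usable with `classify_exons(method = "external")`).
#' @export
read_rmats_se <- function(path, cond1_label = "cold", cond2_label = "warm") {
  tab <- read_tsv(path)
  need <- c("ID", "chr", "strand", "exonStart_0base", "exonEnd",
            "upstreamES", "upstreamEE", "downstreamES", "downstreamEE",
            "IncLevel1", "IncLevel2", "PValue")
  if (!all(need %in% names(tab)))
    stop("input error: rMATS SE table needs columns ",
         paste(setdiff(need, names(tab)), collapse = ", "), call. = FALSE)
  events <- data.frame(event_id = as.character(tab$ID),
                       chrom = tab$chr,
                       strand = tab$strand,
                       up_start = tab$upstreamES,
                       up_end = tab$upstreamEE,
                       cassette_start = tab$exonStart_0base,
                       cassette_end = tab$exonEnd,
                       down_start = tab$downstreamES,
                       down_end = tab$downstreamEE,
                       stringsAsFactors = FALSE)
  parse_inc <- function(txt, label) {
    vals <- strsplit(as.character(txt), ",", fixed = TRUE)
    n <- lengths(vals)
    data.frame(event_id = rep(events$event_id, n),
               condition = label,
               replicate = unlist(lapply(n, seq_len), use.names = FALSE),
               psi = suppressWarnings(as.numeric(unlist(vals, use.names = FALSE))),
               stringsAsFactors = FALSE)
  }
  psi <- rbind(parse_inc(tab$IncLevel1, cond1_label),
               parse_inc(tab$IncLevel2, cond2_label))
  psi <- psi[!is.na(psi$psi), , drop = FALSE]
  list(events = validate_events(events),
       psi = psi,
       p_values = stats::setNames(tab$PValue, events$event_id))
}
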
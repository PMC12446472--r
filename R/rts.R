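#' @importFrom GenomicRanges GRanges findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

validate_peaks <- function(peaks) {
  need <- c("chrom", "start", "end", "name", "rts")
  if (!all(need %in% names(peaks)))
    stop("input error: peaks need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(peaks$end <= peaks$start))
    stop("input error: peak intervals must satisfy end > start", call. = FALSE)
  if (any(peaks$rts < 0))
    stop("input error: RTS values must be non-negative", call. = FALSE)
  peaks
}

# Per (event, peak) overlap within the +-flank window of `region`, as
# junction-relative covered positions. Returns a list with the event index,
# peak index and an integer matrix [lo, hi] of covered window offsets
# (1..2*flank, already strand-flipped to transcript orientation).
window_peak_hits <- function(events, peaks, region, flank = 200L) {
  validate_peaks(peaks)
  anchor <- splice_site_anchor(events, region)
  wstart <- anchor - flank
  wend <- anchor + flank
  known <- peaks$chrom %in% unique(events$chrom)
  if (any(!known))
    message(sum(!known), " peak(s) on contigs absent from the event table; skipped")
  pk <- peaks[known, , drop = FALSE]
  inb <- which(wstart >= 0L)
  if (length(inb) < nrow(events))
    message(nrow(events) - length(inb), " event window(s) out of contig ",
            "bounds; skipped")
  if (!nrow(pk) || !length(inb))
    return(list(event = integer(), peak = integer(),
                lo = integer(), hi = integer()))
  wgr <- GenomicRanges::GRanges(events$chrom[inb],
                                IRanges::IRanges(start = wstart[inb] + 1L,
                                                 end = wend[inb]))
  pgr <- GenomicRanges::GRanges(pk$chrom,
                                IRanges::IRanges(start = pk$start + 1L, end = pk$end))
  hits <- GenomicRanges::findOverlaps(wgr, pgr)
  ev <- inb[S4Vectors::queryHits(hits)]
  pe <- S4Vectors::subjectHits(hits)
  # genomic intersection, as 0-based offsets into the window (0..2*flank-1)
  lo <- pmax(pk$start[pe], wstart[ev]) - wstart[ev]
  hi <- pmin(pk$end[pe], wend[ev]) - wstart[ev] - 1L
  minus <- events$strand[ev] == "-"
  lo2 <- ifelse(minus, 2L * flank - 1L - hi, lo)
  hi2 <- ifelse(minus, 2L * flank - 1L - lo, hi)
  list(event = ev, peak = which(known)[pe],
       lo = as.integer(lo2) + 1L, hi = as.integer(hi2) + 1L) # 1-based offsets
}

#' Exon-overlap counts around splice sites
#'
#' For each junction-relative position from `-flank` to `+flank`, counts
#' the events of each category whose genomic base at that position
#' (strand-mapped to transcript orientation) lies inside at least one
#' peak; an event contributes at most once per position regardless of how
#' many peaks cover it.
#'
#' @param events event data frame.
#' @param peaks RTS peak data frame (`chrom`, `start`, `end`, `name`,
#'   `rts`; 0-based half-open).
#' @param categories named category vector or `rg4_classification`.
#' @param region splice-site region.
#' @param flank half-width of the profiled window (default 200).
#' @return matrix of counts, one row per category, `2 * flank` columns
#'   named by relative position (`-flank..-1`, `+1..+flank`).
#' @export
overlap_counts <- function(events, peaks, categories, region, flank = 200L) {
  categories <- as_category_map(categories)
  hits <- window_peak_hits(events, peaks, region, flank)
  cats <- sort(unique(unname(categories)))
  out <- matrix(0L, nrow = length(cats), ncol = 2L * flank,
                dimnames = list(cats, rel_position(seq_len(2L * flank), flank)))
  if (!length(hits$event)) return(out)
  for (ev in unique(hits$event)) {
    cat <- categories[events$event_id[ev]]
    if (is.na(cat)) next
    sel <- hits$event == ev
    covered <- rep(FALSE, 2L * flank)
    for (j in which(sel)) covered[hits$lo[j]:hits$hi[j]] <- TRUE
    out[cat, ] <- out[cat, ] + covered
  }
  out
}

#' Cumulative RTS values around splice sites
#'
#' At each junction-relative position, sums the RTS values of every
#' (event, peak) incidence covering that position, separately per
#' category: a peak overlapping two events contributes to both, and two
#' peaks on one event both contribute.
#'
#' @inheritParams overlap_counts
#' @return matrix of cumulative RTS, one row per category, columns as
#'   [overlap_counts()].
#' @export
cumulative_rts <- function(events, peaks, categories, region, flank = 200L) {
  categories <- as_category_map(categories)
  hits <- window_peak_hits(events, peaks, region, flank)
  cats <- sort(unique(unname(categories)))
  out <- matrix(0, nrow = length(cats), ncol = 2L * flank,
                dimnames = list(cats, rel_position(seq_len(2L * flank), flank)))
  if (!length(hits$event)) return(out)
  for (j in seq_along(hits$event)) {
    cat <- categories[events$event_id[hits$event[j]]]
    if (is.na(cat)) next
    idx <- hits$lo[j]:hits$hi[j]
    out[cat, idx] <- out[cat, idx] + peaks$rts[hits$peak[j]]
  }
  out
}

#' Moving-average smoothing with shrinking edges
#'
#' Centred moving average of width `w`; near the edges the window shrinks
#' to its in-bounds part (no zero padding, so the profile does not decay
#' artificially at the boundaries). For even `w` the window extends one
#' base further to the left. `w = 1` is the identity; `w` larger than the
#' vector yields the whole-vector mean everywhere (degenerate, messaged).
#'
#' @param x numeric vector.
#' @param w window width (default 30).
#' @return smoothed numeric vector, same length and names as `x`.
#' @examples
#' smooth_profile(c(0, 0, 1, 0, 0), w = 3)
#' @export
smooth_profile <- function(x, w = 30L) {
  w <- as.integer(w)
  stopifnot(w >= 1L)
  n <- length(x)
  if (n == 0L) return(x)
  if (w >= n) {
    if (w > n) message("smoothing window (", w, ") exceeds vector length (",
                       n, "); returning the overall mean")
    return(stats::setNames(rep(mean(x), n), names(x)))
  }
  left <- w %/% 2L
  right <- w - left - 1L
  cs <- c(0, cumsum(as.numeric(x)))
  i <- seq_len(n)
  lo <- pmax(1L, i - left)
  hi <- pmin(n, i + right)
  stats::setNames((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L), names(x))
}

#' rG4-seq metaprofile around splice sites
#'
#' Combines [overlap_counts()] (with 30-nt smoothing by default) and
#' [cumulative_rts()] into one long table per region and category.
#'
#' @inheritParams overlap_counts
#' @param regions regions to profile (default `SS3` and `SS5`).
#' @param smooth smoothing window in nt (default 30).
#' @return long data frame `region`, `category`, `rel_pos`, `count`,
#'   `smoothed`, `cum_rts`.
#' @export
rts_metaprofile <- function(events, peaks, categories,
                            regions = c("SS3", "SS5"), flank = 200L,
                            smooth = 30L) {
  out <- list()
  for (region in regions) {
    counts <- overlap_counts(events, peaks, categories, region, flank)
    rts <- cumulative_rts(events, peaks, categories, region, flank)
    for (cat in rownames(counts)) {
      out[[paste(region, cat)]] <- data.frame(
        region = region, category = cat,
        rel_pos = as.integer(colnames(counts)),
        count = as.numeric(counts[cat, ]),
        smoothed = as.numeric(smooth_profile(counts[cat, ], smooth)),
        cum_rts = as.numeric(rts[cat, ]),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
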
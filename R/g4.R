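#' Canonical G4 motif definition
#'
#' The canonical intramolecular quadruplex pattern: `n_runs` runs of at
#' least `min_run` consecutive G separated by loops of `loop_min` to
#' `loop_max` non-G bases. The default (four runs of >= 3 G, loops 1-7 nt)
#' is the standard putative-quadruplex-forming-sequence definition; all
#' fields are configurable so an alternative motif catalogue can be swapped
#' in.
#'
#' @param min_run minimum G-run length (>= 2).
#' @param loop_min,loop_max loop length bounds in bases.
#' @param n_runs number of G runs (>= 2).
#' @return an object of class `g4_motif`.
#' @examples
#' g4_motif()
#' @export
g4_motif <- function(min_run = 3L, loop_min = 1L, loop_max = 7L, n_runs = 4L) {
  min_run <- as.integer(min_run); loop_min <- as.integer(loop_min)
  loop_max <- as.integer(loop_max); n_runs <- as.integer(n_runs)
  if (min_run < 2L) stop("input error: min_run must be >= 2", call. = FALSE)
  if (loop_min < 1L || loop_max < loop_min)
    stop("input error: need 1 <= loop_min <= loop_max", call. = FALSE)
  if (n_runs < 2L) stop("input error: n_runs must be >= 2", call. = FALSE)
  structure(list(min_run = min_run, loop_min = loop_min,
                 loop_max = loop_max, n_runs = n_runs),
            class = "g4_motif")
}

#' @export
print.g4_motif <- function(x, ...) {
  cat(sprintf("G4 motif: %d runs of >=%d G, loops %d-%d non-G bases\n",
              x$n_runs, x$min_run, x$loop_min, x$loop_max))
  invisible(x)
}

#' G content of sequences
#'
#' Fraction of G bases; any non-G character (including N) counts in the
#' denominator only.
#'
#' @param sequence character vector of DNA/RNA sequences (U is treated
#'   as T).
#' @return numeric vector of fractions in \[0, 1\].
#' @examples
#' g_content(c("GATC", "GGGG"))
#' @export
g_content <- function(sequence) {
  if (any(!nzchar(sequence)) || any(is.na(sequence)))
    stop("input error: empty sequence", call. = FALSE)
  s <- toupper(chartr("U", "T", sequence))
  vapply(strsplit(s, "", fixed = TRUE),
         function(ch) sum(ch == "G") / length(ch), numeric(1))
}

# Maximal single-base runs of a sequence, as a data frame
# (char, start, end 1-based inclusive, length).
base_runs <- function(sequence) {
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  r <- rle(ch)
  end <- cumsum(r$lengths)
  data.frame(char = r$values, start = end - r$lengths + 1L, end = end,
             length = r$lengths, stringsAsFactors = FALSE)
}

#' Find canonical G4 motif matches
#'
#' Scans one sequence for matches of the [g4_motif()] pattern. A match is
#' `n_runs` consecutive maximal G runs, each of length >= `min_run`,
#' whose gaps (the loops, necessarily G-free) are `loop_min..loop_max`
#' bases. Matches are reported maximal, non-overlapping and left-greedy:
#' the scanner takes the longest match at the leftmost feasible start,
#' then resumes after its end.
#'
#' @param sequence a single DNA/RNA string (U treated as T).
#' @param motif a [g4_motif()] definition.
#' @return data frame with columns `start`, `end` (1-based inclusive) and
#'   `match`; zero rows if no match.
#' @examples
#' find_g4_motifs("GGGAGGGAGGGAGGG")
#' @export
find_g4_motifs <- function(sequence, motif = g4_motif()) {
  stopifnot(length(sequence) == 1L, inherits(motif, "g4_motif"))
  s <- toupper(chartr("U", "T", sequence))
  empty <- data.frame(start = integer(), end = integer(),
                      match = character(), stringsAsFactors = FALSE)
  runs <- base_runs(s)
  g <- runs[runs$char == "G", , drop = FALSE]
  if (nrow(g) < motif$n_runs) return(empty)
  k <- motif$n_runs
  hits <- list()
  i <- 1L
  while (i <= nrow(g) - k + 1L) {
    ok <- all(g$length[i:(i + k - 1L)] >= motif$min_run)
    if (ok) {
      gaps <- g$start[(i + 1L):(i + k - 1L)] - g$end[i:(i + k - 2L)] - 1L
      ok <- all(gaps >= motif$loop_min & gaps <= motif$loop_max)
    }
    if (ok) {
      hits[[length(hits) + 1L]] <- c(g$start[i], g$end[i + k - 1L])
      i <- i + k
    } else i <- i + 1L
  }
  if (!length(hits)) return(empty)
  m <- do.call(rbind, hits)
  data.frame(start = m[, 1], end = m[, 2],
             match = substring(s, m[, 1], m[, 2]), stringsAsFactors = FALSE)
}

#' Does each sequence contain a canonical G4 motif?
#'
#' Vectorised presence/absence wrapper over [find_g4_motifs()] — the
#' quantity entering the motif-proportion enrichment test.
#'
#' @param sequences character vector.
#' @param motif a [g4_motif()] definition.
#' @return logical vector.
#' @export
has_g4_motif <- function(sequences, motif = g4_motif()) {
  vapply(sequences, function(s) nrow(find_g4_motifs(s, motif)) > 0L,
         logical(1), USE.NAMES = FALSE)
}

#' G4Hunter per-base scores
#'
#' Each base in a run of `k` consecutive G scores `+min(k, 4)`; each base
#' in a run of `k` consecutive C scores `-min(k, 4)`; every other base
#' (including N, which also breaks runs) scores 0.
#'
#' @param sequence a single DNA/RNA string (U treated as T).
#' @return integer vector of per-base scores in -4..4, same length as the
#'   sequence.
#' @examples
#' g4hunter_base_scores("GGGTTACCC")
#' @export
g4hunter_base_scores <- function(sequence) {
  stopifnot(length(sequence) == 1L)
  if (!nzchar(sequence)) return(integer(0))
  s <- toupper(chartr("U", "T", sequence))
  r <- rle(strsplit(s, "", fixed = TRUE)[[1]])
  val <- ifelse(r$values == "G", pmin(r$lengths, 4L),
                ifelse(r$values == "C", -pmin(r$lengths, 4L), 0L))
  rep(as.integer(val), r$lengths)
}

#' G4Hunter sliding-window scores
#'
#' Mean of [g4hunter_base_scores()] over every window of `w` bases, the
#' score being assigned to the window start (`assign = "start"`) or its
#' centre (`assign = "center"`, for plotting). Computed with a running sum;
#' base scores are integers, so the result is exactly the per-window mean.
#' Sequences shorter than `w` are scored as a single whole-sequence window.
#'
#' @param sequence a single DNA/RNA string.
#' @param w window width in bases (default 25).
#' @param assign where the window score is anchored.
#' @return numeric vector of window scores (length `nchar - w + 1`, or 1
#'   for short sequences), each in \[-4, 4\]. The assignment rule is kept
#'   as attribute `"assign"`.
#' @examples
#' g4hunter_window_scores(strrep("G", 30), w = 25)
#' @export
g4hunter_window_scores <- function(sequence, w = 25L, assign = c("start", "center")) {
  assign <- match.arg(assign)
  w <- as.integer(w)
  stopifnot(w >= 1L)
  b <- g4hunter_base_scores(sequence)
  n <- length(b)
  if (n == 0L) stop("input error: empty sequence", call. = FALSE)
  if (n < w) {
    out <- mean(b)
  } else {
    cs <- c(0, cumsum(as.numeric(b)))
    out <- (cs[(w + 1L):(n + 1L)] - cs[1:(n - w + 1L)]) / w
  }
  attr(out, "assign") <- assign
  out
}

#' Positional G4Hunter profiles over splice-site flanks
#'
#' Extracts the +-`flank` window of each event at each requested region and
#' scans it with `w`-base G4Hunter windows. Scores are indexed by the
#' junction-relative position of the window start (or centre, see
#' [g4hunter_window_scores()]); positions `-flank..-1` are 5' of the
#' junction, `+1..+flank` 3' of it.
#'
#' @param genome genome ([Biostrings::DNAStringSet] or named character).
#' @param events event data frame.
#' @param regions splice-site regions to scan (default cassette SS3 and
#'   SS5).
#' @param flank half-width of the scanned window (default 200).
#' @param w G4Hunter window width (default 25).
#' @param assign window-score anchoring, see [g4hunter_window_scores()].
#' @return long data frame `event_id`, `region`, `rel_pos`, `score`; the
#'   per-region count of dropped (out-of-bounds) windows is in
#'   `attr(, "dropped")`.
#' @export
score_flanks <- function(genome, events, regions = c("SS3", "SS5"),
                         flank = 200L, w = 25L, assign = c("start", "center")) {
  assign <- match.arg(assign)
  genome <- as_genome(genome)
  dropped <- integer(0)
  out <- list()
  for (region in regions) {
    win <- extract_flanks(genome, events, region, flank = flank)
    dropped[region] <- attr(win, "dropped")
    if (!nrow(win)) next
    scores <- lapply(win$sequence, g4hunter_window_scores, w = w)
    len <- lengths(scores)
    idx <- unlist(lapply(len, seq_len), use.names = FALSE)
    if (assign == "center") idx <- idx + (w %/% 2L)
    out[[region]] <- data.frame(
      event_id = rep(win$event_id, len),
      region = region,
      rel_pos = rel_position(idx, flank),
      score = unlist(scores, use.names = FALSE),
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(event_id = character(), region = character(),
               rel_pos = integer(), score = numeric(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "dropped") <- dropped
  res
}

#' Per-event maximum G4 scores around the cassette exon
#'
#' Summarises flank profiles into the per-event maxima used for the
#' "predicted rG4" call: `max_SS3`, `max_SS5`, their maximum `max_SS35`,
#' and `has_g4 = max_SS35 > threshold` (strict inequality; the
#' conventional G4Hunter call threshold is 1). Events missing either
#' region's profile (dropped windows) get `NA` and are excluded from
#' downstream proportions; their count is messaged.
#'
#' @param profiles long profile data frame from [score_flanks()] holding
#'   both `SS3` and `SS5` rows.
#' @param threshold G4 call threshold on the window score (default 1).
#' @return data frame `event_id`, `max_SS3`, `max_SS5`, `max_SS35`,
#'   `has_g4`.
#' @export
region_max_scores <- function(profiles, threshold = 1) {
  need <- c("SS3", "SS5")
  ids <- unique(profiles$event_id)
  mx <- function(region) {
    sub <- profiles[profiles$region == region, , drop = FALSE]
    v <- tapply(sub$score, sub$event_id, max)
    unname(v[ids])
  }
  out <- data.frame(event_id = ids,
                    max_SS3 = as.numeric(mx("SS3")),
                    max_SS5 = as.numeric(mx("SS5")),
                    stringsAsFactors = FALSE)
  out$max_SS35 <- pmax(out$max_SS3, out$max_SS5)
  out$has_g4 <- out$max_SS35 > threshold
  n_na <- sum(is.na(out$max_SS35))
  if (n_na > 0)
    message(n_na, " event(s) missing an SS3 or SS5 profile; excluded from ",
            "G4-call proportions")
  out
}
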
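# Independent slow oracles used to cross-check the package implementations.

random_dna <- function(n, weights = c(A = 1, C = 1, G = 1, T = 1)) {
  paste(sample(names(weights), n, replace = TRUE, prob = weights),
        collapse = "")
}

# Per-base G4Hunter scores by expanding each position's containing run with
# explicit left/right scans (no run-length encoding).
oracle_base_scores <- function(sequence) {
  ch <- strsplit(toupper(chartr("U", "T", sequence)), "")[[1]]
  n <- length(ch)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (ch[i] != "G" && ch[i] != "C") next
    k <- 1L
    j <- i - 1L
    while (j >= 1L && ch[j] == ch[i]) { k <- k + 1L; j <- j - 1L }
    j <- i + 1L
    while (j <= n && ch[j] == ch[i]) { k <- k + 1L; j <- j + 1L }
    out[i] <- if (ch[i] == "G") min(k, 4L) else -min(k, 4L)
  }
  out
}

# Brute-force per-window means of the oracle base scores.
oracle_window_scores <- function(sequence, w = 25L) {
  b <- oracle_base_scores(sequence)
  n <- length(b)
  if (n < w) return(mean(b))
  vapply(seq_len(n - w + 1L), function(i) mean(b[i:(i + w - 1L)]), numeric(1))
}

motif_regex <- function(motif = g4_motif()) {
  sprintf("G{%d,}([^G]{%d,%d}G{%d,}){%d}",
          motif$min_run, motif$loop_min, motif$loop_max, motif$min_run,
          motif$n_runs - 1L)
}

# Left-greedy, longest-first motif matches via the PCRE regex engine
# (leftmost match, greedy quantifiers; with G-free loops the match at a
# given start is unique, hence maximal).
oracle_motifs_regex <- function(sequence, motif = g4_motif()) {
  s <- toupper(chartr("U", "T", sequence))
  m <- gregexpr(motif_regex(motif), s, perl = TRUE)[[1]]
  if (m[1] == -1L)
    return(data.frame(start = integer(), end = integer(),
                      match = character(), stringsAsFactors = FALSE))
  start <- as.integer(m)
  end <- start + attr(m, "match.length") - 1L
  data.frame(start = start, end = end, match = substring(s, start, end),
             stringsAsFactors = FALSE)
}

# Fully brute-force motif matches: enumerate substrings, keep those that
# full-match the anchored pattern, then take the longest match at the
# leftmost position and continue after its end.
oracle_motifs_bruteforce <- function(sequence, motif = g4_motif()) {
  s <- toupper(chartr("U", "T", sequence))
  n <- nchar(s)
  pat <- paste0("^", motif_regex(motif), "$")
  hits <- list()
  p <- 1L
  while (p <= n) {
    best <- 0L
    for (e in n:p) {
      if (grepl(pat, substr(s, p, e), perl = TRUE)) { best <- e; break }
    }
    if (best > 0L) {
      hits[[length(hits) + 1L]] <- c(p, best)
      p <- best + 1L
    } else p <- p + 1L
  }
  if (!length(hits))
    return(data.frame(start = integer(), end = integer(),
                      match = character(), stringsAsFactors = FALSE))
  m <- do.call(rbind, hits)
  data.frame(start = m[, 1], end = m[, 2], match = substring(s, m[, 1], m[, 2]),
             stringsAsFactors = FALSE)
}

# Exact two-sided rank-sum p-value by enumerating every assignment of the
# pooled ranks to the first group.
oracle_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_along(x)])
  combos <- utils::combn(length(pooled), length(x))
  w_all <- apply(combos, 2, function(idx) sum(r[idx]))
  mu <- mean(w_all)
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Exact hypergeometric over-representation p by enumerating every draw of
# size n from a population of N with K successes.
oracle_hyper_p <- function(k, n, K, N) {
  draws <- utils::combn(N, n)
  mean(apply(draws, 2, function(idx) sum(idx <= K) >= k))
}
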
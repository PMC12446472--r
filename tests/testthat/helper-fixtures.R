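# Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, config) {
  if (is.null(.fixture_cache[[name]])) {
    dir <- file.path(tempdir(), paste0("rg4_fx_", name))
    .fixture_cache[[name]] <- suppressMessages(synth_fixture(config, dir))
  }
  .fixture_cache[[name]]
}

# The study-condition fixture: planted delta PSI 0.3, replicate noise sd
# 0.05, 4 replicates, 100 events per category, default planting rates.
default_fixture <- function() cached_fixture("default", synth_config(seed = 42))

# A single plus-strand event with round coordinates on a 1 kb contig.
toy_event <- function(strand = "+") {
  data.frame(event_id = "e1", chrom = "chrS", strand = strand,
             up_start = 100L, up_end = 200L,
             cassette_start = 400L, cassette_end = 500L,
             down_start = 700L, down_end = 800L,
             stringsAsFactors = FALSE)
}

toy_genome <- function(n = 1000L, seed = 7L) {
  set.seed(seed)
  Biostrings::DNAStringSet(c(chrS = random_dna(n)))
}

# Long PSI table from per-event replicate vectors.
psi_table <- function(cold, warm) {
  ids <- names(cold)
  do.call(rbind, lapply(ids, function(id) {
    rbind(data.frame(event_id = id, condition = "cold",
                     replicate = seq_along(cold[[id]]), psi = cold[[id]]),
          data.frame(event_id = id, condition = "warm",
                     replicate = seq_along(warm[[id]]), psi = warm[[id]]))
  }))
}

# Minimal event table with the given cassette lengths.
length_events <- function(ids, cassette_length = 100L) {
  n <- length(ids)
  len <- rep_len(cassette_length, n)
  start <- seq(0L, by = 10000L, length.out = n) + 1000L
  data.frame(event_id = ids, chrom = "chrS", strand = "+",
             up_start = start - 600L, up_end = start - 400L,
             cassette_start = start, cassette_end = start + len,
             down_start = start + len + 400L, down_end = start + len + 600L,
             stringsAsFactors = FALSE)
}
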
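test_that("genome generation respects length, composition and seed", {
  expect_error(synth_config(n_events_per_category = c(CRE = 0, CIE = 0, NT = 0)),
               "at least one event")
  cfg <- synth_config(seed = 7, genome_length = 0,
                      n_events_per_category = c(CRE = 1, CIE = 1, NT = 1))
  expect_error(synth_genome(cfg), "genome_length must be positive")

  cfg_gc <- synth_config(seed = 7, genome_length = 100, gc_background = 1,
                         n_events_per_category = c(CRE = 1, CIE = 1, NT = 1))
  g <- as.character(synth_genome(cfg_gc)[[1]])
  expect_equal(nchar(g), 100L)
  expect_true(grepl("^[GC]+$", g))

  cfg7 <- synth_config(seed = 7, genome_length = 5000,
                       n_events_per_category = c(CRE = 1, CIE = 1, NT = 1))
  expect_identical(as.character(synth_genome(cfg7)),
                   as.character(synth_genome(cfg7)))
})

test_that("planting is truthful, strand-aware and recoverable by the scanner", {
  zero <- matrix(0, 3, 2, dimnames = list(c("CRE", "CIE", "NT"), c("SS3", "SS5")))
  cfg0 <- synth_config(seed = 3, motif_rate = zero,
                       n_events_per_category = c(CRE = 3, CIE = 3, NT = 3))
  g0 <- synth_genome(cfg0)
  out0 <- synth_events(cfg0, g0)
  expect_identical(as.character(out0$genome), as.character(g0))
  expect_false(any(out0$truth$motif_SS3, out0$truth$motif_SS5))

  all_ss5 <- zero; all_ss5["CRE", "SS5"] <- 1
  cfg1 <- synth_config(seed = 5, motif_rate = all_ss5,
                       n_events_per_category = c(CRE = 5, CIE = 2, NT = 2))
  out1 <- synth_events(cfg1, synth_genome(cfg1))
  cre <- out1$events[grepl("CRE", out1$events$event_id), ]
  win <- extract_windows(out1$genome, cre, "SS5", half_width = 25)
  expect_equal(nrow(win), 5L)
  expect_true(all(has_g4_motif(win$sequence)))
  expect_true(all(out1$truth$motif_SS5[out1$truth$category == "CRE"]))

  # a minus-strand planted event carries the pattern only after sense-strand
  # extraction (reverse complement in genome coordinates)
  planted <- merge(cre, out1$truth)
  minus <- planted[planted$strand == "-", ]
  expect_gt(nrow(minus), 0)
  ev <- minus[1, ]
  anchor <- splice_site_anchor(ev, "SS5")
  raw <- as.character(Biostrings::subseq(out1$genome[[1]], anchor - 24, anchor + 25))
  sense <- extract_windows(out1$genome, ev, "SS5", half_width = 25)$sequence
  expect_identical(sense, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(raw))))
  expect_true(has_g4_motif(sense))
})

test_that("PSI simulation hits the planted means, clamps, and stays in [0,1]", {
  mk <- function(base, effect, sd) synth_config(
    seed = 1, psi_base = base, delta_effect = effect, psi_noise_sd = sd,
    n_events_per_category = c(CRE = 2, CIE = 2, NT = 2))
  truth <- data.frame(event_id = c("a", "b", "c"),
                      category = c("CRE", "NT", "CIE"),
                      stringsAsFactors = FALSE)
  psi0 <- synth_psi(mk(0.5, 0.3, 0), truth)
  expect_equal(unique(psi0$psi[psi0$event_id == "a" & psi0$condition == "cold"]), 0.2)
  expect_equal(unique(psi0$psi[psi0$event_id == "a" & psi0$condition == "warm"]), 0.5)
  expect_equal(psi0$psi[psi0$event_id == "b" & psi0$condition == "cold"],
               psi0$psi[psi0$event_id == "b" & psi0$condition == "warm"])

  clamped <- synth_psi(mk(0.9, 0.3, 0), truth)
  expect_equal(unique(clamped$psi[clamped$event_id == "c" &
                                  clamped$condition == "cold"]), 1.0)

  noisy <- synth_psi(mk(0.5, 0.3, 0.4), truth)
  expect_true(all(noisy$psi >= 0 & noisy$psi <= 1))
  expect_error(synth_config(psi_noise_sd = -1), "psi_noise_sd")
})

test_that("RTS peaks target CRE flanks, with positive values", {
  cfg_off <- synth_config(seed = 2, rts_peak_rate = 0, rts_background_rate = 0,
                          n_events_per_category = c(CRE = 2, CIE = 2, NT = 2))
  out <- synth_events(cfg_off, synth_genome(cfg_off))
  pk0 <- synth_rts_peaks(cfg_off, out$events, out$truth, out$genome)
  expect_equal(nrow(pk0), 0L)

  cfg_on <- synth_config(seed = 2, rts_peak_rate = 1, rts_background_rate = 0,
                         n_events_per_category = c(CRE = 3, CIE = 1, NT = 1))
  out <- synth_events(cfg_on, synth_genome(cfg_on))
  pk <- synth_rts_peaks(cfg_on, out$events, out$truth, out$genome)
  expect_gte(nrow(pk), 3L)
  expect_true(all(pk$rts > 0))
  cre <- out$events[grepl("CRE", out$events$event_id), ]
  flank_hit <- vapply(seq_len(nrow(pk)), function(i) {
    any(vapply(c("SS3", "SS5"), function(r) {
      a <- splice_site_anchor(cre, r)
      any(pk$start[i] < a + 200 & pk$end[i] > a - 200)
    }, logical(1)))
  }, logical(1))
  expect_true(all(flank_hit))
})

test_that("scanning flanks of distinct events never overlap", {
  fx <- default_fixture()
  ev <- fx$events
  spans <- do.call(rbind, lapply(c("USS5", "SS3", "SS5", "DSS3"), function(r) {
    a <- splice_site_anchor(ev, r)
    data.frame(event = ev$event_id, lo = a - 200, hi = a + 200)
  }))
  spans <- spans[order(spans$lo), ]
  adjacent <- spans$event[-1] != spans$event[-nrow(spans)]
  gap_ok <- spans$lo[-1] >= spans$hi[-nrow(spans)]
  expect_true(all(gap_ok[adjacent]))
})

test_that("fixture files are byte-identical across regenerations", {
  cfg <- synth_config(seed = 11, n_events_per_category = c(CRE = 5, CIE = 5, NT = 5))
  d1 <- file.path(tempdir(), "fx_det1"); d2 <- file.path(tempdir(), "fx_det2")
  f1 <- suppressMessages(synth_fixture(cfg, d1))
  f2 <- suppressMessages(synth_fixture(cfg, d2))
  for (nm in names(f1$paths))
    expect_identical(unname(tools::md5sum(f1$paths[[nm]])),
                     unname(tools::md5sum(f2$paths[[nm]])), label = nm)
})
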
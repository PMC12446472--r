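test_that("G content counts G over the full denominator", {
  expect_equal(g_content(c("AAAA", "GGGG", "GATC")), c(0, 1, 0.25))
  expect_equal(g_content("GGNN"), 0.5)  # N stays in the denominator
  expect_error(g_content(""), "empty")
})

test_that("motif scanner matches the canonical pattern examples", {
  hit <- find_g4_motifs("GGGAGGGAGGGAGGG")
  expect_equal(nrow(hit), 1L)
  expect_equal(c(hit$start, hit$end), c(1L, 15L))
  expect_equal(nrow(find_g4_motifs("GGAGGAGGAGG")), 0L)  # no run of >= 3 G
  # two tandem motifs are reported as non-overlapping matches
  two <- find_g4_motifs(strrep("GGGA", 8))
  expect_equal(nrow(two), 2L)
  # configurable definition: two runs of >= 2 G
  loose <- g4_motif(min_run = 2, n_runs = 2)
  expect_equal(nrow(find_g4_motifs("GGAGG", loose)), 1L)
  expect_error(g4_motif(min_run = 1), "min_run")
})

test_that("the 22-nt G-rich RNA hairpin control has no canonical 4-run match", {
  r1 <- "GGGGGUGGAGGGCAGCGGCAGA"  # two runs of >= 3 G only
  expect_equal(nrow(find_g4_motifs(r1)), 0L)
  runs <- rle(strsplit(chartr("U", "T", r1), "")[[1]])
  expect_equal(sum(runs$values == "G" & runs$lengths >= 3), 2L)
  # its whole-sequence G4Hunter mean agrees with the per-base oracle
  expect_equal(as.numeric(g4hunter_window_scores(r1, w = 25)),
               mean(oracle_base_scores(r1)))
})

test_that("motif scanner equals regex and brute-force substring oracles", {
  set.seed(101)
  for (i in 1:250) {
    s <- random_dna(sample(10:60, 1), c(A = 1, C = 1, G = 3, T = 1))
    expect_identical(find_g4_motifs(s), oracle_motifs_regex(s), label = s)
  }
  for (i in 1:40) {
    s <- random_dna(sample(15:40, 1), c(A = 1, C = 1, G = 4, T = 1))
    expect_identical(find_g4_motifs(s), oracle_motifs_bruteforce(s), label = s)
  }
})

test_that("per-base run scores follow the G4Hunter rules", {
  expect_equal(g4hunter_base_scores("GGGTTACCC"),
               c(3, 3, 3, 0, 0, 0, -3, -3, -3))
  expect_equal(g4hunter_base_scores("GGGGGG"), rep(4, 6))  # capped at 4
  expect_equal(g4hunter_base_scores("ATAT"), rep(0, 4))
  expect_equal(g4hunter_base_scores("GGNGG"), c(2, 2, 0, 2, 2))  # N breaks runs
})

test_that("base scores of the reverse complement are the reversed negation", {
  set.seed(7)
  for (i in 1:50) {
    s <- random_dna(sample(5:80, 1), c(A = 1, C = 2, G = 2, T = 1))
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_identical(g4hunter_base_scores(rc), rev(-g4hunter_base_scores(s)))
  }
})

test_that("window scores: bounds, fallback, and exact running-sum identity", {
  expect_equal(as.numeric(g4hunter_window_scores(strrep("G", 25), w = 25)), 4)
  expect_equal(as.numeric(g4hunter_window_scores("GGGTTACCC", w = 9)), 0)
  short <- g4hunter_window_scores("GGG", w = 25)  # whole-sequence fallback
  expect_length(as.numeric(short), 1L)
  expect_equal(as.numeric(short), 3)
  set.seed(13)
  for (i in 1:50) {
    s <- random_dna(sample(26:200, 1), c(A = 1, C = 2, G = 2, T = 1))
    v <- as.numeric(g4hunter_window_scores(s, w = 25))
    expect_true(all(v >= -4 & v <= 4))
    expect_identical(v, oracle_window_scores(s, 25))
  }
  # w = 1 reduces to the per-base scores
  s <- random_dna(40, c(A = 1, C = 2, G = 2, T = 1))
  expect_equal(as.numeric(g4hunter_window_scores(s, w = 1)),
               as.numeric(g4hunter_base_scores(s)))
})

test_that("flank profiles index window starts by junction-relative position", {
  g <- toy_genome(2000)
  ev <- toy_event("+")
  prof <- score_flanks(g, ev, regions = "SS5", flank = 200, w = 25)
  expect_equal(range(prof$rel_pos), c(-200L, 176L))
  expect_equal(nrow(prof), 400 - 25 + 1)
  fl <- extract_flanks(g, ev, "SS5", flank = 200)$sequence
  expect_equal(prof$score, as.numeric(g4hunter_window_scores(fl, 25)))
})

test_that("per-event maxima and the strict score > 1 call", {
  prof <- data.frame(
    event_id = rep(c("a", "b", "c"), each = 4),
    region = rep(c("SS3", "SS3", "SS5", "SS5"), 3),
    rel_pos = rep(c(-1L, 1L), 6),
    score = c(0.4, 0.2, 1.3, 0.9,   # a: max 1.3 -> called
              0, 0, 0, 0,           # b: all zero
              1.0, 0.8, 0.6, 0.2))  # c: max exactly 1 -> NOT called
  rs <- region_max_scores(prof, threshold = 1)
  expect_equal(rs$max_SS35, c(1.3, 0, 1.0))
  expect_identical(rs$has_g4, c(TRUE, FALSE, FALSE))
  # a missing region yields NA and a message
  miss <- prof[!(prof$event_id == "b" & prof$region == "SS5"), ]
  expect_message(rs2 <- region_max_scores(miss), "missing")
  expect_true(is.na(rs2$max_SS35[rs2$event_id == "b"]))
})
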
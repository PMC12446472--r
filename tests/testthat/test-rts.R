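peak <- function(start, end, rts = 1, name = "p1", chrom = "chrS")
  data.frame(chrom = chrom, start = start, end = end, name = name, rts = rts,
             stringsAsFactors = FALSE)

test_that("overlap counts map peak coverage into junction-relative positions", {
  ev <- toy_event("+")
  cats <- c(e1 = "CRE")
  zero <- overlap_counts(ev, peak(0, 10)[0, ], cats, "SS5")
  expect_true(all(zero == 0))
  # SS5 anchor = 500; genomic [500, 510) is relative +1..+10
  oc <- overlap_counts(ev, peak(500, 510), cats, "SS5")
  expect_equal(unname(oc["CRE", as.character(1:10)]), rep(1L, 10))
  expect_equal(sum(oc), 10L)
  # two overlapping peaks still count the event once per position
  two <- rbind(peak(500, 510), peak(505, 515, name = "p2"))
  oc2 <- overlap_counts(ev, two, cats, "SS5")
  expect_equal(max(oc2), 1L)
  expect_equal(sum(oc2), 15L)
  # peak on an unknown contig is skipped with a message
  expect_message(oc3 <- overlap_counts(ev, peak(500, 510, chrom = "chrX"),
                                       cats, "SS5"), "skipped")
  expect_true(all(oc3 == 0))
})

test_that("cumulative RTS sums per incidence and scales linearly", {
  ev <- toy_event("+")
  cats <- c(e1 = "CRE", ghost = "NT")  # category with no events stays zero
  cr <- cumulative_rts(ev, peak(500, 505, rts = 2.5), cats, "SS5")
  expect_equal(unname(cr["CRE", as.character(1:5)]), rep(2.5, 5))
  expect_equal(sum(cr["CRE", ]), 12.5)
  expect_true(all(cr["NT", ] == 0))
  two <- rbind(peak(500, 505, rts = 2.5), peak(503, 508, rts = 1, name = "p2"))
  cr2 <- cumulative_rts(ev, two, cats, "SS5")
  expect_equal(unname(cr2["CRE", "4"]), 3.5)  # incidences add, unlike counts
  cr2x <- cumulative_rts(ev, transform(two, rts = 2 * rts), cats, "SS5")
  expect_equal(cr2x, 2 * cr2)
})

test_that("raw count mass equals a naive per-position double loop", {
  set.seed(23)
  fx <- cached_fixture("rts_small", synth_config(
    seed = 8, n_events_per_category = c(CRE = 10, CIE = 10, NT = 10),
    rts_peak_rate = 1, rts_background_rate = 0.2))
  cats <- with(fx$truth, setNames(category, event_id))
  for (region in c("SS3", "SS5")) {
    oc <- overlap_counts(fx$events, fx$peaks, cats, region)
    anchors <- splice_site_anchor(fx$events, region)
    naive <- 0L
    for (i in seq_len(nrow(fx$events))) {
      for (g in (anchors[i] - 200):(anchors[i] + 199)) {
        hit <- any(fx$peaks$start <= g & g < fx$peaks$end)
        naive <- naive + hit
      }
    }
    expect_equal(sum(oc), naive, label = region)
  }
})

test_that("mirrored minus-strand fixtures reproduce the plus-strand profile", {
  n <- 3000L
  ev <- toy_event("+")
  twin <- data.frame(event_id = "e1", chrom = "chrS", strand = "-",
                     up_start = n - ev$up_end, up_end = n - ev$up_start,
                     cassette_start = n - ev$cassette_end,
                     cassette_end = n - ev$cassette_start,
                     down_start = n - ev$down_end, down_end = n - ev$down_start)
  pk <- rbind(peak(480, 520), peak(560, 575, rts = 3, name = "p2"))
  pk_m <- transform(pk, start = n - pk$end, end = n - pk$start)
  cats <- c(e1 = "CRE")
  for (region in c("SS3", "SS5")) {
    expect_equal(overlap_counts(ev, pk, cats, region),
                 overlap_counts(twin, pk_m, cats, region), label = region)
    expect_equal(cumulative_rts(ev, pk, cats, region),
                 cumulative_rts(twin, pk_m, cats, region), label = region)
  }
})

test_that("smoothing: centred shrinking-window moving average", {
  expect_equal(smooth_profile(rep(2.5, 50), w = 30), rep(2.5, 50))
  expect_equal(smooth_profile(c(0, 0, 1, 0, 0), w = 1), c(0, 0, 1, 0, 0))
  x <- rep(0, 400); x[200] <- 1
  sm <- smooth_profile(x, w = 30)
  expect_equal(sum(sm > 0), 30L)           # plateau width = window
  expect_equal(unique(round(sm[sm > 0], 10)), round(1 / 30, 10))
  expect_equal(sum(sm), 1)                 # interior mass is conserved
  expect_message(deg <- smooth_profile(1:5, w = 10), "exceeds")
  expect_equal(deg, rep(3, 5))
  # edge windows shrink instead of zero-padding
  y <- c(1, rep(0, 99))
  expect_equal(smooth_profile(y, w = 30)[1], 1 / 15)  # self + 14 in-bounds right
})

test_that("metaprofile concentrates CRE cumulative RTS above other categories", {
  fx <- default_fixture()
  cls <- classify_exons(fx$events, fx$psi)
  mp <- rts_metaprofile(fx$events, fx$peaks, cls)
  expect_setequal(names(mp),
                  c("region", "category", "rel_pos", "count", "smoothed", "cum_rts"))
  mx <- tapply(mp$cum_rts, mp$category, max)
  expect_gt(mx["CRE"], mx["NT"])
  expect_gt(mx["CRE"], mx["CIE"])
  # smoothing preserves interior mass per category x region
  for (region in c("SS3", "SS5")) {
    sub <- mp[mp$region == region & mp$category == "CRE", ]
    expect_equal(sum(sub$smoothed), sum(sub$count), tolerance = 0.05)
  }
})
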
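test_that("contrast summary computes cold-minus-warm deltas and drops orphans", {
  psi <- psi_table(cold = list(a = c(0.2, 0.2), b = c(0.5, 0.5)),
                   warm = list(a = c(0.5, 0.5), b = c(0.5, 0.5)))
  cmp <- summarize_contrast(psi, "cold", "warm")
  expect_equal(cmp$delta_psi[cmp$event_id == "a"], -0.3)
  expect_equal(cmp$delta_psi[cmp$event_id == "b"], 0)

  orphan <- rbind(psi, data.frame(event_id = "c", condition = "warm",
                                  replicate = 1:2, psi = c(0.4, 0.4)))
  expect_message(cmp2 <- summarize_contrast(orphan, "cold", "warm"), "missing")
  expect_false("c" %in% cmp2$event_id)
  expect_identical(attr(cmp2, "dropped_events"), "c")

  expect_error(summarize_contrast(psi, "frozen", "warm"), "available: cold, warm")
  expect_error(summarize_contrast(psi[0, ], "cold", "warm"), "empty")
})

test_that("per-event tests: passthrough, no-effect guard, exact rank test", {
  expect_identical(test_event(method = "external", p = 0.003), 0.003)
  expect_equal(test_event(c(0.3, 0.4, 0.5), c(0.3, 0.4, 0.5), "welch"), 1)
  expect_equal(test_event(c(0.3, 0.3), c(0.3, 0.3), "welch"), 1)
  expect_error(test_event(0.5, c(0.4, 0.4), "welch"), "2 replicates")

  # complete separation at n = 3,3: exact two-sided rank-permutation value
  p_exact <- oracle_ranksum_p(c(0.1, 0.1, 0.1) + c(0, 1e-3, 2e-3),
                              c(0.9, 0.9, 0.9) + c(0, 1e-3, 2e-3))
  p_pkg <- test_event(c(0.1, 0.101, 0.102), c(0.9, 0.901, 0.902), "mann_whitney")
  expect_equal(p_pkg, p_exact)
  expect_equal(p_pkg, 2 / choose(6, 3))
})

test_that("classification applies filters, thresholds and BH as specified", {
  ids <- c("cre_bnd", "hi_psi", "weak", "plain")
  events <- length_events(ids, cassette_length = c(80L, 80L, 80L, 80L))
  psi <- psi_table(
    cold = list(cre_bnd = rep(0.40, 3), hi_psi = rep(0.94, 3),
                weak = rep(0.30, 3), plain = rep(0.50, 3)),
    warm = list(cre_bnd = rep(0.50, 3), hi_psi = rep(0.99, 3),
                weak = rep(0.70, 3), plain = rep(0.50, 3)))
  pv <- c(cre_bnd = 0.001, hi_psi = 0.0001, weak = 0.9, plain = 0.9)
  cls <- classify_exons(events, psi, method = "external", p_values = pv)
  cat_of <- function(id) cls$category[cls$event_id == id]
  # delta = -0.1 exactly, significant: boundary is inclusive -> CRE
  expect_equal(cls$delta_psi[cls$event_id == "cre_bnd"], -0.1)
  expect_equal(cat_of("cre_bnd"), "CRE")
  # mean PSI 0.965 > 0.95 -> excluded regardless of delta and p
  expect_equal(cat_of("hi_psi"), "excluded")
  expect_true(is.na(cls$p_adj[cls$event_id == "hi_psi"]))
  # strong delta but non-significant -> NT
  expect_equal(cat_of("weak"), "NT")
  # short cassette exon -> excluded
  ev_short <- length_events("tiny", cassette_length = 20L)
  psi_short <- psi_table(cold = list(tiny = rep(0.2, 3)),
                         warm = list(tiny = rep(0.6, 3)))
  cls_short <- classify_exons(ev_short, psi_short, method = "external",
                              p_values = c(tiny = 0.001))
  expect_equal(cls_short$category, "excluded")
})

test_that("every event gets exactly one category and thresholds are monotone", {
  fx <- default_fixture()
  cls <- classify_exons(fx$events, fx$psi)
  expect_setequal(cls$event_id, fx$events$event_id)
  expect_true(all(cls$category %in% c("CRE", "CIE", "NT", "excluded")))
  loose <- classify_exons(fx$events, fx$psi, delta_threshold = 0.05)
  called <- function(x) x$event_id[x$category %in% c("CRE", "CIE")]
  expect_true(all(called(cls) %in% called(loose)))
})

test_that("classification intersection: strict vs relaxed sign-only rule", {
  mk <- function(delta, p_adj, category) {
    structure(data.frame(event_id = c("x", "y", "z"), delta_psi = delta,
                         p_adj = p_adj, category = category,
                         stringsAsFactors = FALSE),
              class = c("rg4_classification", "data.frame"))
  }
  a <- mk(c(-0.3, -0.3, 0.0), c(0.01, 0.01, 0.8), c("CRE", "CRE", "NT"))
  b <- mk(c(-0.05, -0.3, -0.3), c(0.01, 0.01, 0.01), c("NT", "CRE", "CRE"))
  expect_identical(intersect_classifications(a, a), # idempotence
                   list(CRE = c("x", "y"), CIE = character(), NT = "z"))
  strict <- intersect_classifications(a, b)
  relaxed <- intersect_classifications(a, b, relaxed = TRUE)
  expect_false("x" %in% strict$CRE)  # |delta| < 0.1 in b under strict rule
  expect_true("x" %in% relaxed$CRE)  # sign-only rule admits it
  expect_false("z" %in% strict$NT)   # NT in a but CRE in b
  disjoint <- mk(c(0, 0, 0), c(1, 1, 1), c("NT", "NT", "NT"))
  disjoint$event_id <- c("q1", "q2", "q3")
  expect_warning(res <- intersect_classifications(a, disjoint), "disjoint")
  expect_identical(res$NT, character())
})

test_that("the rMATS SE dialect round-trips into events, PSI and p-values", {
  tab <- data.frame(ID = 1:2, GeneID = c("g1", "g2"), chr = "chrS",
                    strand = c("+", "-"),
                    exonStart_0base = c(1000L, 5000L), exonEnd = c(1100L, 5080L),
                    upstreamES = c(400L, 5500L), upstreamEE = c(500L, 5600L),
                    downstreamES = c(1500L, 4400L), downstreamEE = c(1600L, 4500L),
                    IncLevel1 = c("0.2,0.25,0.21", "0.8,0.82"),
                    IncLevel2 = c("0.5,0.52,0.51", "0.8,0.81"),
                    PValue = c(1e-5, 0.7), FDR = c(1e-4, 0.8))
  tf <- tempfile(fileext = ".txt")
  write.table(tab, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  parsed <- read_rmats_se(tf)
  expect_equal(nrow(parsed$events), 2L)
  expect_equal(sum(parsed$psi$condition == "cold"), 5L)
  cls <- classify_exons(parsed$events, parsed$psi, method = "external",
                        p_values = parsed$p_values)
  expect_equal(cls$category[cls$event_id == "1"], "CRE")
  expect_equal(cls$category[cls$event_id == "2"], "NT")
})
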
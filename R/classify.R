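#' Per-event PSI contrast summary
#'
#' Averages replicate PSI values within each condition and forms
#' `delta_psi = mean(cold) - mean(warm)` per event, the cold-minus-warm
#' orientation in which cold-repressed exons have negative delta PSI.
#' Events missing either condition are reported and dropped.
#'
#' @param psi long PSI data frame with columns `event_id`, `condition`,
#'   `replicate`, `psi`.
#' @param cold_label,warm_label condition labels of the contrast.
#' @return data frame `event_id`, `psi_cold`, `psi_warm`, `delta_psi`,
#'   `psi_all` (mean over all samples of the contrast), `n_cold`,
#'   `n_warm`; dropped event ids in `attr(, "dropped_events")`.
#' @examples
#' psi <- data.frame(event_id = "e1", condition = rep(c("cold", "warm"), each = 2),
#'                   replicate = c(1, 2, 1, 2), psi = c(0.2, 0.2, 0.5, 0.5))
#' summarize_contrast(psi, "cold", "warm")$delta_psi
#' @export
summarize_contrast <- function(psi, cold_label = "cold", warm_label = "warm") {
  need <- c("event_id", "condition", "replicate", "psi")
  if (!all(need %in% names(psi)))
    stop("input error: PSI table needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (nrow(psi) == 0L)
    stop("input error: PSI table is empty", call. = FALSE)
  labels <- unique(psi$condition)
  for (lab in c(cold_label, warm_label))
    if (!lab %in% labels)
      stop("input error: condition '", lab, "' not found; available: ",
           paste(labels, collapse = ", "), call. = FALSE)
  if (any(psi$psi < 0 | psi$psi > 1, na.rm = TRUE))
    stop("input error: PSI values must lie in [0, 1]", call. = FALSE)
  sub <- psi[psi$condition %in% c(cold_label, warm_label), , drop = FALSE]
  ids <- unique(sub$event_id)
  agg <- function(lab) {
    x <- sub[sub$condition == lab, , drop = FALSE]
    m <- tapply(x$psi, x$event_id, mean)
    n <- tapply(x$psi, x$event_id, length)
    list(mean = unname(m[ids]), n = as.integer(unname(n[ids])))
  }
  cold <- agg(cold_label); warm <- agg(warm_label)
  keep <- !is.na(cold$mean) & !is.na(warm$mean)
  dropped <- ids[!keep]
  if (length(dropped))
    message(length(dropped), " event(s) missing a condition; dropped: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ...")
  out <- data.frame(event_id = ids[keep],
                    psi_cold = cold$mean[keep],
                    psi_warm = warm$mean[keep],
                    delta_psi = cold$mean[keep] - warm$mean[keep],
                    psi_all = (cold$mean[keep] * cold$n[keep] +
                               warm$mean[keep] * warm$n[keep]) /
                              (cold$n[keep] + warm$n[keep]),
                    n_cold = cold$n[keep],
                    n_warm = warm$n[keep],
                    stringsAsFactors = FALSE)
  attr(out, "dropped_events") <- dropped
  out
}

#' Per-event differential-PSI test
#'
#' The upstream splicing caller's likelihood-ratio test is consumed as
#' input wherever available (`method = "external"`, a pass-through);
#' otherwise a two-sided Welch t test or exact Mann-Whitney test on the
#' replicate PSI values substitutes for it.
#'
#' With `method = "welch"` and zero variance on both sides the t statistic
#' is undefined; the test returns 1 when the group means are equal (no
#' evidence of change) and 0 when they differ (noiseless separation).
#'
#' @param psi_cold,psi_warm numeric replicate PSI vectors (>= 2 each for
#'   internal methods).
#' @param method `"welch"`, `"mann_whitney"`, or `"external"`.
#' @param p external p-value (required when `method = "external"`).
#' @return a two-sided p-value in \[0, 1\].
#' @examples
#' test_event(c(0.1, 0.12, 0.09), c(0.5, 0.52, 0.48), "welch")
#' @export
test_event <- function(psi_cold, psi_warm,
                       method = c("welch", "mann_whitney", "external"), p = NULL) {
  method <- match.arg(method)
  if (method == "external") {
    if (is.null(p)) stop("input error: method = 'external' needs a p-value",
                         call. = FALSE)
    return(p)
  }
  if (length(psi_cold) < 2L || length(psi_warm) < 2L)
    stop("degenerate input: internal tests need >= 2 replicates per condition",
         call. = FALSE)
  if (method == "welch") {
    if (stats::sd(psi_cold) == 0 && stats::sd(psi_warm) == 0)
      return(if (isTRUE(all.equal(mean(psi_cold), mean(psi_warm)))) 1 else 0)
    return(stats::t.test(psi_cold, psi_warm)$p.value)
  }
  suppressWarnings(stats::wilcox.test(psi_cold, psi_warm,
                                      alternative = "two.sided"))$p.value
}

#' Classify cassette exons for a temperature contrast
#'
#' Applies the standard filters and thresholds: events with overall mean
#' PSI outside (`psi_min`, `psi_max`) or cassette length <= `min_length`
#' are `excluded`; the remaining events are tested (external p-values or a
#' replicate-level test), Benjamini-Hochberg adjusted within the contrast,
#' and called `CRE` when `delta_psi <= -delta_threshold` with
#' `p_adj < alpha`, `CIE` when `delta_psi >= +delta_threshold` with
#' `p_adj < alpha`, and `NT` otherwise. Delta-PSI thresholds are
#' inclusive; the significance threshold is strict.
#'
#' @param events event data frame (used for cassette lengths; events
#'   absent from it are dropped).
#' @param psi long PSI table (see [summarize_contrast()]).
#' @param cold_label,warm_label contrast condition labels.
#' @param method per-event test: `"external"` requires `p_values`;
#'   `"welch"` (default) or `"mann_whitney"` test replicate PSI values.
#' @param p_values named numeric vector of externally computed per-event
#'   p-values (e.g. from the upstream splicing caller).
#' @param delta_threshold |delta PSI| threshold (default 0.1, inclusive).
#' @param alpha adjusted-p threshold (default 0.05, strict).
#' @param psi_min,psi_max open PSI-filter bounds (defaults 0.05, 0.95).
#' @param min_length minimum cassette length in bases, strict (default 20).
#' @param psi_filter apply the PSI bounds to the `"mean"` PSI over all
#'   samples of the contrast (default) or to every sample
#'   (`"per_sample"`).
#' @return an object of class `rg4_classification`: a data frame with
#'   `event_id`, `psi_cold`, `psi_warm`, `delta_psi`, `exon_length`,
#'   `p_value`, `p_adj`, `category` (one of `CRE`, `CIE`, `NT`,
#'   `excluded`); thresholds are stored in attributes.
#' @export
classify_exons <- function(events, psi, cold_label = "cold", warm_label = "warm",
                           method = c("welch", "mann_whitney", "external"),
                           p_values = NULL,
                           delta_threshold = 0.1, alpha = 0.05,
                           psi_min = 0.05, psi_max = 0.95, min_length = 20L,
                           psi_filter = c("mean", "per_sample")) {
  method <- match.arg(method)
  psi_filter <- match.arg(psi_filter)
  cmp <- summarize_contrast(psi, cold_label, warm_label)
  lens <- stats::setNames(events$cassette_end - events$cassette_start,
                          events$event_id)
  known <- cmp$event_id %in% names(lens)
  if (any(!known))
    message(sum(!known), " PSI event(s) absent from the event table; dropped")
  cmp <- cmp[known, , drop = FALSE]
  if (nrow(cmp) == 0L)
    stop("classification: no events shared between PSI table and event table",
         call. = FALSE)
  cmp$exon_length <- as.integer(lens[cmp$event_id])

  pass_psi <- if (psi_filter == "mean") {
    cmp$psi_all > psi_min & cmp$psi_all < psi_max
  } else {
    sub <- psi[psi$condition %in% c(cold_label, warm_label), , drop = FALSE]
    ok <- tapply(sub$psi > psi_min & sub$psi < psi_max, sub$event_id, all)
    as.logical(ok[cmp$event_id])
  }
  pass <- pass_psi & cmp$exon_length > min_length

  # filter-then-test: BH family = events passing the PSI/length filters
  cmp$p_value <- NA_real_
  tested <- which(pass)
  if (length(tested)) {
    if (method == "external") {
      if (is.null(p_values))
        stop("input error: method = 'external' needs p_values", call. = FALSE)
      cmp$p_value[tested] <- unname(p_values[cmp$event_id[tested]])
      if (anyNA(cmp$p_value[tested]))
        stop("input error: external p-values missing for some tested events",
             call. = FALSE)
    } else {
      sub <- psi[psi$condition %in% c(cold_label, warm_label), , drop = FALSE]
      cold <- split(sub$psi[sub$condition == cold_label],
                    sub$event_id[sub$condition == cold_label])
      warm <- split(sub$psi[sub$condition == warm_label],
                    sub$event_id[sub$condition == warm_label])
      cmp$p_value[tested] <- vapply(cmp$event_id[tested], function(id)
        test_event(cold[[id]], warm[[id]], method), numeric(1))
    }
  }
  cmp$p_adj <- NA_real_
  cmp$p_adj[tested] <- bh_adjust(cmp$p_value[tested])

  cmp$category <- "excluded"
  sig <- pass & cmp$p_adj < alpha
  cmp$category[pass] <- "NT"
  # inclusive delta-PSI thresholds, with a tolerance so that means computed
  # in floating point (e.g. 0.4 - 0.5) still sit on the boundary
  eps <- 1e-9
  cmp$category[sig & cmp$delta_psi <= -delta_threshold + eps] <- "CRE"
  cmp$category[sig & cmp$delta_psi >= delta_threshold - eps] <- "CIE"

  cmp <- cmp[, c("event_id", "psi_cold", "psi_warm", "delta_psi", "psi_all",
                 "exon_length", "p_value", "p_adj", "category")]
  attr(cmp, "thresholds") <- list(delta_threshold = delta_threshold,
                                  alpha = alpha, psi_min = psi_min,
                                  psi_max = psi_max, min_length = min_length,
                                  psi_filter = psi_filter, method = method)
  attr(cmp, "contrast") <- c(cold = cold_label, warm = warm_label)
  class(cmp) <- c("rg4_classification", "data.frame")
  cmp
}

#' @export
print.rg4_classification <- function(x, ...) {
  ct <- attr(x, "contrast")
  cat("Cassette-exon classification (", ct["cold"], " vs ", ct["warm"], ")\n",
      sep = "")
  tab <- table(factor(x$category, levels = c("CRE", "CIE", "NT", "excluded")))
  print(tab)
  th <- attr(x, "thresholds")
  cat(sprintf("thresholds: |dPSI| >= %.2g, BH p < %.2g, PSI in (%.2g, %.2g), length > %d, test = %s\n",
              th$delta_threshold, th$alpha, th$psi_min, th$psi_max,
              th$min_length, th$method))
  invisible(x)
}

#' Intersect two classifications
#'
#' Shared categories across two contrasts (e.g. two cell lines or two
#' temperature comparisons): shared NTs are the intersection of NT calls.
#' Under the strict rule, shared CREs/CIEs are events called so in both
#' inputs; under the relaxed rule they are events with `p_adj < alpha` in
#' both inputs and delta PSI of the matching sign in both (no magnitude
#' requirement) — the convention for building a high-confidence shared set.
#'
#' @param a,b `rg4_classification` objects.
#' @param relaxed use the sign-only rule for CRE/CIE (default `FALSE`).
#' @param alpha adjusted-p threshold for the relaxed rule.
#' @return list with character vectors `CRE`, `CIE`, `NT` of shared event
#'   ids.
#' @export
intersect_classifications <- function(a, b, relaxed = FALSE, alpha = 0.05) {
  common <- intersect(a$event_id, b$event_id)
  if (!length(common)) {
    warning("disjoint event universes; empty intersection")
    return(list(CRE = character(), CIE = character(), NT = character()))
  }
  pick <- function(x, cat) x$event_id[x$category == cat]
  nt <- intersect(pick(a, "NT"), pick(b, "NT"))
  if (relaxed) {
    rel <- function(x, sign) {
      ok <- !is.na(x$p_adj) & x$p_adj < alpha & sign * x$delta_psi > 0
      x$event_id[ok]
    }
    cre <- intersect(rel(a, -1), rel(b, -1))
    cie <- intersect(rel(a, 1), rel(b, 1))
  } else {
    cre <- intersect(pick(a, "CRE"), pick(b, "CRE"))
    cie <- intersect(pick(a, "CIE"), pick(b, "CIE"))
  }
  list(CRE = cre, CIE = cie, NT = nt)
}
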
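#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (via [stats::p.adjust()]) with
#' input validation: monotone after sorting, capped at 1, order-preserving
#' with the input.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order as input.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("input error: p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Compare G content between exon categories
#'
#' Two-sided Wilcoxon rank-sum tests of per-event G content (or any
#' per-event score) for the requested contrasts, by default CRE vs NT and
#' CRE vs CIE. [stats::wilcox.test()] uses the exact distribution for
#' small untied samples and the tie-corrected normal approximation
#' otherwise. The effect size is the difference of group medians.
#'
#' @param values numeric vector of per-event values.
#' @param categories character vector of categories, parallel to `values`.
#' @param region region label carried into the result.
#' @param contrasts list of length-2 character vectors of categories to
#'   compare.
#' @return data frame with one row per contrast: `region`, `contrast`,
#'   `test`, `statistic`, `p_value`, `effect` (median difference), `n1`,
#'   `n2`. Contrasts with fewer than two observations in a group are
#'   skipped with a message.
#' @export
compare_gcontent <- function(values, categories, region = NA_character_,
                             contrasts = list(c("CRE", "NT"), c("CRE", "CIE"))) {
  stopifnot(length(values) == length(categories))
  rows <- list()
  for (ct in contrasts) {
    x <- values[categories == ct[1]]
    y <- values[categories == ct[2]]
    if (length(x) < 2L || length(y) < 2L) {
      message("contrast ", ct[1], " vs ", ct[2], " skipped in ", region,
              ": fewer than 2 observations in a group")
      next
    }
    wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
    rows[[length(rows) + 1L]] <- data.frame(
      region = region, contrast = paste(ct[1], "vs", ct[2]),
      test = "wilcoxon", statistic = unname(wt$statistic),
      p_value = wt$p.value,
      effect = stats::median(x) - stats::median(y),
      n1 = length(x), n2 = length(y), stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(region = character(), contrast = character(),
                      test = character(), statistic = numeric(),
                      p_value = numeric(), effect = numeric(),
                      n1 = integer(), n2 = integer(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Hypergeometric motif-proportion enrichment
#'
#' One-sided over-representation test: with `K` motif-bearing events among
#' `N` in the population, the probability of observing at least `k`
#' motif-bearing events in a category of size `n`,
#' `P[X >= k], X ~ Hypergeometric(N, K, n)`. The effect size is the
#' proportion difference `k/n - K/N`.
#'
#' @param k motif-bearing events in the category.
#' @param n category size.
#' @param K motif-bearing events in the population.
#' @param N population size.
#' @return one-row data frame `test`, `statistic` (= `k`), `p_value`,
#'   `effect`, `n1` (= `n`), `n2` (= `N`).
#' @examples
#' motif_enrichment(5, 5, 5, 10)  # p = 1 / choose(10, 5)
#' @export
motif_enrichment <- function(k, n, K, N) {
  vals <- c(k = k, n = n, K = K, N = N)
  if (any(vals < 0) || k > n || k > K || n > N || K > N)
    stop("input error: need 0 <= k <= min(n, K) and n, K <= N", call. = FALSE)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  data.frame(test = "hypergeometric", statistic = k, p_value = p,
             effect = k / n - K / N, n1 = n, n2 = N, stringsAsFactors = FALSE)
}

#' Category-mean positional score profiles
#'
#' Position-wise arithmetic mean of per-event window-score profiles within
#' each category; positions missing some events (dropped windows) are
#' averaged over the available events, with `n` reported per position.
#'
#' @param profiles long profile data frame (`event_id`, `region`,
#'   `rel_pos`, `score`), e.g. from [score_flanks()].
#' @param categories named character vector mapping `event_id` to
#'   category, or an `rg4_classification`.
#' @param region region to summarise (default: all regions present).
#' @return long data frame `region`, `category`, `rel_pos`, `mean_score`,
#'   `n`. Empty categories yield no rows, with a warning.
#' @export
mean_profile <- function(profiles, categories, region = NULL) {
  categories <- as_category_map(categories)
  if (!is.null(region))
    profiles <- profiles[profiles$region %in% region, , drop = FALSE]
  profiles$category <- unname(categories[profiles$event_id])
  profiles <- profiles[!is.na(profiles$category), , drop = FALSE]
  if (!nrow(profiles)) {
    warning("no profiles for the requested categories")
    return(data.frame(region = character(), category = character(),
                      rel_pos = integer(), mean_score = numeric(),
                      n = integer(), stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(score ~ region + category + rel_pos, data = profiles,
                          FUN = function(v) c(mean = mean(v), n = length(v)))
  out <- data.frame(region = agg$region, category = agg$category,
                    rel_pos = agg$rel_pos,
                    mean_score = agg$score[, "mean"],
                    n = as.integer(agg$score[, "n"]),
                    stringsAsFactors = FALSE)
  out[order(out$region, out$category, out$rel_pos), , drop = FALSE]
}

as_category_map <- function(categories) {
  if (inherits(categories, "rg4_classification") || is.data.frame(categories))
    return(stats::setNames(categories$category, categories$event_id))
  if (is.null(names(categories)))
    stop("input error: categories must be named by event_id", call. = FALSE)
  categories
}

#' Per-position correlation of G4 score with delta PSI
#'
#' At each junction-relative position, correlates the window score at that
#' position with per-event delta PSI across events (Spearman rank
#' correlation by default; Pearson by flag). Positions where the scores or
#' the delta-PSI values have zero variance give an undefined coefficient,
#' reported as `NA` (distinct from 0).
#'
#' @param profiles long profile data frame (`event_id`, `region`,
#'   `rel_pos`, `score`).
#' @param delta_psi named numeric vector mapping `event_id` to delta PSI,
#'   or an `rg4_classification`.
#' @param region single region to correlate.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param min_events minimum events per position (default 3).
#' @return data frame `region`, `rel_pos`, `coefficient`, `p_value`, `n`.
#' @export
positional_correlation <- function(profiles, delta_psi, region,
                                   method = c("spearman", "pearson"),
                                   min_events = 3L) {
  method <- match.arg(method)
  if (inherits(delta_psi, "rg4_classification") || is.data.frame(delta_psi))
    delta_psi <- stats::setNames(delta_psi$delta_psi, delta_psi$event_id)
  sub <- profiles[profiles$region == region, , drop = FALSE]
  sub$dpsi <- unname(delta_psi[sub$event_id])
  sub <- sub[!is.na(sub$dpsi), , drop = FALSE]
  positions <- sort(unique(sub$rel_pos))
  rows <- lapply(positions, function(p) {
    at <- sub[sub$rel_pos == p, , drop = FALSE]
    n <- nrow(at)
    if (n < min_events)
      return(data.frame(region = region, rel_pos = p, coefficient = NA_real_,
                        p_value = NA_real_, n = n, stringsAsFactors = FALSE))
    if (stats::sd(at$score) == 0 || stats::sd(at$dpsi) == 0)
      return(data.frame(region = region, rel_pos = p, coefficient = NA_real_,
                        p_value = NA_real_, n = n, stringsAsFactors = FALSE))
    ct <- suppressWarnings(stats::cor.test(at$score, at$dpsi, method = method,
                                           exact = FALSE))
    data.frame(region = region, rel_pos = p,
               coefficient = unname(ct$estimate), p_value = ct$p.value,
               n = n, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
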
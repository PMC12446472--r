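#' Pipeline run configuration
#'
#' Collects inputs, thresholds and statistical choices for the end-to-end
#' analysis. Inputs may be file paths (genome FASTA, events TSV, PSI TSV,
#' peaks BED) or the corresponding in-memory objects.
#'
#' @param genome genome FASTA path or [Biostrings::DNAStringSet].
#' @param events events TSV path or event data frame.
#' @param psi PSI TSV path or long PSI data frame.
#' @param peaks optional RTS peaks BED path or data frame; `NULL` skips
#'   the rG4-seq stage.
#' @param output_dir optional directory; when set, every stage writes its
#'   table there and the manifest records file checksums.
#' @param cold_label,warm_label contrast condition labels.
#' @param test_method per-event test (see [classify_exons()]).
#' @param p_values external per-event p-values for
#'   `test_method = "external"`.
#' @param delta_threshold,alpha,psi_min,psi_max,min_length classification
#'   thresholds (defaults 0.1, 0.05, 0.05, 0.95, 20).
#' @param g4_threshold G4 call threshold on the window score (default 1,
#'   strict `>`).
#' @param window composition/motif window half-width (default 25).
#' @param flank scanning flank half-width (default 200).
#' @param w G4Hunter window width (default 25).
#' @param smooth RTS metaprofile smoothing window in nt (default 30).
#' @param cor_method positional-correlation flavour (default
#'   `"spearman"`).
#' @param motif [g4_motif()] definition used by the motif scanner.
#' @param seed integer seed recorded in the manifest (the analysis itself
#'   is deterministic).
#' @return an object of class `rg4_config`.
#' @export
run_config <- function(genome, events, psi, peaks = NULL, output_dir = NULL,
                       cold_label = "cold", warm_label = "warm",
                       test_method = c("welch", "mann_whitney", "external"),
                       p_values = NULL,
                       delta_threshold = 0.1, alpha = 0.05,
                       psi_min = 0.05, psi_max = 0.95, min_length = 20L,
                       g4_threshold = 1, window = 25L, flank = 200L, w = 25L,
                       smooth = 30L, cor_method = c("spearman", "pearson"),
                       motif = g4_motif(), seed = 1L) {
  test_method <- match.arg(test_method)
  cor_method <- match.arg(cor_method)
  for (v in c(delta_threshold = delta_threshold, alpha = alpha,
              window = window, flank = flank, w = w, smooth = smooth))
    if (v <= 0) stop("configuration error: thresholds and window sizes must ",
                     "be positive", call. = FALSE)
  structure(list(genome = genome, events = events, psi = psi, peaks = peaks,
                 output_dir = output_dir,
                 cold_label = cold_label, warm_label = warm_label,
                 test_method = test_method, p_values = p_values,
                 delta_threshold = delta_threshold, alpha = alpha,
                 psi_min = psi_min, psi_max = psi_max,
                 min_length = as.integer(min_length),
                 g4_threshold = g4_threshold,
                 window = as.integer(window), flank = as.integer(flank),
                 w = as.integer(w), smooth = as.integer(smooth),
                 cor_method = cor_method, motif = motif,
                 seed = as.integer(seed)),
            class = "rg4_config")
}

load_input <- function(x, reader) if (is.character(x) && length(x) == 1L)
  reader(x) else x

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the end-to-end splice-site rG4 analysis
#'
#' Orchestrates classification, window extraction, G-content / motif /
#' G4Hunter scoring, category enrichment statistics, positional
#' score-delta-PSI correlation and (when peaks are supplied) rG4-seq RTS
#' metaprofiles, from one [run_config()]. Deterministic given the
#' configuration; when `output_dir` is set, every stage writes a TSV and
#' the manifest records their md5 checksums.
#'
#' @param config an [run_config()] object.
#' @return an object of class `rg4_run`: a list with `classification`,
#'   `gcontent` (per-event per-region G content and motif flags),
#'   `enrichment` (Wilcoxon and hypergeometric rows with BH adjustment
#'   within each test family), `profiles` (long G4Hunter flank profiles),
#'   `mean_profiles`, `region_scores` (per-event maxima and G4 calls),
#'   `g4_summary` (per-category n, n with score > threshold, fraction),
#'   `correlation`, `rts` (metaprofile or `NULL`) and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "rg4_config"))
  genome <- stage("load", load_input(config$genome, read_genome_fasta))
  genome <- as_genome(genome)
  events <- stage("load", validate_events(load_input(config$events, read_events_tsv)))
  psi <- stage("load", load_input(config$psi, read_psi_tsv))
  peaks <- if (is.null(config$peaks)) NULL else
    stage("load", validate_peaks(load_input(config$peaks, read_peaks_bed)))

  cls <- stage("classification",
    classify_exons(events, psi, config$cold_label, config$warm_label,
                   method = config$test_method, p_values = config$p_values,
                   delta_threshold = config$delta_threshold,
                   alpha = config$alpha, psi_min = config$psi_min,
                   psi_max = config$psi_max, min_length = config$min_length))
  kept <- cls[cls$category != "excluded", , drop = FALSE]
  ev_kept <- events[match(kept$event_id, events$event_id), , drop = FALSE]
  catmap <- stats::setNames(kept$category, kept$event_id)

  # 50-bp windows: G content + motif presence per region
  gcontent <- stage("windows", {
    rows <- lapply(SPLICE_REGIONS, function(region) {
      win <- extract_windows(genome, ev_kept, region,
                             half_width = config$window)
      data.frame(event_id = win$event_id, region = region,
                 g_content = g_content(win$sequence),
                 has_motif = has_g4_motif(win$sequence, config$motif),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  gcontent$category <- unname(catmap[gcontent$event_id])

  enrichment <- stage("enrichment", {
    gtests <- do.call(rbind, lapply(SPLICE_REGIONS, function(region) {
      sub <- gcontent[gcontent$region == region, , drop = FALSE]
      compare_gcontent(sub$g_content, sub$category, region = region)
    }))
    if (nrow(gtests)) gtests$p_adj <- bh_adjust(gtests$p_value)
    mtests <- do.call(rbind, lapply(SPLICE_REGIONS, function(region) {
      sub <- gcontent[gcontent$region == region, , drop = FALSE]
      do.call(rbind, lapply(list(c("CRE", "NT"), c("CRE", "CIE")), function(ct) {
        a <- sub[sub$category == ct[1], , drop = FALSE]
        b <- sub[sub$category == ct[2], , drop = FALSE]
        if (nrow(a) == 0L || nrow(b) == 0L) return(NULL)
        row <- motif_enrichment(sum(a$has_motif), nrow(a),
                                sum(a$has_motif) + sum(b$has_motif),
                                nrow(a) + nrow(b))
        cbind(data.frame(region = region,
                         contrast = paste(ct[1], "vs", ct[2]),
                         stringsAsFactors = FALSE), row)
      }))
    }))
    if (!is.null(mtests) && nrow(mtests)) mtests$p_adj <- bh_adjust(mtests$p_value)
    rbind(gtests, mtests)
  })

  profiles <- stage("scanning",
    score_flanks(genome, ev_kept, regions = c("SS3", "SS5"),
                 flank = config$flank, w = config$w))
  meanprof <- stage("scanning", mean_profile(profiles, catmap))
  rscores <- stage("scanning",
                   region_max_scores(profiles, threshold = config$g4_threshold))
  rscores$category <- unname(catmap[rscores$event_id])
  g4_summary <- stage("scanning", {
    ok <- !is.na(rscores$max_SS35)
    agg <- tapply(rscores$has_g4[ok], rscores$category[ok],
                  function(v) c(n = length(v), n_g4 = sum(v)))
    cats <- names(agg)
    data.frame(category = cats,
               n = vapply(agg, `[[`, numeric(1), "n"),
               n_g4 = vapply(agg, `[[`, numeric(1), "n_g4"),
               fraction_g4 = vapply(agg, function(z) z["n_g4"] / z["n"],
                                    numeric(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  })

  correlation <- stage("correlation", {
    do.call(rbind, lapply(c("SS3", "SS5"), function(region)
      positional_correlation(profiles, kept, region,
                             method = config$cor_method)))
  })

  rts <- if (is.null(peaks)) NULL else
    stage("rts", rts_metaprofile(ev_kept, peaks, catmap,
                                 regions = c("SS3", "SS5"),
                                 flank = config$flank,
                                 smooth = config$smooth))

  manifest <- list(
    package_version = as.character(utils::packageVersion("rg4splice")),
    config_hash = config_hash(config),
    seed = config$seed,
    n_events_in = nrow(events),
    n_excluded = sum(cls$category == "excluded"),
    n_CRE = sum(cls$category == "CRE"),
    n_CIE = sum(cls$category == "CIE"),
    n_NT = sum(cls$category == "NT"),
    n_peaks = if (is.null(peaks)) 0L else nrow(peaks))

  run <- structure(list(classification = cls, gcontent = gcontent,
                        enrichment = enrichment, profiles = profiles,
                        mean_profiles = meanprof, region_scores = rscores,
                        g4_summary = g4_summary, correlation = correlation,
                        rts = rts, manifest = manifest, config = config),
                   class = "rg4_run")
  if (!is.null(config$output_dir)) {
    run$manifest$checksums <- write_run(run, config$output_dir)
  } else {
    run$manifest$checksums <- in_memory_checksums(run)
  }
  run
}

config_hash <- function(config) {
  flat <- config[setdiff(names(config),
                         c("genome", "events", "psi", "peaks", "p_values",
                           "output_dir"))]
  digest_text(paste(deparse(flat), collapse = "\n"))
}

digest_text <- function(txt) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(txt, tf)
  unname(tools::md5sum(tf))
}

run_tables <- function(run) {
  tabs <- list(classification = as.data.frame(run$classification),
               gcontent = run$gcontent,
               enrichment = run$enrichment,
               profiles = run$profiles,
               mean_profiles = run$mean_profiles,
               region_scores = run$region_scores,
               g4_summary = run$g4_summary,
               correlation = run$correlation)
  if (!is.null(run$rts)) tabs$rts <- run$rts
  tabs
}

in_memory_checksums <- function(run) {
  vapply(run_tables(run), function(df) {
    tf <- tempfile(fileext = ".tsv")
    on.exit(unlink(tf))
    write_tsv(df, tf)
    unname(tools::md5sum(tf))
  }, character(1))
}

#' Write every result table of a run
#'
#' One TSV per stage plus a `manifest.txt` of `key=value` lines including
#' md5 checksums of the written tables.
#'
#' @param run an `rg4_run` object.
#' @param dir output directory (created if needed).
#' @return named vector of table checksums, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- run_tables(run)
  paths <- character(0)
  for (nm in names(tabs))
    paths[nm] <- write_tsv(tabs[[nm]], file.path(dir, paste0(nm, ".tsv")))
  sums <- tools::md5sum(paths)
  names(sums) <- names(paths)
  m <- run$manifest
  m$checksums <- NULL
  lines <- c(paste0(names(m), "=", unlist(m)),
             paste0("md5.", names(sums), "=", sums))
  writeLines(lines, file.path(dir, "manifest.txt"))
  invisible(sums)
}

#' @export
print.rg4_run <- function(x, ...) {
  m <- x$manifest
  cat("Splice-site rG4 analysis run\n")
  cat(sprintf("  events: %d in, %d excluded | CRE %d, CIE %d, NT %d\n",
              m$n_events_in, m$n_excluded, m$n_CRE, m$n_CIE, m$n_NT))
  if (!is.null(x$g4_summary) && nrow(x$g4_summary)) {
    cre <- x$g4_summary[x$g4_summary$category == "CRE", , drop = FALSE]
    if (nrow(cre))
      cat(sprintf("  CRE with predicted rG4 (max SS3/5 score > %g): %d/%d (%.1f%%)\n",
                  x$config$g4_threshold, cre$n_g4, cre$n, 100 * cre$fraction_g4))
  }
  cat("  config hash:", m$config_hash, "\n")
  invisible(x)
}

#' @export
summary.rg4_run <- function(object, ...) {
  cat("Category G4 calls (max SS3/SS5 window score > ",
      object$config$g4_threshold, "):\n", sep = "")
  print(object$g4_summary, row.names = FALSE)
  cat("\nEnrichment tests:\n")
  print(object$enrichment, row.names = FALSE, digits = 3)
  invisible(object)
}

#' Plot category-mean G4 score profiles
#'
#' Base-graphics line plot of the mean G4Hunter window score per category
#' around the requested splice site, the in-silico analogue of a
#' metaprofile figure.
#'
#' @param x an `rg4_run` object.
#' @param region region to plot (default `"SS5"`).
#' @param ... further arguments passed to [graphics::matplot()].
#' @return the plotted data, invisibly.
#' @export
plot.rg4_run <- function(x, region = "SS5", ...) {
  mp <- x$mean_profiles[x$mean_profiles$region == region, , drop = FALSE]
  if (!nrow(mp)) stop("no mean profile for region ", region, call. = FALSE)
  cats <- sort(unique(mp$category))
  pos <- sort(unique(mp$rel_pos))
  mat <- sapply(cats, function(ct) {
    v <- mp$mean_score[mp$category == ct][match(pos, mp$rel_pos[mp$category == ct])]
    v
  })
  graphics::matplot(pos, mat, type = "l", lty = 1, lwd = 2,
                    col = seq_along(cats),
                    xlab = paste("position relative to", region, "junction (nt)"),
                    ylab = "mean G4Hunter window score", ...)
  graphics::abline(v = 0, lty = 3)
  graphics::legend("topright", legend = cats, col = seq_along(cats),
                   lwd = 2, bty = "n")
  invisible(mp)
}
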
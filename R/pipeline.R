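#' Validate a pipeline configuration
#'
#' Reads a YAML configuration file (or takes a named list), fills in
#' defaults, and checks cross-field constraints. Unknown keys and violated
#' constraints are rejected with messages naming the key.
#'
#' @param config path to a YAML file, or a named list.
#' @return A validated list of class \code{pipeline_config} with all
#'   defaults applied.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    mode = "synthetic",
    n_male = 9L, n_female = 9L, duration_s = 3600,
    onset_range = c(0.25, 0.5), error_rate = 0.1,
    window_s = 120, step_s = 60,
    alpha = 0.01, test_fraction = 0.2, min_samples = 5L,
    subset_sizes = c(2L, 3L, 4L),
    groups = c("all", "male", "female"),
    seed = NULL, out_dir = NULL,
    resample_hz = 4, band_vlf = c(0.0033, 0.04),
    band_lf = c(0.04, 0.15), band_hf = c(0.15, 0.40),
    spectral_window_s = 64, spectral_overlap = 0.5
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config)
  if (!cfg$mode %in% c("synthetic", "rr")) {
    stop("mode must be 'synthetic' or 'rr'")
  }
  if (cfg$mode == "synthetic" && is.null(cfg$seed)) {
    stop("seed is mandatory in synthetic mode")
  }
  if (cfg$step_s > cfg$window_s) {
    stop("constraint violated: step_s must not exceed window_s")
  }
  if (cfg$window_s > cfg$duration_s) {
    stop("constraint violated: window_s must not exceed duration_s")
  }
  # these constructors validate their own fields
  cohort_config(cfg$n_male, cfg$n_female, cfg$duration_s, cfg$onset_range,
                cfg$error_rate, if (is.null(cfg$seed)) 1L else cfg$seed)
  spectral_config(cfg$resample_hz, cfg$band_vlf, cfg$band_lf, cfg$band_hf,
                  cfg$spectral_window_s, cfg$spectral_overlap)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Segment and label a simulated cohort
#'
#' Cuts each subject's RR recording into overlapping windows, applies the
#' expert-consensus label, and drops discordant segments.
#'
#' @param cohort list of subjects from \code{simulate_cohort}.
#' @param duration_s,window_s,step_s windowing parameters (s).
#' @param quiet suppress count messages.
#' @return List of labelled, non-discordant \code{segment}s pooled over
#'   subjects; attribute \code{n_total} holds the pre-filter count.
#' @export
cohort_segments <- function(cohort, duration_s, window_s = 120, step_s = 60,
                            quiet = TRUE) {
  segs <- unlist(lapply(cohort, function(subj) {
    s <- segment_recording(subj$rr, duration_s, window_s, step_s,
                           subject_id = subj$subject_id, sex = subj$sex)
    label_segments(s, subj$votes)
  }), recursive = FALSE)
  out <- suppressWarnings(filter_discordant(segs, quiet = quiet))
  attr(out, "n_total") <- length(segs)
  out
}

#' Run the full fatigue-detection study pipeline
#'
#' Synthetic mode: simulates the cohort, windows and labels the recordings,
#' extracts the twenty HRV features per segment, produces per-group
#' alert-vs-fatigued comparison tables with the direction-of-change summary,
#' and runs the exhaustive feature-subset searches. All tables are returned
#' and, when \code{out_dir} is set, written as tab-delimited text. Identical
#' configuration and seed reproduce identical outputs.
#'
#' @param config a \code{pipeline_config} (or anything
#'   \code{validate_config} accepts).
#' @param quiet suppress stage progress messages.
#' @return List of class \code{run_report}: \code{config}, \code{segments}
#'   (segment table), \code{features} (feature matrix), \code{comparisons}
#'   (per group), \code{directions}, \code{search} (per group, per subset
#'   size), \code{counts}.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  cfg <- validate_config(if (inherits(config, "pipeline_config")) {
    unclass(config)
  } else config)
  say <- function(...) if (!quiet) message(sprintf(...))
  stopifnot(cfg$mode == "synthetic")

  t0 <- proc.time()[3]
  cc <- cohort_config(cfg$n_male, cfg$n_female, cfg$duration_s,
                      cfg$onset_range, cfg$error_rate, cfg$seed)
  cohort <- simulate_cohort(cc)
  say("simulated %d subjects (%.1f s)", length(cohort), proc.time()[3] - t0)

  segs <- cohort_segments(cohort, cfg$duration_s, cfg$window_s, cfg$step_s)
  seg_tab <- segment_table(segs)
  say("segments: %d retained of %d windows", length(segs),
      attr(segs, "n_total"))

  scfg <- spectral_config(cfg$resample_hz, cfg$band_vlf, cfg$band_lf,
                          cfg$band_hf, cfg$spectral_window_s,
                          cfg$spectral_overlap)
  feats <- feature_matrix(segs, scfg)
  say("features: %d rows x %d features", nrow(feats),
      length(hrv_feature_names()))

  comparisons <- list()
  for (g in cfg$groups) {
    comparisons[[g]] <- compare_states(feats, g, alpha = cfg$alpha)
    say("group %s: %d/%d features significant at alpha = %g", g,
        sum(comparisons[[g]]$significant), length(hrv_feature_names()),
        cfg$alpha)
  }
  directions <- do.call(direction_summary, unname(comparisons))

  search <- list()
  for (g in cfg$groups) {
    gf <- if (g == "all") feats else feats[feats$sex == g, ]
    search[[g]] <- lapply(cfg$subset_sizes, function(k) {
      res <- exhaustive_subset_search(gf, k, min_samples = cfg$min_samples,
                                      seed = cfg$seed,
                                      test_fraction = cfg$test_fraction)
      say("group %s, k = %d: %d subsets, best ACC %.1f%% (%s)", g, k,
          nrow(res), res$ACC[1], res$subset[1])
      res
    })
    names(search[[g]]) <- paste0("k", cfg$subset_sizes)
  }

  counts <- list(
    n_subjects = length(cohort),
    n_windows = attr(segs, "n_total"),
    n_alert = sum(seg_tab$label == "alert"),
    n_fatigued = sum(seg_tab$label == "fatigued"),
    n_discordant = attr(segs, "n_total") - nrow(seg_tab)
  )

  report <- structure(
    list(config = cfg, segments = seg_tab, features = feats,
         comparisons = comparisons, directions = directions,
         search = search, counts = counts),
    class = "run_report"
  )
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' Write the tables of a run report as delimited text
#'
#' @param report a \code{run_report}.
#' @param out_dir output directory (created if needed).
#' @return \code{out_dir}, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  wt(report$segments, "segments.tsv")
  wt(report$features, "features.tsv")
  for (g in names(report$comparisons)) {
    wt(report$comparisons[[g]], sprintf("comparison_%s.tsv", g))
  }
  wt(report$directions, "directions.tsv")
  for (g in names(report$search)) {
    for (k in names(report$search[[g]])) {
      wt(utils::head(report$search[[g]][[k]], 50),
         sprintf("search_%s_%s.tsv", g, k))
    }
  }
  writeLines(yaml::as.yaml(unclass(report$config)),
             file.path(out_dir, "config_echo.yaml"))
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Fatigue-detection pipeline report\n")
  cat(sprintf("  subjects: %d, windows: %d (alert %d / fatigued %d / discordant %d)\n",
              x$counts$n_subjects, x$counts$n_windows, x$counts$n_alert,
              x$counts$n_fatigued, x$counts$n_discordant))
  for (g in names(x$comparisons)) {
    cat(sprintf("  %s: %d/20 features significant", g,
                sum(x$comparisons[[g]]$significant)))
    if (g %in% names(x$search)) {
      accs <- vapply(x$search[[g]], function(r) r$ACC[1], numeric(1))
      cat(sprintf("; best ACC %s",
                  paste(sprintf("%s=%.1f%%", names(accs), accs),
                        collapse = " ")))
    }
    cat("\n")
  }
  invisible(x)
}
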
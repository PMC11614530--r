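# End-to-end analysis: events -> filters -> ratios/CV -> uniform null + KS ->
# on/off battery -> mixed models -> report bundle.

#' Pipeline configuration
#'
#' @param min_ratios_overall Minimum interval ratios per individual for the
#'   pooled analyses (default 50).
#' @param min_ratios_mode Minimum ratios per individual within a mode for the
#'   per-mode analyses (default 25).
#' @param min_displays_tempo Minimum displays (within the mode view) for the
#'   tempo comparison (default 4).
#' @param n_null_draws Draws of the simulated uniform null (default 100000).
#' @param alpha Significance level after BH correction (default 0.05).
#' @param seed Master seed; every stochastic stage derives its own seed from
#'   it deterministically.
#' @param scheme Rhythm-category scheme (default [rhythm_scheme()]).
#' @param neighbours Off-bin combination rule for the battery
#'   (`"pool"`/`"mean"`).
#' @param write_null_draws Also write the raw null draws CSV (large; default
#'   `FALSE`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_ratios_overall = 50L,
                            min_ratios_mode = 25L,
                            min_displays_tempo = 4L,
                            n_null_draws = 100000L,
                            alpha = 0.05,
                            seed = 1L,
                            scheme = rhythm_scheme(),
                            neighbours = "pool",
                            write_null_draws = FALSE) {
  stopifnot(min_ratios_overall >= 1, min_ratios_mode >= 1,
            min_displays_tempo >= 1, n_null_draws >= 1,
            alpha > 0, alpha < 1)
  structure(as.list(environment()), class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full rhythm analysis
#'
#' Executes every analysis stage on an assembled observation set: interval
#' and ratio extraction, inclusion filtering, per-sequence regularity (CV),
#' bin-width-normalised density profiles, the simulated-uniform-null KS
#' comparison and the paired on/off Wilcoxon battery for the pooled, vocal
#' and motoric subsets (each against a null built on its own observed
#' interval range), the CV linear mixed model and the isochrony-rate binomial
#' mixed model, and per-individual tempo summaries. All stochastic stages
#' derive their seeds from `config$seed`, so identical inputs and config
#' reproduce every number exactly.
#'
#' Subsets that do not meet a stage's requirements (no data in a mode, too
#' few individuals for a paired test, fewer than two levels of a fixed
#' effect) are marked not-applicable in the report rather than aborting the
#' run; genuine stage errors abort with the stage name.
#'
#' @param obs An `observation_set`, or a path to a unified event CSV.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory; when given, all report tables
#'   are written as tidy CSVs plus a JSON run manifest.
#' @return A list of class `rhythm_report`; see the element names for the
#'   stage outputs.
#' @export
run_full_analysis <- function(obs, config = pipeline_config(),
                              out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  notes <- character()
  note <- function(msg) notes <<- c(notes, msg)

  obs <- run_stage("read", {
    if (is.character(obs)) obs <- assemble_observation_set(read_events_csv(obs))
    stopifnot(inherits(obs, "observation_set"))
    obs
  })
  scheme <- config$scheme

  intervals <- run_stage("intervals", sequence_intervals(obs))
  ratios <- run_stage("ratios", interval_ratios_table(intervals, scheme))
  filters <- run_stage("filters", apply_inclusion_filters(
    ratios, config$min_ratios_overall, config$min_ratios_mode,
    config$min_displays_tempo
  ))
  stats_tbl <- run_stage("sequence_stats", sequence_stats(intervals))

  subsets <- list(
    all = list(individuals = filters$overall, mode = c("vocal", "motoric")),
    vocal = list(individuals = filters$vocal, mode = "vocal"),
    motoric = list(individuals = filters$motoric, mode = "motoric")
  )

  ks_rows <- list()
  battery_rows <- list()
  profile_rows <- list()
  nulls <- list()
  for (label in names(subsets)) {
    sub <- subsets[[label]]
    r_sub <- ratios[ratios$individual_id %in% sub$individuals &
                      ratios$mode %in% sub$mode, ]
    iv_sub <- intervals[intervals$individual_id %in% sub$individuals &
                          intervals$mode %in% sub$mode, ]
    if (nrow(r_sub) == 0) {
      note(paste0("subset '", label, "': no ratios after filtering; ",
                  "not applicable"))
      next
    }
    prof <- run_stage(paste0("density_profile[", label, "]"),
                      density_profile(r_sub, scheme))
    prof$subset <- label
    profile_rows[[label]] <- prof

    null <- run_stage(paste0("null[", label, "]"), simulate_null_ratios(
      min(iv_sub$t_s), max(iv_sub$t_s), config$n_null_draws,
      seed = derive_seed(config$seed, label)
    ))
    nulls[[label]] <- null
    ks <- run_stage(paste0("ks[", label, "]"), ks_compare(r_sub$r, null))
    ks$subset <- label
    ks$interval_min_s <- null$interval_min_s
    ks$interval_max_s <- null$interval_max_s
    ks_rows[[label]] <- ks

    if (length(unique(r_sub$individual_id)) >= 2) {
      bat <- run_stage(paste0("battery[", label, "]"),
                       on_off_battery(prof, scheme,
                                      neighbours = config$neighbours))
      bat$subset <- label
      battery_rows[[label]] <- bat
    } else {
      note(paste0("subset '", label, "': fewer than 2 individuals; ",
                  "on/off battery not applicable"))
    }
  }

  # mixed models on the overall-filtered individuals
  model_results <- list()
  model_fits <- list()
  stats_inc <- stats_tbl[stats_tbl$individual_id %in% filters$overall, ]
  ratios_inc <- ratios[ratios$individual_id %in% filters$overall, ]
  usable_fixed <- function(dat) {
    fx <- c("zoo", "mode", "context")
    keep <- fx[vapply(fx, function(f) length(unique(dat[[f]])) >= 2,
                      logical(1))]
    dropped <- setdiff(fx, keep)
    if (length(dropped) > 0) {
      note(paste0("fixed effect(s) with <2 levels dropped: ",
                  paste(dropped, collapse = ", ")))
    }
    keep
  }
  fx_lmm <- usable_fixed(stats_inc[!is.na(stats_inc$cv_unbiased), ])
  if (length(fx_lmm) > 0 &&
      length(unique(stats_inc$individual_id)) >= 2) {
    lmm <- run_stage("cv_lmm",
                     suppressMessages(fit_cv_lmm(stats_inc, fixed = fx_lmm)))
    model_fits$cv_lmm <- lmm
    tr <- lmm$terms
    tr$model <- "cv_lmm"
    tr$p_adjusted <- bh_adjust(tr$p_value)
    model_results$cv_lmm <- tr
  } else {
    note("CV LMM not applicable (no usable fixed effects or <2 individuals)")
  }
  fx_glmm <- usable_fixed(ratios_inc)
  if (length(fx_glmm) > 0 && nrow(ratios_inc) > 0 &&
      length(unique(ratios_inc$individual_id)) >= 2) {
    glmm <- run_stage("isochrony_glmm",
                      fit_isochrony_glmm(ratios_inc, fixed = fx_glmm))
    model_fits$isochrony_glmm <- glmm
    tr <- glmm$terms
    tr$model <- "isochrony_glmm"
    tr$p_adjusted <- bh_adjust(tr$p_value)
    model_results$isochrony_glmm <- tr
  } else {
    note("isochrony GLMM not applicable")
  }

  tempo <- dplyr::bind_rows(
    vocal = tempo_summary(intervals[intervals$mode == "vocal", ],
                          filters$tempo_vocal),
    motoric = tempo_summary(intervals[intervals$mode == "motoric", ],
                            filters$tempo_motoric),
    .id = "view"
  )

  iso_rates <- dplyr::distinct(
    dplyr::bind_rows(profile_rows)[c("subset", "individual_id", "n_in_scheme",
                                     "n_outside", "isochrony_rate")]
  )

  report <- structure(
    list(
      config = config,
      intervals = intervals,
      ratios = ratios,
      sequence_stats = stats_tbl,
      filter_report = filters$report,
      filters = filters[c("overall", "vocal", "motoric", "tempo_vocal",
                          "tempo_motoric")],
      density_profiles = dplyr::bind_rows(profile_rows),
      ks_results = dplyr::bind_rows(ks_rows),
      battery_results = dplyr::bind_rows(battery_rows),
      model_results = dplyr::bind_rows(model_results),
      model_fits = model_fits,
      tempo_summary = tempo,
      isochrony_rates = iso_rates,
      nulls = nulls,
      notes = notes
    ),
    class = "rhythm_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.rhythm_report <- function(x, ...) {
  cat("<rhythm_report>\n")
  cat("  sequences:", nrow(x$sequence_stats), " ratios:", nrow(x$ratios), "\n")
  cat("  included individuals (overall/vocal/motoric): ",
      length(x$filters$overall), "/", length(x$filters$vocal), "/",
      length(x$filters$motoric), "\n", sep = "")
  if (nrow(x$ks_results) > 0) {
    cat("  KS vs uniform null:\n")
    for (i in seq_len(nrow(x$ks_results))) {
      cat(sprintf("    %-8s D = %.3f, p = %.3g\n", x$ks_results$subset[[i]],
                  x$ks_results$statistic[[i]], x$ks_results$p_value[[i]]))
    }
  }
  if (nrow(x$model_results) > 0) {
    cat("  mixed-model terms:\n")
    mr <- x$model_results
    for (i in seq_len(nrow(mr))) {
      cat(sprintf("    %-16s %-18s est = %7.3f, se = %.3f, %s = %6.3f, p = %.3g\n",
                  mr$model[[i]], mr$term[[i]], mr$estimate[[i]],
                  mr$std_error[[i]], mr$statistic_name[[i]],
                  mr$statistic[[i]], mr$p_value[[i]]))
    }
  }
  if (length(x$notes) > 0) {
    cat("  notes:\n")
    for (n in x$notes) cat("    -", n, "\n")
  }
  invisible(x)
}

#' Write the report bundle as tidy CSVs plus a manifest
#'
#' @param report A `rhythm_report`.
#' @param out_dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "rhythm_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(tbl, name) {
    readr::write_csv(tbl, file.path(out_dir, name), progress = FALSE, na = "")
  }
  wr(report$intervals, "intervals.csv")
  wr(report$ratios, "ratios.csv")
  wr(report$sequence_stats, "sequence_stats.csv")
  wr(report$filter_report, "filter_report.csv")
  wr(report$density_profiles, "density_profiles.csv")
  wr(report$ks_results, "ks_results.csv")
  wr(report$battery_results, "wilcoxon_results.csv")
  if (nrow(report$model_results) > 0) {
    wr(report$model_results, "model_results.csv")
  }
  wr(report$tempo_summary, "tempo_summary.csv")
  wr(report$isochrony_rates, "isochrony_rates.csv")
  if (isTRUE(report$config$write_null_draws) && length(report$nulls) > 0) {
    nd <- dplyr::bind_rows(lapply(names(report$nulls), function(label) {
      n <- report$nulls[[label]]
      tibble::tibble(subset = label, seed = n$seed,
                     draw = seq_along(n$draws), r = n$draws)
    }))
    wr(nd, "null_draws.csv")
  }
  cfg <- report$config
  manifest <- list(
    package = "ioiratio",
    version = as.character(utils::packageVersion("ioiratio")),
    seed = cfg$seed,
    config = cfg[c("min_ratios_overall", "min_ratios_mode",
                   "min_displays_tempo", "n_null_draws", "alpha",
                   "neighbours")],
    counts = list(
      events = nrow(report$intervals) + nrow(report$sequence_stats),
      sequences = nrow(report$sequence_stats),
      ratios = nrow(report$ratios),
      included_individuals = lapply(report$filters, length)
    ),
    notes = report$notes
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
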
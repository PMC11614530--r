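# Synthetic-colony generator: displaying individuals with known ground-truth
# rhythm structure, so every pipeline stage can be validated without the
# original recordings.
#
# Generative model, per interval: t_k = base_display_tempo * exp(e_k) with
# e_k ~ Normal(0, sigma(mode, context)); the display-level tempo is the
# individual's mode-specific base tempo times a log-normal display wobble.
# Directedness scales the jitter sigma (directed displays are noisier, i.e.
# less isochronous), not the tempo. Occasional small-integer-ratio insertions
# double or halve one interval so genuine 1:2 / 2:1 ratios arise from a
# realisable onset sequence. "Arrhythmic" individuals instead draw iid
# uniform intervals, reproducing the chance regime of the uniform null.

#' Configuration for the synthetic colony generator
#'
#' Defaults emulate the observed study system: two zoo colonies of two groups
#' each, about thirty displaying individuals contributing on the order of 130
#' displays; motoric sequences are slower (longer mean IOI) and tighter
#' (smaller jitter) than vocal ones; directed displays carry 1.6x the
#' log-IOI jitter of undirected ones, making them less isochronous.
#'
#' @param n_zoos,groups_per_zoo Colony structure (defaults 2 and 2).
#' @param n_individuals Number of displaying individuals (default 30).
#' @param displays_per_individual_mean Poisson mean of displays per
#'   individual, minimum 1 (default 5).
#' @param elements_per_sequence_mean Poisson mean of events per sequence,
#'   minimum 3 (default 8).
#' @param p_directed Probability a display is directed (default 0.4).
#' @param mode_mix Probabilities that a display is vocal-only, motoric-only,
#'   or bimodal; default `c(22, 59, 51)/132`, the observed composition.
#' @param mean_vocal_s,mean_motoric_s Population median IOI per mode in
#'   seconds (defaults 0.45 and 0.9).
#' @param sd_log_tempo_individual Between-individual SD of log base tempo
#'   (default 0.25); `sd_log_tempo_display` is the display-level wobble
#'   (default 0.1).
#' @param sigma_vocal,sigma_motoric Log-IOI jitter SD of undirected
#'   sequences per mode (defaults 0.15 and 0.08).
#' @param directed_multiplier Multiplier on jitter for directed displays
#'   (default 1.6).
#' @param p_sir_insertion Per-interval probability of doubling or halving the
#'   local IOI, seeding genuine 1:2/2:1 ratios (default 0.05).
#' @param arrhythmic_fraction Fraction of individuals whose intervals are iid
#'   uniform on `arrhythmic_range_s` (default 0; used for type-I studies).
#' @param arrhythmic_range_s Interval range of arrhythmic individuals in
#'   seconds (default `c(0.3, 1.5)`, spanning the vocal-to-motoric tempo
#'   range).
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_zoos = 2L,
                              groups_per_zoo = 2L,
                              n_individuals = 30L,
                              displays_per_individual_mean = 5,
                              elements_per_sequence_mean = 8,
                              p_directed = 0.4,
                              mode_mix = c(vocal_only = 22, motoric_only = 59,
                                           bimodal = 51) / 132,
                              mean_vocal_s = 0.45,
                              mean_motoric_s = 0.9,
                              sd_log_tempo_individual = 0.25,
                              sd_log_tempo_display = 0.1,
                              sigma_vocal = 0.15,
                              sigma_motoric = 0.08,
                              directed_multiplier = 1.6,
                              p_sir_insertion = 0.05,
                              arrhythmic_fraction = 0,
                              arrhythmic_range_s = c(0.3, 1.5)) {
  cfg <- as.list(environment())
  bad <- character()
  if (!(cfg$n_zoos >= 1)) bad <- c(bad, "n_zoos")
  if (!(cfg$groups_per_zoo >= 1)) bad <- c(bad, "groups_per_zoo")
  if (!(cfg$n_individuals >= 1)) bad <- c(bad, "n_individuals")
  if (!(cfg$displays_per_individual_mean > 0)) {
    bad <- c(bad, "displays_per_individual_mean")
  }
  if (!(cfg$elements_per_sequence_mean > 0)) {
    bad <- c(bad, "elements_per_sequence_mean")
  }
  for (p in c("p_directed", "p_sir_insertion", "arrhythmic_fraction")) {
    if (!(cfg[[p]] >= 0 && cfg[[p]] <= 1)) bad <- c(bad, p)
  }
  if (abs(sum(cfg$mode_mix) - 1) > 1e-8 || any(cfg$mode_mix < 0)) {
    bad <- c(bad, "mode_mix")
  }
  for (s in c("sigma_vocal", "sigma_motoric", "sd_log_tempo_individual",
              "sd_log_tempo_display")) {
    if (!(cfg[[s]] > 0)) bad <- c(bad, s)
  }
  if (!(cfg$mean_vocal_s > 0 && cfg$mean_motoric_s > 0)) {
    bad <- c(bad, "mean_vocal_s/mean_motoric_s")
  }
  if (!(cfg$directed_multiplier > 0)) bad <- c(bad, "directed_multiplier")
  if (length(cfg$arrhythmic_range_s) != 2 ||
      !(cfg$arrhythmic_range_s[[1]] > 0) ||
      !(cfg$arrhythmic_range_s[[1]] < cfg$arrhythmic_range_s[[2]])) {
    bad <- c(bad, "arrhythmic_range_s")
  }
  if (length(bad) > 0) {
    stop("invalid simulation config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(cfg, class = "simulation_config")
}

VOCAL_LABELS <- c("pant", "hoot", "grunt", "scream", "bark")
MOTORIC_LABELS <- c("sway", "stomp", "drum", "run", "slap")

#' Simulate a colony of displaying individuals
#'
#' Draws individuals (with zoo, group, sex and age), their displays (context
#' and mode composition) and event streams under the generative model in
#' [simulation_config()], returning both the assembled observations and the
#' generative ground truth. Deterministic given `(config, seed)`.
#'
#' @param config A [simulation_config()].
#' @param seed Integer master seed.
#' @return A list of class `colony_simulation` with elements `observations`
#'   (an `observation_set`), `individuals`, `displays` and `intervals`
#'   (ground-truth tibbles: true base tempi, true jitter per sequence, and
#'   the generative class of every interval).
#' @export
simulate_colony <- function(config = simulation_config(), seed = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(as.integer(seed), simulate_colony_impl(config))
}

simulate_colony_impl <- function(config) {
  zoos <- LETTERS[seq_len(config$n_zoos)]
  ind <- tibble::tibble(
    individual_id = sprintf("I%02d", seq_len(config$n_individuals)),
    zoo = sample(zoos, config$n_individuals, replace = TRUE),
    sex = sample(c("male", "female"), config$n_individuals, replace = TRUE,
                 prob = c(0.6, 0.4)),
    age_years = round(stats::runif(config$n_individuals, 3, 45)),
    arrhythmic = stats::runif(config$n_individuals) <
      config$arrhythmic_fraction,
    base_vocal_s = config$mean_vocal_s *
      exp(stats::rnorm(config$n_individuals, 0,
                       config$sd_log_tempo_individual)),
    base_motoric_s = config$mean_motoric_s *
      exp(stats::rnorm(config$n_individuals, 0,
                       config$sd_log_tempo_individual))
  )
  ind$group <- paste0(ind$zoo,
                      sample(seq_len(config$groups_per_zoo),
                             config$n_individuals, replace = TRUE))
  n_disp <- pmax(1L, stats::rpois(config$n_individuals,
                                  config$displays_per_individual_mean))
  displays <- tibble::tibble(
    individual_id = rep(ind$individual_id, n_disp),
    display_index = unlist(lapply(n_disp, seq_len))
  )
  displays$display_id <- sprintf("%s_D%02d", displays$individual_id,
                                 displays$display_index)
  displays$context <- ifelse(stats::runif(nrow(displays)) < config$p_directed,
                             "directed", "undirected")
  comp <- sample(c("vocal_only", "motoric_only", "bimodal"), nrow(displays),
                 replace = TRUE, prob = config$mode_mix)
  displays$has_vocal <- comp != "motoric_only"
  displays$has_motoric <- comp != "vocal_only"
  displays <- dplyr::left_join(
    displays, ind[c("individual_id", "zoo", "group", "sex", "age_years",
                    "arrhythmic", "base_vocal_s", "base_motoric_s")],
    by = "individual_id"
  )

  # one row per (display, mode) sequence, then all interval draws vectorised
  seqs <- dplyr::bind_rows(
    dplyr::mutate(displays[displays$has_vocal, ], mode = "vocal"),
    dplyr::mutate(displays[displays$has_motoric, ], mode = "motoric")
  )
  n_seq <- nrow(seqs)
  seqs$n_ev <- pmax(3L, stats::rpois(n_seq, config$elements_per_sequence_mean))
  seqs$n_iv <- seqs$n_ev - 1L
  seqs$base <- ifelse(seqs$mode == "vocal", seqs$base_vocal_s,
                      seqs$base_motoric_s)
  seqs$sigma <- ifelse(seqs$mode == "vocal", config$sigma_vocal,
                       config$sigma_motoric) *
    ifelse(seqs$context == "directed", config$directed_multiplier, 1)
  seqs$tempo <- ifelse(seqs$arrhythmic, NA_real_,
                       seqs$base * exp(stats::rnorm(n_seq, 0,
                                                    config$sd_log_tempo_display)))
  total_iv <- sum(seqs$n_iv)
  seq_of_iv <- rep.int(seq_len(n_seq), seqs$n_iv)
  arr <- seqs$arrhythmic[seq_of_iv]
  t <- numeric(total_iv)
  t[!arr] <- seqs$tempo[seq_of_iv][!arr] *
    exp(stats::rnorm(sum(!arr), 0, seqs$sigma[seq_of_iv][!arr]))
  t[arr] <- stats::runif(sum(arr), config$arrhythmic_range_s[[1]],
                         config$arrhythmic_range_s[[2]])
  cls <- ifelse(arr, "arrhythmic", "isochronous_jittered")
  sir <- !arr & stats::runif(total_iv) < config$p_sir_insertion
  if (any(sir)) {
    t[sir] <- t[sir] * sample(c(0.5, 2), sum(sir), replace = TRUE)
    cls[sir] <- "sir_inserted"
  }
  k_of_iv <- sequence(seqs$n_iv)
  truth <- tibble::tibble(
    individual_id = seqs$individual_id[seq_of_iv],
    display_id = seqs$display_id[seq_of_iv],
    mode = seqs$mode[seq_of_iv], context = seqs$context[seq_of_iv],
    k = k_of_iv, t_s = t, generative_class = cls,
    display_tempo_s = seqs$tempo[seq_of_iv],
    sigma_log_ioi = ifelse(arr, NA_real_, seqs$sigma[seq_of_iv])
  )
  # onsets: per-sequence cumulative sums of (0, t_1, ..., t_{n-1})
  seq_of_ev <- rep.int(seq_len(n_seq), seqs$n_ev)
  k_of_ev <- sequence(seqs$n_ev)
  t_step <- numeric(length(seq_of_ev))
  t_step[k_of_ev > 1L] <- t
  onset <- stats::ave(t_step, seq_of_ev, FUN = cumsum)
  # duration of the event: 0.6 x the following interval (last event reuses
  # the final interval)
  nxt <- numeric(length(seq_of_ev))
  nxt[k_of_ev < seqs$n_ev[seq_of_ev]] <- t
  last <- k_of_ev == seqs$n_ev[seq_of_ev]
  nxt[last] <- t[cumsum(seqs$n_iv)]
  n_ev_total <- length(seq_of_ev)
  labels <- character(n_ev_total)
  voc_ev <- seqs$mode[seq_of_ev] == "vocal"
  labels[voc_ev] <- sample(VOCAL_LABELS, sum(voc_ev), replace = TRUE)
  labels[!voc_ev] <- sample(MOTORIC_LABELS, sum(!voc_ev), replace = TRUE)
  ev <- tibble::tibble(
    individual_id = seqs$individual_id[seq_of_ev],
    display_id = seqs$display_id[seq_of_ev],
    zoo = seqs$zoo[seq_of_ev], group = seqs$group[seq_of_ev],
    mode = seqs$mode[seq_of_ev], context = seqs$context[seq_of_ev],
    behaviour = labels, onset_s = onset, offset_s = onset + 0.6 * nxt,
    sex = seqs$sex[seq_of_ev], age_years = seqs$age_years[seq_of_ev]
  )
  truth_iv <- list(truth)
  obs <- assemble_observation_set(ev)
  structure(
    list(
      observations = obs,
      individuals = ind,
      displays = displays[c("display_id", "individual_id", "zoo", "group",
                            "context", "has_vocal", "has_motoric",
                            "arrhythmic")],
      intervals = dplyr::bind_rows(truth_iv)
    ),
    class = "colony_simulation"
  )
}

#' @export
print.colony_simulation <- function(x, ...) {
  cat("<colony_simulation>\n")
  cat("  individuals:", nrow(x$individuals),
      sprintf("(%d arrhythmic)\n", sum(x$individuals$arrhythmic)))
  cat("  displays:   ", nrow(x$displays), "\n")
  print(x$observations)
  invisible(x)
}

#' Write a synthetic observation set in the supported input formats
#'
#' Emits, per requested format: one TextGrid per display with vocal events,
#' one BORIS-style CSV per display with motoric events, and/or the unified
#' event CSV; always accompanied by the display metadata CSV and, when the
#' simulation object is given, the ground-truth CSV.
#'
#' @param sim A `colony_simulation` (or an `observation_set`, in which case
#'   no ground truth is written).
#' @param out_dir Output directory (created if needed).
#' @param formats Subset of `c("unified", "textgrid", "boris")`.
#' @return Character vector of the files written, invisibly.
#' @export
write_fixture_bundle <- function(sim, out_dir,
                                 formats = c("unified", "textgrid", "boris")) {
  formats <- match.arg(formats, several.ok = TRUE)
  obs <- if (inherits(sim, "colony_simulation")) sim$observations else sim
  stopifnot(inherits(obs, "observation_set"))
  if (nrow(obs$events) == 0L) {
    stop("observation set is empty; nothing to write", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  ev <- obs$events
  if ("unified" %in% formats) {
    p <- file.path(out_dir, "events.csv")
    write_events_csv(ev[setdiff(names(ev), "sequence_id")], p)
    written <- c(written, p)
  }
  if ("textgrid" %in% formats) {
    voc <- ev[ev$mode == "vocal", ]
    for (d in unique(voc$display_id)) {
      p <- file.path(out_dir, paste0(d, ".TextGrid"))
      write_textgrid(voc[voc$display_id == d, ], p)
      written <- c(written, p)
    }
  }
  if ("boris" %in% formats) {
    mot <- ev[ev$mode == "motoric", ]
    for (d in unique(mot$display_id)) {
      p <- file.path(out_dir, paste0(d, "_boris.csv"))
      write_boris_csv(mot[mot$display_id == d, ], p)
      written <- c(written, p)
    }
  }
  md <- dplyr::distinct(ev[c("display_id", "individual_id", "zoo", "group",
                             "context")])
  p <- file.path(out_dir, "metadata.csv")
  readr::write_csv(md, p, progress = FALSE)
  written <- c(written, p)
  if (inherits(sim, "colony_simulation")) {
    p <- file.path(out_dir, "ground_truth.csv")
    readr::write_csv(sim$intervals, p, progress = FALSE, na = "")
    written <- c(written, p)
  }
  invisible(written)
}
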
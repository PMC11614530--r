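# Interval extraction, ratio computation, rhythm-category classification and
# regularity statistics.
#
# The central quantities: for a display sequence with onsets o_1 < ... < o_n,
# the inter-onset intervals are t_k = o_{k+1} - o_k, and the interval ratio of
# two consecutive intervals is r_k = t_k / (t_k + t_{k+1}) in (0, 1).
# r = 0.5 marks isochrony (1:1); 0.25, 1/3, 2/3 and 0.75 mark the small-integer
# rhythm ratios 1:3, 1:2, 2:1 and 3:1.

SEQUENCE_KEY <- c("sequence_id", "display_id", "individual_id", "mode",
                  "context", "zoo", "group")

#' Interval ratio of consecutive inter-onset intervals
#'
#' `interval_ratio(t, t_next)` computes `t / (t + t_next)`, the ratio that maps
#' each adjacent interval pair into (0, 1). Equal intervals give 0.5
#' (isochrony); a 1:3 pair gives 0.25, 1:2 gives 1/3, 2:1 gives 2/3, 3:1 gives
#' 0.75.
#'
#' @param t,t_next Positive interval durations (vectorised).
#' @return Numeric vector of ratios in (0, 1).
#' @examples
#' interval_ratio(1, 1)  # 0.5, isochrony
#' interval_ratio(1, 3)  # 0.25, the 1:3 rhythm
#' @export
interval_ratio <- function(t, t_next) {
  if (any(t <= 0) || any(t_next <= 0)) {
    stop("intervals must be strictly positive", call. = FALSE)
  }
  t / (t + t_next)
}

#' Inter-onset intervals of every display sequence
#'
#' Computes t_k = onset_{k+1} - onset_k within each display sequence (never
#' across displays or modes). Sequences with fewer than two events contribute
#' no rows. Duplicate onsets within a sequence are merged to a single event
#' (first label kept) with a warning, since zero-length intervals are not
#' interpretable as rhythm.
#'
#' @param obs An `observation_set` from [assemble_observation_set()].
#' @return A tibble with the sequence key columns, the interval index `k`
#'   (1-based), and the interval `t_s` in seconds.
#' @export
sequence_intervals <- function(obs) {
  stopifnot(inherits(obs, "observation_set"))
  ev <- obs$events
  if (nrow(ev) == 0L) {
    return(tibble::tibble(sequence_id = character(), display_id = character(),
                          individual_id = character(), mode = character(),
                          context = character(), zoo = character(),
                          group = character(), k = integer(), t_s = double()))
  }
  dup <- duplicated(ev[c("sequence_id", "onset_s")])
  if (any(dup)) {
    warning(sum(dup), " event(s) with duplicate onsets merged within their ",
            "sequence", call. = FALSE)
    ev <- ev[!dup, ]
  }
  ev <- dplyr::arrange(ev, .data$sequence_id, .data$onset_s)
  grouped <- dplyr::group_by(ev, dplyr::across(dplyr::all_of(SEQUENCE_KEY)))
  iv <- dplyr::reframe(grouped, k = seq_len(max(dplyr::n() - 1L, 0L)),
                       t_s = diff(.data$onset_s))
  iv
}

#' Interval ratios of every display sequence
#'
#' Computes r_k = t_k / (t_k + t_{k+1}) for consecutive interval pairs within
#' each sequence. A sequence with fewer than two intervals contributes no
#' ratios. When a `scheme` is supplied each ratio is classified into its
#' rhythm-category bin ([classify_ratios()]).
#'
#' @param intervals Output of [sequence_intervals()].
#' @param scheme Optional [rhythm_scheme()]; adds a `bin` column.
#' @return A tibble with the sequence key, ratio index `k`, ratio `r`, and
#'   (with a scheme) the bin label.
#' @export
interval_ratios_table <- function(intervals, scheme = NULL) {
  grouped <- dplyr::group_by(intervals,
                             dplyr::across(dplyr::all_of(SEQUENCE_KEY)))
  ratios <- dplyr::reframe(
    grouped,
    k = seq_len(max(dplyr::n() - 1L, 0L)),
    r = if (dplyr::n() >= 2L) {
      interval_ratio(.data$t_s[-dplyr::n()], .data$t_s[-1L])
    } else {
      double()
    }
  )
  if (!is.null(scheme)) {
    ratios$bin <- classify_ratios(ratios$r, scheme)
    iso <- scheme$name[scheme$kind == "on_integer" & scheme$center == 0.5]
    ratios$isochronous <- ratios$bin == iso
  }
  ratios
}

#' Unbiased coefficient of variation of a vector of intervals
#'
#' The sample coefficient of variation s/m (standard deviation with divisor
#' n - 1 over the mean) multiplied by the small-sample correction factor
#' (1 + 1/(4n)). Lower values mean more regular (more isochronous) sequences;
#' a perfectly regular sequence has CV 0. Undefined for fewer than two
#' intervals.
#'
#' @param t Numeric vector of positive intervals, length >= 2.
#' @return The corrected coefficient of variation (dimensionless).
#' @examples
#' unbiased_cv(c(1, 2, 1, 2))  # 0.40896
#' @export
unbiased_cv <- function(t) {
  n <- length(t)
  if (n < 2L) return(NA_real_)
  (1 + 1 / (4 * n)) * stats::sd(t) / mean(t)
}

#' Per-sequence regularity statistics
#'
#' @param intervals Output of [sequence_intervals()].
#' @return A tibble with one row per sequence: `n_intervals`, `mean_ioi_s`,
#'   and `cv_unbiased` (NA for sequences with a single interval, which are
#'   excluded from CV analyses).
#' @export
sequence_stats <- function(intervals) {
  grouped <- dplyr::group_by(intervals,
                             dplyr::across(dplyr::all_of(SEQUENCE_KEY)))
  dplyr::summarise(
    grouped,
    n_intervals = dplyr::n(),
    mean_ioi_s = mean(.data$t_s),
    cv_unbiased = unbiased_cv(.data$t_s),
    .groups = "drop"
  )
}

# --- Rhythm category scheme -------------------------------------------------

#' Build a rhythm-category bin scheme
#'
#' Constructs the ordered on-/off-integer bins over which interval ratios are
#' classified. On-integer (rhythmic) bins are centred on the small-integer
#' ratios 1:3, 1:2, 1:1, 2:1, 3:1, i.e. r = 1/4, 1/3, 1/2, 2/3, 3/4; an
#' off-integer (arrhythmic) bin sits between each adjacent pair of on-bins,
#' centred at their midpoint. Bin edges are placed midway between adjacent
#' centres of the merged centre list, and the outermost on-bins are made
#' symmetric about their centres, so the default scheme covers
#' [0.22917, 0.77083]. Ratios outside that range are labelled `"outside"`.
#' Bins are half-open `[lower, upper)`, with the final bin closed, so every
#' in-range ratio belongs to exactly one bin.
#'
#' @param on_centers Increasing vector of on-integer centres in (0, 1).
#' @param on_names Labels for the on-bins, parallel to `on_centers`.
#' @return A tibble of class `rhythm_scheme` with columns `name`, `kind`
#'   (`on_integer`/`off_integer`), `center`, `lower`, `upper`, `width`.
#' @export
rhythm_scheme <- function(on_centers = c(1/4, 1/3, 1/2, 2/3, 3/4),
                          on_names = c("1:3", "1:2", "1:1", "2:1", "3:1")) {
  stopifnot(length(on_centers) >= 2, !is.unsorted(on_centers, strictly = TRUE),
            all(on_centers > 0 & on_centers < 1),
            length(on_names) == length(on_centers))
  off_centers <- (on_centers[-1] + on_centers[-length(on_centers)]) / 2
  off_names <- paste0("off(", on_names[-length(on_names)], "-",
                      on_names[-1], ")")
  centers <- c(rbind(on_centers,
                     c(off_centers, NA)))[seq_len(2 * length(on_centers) - 1)]
  names_all <- c(rbind(on_names,
                       c(off_names, NA)))[seq_len(2 * length(on_names) - 1)]
  kind <- rep(c("on_integer", "off_integer"),
              length.out = length(centers))
  inner_edges <- (centers[-1] + centers[-length(centers)]) / 2
  lower <- c(2 * centers[[1]] - inner_edges[[1]], inner_edges)
  upper <- c(inner_edges, 2 * centers[[length(centers)]] -
               inner_edges[[length(inner_edges)]])
  scheme <- tibble::tibble(
    name = names_all, kind = kind, center = centers,
    lower = lower, upper = upper, width = upper - lower
  )
  stopifnot(all(scheme$width > 0))
  class(scheme) <- c("rhythm_scheme", class(scheme))
  scheme
}

#' Classify ratios into rhythm-category bins
#'
#' Each ratio in (0, 1) is assigned the unique bin whose half-open interval
#' `[lower, upper)` contains it (the final bin is closed above); ratios below
#' the first or above the last bin are labelled `"outside"`.
#'
#' @param r Numeric vector of ratios in (0, 1).
#' @param scheme A [rhythm_scheme()].
#' @return Character vector of bin names (or `"outside"`).
#' @export
classify_ratios <- function(r, scheme = rhythm_scheme()) {
  if (any(!is.na(r) & (r <= 0 | r >= 1))) {
    stop("ratios must lie strictly inside (0, 1)", call. = FALSE)
  }
  edges <- c(scheme$lower, scheme$upper[[nrow(scheme)]])
  idx <- findInterval(r, edges, rightmost.closed = TRUE)
  out <- rep("outside", length(r))
  inside <- !is.na(idx) & idx >= 1 & idx <= nrow(scheme)
  out[inside] <- scheme$name[idx[inside]]
  out[is.na(r)] <- NA_character_
  out
}

#' Bin-width-normalised density profile of classified ratios
#'
#' For each group (by default each individual) counts the ratios in every bin
#' of the scheme and divides by the bin width, normalising the unequal bin
#' sizes so densities are comparable across categories. Reports per group the
#' in-scheme and outside counts and the isochrony rate (ratios in the 1:1 bin
#' over all in-scheme ratios; `NA` and flagged when the group has no in-scheme
#' ratios).
#'
#' @param ratios Output of [interval_ratios_table()] with a `bin` column.
#' @param scheme The [rhythm_scheme()] used for classification.
#' @param by Grouping columns (default `"individual_id"`).
#' @return A tibble with one row per group x bin: `count`, `width`, `density`,
#'   plus per-group `n_in_scheme`, `n_outside`, `isochrony_rate` and `empty`.
#' @export
density_profile <- function(ratios, scheme = rhythm_scheme(),
                            by = "individual_id") {
  stopifnot("bin" %in% names(ratios))
  groups <- dplyr::distinct(ratios[, by, drop = FALSE])
  grid <- tidyr::crossing(groups, scheme[c("name", "kind", "center", "width")])
  counts <- dplyr::count(ratios[ratios$bin != "outside", ],
                         dplyr::across(dplyr::all_of(c(by, "bin"))),
                         name = "count")
  outside <- dplyr::count(ratios[ratios$bin == "outside", ],
                          dplyr::across(dplyr::all_of(by)),
                          name = "n_outside")
  prof <- dplyr::left_join(grid, counts,
                           by = stats::setNames(c(by, "bin"), c(by, "name")))
  prof$count[is.na(prof$count)] <- 0L
  prof$density <- prof$count / prof$width
  prof <- dplyr::left_join(prof, outside, by = by)
  prof$n_outside[is.na(prof$n_outside)] <- 0L
  iso_name <- scheme$name[scheme$kind == "on_integer" & scheme$center == 0.5]
  per_group <- dplyr::summarise(
    dplyr::group_by(prof, dplyr::across(dplyr::all_of(by))),
    n_in_scheme = sum(.data$count),
    iso_count = sum(.data$count[.data$name == iso_name]),
    .groups = "drop"
  )
  per_group$isochrony_rate <- ifelse(per_group$n_in_scheme > 0,
                                     per_group$iso_count / per_group$n_in_scheme,
                                     NA_real_)
  per_group$empty <- per_group$n_in_scheme == 0
  prof <- dplyr::left_join(prof, per_group, by = by)
  prof$iso_count <- NULL
  dplyr::arrange(prof, dplyr::across(dplyr::all_of(by)), .data$center)
}

# --- Inclusion filters ------------------------------------------------------

#' Apply the analysis inclusion filters
#'
#' Three nested views of the data, mirroring how the ratio analyses are
#' restricted: the overall view keeps individuals with at least
#' `min_ratios_overall` interval ratios across the whole dataset; the per-mode
#' views keep individuals with at least `min_ratios_mode` ratios in that mode;
#' the tempo views additionally require, of the individuals already selected
#' for a mode, at least `min_displays_tempo` displays in that mode (guarding
#' the between-individual tempo comparison against individuals whose apparent
#' consistency just reflects having few displays).
#'
#' @param ratios Output of [interval_ratios_table()].
#' @param min_ratios_overall,min_ratios_mode,min_displays_tempo Integer
#'   thresholds (defaults 50, 25, 4).
#' @return A list with character vectors `overall`, `vocal`, `motoric`,
#'   `tempo_vocal`, `tempo_motoric` of included individual ids, and a tibble
#'   `report` listing every individual's counts and inclusion flags.
#' @export
apply_inclusion_filters <- function(ratios, min_ratios_overall = 50,
                                    min_ratios_mode = 25,
                                    min_displays_tempo = 4) {
  per_ind <- dplyr::summarise(
    dplyr::group_by(ratios, .data$individual_id),
    n_ratios_total = dplyr::n(),
    n_ratios_vocal = sum(.data$mode == "vocal"),
    n_ratios_motoric = sum(.data$mode == "motoric"),
    n_displays_vocal = dplyr::n_distinct(.data$display_id[.data$mode == "vocal"]),
    n_displays_motoric = dplyr::n_distinct(.data$display_id[.data$mode == "motoric"]),
    .groups = "drop"
  )
  per_ind$in_overall <- per_ind$n_ratios_total >= min_ratios_overall
  per_ind$in_vocal <- per_ind$n_ratios_vocal >= min_ratios_mode
  per_ind$in_motoric <- per_ind$n_ratios_motoric >= min_ratios_mode
  per_ind$in_tempo_vocal <- per_ind$in_vocal &
    per_ind$n_displays_vocal >= min_displays_tempo
  per_ind$in_tempo_motoric <- per_ind$in_motoric &
    per_ind$n_displays_motoric >= min_displays_tempo
  list(
    overall = per_ind$individual_id[per_ind$in_overall],
    vocal = per_ind$individual_id[per_ind$in_vocal],
    motoric = per_ind$individual_id[per_ind$in_motoric],
    tempo_vocal = per_ind$individual_id[per_ind$in_tempo_vocal],
    tempo_motoric = per_ind$individual_id[per_ind$in_tempo_motoric],
    report = per_ind
  )
}

#' Per-display mean interval (tempo) summary
#'
#' Average interval duration per display per individual, reported separately
#' by mode — the quantity used to visualise individual-specific tempi.
#'
#' @param intervals Output of [sequence_intervals()].
#' @param individuals Optional character vector restricting to the tempo-view
#'   individuals of [apply_inclusion_filters()].
#' @return A tibble: individual, display, mode, `n_intervals`, `mean_ioi_s`.
#' @export
tempo_summary <- function(intervals, individuals = NULL) {
  if (!is.null(individuals)) {
    intervals <- intervals[intervals$individual_id %in% individuals, ]
  }
  dplyr::summarise(
    dplyr::group_by(intervals, .data$individual_id, .data$display_id,
                    .data$mode),
    n_intervals = dplyr::n(),
    mean_ioi_s = mean(.data$t_s),
    .groups = "drop"
  )
}
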
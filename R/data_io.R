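# Readers/writers for behavioural annotation formats and assembly of the
# hierarchical observation set (colony -> group -> individual -> display ->
# sequence -> event).

EVENT_COLUMNS <- c(
  "individual_id", "display_id", "zoo", "group", "mode", "context",
  "behaviour", "onset_s", "offset_s", "sex", "age_years"
)

MODES <- c("vocal", "motoric")
CONTEXTS <- c("directed", "undirected")

empty_events <- function() {
  tibble::tibble(
    individual_id = character(), display_id = character(),
    zoo = character(), group = character(),
    mode = character(), context = character(),
    behaviour = character(),
    onset_s = double(), offset_s = double(),
    sex = character(), age_years = double()
  )
}

#' Validate a behavioural event table
#'
#' Checks the invariants of the unified event table: required columns present,
#' non-empty ids, non-negative onsets, offsets (when present) at or after
#' onsets, and recognised `mode`/`context` levels where they are filled in.
#'
#' @param events A data frame of behavioural events.
#' @param require_metadata If `TRUE`, `zoo`, `group`, `mode` and `context`
#'   must be non-missing for every event.
#' @param allow_missing_ids If `TRUE`, `individual_id`/`display_id` may be
#'   `NA` (readers produce such partial events; assembly fills the ids from
#'   metadata).
#' @return The events as a tibble, invisibly unchanged apart from column
#'   ordering. Errors describe the first violated invariant.
#' @export
validate_events <- function(events, require_metadata = FALSE,
                            allow_missing_ids = FALSE) {
  events <- tibble::as_tibble(events)
  missing_cols <- setdiff(EVENT_COLUMNS, names(events))
  for (col in missing_cols) events[[col]] <- NA
  events <- events[EVENT_COLUMNS]
  events$onset_s <- as.numeric(events$onset_s)
  events$offset_s <- as.numeric(events$offset_s)
  events$age_years <- as.numeric(events$age_years)
  if (nrow(events) == 0L) return(events)

  for (idcol in c("individual_id", "display_id")) {
    empty <- events[[idcol]] == ""
    if (!allow_missing_ids) empty <- empty | is.na(events[[idcol]])
    if (any(empty, na.rm = TRUE)) {
      stop("events have empty ", idcol, call. = FALSE)
    }
  }
  if (any(is.na(events$onset_s)) || any(events$onset_s < 0)) {
    stop("onset_s must be present and >= 0 for every event", call. = FALSE)
  }
  bad_off <- !is.na(events$offset_s) & events$offset_s < events$onset_s
  if (any(bad_off)) {
    stop(sum(bad_off), " event(s) have offset_s < onset_s", call. = FALSE)
  }
  known_mode <- is.na(events$mode) | events$mode %in% MODES
  if (!all(known_mode)) {
    stop("unknown mode value(s): ",
         paste(unique(events$mode[!known_mode]), collapse = ", "),
         call. = FALSE)
  }
  known_ctx <- is.na(events$context) | events$context %in% CONTEXTS
  if (!all(known_ctx)) {
    stop("unknown context value(s): ",
         paste(unique(events$context[!known_ctx]), collapse = ", "),
         call. = FALSE)
  }
  if (require_metadata) {
    for (col in c("zoo", "group", "mode", "context")) {
      if (any(is.na(events[[col]]))) {
        stop("column '", col, "' has missing values but metadata is required",
             call. = FALSE)
      }
    }
  }
  events
}

# --- Praat TextGrid ---------------------------------------------------------

# Tokenises a TextGrid body so that the long ("xmin = 0") and short (bare
# values) dialects parse through the same path: keep quoted strings and bare
# numeric/flag tokens, in file order.
textgrid_tokens <- function(lines) {
  tokens <- character()
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    # strip long-format "key =" prefixes (incl. "intervals: size =") and the
    # "tiers?" keyword, keeping only values
    line <- sub("^\\s*tiers\\?\\s*", "", line)
    line <- sub("^\\s*[A-Za-z_][][A-Za-z0-9_ :]*=", "", line)
    line <- trimws(line)
    if (line == "" || grepl("^(item|intervals|points)\\s*\\[", line)) next
    if (grepl("^\"", line)) {
      if (!grepl("\"\\s*$", line)) {
        stop("malformed TextGrid: unterminated string at line ", i,
             call. = FALSE)
      }
      tokens <- c(tokens, gsub("^\"|\"$", "", line))
    } else {
      tokens <- c(tokens, strsplit(line, "\\s+")[[1]])
    }
  }
  tokens
}

#' Read behavioural events from a Praat TextGrid
#'
#' Parses interval and point tiers from a TextGrid file (long or short text
#' dialect, UTF-8). Each non-empty labelled interval becomes one event with
#' onset and offset; each labelled point becomes one event with the offset
#' absent. Empty labels are Praat's convention for silence and are skipped.
#'
#' @param path Path to a `.TextGrid` file.
#' @param tier_map Named character vector mapping tier names to production
#'   modes, e.g. `c(calls = "vocal")`. Tiers absent from the map raise a
#'   configuration error; pass `NULL` to accept all tiers with mode `NA`.
#' @param individual_id,display_id Optional ids attached to every event
#'   (TextGrids carry no subject metadata of their own).
#' @return A tibble of behavioural events (one row per annotation).
#' @examples
#' tg <- tempfile(fileext = ".TextGrid")
#' writeLines(c(
#'   "File type = \"ooTextFile\"", "Object class = \"TextGrid\"", "",
#'   "0", "1", "<exists>", "1", "\"IntervalTier\"", "\"calls\"",
#'   "0", "1", "2", "0", "0.4", "\"pant\"", "0.5", "1", "\"pant\""
#' ), tg)
#' read_textgrid(tg, tier_map = c(calls = "vocal"))
#' @export
read_textgrid <- function(path, tier_map = NULL, individual_id = NA_character_,
                          display_id = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) < 3 || !grepl("ooTextFile", lines[[1]]) ||
      !grepl("TextGrid", lines[[2]])) {
    stop("malformed TextGrid (missing header) at line 1: ", path,
         call. = FALSE)
  }
  tok <- textgrid_tokens(lines[-(1:2)])
  # layout: xmin xmax <exists> n_tiers, then per tier:
  #   class name xmin xmax n_items, then items
  pos <- 1L
  take <- function() {
    if (pos > length(tok)) stop("malformed TextGrid: truncated file ", path,
                                call. = FALSE)
    val <- tok[[pos]]
    pos <<- pos + 1L
    val
  }
  take()  # file xmin
  take()  # file xmax
  flag <- take()
  if (!flag %in% c("<exists>", "1")) {
    stop("malformed TextGrid: tiers flag '", flag, "' in ", path,
         call. = FALSE)
  }
  n_tiers <- as.integer(take())
  out <- list()
  for (ti in seq_len(n_tiers)) {
    tier_class <- take()
    tier_name <- take()
    take()  # tier xmin
    take()  # tier xmax
    n_items <- as.integer(take())
    if (is.na(n_items)) {
      stop("malformed TextGrid: non-numeric item count in tier '",
           tier_name, "'", call. = FALSE)
    }
    if (tier_class == "IntervalTier") {
      xmin <- xmax <- numeric(n_items)
      lab <- character(n_items)
      for (k in seq_len(n_items)) {
        xmin[[k]] <- as.numeric(take())
        xmax[[k]] <- as.numeric(take())
        lab[[k]] <- take()
      }
      keep <- !is.na(lab) & trimws(lab) != ""
      tier_events <- tibble::tibble(
        tier = tier_name, behaviour = lab[keep],
        onset_s = xmin[keep], offset_s = xmax[keep]
      )
    } else if (tier_class == "TextTier") {
      tpos <- numeric(n_items)
      lab <- character(n_items)
      for (k in seq_len(n_items)) {
        tpos[[k]] <- as.numeric(take())
        lab[[k]] <- take()
      }
      keep <- !is.na(lab) & trimws(lab) != ""
      tier_events <- tibble::tibble(
        tier = tier_name, behaviour = lab[keep],
        onset_s = tpos[keep], offset_s = NA_real_
      )
    } else {
      stop("malformed TextGrid: unknown tier class '", tier_class, "'",
           call. = FALSE)
    }
    out[[ti]] <- tier_events
  }
  ev <- dplyr::bind_rows(out)
  if (nrow(ev) > 0 && anyNA(ev$onset_s)) {
    stop("malformed TextGrid: non-numeric time value in ", path,
         call. = FALSE)
  }
  if (!is.null(tier_map)) {
    unknown <- setdiff(unique(ev$tier), names(tier_map))
    if (length(unknown) > 0) {
      stop("tier(s) not in tier_map: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    ev$mode <- unname(tier_map[ev$tier])
  } else {
    ev$mode <- NA_character_
  }
  ev <- ev[order(ev$onset_s), ]
  res <- empty_events()
  res <- tibble::add_row(
    res,
    individual_id = rep(individual_id, nrow(ev)),
    display_id = rep(display_id, nrow(ev)),
    mode = ev$mode, behaviour = ev$behaviour,
    onset_s = ev$onset_s, offset_s = ev$offset_s
  )
  res
}

#' Write events to a Praat TextGrid (long dialect)
#'
#' Inverse of [read_textgrid()]: writes one interval tier per distinct mode.
#' Events without an offset get a nominal 1 ms interval so that Praat accepts
#' the file; [read_textgrid()] restores the onset exactly.
#'
#' @param events Event tibble (one display's worth is the usual unit).
#' @param path Output path.
#' @param tier_for_mode Named character vector mapping mode to tier name.
#' @return `path`, invisibly.
#' @export
write_textgrid <- function(events, path,
                           tier_for_mode = c(vocal = "calls",
                                             motoric = "actions")) {
  events <- validate_events(events, allow_missing_ids = TRUE)
  if (nrow(events) == 0L) stop("cannot write an empty TextGrid", call. = FALSE)
  offset <- ifelse(is.na(events$offset_s),
                   events$onset_s + 0.001, events$offset_s)
  xmax <- max(offset) + 0.5
  modes_here <- unique(events$mode)
  lines <- c(
    "File type = \"ooTextFile\"",
    "Object class = \"TextGrid\"",
    "",
    "xmin = 0",
    sprintf("xmax = %.6f", xmax),
    "tiers? <exists>",
    sprintf("size = %d", length(modes_here)),
    "item []:"
  )
  for (mi in seq_along(modes_here)) {
    mode <- modes_here[[mi]]
    sub <- events[events$mode %in% mode, ]
    sub <- sub[order(sub$onset_s), ]
    sub_off <- ifelse(is.na(sub$offset_s), sub$onset_s + 0.001, sub$offset_s)
    # fill silence between annotations so intervals tile [0, xmax]
    iv_min <- c()
    iv_max <- c()
    iv_lab <- c()
    cursor <- 0
    for (k in seq_len(nrow(sub))) {
      if (sub$onset_s[[k]] > cursor + 1e-9) {
        iv_min <- c(iv_min, cursor); iv_max <- c(iv_max, sub$onset_s[[k]])
        iv_lab <- c(iv_lab, "")
      }
      iv_min <- c(iv_min, sub$onset_s[[k]]); iv_max <- c(iv_max, sub_off[[k]])
      iv_lab <- c(iv_lab, sub$behaviour[[k]])
      cursor <- sub_off[[k]]
    }
    if (cursor < xmax) {
      iv_min <- c(iv_min, cursor); iv_max <- c(iv_max, xmax); iv_lab <- c(iv_lab, "")
    }
    tier_name <- if (mode %in% names(tier_for_mode)) {
      tier_for_mode[[mode]]
    } else {
      mode
    }
    lines <- c(
      lines,
      sprintf("    item [%d]:", mi),
      "        class = \"IntervalTier\"",
      sprintf("        name = \"%s\"", tier_name),
      "        xmin = 0",
      sprintf("        xmax = %.6f", xmax),
      sprintf("        intervals: size = %d", length(iv_min)),
      unlist(lapply(seq_along(iv_min), function(k) {
        c(sprintf("        intervals [%d]:", k),
          sprintf("            xmin = %.6f", iv_min[[k]]),
          sprintf("            xmax = %.6f", iv_max[[k]]),
          sprintf("            text = \"%s\"", iv_lab[[k]]))
      }))
    )
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# --- BORIS-style event log --------------------------------------------------

#' Read behavioural events from a BORIS-style event log
#'
#' Reads a delimited export from BORIS (or compatible event loggers). State
#' events use the start time as the onset and the stop time as the offset;
#' point events have no offset.
#'
#' @param path Path to the delimited file.
#' @param column_map Named list mapping the roles `subject`, `behaviour`,
#'   `start`, and optionally `stop`, to column names in the file.
#' @param delim Field delimiter (default comma).
#' @param display_id Optional display id attached to every event.
#' @param mode Production mode attached to every event (BORIS logs are used
#'   for motoric annotation here, so the default is `"motoric"`).
#' @return A tibble of behavioural events.
#' @export
read_boris_csv <- function(path,
                           column_map = list(subject = "Subject",
                                             behaviour = "Behavior",
                                             start = "Start (s)",
                                             stop = "Stop (s)"),
                           delim = ",",
                           display_id = NA_character_,
                           mode = "motoric") {
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  for (role in c("subject", "behaviour", "start")) {
    col <- column_map[[role]]
    if (is.null(col) || !col %in% names(raw)) {
      stop("column for role '", role, "' ",
           if (is.null(col)) "not configured" else paste0("('", col, "') missing from file"),
           call. = FALSE)
    }
  }
  start <- suppressWarnings(as.numeric(raw[[column_map$start]]))
  bad <- which(is.na(start) & !is.na(raw[[column_map$start]]) &
                 raw[[column_map$start]] != "")
  bad <- union(bad, which(is.na(raw[[column_map$start]]) |
                            raw[[column_map$start]] == ""))
  if (length(bad) > 0) {
    stop("non-numeric or missing start time in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  stop_col <- column_map$stop
  if (!is.null(stop_col) && stop_col %in% names(raw)) {
    stop_t <- suppressWarnings(as.numeric(raw[[stop_col]]))
  } else {
    stop_t <- rep(NA_real_, nrow(raw))
  }
  bad_stop <- which(!is.na(stop_t) & stop_t < start)
  if (length(bad_stop) > 0) {
    stop("stop time before start time in row(s): ",
         paste(utils::head(bad_stop, 5), collapse = ", "), call. = FALSE)
  }
  res <- empty_events()
  res <- tibble::add_row(
    res,
    individual_id = as.character(raw[[column_map$subject]]),
    display_id = rep(display_id, nrow(raw)),
    mode = rep(mode, nrow(raw)),
    behaviour = as.character(raw[[column_map$behaviour]]),
    onset_s = start, offset_s = stop_t
  )
  validate_events(res, allow_missing_ids = TRUE)
}

#' Write events as a BORIS-style event log
#'
#' @param events Event tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_boris_csv <- function(events, path) {
  events <- validate_events(events, allow_missing_ids = TRUE)
  out <- tibble::tibble(
    "Subject" = events$individual_id,
    "Behavior" = events$behaviour,
    "Behavior type" = ifelse(is.na(events$offset_s), "POINT", "STATE"),
    "Start (s)" = events$onset_s,
    "Stop (s)" = events$offset_s
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

# --- Unified event CSV ------------------------------------------------------

#' Read the unified event CSV
#'
#' The canonical interchange format of the package: one row per annotated
#' event with the exact header
#' `individual_id,display_id,zoo,group,mode,context,behaviour,onset_s,offset_s,sex,age_years`.
#'
#' @param path Path to the CSV.
#' @return A validated tibble of behavioural events.
#' @export
read_events_csv <- function(path) {
  ev <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          individual_id = readr::col_character(),
                          display_id = readr::col_character(),
                          zoo = readr::col_character(),
                          group = readr::col_character(),
                          mode = readr::col_character(),
                          context = readr::col_character(),
                          behaviour = readr::col_character(),
                          onset_s = readr::col_double(),
                          offset_s = readr::col_double(),
                          sex = readr::col_character(),
                          age_years = readr::col_double()
                        ))
  validate_events(ev)
}

#' Write the unified event CSV
#'
#' @param events Event tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  events <- validate_events(events)
  readr::write_csv(events, path, progress = FALSE, na = "")
  invisible(path)
}

#' Read a display metadata table
#'
#' Expected columns: `display_id,individual_id,zoo,group,context`.
#'
#' @param path Path to the CSV.
#' @return A tibble.
#' @export
read_metadata_csv <- function(path) {
  md <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  needed <- c("display_id", "individual_id", "zoo", "group", "context")
  missing <- setdiff(needed, names(md))
  if (length(missing) > 0) {
    stop("metadata missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  md[needed]
}

# --- Observation set --------------------------------------------------------

#' Assemble an observation set from events and display metadata
#'
#' Joins events to display-level metadata (individual, zoo, group, context),
#' then groups them into display sequences: ordered runs of same-mode events
#' of one display by one individual, sorted by onset. A display with both
#' vocal and motoric events yields two sequences, one per mode; intervals and
#' ratios are never computed across modes or displays.
#'
#' @param events Event tibble (ids and onsets required; `zoo`, `group`,
#'   `context` may be supplied by `metadata` instead).
#' @param metadata Optional metadata tibble with columns
#'   `display_id,individual_id,zoo,group,context`; when given it overrides the
#'   corresponding event columns, and every event's display must appear in it.
#' @return An object of class `observation_set`: a list with `events` (the
#'   validated, sequenced event table carrying a `sequence_id` column),
#'   `sequences` (one row per display sequence) and `provenance`.
#' @export
assemble_observation_set <- function(events, metadata = NULL) {
  # with metadata, individual ids may still be absent (filled by the join)
  events <- validate_events(events, allow_missing_ids = !is.null(metadata))
  if (!is.null(metadata)) {
    metadata <- tibble::as_tibble(metadata)
    orphans <- setdiff(unique(events$display_id), metadata$display_id)
    if (length(orphans) > 0) {
      stop("event display_id(s) missing from metadata: ",
           paste(utils::head(orphans, 10), collapse = ", "), call. = FALSE)
    }
    keep <- setdiff(names(events), c("zoo", "group", "context", "individual_id"))
    events <- dplyr::left_join(
      events[keep],
      metadata[c("display_id", "individual_id", "zoo", "group", "context")],
      by = "display_id"
    )
    events <- validate_events(events)
  }
  if (nrow(events) > 0 && anyNA(events$mode)) {
    stop("every event needs a mode before assembly", call. = FALSE)
  }
  events <- dplyr::arrange(events, .data$individual_id, .data$display_id,
                           .data$mode, .data$onset_s)
  dup <- duplicated(events[c("display_id", "mode", "onset_s", "behaviour")])
  if (any(dup)) {
    warning(sum(dup), " duplicate (display, mode, onset, label) event(s) kept",
            call. = FALSE)
  }
  events$sequence_id <- paste(events$display_id, events$mode, sep = ".")
  sequences <- if (nrow(events) == 0L) {
    tibble::tibble(sequence_id = character(), display_id = character(),
                   individual_id = character(), mode = character(),
                   context = character(), zoo = character(),
                   group = character(), n_events = integer(),
                   first_onset_s = double())
  } else {
    dplyr::summarise(
      dplyr::group_by(events, .data$sequence_id, .data$display_id,
                      .data$individual_id, .data$mode, .data$context,
                      .data$zoo, .data$group),
      n_events = dplyr::n(),
      first_onset_s = min(.data$onset_s),
      .groups = "drop"
    )
  }
  # a display id must not recur under a second individual within a mode
  clash <- dplyr::count(sequences, .data$display_id, .data$mode)
  if (any(clash$n > 1)) {
    stop("display_id/mode pair assigned to multiple individuals: ",
         paste(utils::head(clash$display_id[clash$n > 1], 5), collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(events = events, sequences = sequences,
         provenance = character()),
    class = "observation_set"
  )
}

#' @export
print.observation_set <- function(x, ...) {
  cat("<observation_set>\n")
  cat("  events:   ", nrow(x$events), "\n", sep = "")
  cat("  sequences:", nrow(x$sequences),
      sprintf(" (%d vocal, %d motoric)",
              sum(x$sequences$mode == "vocal"),
              sum(x$sequences$mode == "motoric")), "\n", sep = "")
  cat("  displays: ", length(unique(x$sequences$display_id)), "\n", sep = "")
  cat("  individuals: ", length(unique(x$sequences$individual_id)), "\n",
      sep = "")
  invisible(x)
}

#' @export
summary.observation_set <- function(object, ...) {
  dplyr::count(object$sequences, .data$zoo, .data$mode, .data$context,
               name = "n_sequences")
}
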
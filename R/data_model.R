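#' Construct a spike train
#'
#' A spike train is the fundamental unit-level record: an ordered vector of
#' spike times (ms, relative to session start) attached to a probe contact.
#' Multi-unit trains (one per contact) carry the unsorted channel activity
#' that feeds the population rate and the HMM; single-unit trains are the
#' neurons whose population coupling is measured.
#'
#' @param unit_id character identifier, unique within a session.
#' @param channel_index 0-based contact index along the probe; contact 0 is
#'   the most superficial.
#' @param kind `"single_unit"` or `"multi_unit"`.
#' @param spike_times numeric vector of spike times in ms relative to session
#'   start; must be nondecreasing and nonnegative.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(unit_id, channel_index, kind = c("single_unit", "multi_unit"),
                        spike_times = numeric()) {
  kind <- match.arg(kind)
  stopifnot(length(unit_id) == 1L, length(channel_index) == 1L)
  channel_index <- as.integer(channel_index)
  if (is.na(channel_index) || channel_index < 0L)
    stop("channel_index must be a nonnegative integer")
  spike_times <- as.numeric(spike_times)
  if (anyNA(spike_times)) stop("spike_times must not contain NA")
  if (length(spike_times) && any(diff(spike_times) < 0))
    stop(sprintf("spike_times of unit '%s' must be nondecreasing", unit_id))
  if (length(spike_times) && spike_times[1L] < 0)
    stop(sprintf("unit '%s' has a spike before session start (t = %g)",
                 unit_id, spike_times[1L]))
  structure(
    list(unit_id = as.character(unit_id), channel_index = channel_index,
         kind = kind, spike_times = spike_times),
    class = "spike_train")
}

#' Construct a trial-epochs table
#'
#' One row per trial with the three anchoring events of the task (fixation
#' onset, cue onset, first dimming) and the attention condition. The two cue
#' locations away from the recorded receptive fields are pooled into a single
#' `attend_away` condition.
#'
#' @param trial_id vector of trial identifiers.
#' @param fixation_onset_ms,cue_onset_ms,first_dimming_ms event times in ms
#'   relative to session start; must satisfy fixation < cue < dimming per trial.
#' @param condition `"attend_RF"` or `"attend_away"` per trial.
#' @return A `data.frame` of class `trial_epochs`.
#' @export
trial_epochs <- function(trial_id, fixation_onset_ms, cue_onset_ms,
                         first_dimming_ms, condition) {
  df <- data.frame(
    trial_id = as.character(trial_id),
    fixation_onset_ms = as.numeric(fixation_onset_ms),
    cue_onset_ms = as.numeric(cue_onset_ms),
    first_dimming_ms = as.numeric(first_dimming_ms),
    condition = as.character(condition),
    stringsAsFactors = FALSE)
  bad <- !(df$fixation_onset_ms < df$cue_onset_ms &
           df$cue_onset_ms < df$first_dimming_ms)
  if (any(bad))
    stop("trial(s) ", paste(df$trial_id[bad], collapse = ", "),
         ": events must satisfy fixation < cue < first dimming")
  if (!all(df$condition %in% c("attend_RF", "attend_away")))
    stop("condition must be 'attend_RF' or 'attend_away'")
  class(df) <- c("trial_epochs", "data.frame")
  df
}

#' Named analysis windows
#'
#' Windows are defined as offsets relative to a named trial event so they can
#' be resolved on any trial. The spontaneous window is monkey specific
#' (Monkey 1: 200-500 ms after fixation onset, Monkey 2: 100-400 ms); the
#' cue-to-dimming window runs from 400 ms after cue onset to 30 ms after the
#' first dimming. The baseline (-250-0 ms) and onset-response (50-300 ms)
#' windows used by the stimulus-response control are anchored at cue onset,
#' the stimulus-locked event available in the trial table; the pre-dimming
#' window (500-0 ms before first dimming) hosts the noise-correlation counts.
#'
#' @param name one of `"spontaneous"`, `"cue_to_dimming"`, `"pre_dimming"`,
#'   `"baseline"`, `"onset_response"`.
#' @param monkey_profile `"M1"` or `"M2"`; only the spontaneous window differs.
#' @return An object of class `analysis_window` with fields `name`,
#'   `start_anchor`, `start_offset_ms`, `end_anchor`, `end_offset_ms`.
#' @export
analysis_window <- function(name = c("spontaneous", "cue_to_dimming", "pre_dimming",
                                     "baseline", "onset_response"),
                            monkey_profile = c("M1", "M2")) {
  name <- match.arg(name)
  monkey_profile <- match.arg(monkey_profile)
  w <- switch(name,
    spontaneous = if (monkey_profile == "M1")
      list("fixation_onset_ms", 200, "fixation_onset_ms", 500)
    else
      list("fixation_onset_ms", 100, "fixation_onset_ms", 400),
    cue_to_dimming = list("cue_onset_ms", 400, "first_dimming_ms", 30),
    pre_dimming    = list("first_dimming_ms", -500, "first_dimming_ms", 0),
    baseline       = list("cue_onset_ms", -250, "cue_onset_ms", 0),
    onset_response = list("cue_onset_ms", 50, "cue_onset_ms", 300))
  structure(
    list(name = name, monkey_profile = monkey_profile,
         start_anchor = w[[1]], start_offset_ms = w[[2]],
         end_anchor = w[[3]], end_offset_ms = w[[4]]),
    class = "analysis_window")
}

#' Resolve an analysis window on a trial
#'
#' @param window an [analysis_window()].
#' @param trial a single-row trial record (one row of a `trial_epochs` table,
#'   or a list with the event fields).
#' @return Numeric `c(start, end)` in session time (ms); the interval is
#'   half-open `[start, end)`.
#' @export
resolve_window <- function(window, trial) {
  stopifnot(inherits(window, "analysis_window"))
  get_event <- function(anchor) {
    v <- trial[[anchor]]
    if (is.null(v) || length(v) != 1L || is.na(v))
      stop("trial is missing anchoring event '", anchor, "'")
    as.numeric(v)
  }
  start <- get_event(window$start_anchor) + window$start_offset_ms
  end <- get_event(window$end_anchor) + window$end_offset_ms
  if (!(end > start))
    stop(sprintf("window '%s' resolves to an empty interval [%g, %g)",
                 window$name, start, end))
  c(start, end)
}

#' Construct a recording session
#'
#' Bundles the spike trains, trial table and probe geometry of one laminar
#' penetration. Channel areas label each contact as V1 or V4.
#'
#' @param session_id character identifier.
#' @param monkey_profile `"M1"` or `"M2"` (selects monkey-specific windows).
#' @param spike_trains list of [spike_train()] objects (single- and multi-unit).
#' @param trials a `trial_epochs` table.
#' @param n_channels number of probe contacts (default 16).
#' @param areas character vector, length `n_channels`, of `"V1"`/`"V4"` labels.
#' @param probe_spacing_um contact spacing in micrometres (default 150).
#' @param continuous optional list with `matrix` (channels x samples) and
#'   `sampling_rate_hz`, for the laminar submodule.
#' @return An object of class `spike_session`.
#' @export
spike_session <- function(session_id, monkey_profile = c("M1", "M2"),
                          spike_trains, trials, n_channels = 16L,
                          areas = rep("V1", n_channels),
                          probe_spacing_um = 150, continuous = NULL) {
  monkey_profile <- match.arg(monkey_profile)
  s <- structure(
    list(session_id = as.character(session_id),
         monkey_profile = monkey_profile,
         n_channels = as.integer(n_channels),
         probe_spacing_um = as.numeric(probe_spacing_um),
         areas = as.character(areas),
         spike_trains = spike_trains,
         trials = trials,
         continuous = continuous),
    class = "spike_session")
  validate_session(s)
  s
}

#' Validate a session object
#'
#' Checks every invariant of the session data model: spike trains are valid
#' and reference existing channels, unit ids are unique, trial events are
#' ordered, both attention conditions are present, and area labels cover the
#' probe.
#'
#' @param session a `spike_session`.
#' @return The session, invisibly; stops with an informative error otherwise.
#' @export
validate_session <- function(session) {
  stopifnot(inherits(session, "spike_session"))
  if (length(session$areas) != session$n_channels)
    stop("areas must have one label per channel")
  if (!all(session$areas %in% c("V1", "V4")))
    stop("areas must be 'V1' or 'V4'")
  if (!length(session$spike_trains)) stop("session has no units")
  ids <- vapply(session$spike_trains, function(tr) tr$unit_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate unit_id: ", ids[duplicated(ids)][1L])
  for (tr in session$spike_trains) {
    if (!inherits(tr, "spike_train")) stop("spike_trains must contain spike_train objects")
    if (tr$channel_index >= session$n_channels)
      stop(sprintf("unit '%s' references channel %d outside the %d-contact probe",
                   tr$unit_id, tr$channel_index, session$n_channels))
  }
  tr <- session$trials
  if (!is.data.frame(tr) || nrow(tr) == 0L) stop("session has no trials")
  for (cond in c("attend_RF", "attend_away"))
    if (!any(tr$condition == cond))
      stop("session has no trials in condition '", cond, "'")
  bad <- !(tr$fixation_onset_ms < tr$cue_onset_ms &
           tr$cue_onset_ms < tr$first_dimming_ms)
  if (any(bad))
    stop("trial '", tr$trial_id[bad][1L], "' violates event ordering")
  invisible(session)
}

#' Fetch a spike train by unit id
#' @param session a `spike_session`.
#' @param unit_id unit identifier.
#' @return The matching `spike_train`.
#' @export
get_unit <- function(session, unit_id) {
  for (tr in session$spike_trains) if (tr$unit_id == unit_id) return(tr)
  stop("no unit '", unit_id, "' in session '", session$session_id, "'")
}

#' Trials of one attention condition
#' @param session a `spike_session`.
#' @param condition `"attend_RF"` or `"attend_away"`, or `NULL` for all.
#' @return The trial table subset (a data.frame).
#' @export
session_trials <- function(session, condition = NULL) {
  tr <- session$trials
  if (is.null(condition)) return(tr)
  tr[tr$condition == condition, , drop = FALSE]
}

#' Write a session to a directory of plain-text tables
#'
#' Serialises a session as `units.tsv` (unit_id, channel_index, kind),
#' `spikes.tsv` (unit_id, time_ms), `trials.tsv`, `session.json` (id, monkey
#' profile, probe geometry, per-channel areas) and, when present,
#' `continuous.tsv` (channels x samples). Times are written with full double
#' precision, so `read_session()` round-trips exactly at sub-ms precision.
#'
#' @param session a valid `spike_session`.
#' @param path directory to create/fill.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  validate_session(session)
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  units <- data.table::data.table(
    unit_id = vapply(session$spike_trains, `[[`, character(1), "unit_id"),
    channel_index = vapply(session$spike_trains, `[[`, integer(1), "channel_index"),
    kind = vapply(session$spike_trains, `[[`, character(1), "kind"))
  spikes <- data.table::rbindlist(lapply(session$spike_trains, function(tr)
    data.table::data.table(unit_id = rep(tr$unit_id, length(tr$spike_times)),
                           time_ms = tr$spike_times)))
  data.table::fwrite(units, file.path(path, "units.tsv"), sep = "\t")
  data.table::fwrite(spikes, file.path(path, "spikes.tsv"), sep = "\t")
  data.table::fwrite(as.data.frame(session$trials), file.path(path, "trials.tsv"),
                     sep = "\t")
  meta <- list(session_id = session$session_id,
               monkey_profile = session$monkey_profile,
               n_channels = session$n_channels,
               probe_spacing_um = session$probe_spacing_um,
               areas = session$areas)
  if (!is.null(session$continuous))
    meta$continuous_sampling_rate_hz <- session$continuous$sampling_rate_hz
  jsonlite::write_json(meta, file.path(path, "session.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(session$continuous))
    data.table::fwrite(data.table::as.data.table(session$continuous$matrix),
                       file.path(path, "continuous.tsv"), sep = "\t",
                       col.names = FALSE)
  invisible(path)
}

#' Read a session written by [write_session()]
#'
#' @param path session directory.
#' @return A validated `spike_session`.
#' @export
read_session <- function(path) {
  need <- function(f) {
    p <- file.path(path, f)
    if (!file.exists(p)) stop("session directory is missing table '", f, "'")
    p
  }
  meta <- jsonlite::read_json(need("session.json"), simplifyVector = TRUE)
  units <- data.table::fread(need("units.tsv"), sep = "\t",
                             colClasses = list(character = "unit_id"))
  spikes <- data.table::fread(need("spikes.tsv"), sep = "\t",
                              colClasses = list(character = "unit_id",
                                                double = "time_ms"))
  trials_df <- data.table::fread(
    need("trials.tsv"), sep = "\t",
    colClasses = list(character = c("trial_id", "condition"),
                      double = c("fixation_onset_ms", "cue_onset_ms",
                                 "first_dimming_ms")))
  trains <- lapply(seq_len(nrow(units)), function(i) {
    st <- spikes$time_ms[spikes$unit_id == units$unit_id[i]]
    spike_train(units$unit_id[i], units$channel_index[i], units$kind[i],
                sort(st))
  })
  trials <- trial_epochs(trials_df$trial_id, trials_df$fixation_onset_ms,
                         trials_df$cue_onset_ms, trials_df$first_dimming_ms,
                         trials_df$condition)
  continuous <- NULL
  cpath <- file.path(path, "continuous.tsv")
  if (file.exists(cpath)) {
    m <- as.matrix(data.table::fread(cpath, sep = "\t", header = FALSE))
    dimnames(m) <- NULL
    continuous <- list(matrix = m,
                       sampling_rate_hz = meta$continuous_sampling_rate_hz)
  }
  spike_session(meta$session_id, meta$monkey_profile, trains, trials,
                n_channels = meta$n_channels, areas = meta$areas,
                probe_spacing_um = meta$probe_spacing_um,
                continuous = continuous)
}
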
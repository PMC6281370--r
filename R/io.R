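#' Write a session to a directory of plain-text interchange files
#'
#' Layout: `session.json` (scalars and channel/unit metadata),
#' `emg_<channel>.csv` (one `amplitude` column; the fixed rate lives in the
#' sidecar), `spikes.csv` (`unit_id,structure,time_s`), `events.csv`
#' (`label,time_s`), `states.csv` (`start_s,end_s,label`, omitted when the
#' session is unscored), and `ground_truth/` for synthetic sessions. All
#' times are written in seconds with six fractional digits.
#'
#' @param sess A [session].
#' @param path Directory to create/fill.
#' @param overwrite Refuse to write into an existing session directory
#'   unless `TRUE`.
#' @return Invisibly, a manifest: character vector of files written, with
#'   attribute `"omitted"` naming optional files not applicable.
#' @export
write_session <- function(sess, path, overwrite = FALSE) {
  if (!inherits(sess, "session")) stop("write_session: 'sess' must be a session")
  if (file.exists(file.path(path, "session.json")) && !overwrite)
    stop(sprintf("write_session: '%s' already holds a session (use overwrite = TRUE)", path))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(x) sprintf("%.6f", x)
  written <- character(0); omitted <- character(0)

  emg_meta <- lapply(sess$emg, function(s) {
    f <- sprintf("emg_%s.csv", s$channel)
    utils::write.csv(data.frame(amplitude = signif(s$samples, 8)),
                     file.path(path, f), row.names = FALSE)
    written <<- c(written, f)
    list(channel = s$channel, rate_hz = s$rate, t0_s = s$t0,
         rectified = s$rectified, file = f)
  })

  spk <- do.call(rbind, c(list(data.frame(unit_id = character(0),
                                          structure = character(0),
                                          time_s = character(0))),
                          lapply(sess$spikes, function(u)
                            if (length(u$times))
                              data.frame(unit_id = u$unit_id,
                                         structure = u$structure,
                                         time_s = fmt(u$times))
                            else NULL)))
  utils::write.csv(spk, file.path(path, "spikes.csv"), row.names = FALSE,
                   quote = FALSE)
  written <- c(written, "spikes.csv")

  ev <- do.call(rbind, c(list(data.frame(label = character(0),
                                         time_s = character(0))),
                         lapply(sess$events, function(e)
                           if (length(e$times))
                             data.frame(label = e$label,
                                        time_s = fmt(e$times))
                           else NULL)))
  utils::write.csv(ev, file.path(path, "events.csv"), row.names = FALSE,
                   quote = FALSE)
  written <- c(written, "events.csv")

  write_states_csv <- function(st, f) {
    utils::write.csv(data.frame(start_s = fmt(st$start), end_s = fmt(st$end),
                                label = st$label),
                     file.path(path, f), row.names = FALSE, quote = FALSE)
  }
  if (!is.null(sess$states)) {
    write_states_csv(sess$states, "states.csv")
    written <- c(written, "states.csv")
  } else omitted <- c(omitted, "states.csv")

  gt <- sess$ground_truth
  if (!is.null(gt)) {
    dir.create(file.path(path, "ground_truth"), showWarnings = FALSE)
    write_states_csv(gt$true_states, file.path("ground_truth", "true_states.csv"))
    tw <- do.call(rbind, lapply(gt$true_twitches, function(e)
      if (length(e$times)) data.frame(label = e$label, time_s = fmt(e$times))
      else NULL))
    if (is.null(tw)) tw <- data.frame(label = character(0),
                                      time_s = character(0))
    utils::write.csv(tw, file.path(path, "ground_truth", "true_twitches.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(data.frame(time_s = fmt(gt$true_wake_onsets$times)),
                     file.path(path, "ground_truth", "wake_onsets.csv"),
                     row.names = FALSE, quote = FALSE)
    specs <- lapply(gt$unit_specs, function(u)
      list(archetype = u$archetype, unit_id = u$unit_id,
           structure = u$structure, base_rate = as.list(u$base_rate),
           kernels = u$kernels, plateau = u$plateau,
           trigger_muscle = u$trigger_muscle))
    jsonlite::write_json(list(muscles = names(gt$true_twitches),
                              unit_specs = specs,
                              emg_model = gt$emg_model),
                         file.path(path, "ground_truth", "meta.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    written <- c(written, "ground_truth/")
  } else omitted <- c(omitted, "ground_truth/")

  sidecar <- list(
    id = sess$id, duration_s = sess$duration, group = sess$group,
    emg = unname(emg_meta),
    units = unname(lapply(sess$spikes, function(u)
      list(unit_id = u$unit_id, structure = u$structure,
           quality_flags = as.list(u$quality_flags)))),
    event_trains = unname(lapply(sess$events, function(e) e$label)),
    states_threshold = if (!is.null(sess$states) &&
                           is.finite(attr(sess$states, "threshold_used")))
      attr(sess$states, "threshold_used") else NULL,
    writer = "sleepspikes")
  jsonlite::write_json(sidecar, file.path(path, "session.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  written <- c(written, "session.json")
  structure(written, omitted = omitted)
}

read_csv_checked <- function(path, cols) {
  if (!file.exists(path))
    stop(sprintf("read_session: missing mandatory file '%s'", basename(path)))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("read_session: '%s' lacks column(s): %s",
                 basename(path), paste(miss, collapse = ", ")))
  df
}

#' Read a session from its interchange directory
#'
#' Inverse of [write_session()]. All type invariants are validated while
#' reading: non-monotone spike or event times, out-of-range times,
#' overlapping state intervals, or unknown state labels raise an error
#' naming the offending record. Unsorted inputs are rejected, never
#' silently sorted.
#'
#' @param path Session directory.
#' @return A [session].
#' @export
read_session <- function(path) {
  sc_path <- file.path(path, "session.json")
  if (!file.exists(sc_path))
    stop("read_session: missing mandatory file 'session.json'")
  sc <- jsonlite::read_json(sc_path, simplifyVector = FALSE)
  for (f in c("id", "duration_s"))
    if (is.null(sc[[f]]))
      stop(sprintf("read_session: session.json lacks field '%s'", f))
  dur <- as.numeric(sc$duration_s)

  emg <- lapply(sc$emg, function(m) {
    df <- read_csv_checked(file.path(path, m$file), "amplitude")
    sampled_signal(df$amplitude, rate = as.numeric(m$rate_hz),
                   channel = m$channel, t0 = as.numeric(m$t0_s %||% 0),
                   rectified = isTRUE(m$rectified))
  })

  spk_df <- read_csv_checked(file.path(path, "spikes.csv"),
                             c("unit_id", "structure", "time_s"))
  unit_meta <- sc$units %||% list()
  meta_ids <- vapply(unit_meta, function(u) u$unit_id, "")
  all_ids <- union(meta_ids, unique(spk_df$unit_id))
  spikes <- lapply(all_ids, function(uid) {
    sel <- spk_df$unit_id == uid
    structure_lab <- if (uid %in% meta_ids)
      unit_meta[[match(uid, meta_ids)]]$structure
    else if (any(sel)) spk_df$structure[sel][1L] else "other"
    flags <- if (uid %in% meta_ids)
      unlist(unit_meta[[match(uid, meta_ids)]]$quality_flags)
    else character(0)
    spike_train(as.numeric(spk_df$time_s[sel]), unit_id = uid,
                structure = structure_lab,
                quality_flags = as.character(flags %||% character(0)))
  })

  ev_df <- read_csv_checked(file.path(path, "events.csv"),
                            c("label", "time_s"))
  ev_labels <- unlist(sc$event_trains %||% unique(ev_df$label))
  events <- lapply(ev_labels, function(lab)
    event_train(as.numeric(ev_df$time_s[ev_df$label == lab]), lab, dur))

  states <- NULL
  if (file.exists(file.path(path, "states.csv"))) {
    st <- read_csv_checked(file.path(path, "states.csv"),
                           c("start_s", "end_s", "label"))
    states <- state_intervals(as.numeric(st$start_s), as.numeric(st$end_s),
                              st$label,
                              threshold_used =
                                as.numeric(sc$states_threshold %||% NA))
  }

  gt <- NULL
  gt_dir <- file.path(path, "ground_truth")
  if (dir.exists(gt_dir)) {
    meta <- jsonlite::read_json(file.path(gt_dir, "meta.json"),
                                simplifyVector = FALSE)
    st <- read_csv_checked(file.path(gt_dir, "true_states.csv"),
                           c("start_s", "end_s", "label"))
    tw_df <- read_csv_checked(file.path(gt_dir, "true_twitches.csv"),
                              c("label", "time_s"))
    muscles <- unlist(meta$muscles)
    tw <- lapply(muscles, function(m) {
      lab <- paste0("twitch_", m)
      event_train(as.numeric(tw_df$time_s[tw_df$label == lab]), lab, dur)
    })
    names(tw) <- muscles
    wo <- read_csv_checked(file.path(gt_dir, "wake_onsets.csv"), "time_s")
    specs <- lapply(meta$unit_specs, function(u)
      unit_spec(archetype = u$archetype, unit_id = u$unit_id,
                structure = u$structure,
                base_rate = unlist(u$base_rate),
                kernels = if (length(u$kernels))
                  do.call(rbind, lapply(u$kernels, as.data.frame))
                else data.frame(center = numeric(0), width = numeric(0),
                                gain = numeric(0)),
                plateau = if (!is.null(u$plateau)) unlist(u$plateau),
                trigger_muscle = u$trigger_muscle))
    gt <- list(true_states = state_intervals(as.numeric(st$start_s),
                                             as.numeric(st$end_s), st$label),
               true_twitches = tw,
               true_wake_onsets = event_train(as.numeric(wo$time_s),
                                              "wake_onset", dur),
               unit_specs = specs,
               emg_model = lapply(meta$emg_model, as.numeric))
  }

  session(id = sc$id, emg = emg, spikes = spikes, events = events,
          states = states, group = as.character(sc$group %||% "none"),
          duration = dur, ground_truth = gt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
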
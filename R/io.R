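#' Write a simulated dataset to a directory
#'
#' Canonical on-disk layout: one sub-directory per subject containing
#' two-column delimited signal tables (`time_s`, `value`) for ECG and skin
#' conductance, multi-column tables for the motion channels, a JSON header
#' with sampling rates and units, a JSON event table and a JSON ground-truth
#' sidecar. A top-level `meta.json` records the study type and subject
#' count. Everything is plain text and round-trips losslessly.
#'
#' @param dataset a `study1_dataset` or `study2_dataset`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  study <- if (inherits(dataset, "study1_dataset")) "study1" else "study2"
  jsonlite::write_json(
    list(study = study, n_subjects = length(dataset$subjects)),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA
  )
  for (su in dataset$subjects) {
    sd <- file.path(dir, sprintf("subject_%02d", su$subject))
    dir.create(sd, showWarnings = FALSE)
    wtab <- function(df, name) {
      utils::write.table(df, file.path(sd, name), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }
    wtab(data.frame(time_s = su$ecg$time, value = su$ecg$value), "ecg.tsv")
    wtab(data.frame(time_s = su$edr$time, value = su$edr$value), "edr.tsv")
    wtab(stats::setNames(su$accel, c("time_s", "x", "y", "z")), "accel.tsv")
    wtab(stats::setNames(su$orient, c("time_s", "x", "y", "z")), "orient.tsv")
    wtab(stats::setNames(su$flexion, c("time_s", paste0("f", 1:5))), "flexion.tsv")
    jsonlite::write_json(
      list(ecg = list(fs = signal_fs(su$ecg), units = "mV"),
           edr = list(fs = signal_fs(su$edr), units = "uS"),
           motion = list(fs = 1 / median(diff(su$accel$time)))),
      file.path(sd, "channels.json"), auto_unbox = TRUE, digits = NA
    )
    jsonlite::write_json(su$events, file.path(sd, "events.json"),
                         auto_unbox = FALSE, digits = NA)
    jsonlite::write_json(
      list(beat_times = su$truth$beat_times,
           impulses = su$truth$sudomotor$impulses,
           tonic = su$truth$sudomotor$tonic,
           duration = su$truth$sudomotor$duration,
           grab_times = su$truth$grab_times,
           trials = su$truth$trials),
      file.path(sd, "ground_truth.json"), digits = NA
    )
  }
  invisible(dir)
}

#' Read a dataset directory written by [write_study_dataset()]
#'
#' Channels are validated on the way in: sample times must be strictly
#' increasing and consistent with the declared sampling rate to within
#' 1 ppm.
#'
#' @param dir dataset directory.
#' @return a `study1_dataset` or `study2_dataset`.
#' @export
read_study_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  subj_dirs <- sort(list.dirs(dir, recursive = FALSE))
  subjects <- lapply(seq_along(subj_dirs), function(i) {
    sd <- subj_dirs[i]
    ch <- jsonlite::read_json(file.path(sd, "channels.json"), simplifyVector = TRUE)
    rtab <- function(name) {
      utils::read.table(file.path(sd, name), header = TRUE, sep = "\t")
    }
    as_sig <- function(df, fs, units) {
      validate_channel_times(df$time_s, fs, name = basename(sd))
      out <- signal_tbl(df$value, fs = fs, start = df$time_s[1], units = units)
      out
    }
    ecg <- as_sig(rtab("ecg.tsv"), ch$ecg$fs, ch$ecg$units)
    edr <- as_sig(rtab("edr.tsv"), ch$edr$fs, ch$edr$units)
    rn <- function(df) stats::setNames(df, sub("^time_s$", "time", names(df)))
    ev <- jsonlite::read_json(file.path(sd, "events.json"), simplifyVector = TRUE)
    gt <- jsonlite::read_json(file.path(sd, "ground_truth.json"), simplifyVector = TRUE)
    list(
      subject = i,
      ecg = ecg, edr = edr,
      accel = tibble::as_tibble(rn(rtab("accel.tsv"))),
      orient = tibble::as_tibble(rn(rtab("orient.tsv"))),
      flexion = tibble::as_tibble(rn(rtab("flexion.tsv"))),
      events = tibble::as_tibble(ev),
      truth = list(
        beat_times = gt$beat_times,
        sudomotor = sudomotor_truth(gt$impulses, tibble::as_tibble(gt$tonic),
                                    gt$duration),
        grab_times = gt$grab_times,
        trials = if (!is.null(gt$trials)) tibble::as_tibble(gt$trials)
      )
    )
  })
  structure(list(subjects = subjects,
                 protocol = if (meta$study == "study1") study1_protocol() else study2_protocol(),
                 effects = effect_model()),
            class = paste0(meta$study, "_dataset"))
}

validate_channel_times <- function(t, fs, name = "channel") {
  d <- diff(t)
  bad <- which(d <= 0)
  if (length(bad)) {
    abort(sprintf("%s: sample times not strictly increasing at sample %d.",
                  name, bad[1] + 1L))
  }
  implied <- 1 / median(d)
  if (abs(implied - fs) / fs > 1e-6) {
    abort(sprintf("%s: declared fs %.6g Hz inconsistent with timestamps (%.6g Hz).",
                  name, fs, implied))
  }
  invisible(TRUE)
}

#' Run the conditioning analysis end to end
#'
#' Trial-table assembly plus the latency, first-interval SCR and HRV
#' statistics for a study-2 dataset.
#'
#' @param dataset a `study2_dataset`.
#' @return list: `trials`, `latency`, `edr`, `hrv`.
#' @export
run_study2_analysis <- function(dataset) {
  trials <- build_trial_table(dataset)
  list(
    trials = trials,
    latency = latency_stats(trials),
    edr = edr_block_stats(trials),
    hrv = hrv_conditioning_stats(trials)
  )
}
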
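# Trial container and the on-disk trial format.
#
# A trial on disk is a directory with
#   meta.json        subject + trial metadata (rates, units, conventions),
#                    and, for simulated trials, truth events
#   force.tsv        t, fz_l, fy_l, cop_l, fz_r, fy_r, cop_r   @ 1,000 Hz
#   kinematics.tsv   t, hip_l, knee_l, ankle_l, hip_r, knee_r, ankle_r @ 200 Hz
#   truth.tsv        (simulated trials only) per-side truth torques, COM
#                    states, segment angles/rates, contact flag @ 1,000 Hz
# All tables are tab-delimited text with full float precision (%.17g), so
# write -> read is the identity for finite values. Angles are flexion-positive
# radians; forces N; CoP metres relative to the ankle, positive forward.

#' Construct a trial object
#'
#' @param subject a `jw_subject` (or a list with the same fields).
#' @param jump_type one of [JUMP_TYPES].
#' @param drop_height drop height, m.
#' @param force per-plate force [timeseries()] with channels
#'   `fz_l, fy_l, cop_l, fz_r, fy_r, cop_r` at 1,000 Hz.
#' @param kinematics joint-angle [timeseries()] with channels
#'   `hip_l, knee_l, ankle_l, hip_r, knee_r, ankle_r` at 200 Hz.
#' @param truth optional simulator ground truth (see [simulate_trial()]).
#' @param meta free-form metadata list.
#' @return An object of class `jw_trial`.
#' @export
new_trial <- function(subject, jump_type, drop_height, force, kinematics,
                      truth = NULL, meta = list()) {
  trial <- structure(
    list(subject = subject, jump_type = jump_type, drop_height = drop_height,
         force = force, kinematics = kinematics, truth = truth, meta = meta),
    class = "jw_trial"
  )
  trial
}

#' @export
print.jw_trial <- function(x, ...) {
  cat(sprintf("<jw_trial> %s %s (drop %.2f m), %.2f s, %s truth\n",
              x$subject$subject_id, x$jump_type, x$drop_height,
              x$force$t[ts_n(x$force)], if (is.null(x$truth)) "no" else "with"))
  invisible(x)
}

FORCE_CHANNELS <- c("fz_l", "fy_l", "cop_l", "fz_r", "fy_r", "cop_r")
KIN_CHANNELS <- c("hip_l", "knee_l", "ankle_l", "hip_r", "knee_r", "ankle_r")

# Invariant checks shared by write_trial and read_trial.
check_trial <- function(trial, strict = TRUE) {
  problems <- character()
  note <- function(msg) problems <<- c(problems, msg)
  for (nm in c("force", "kinematics")) {
    ts <- trial[[nm]]
    ok <- tryCatch({ validate_timeseries(ts); TRUE },
                   jw_format_error = function(e) { note(sprintf("%s: %s", nm, conditionMessage(e))); FALSE })
    if (!ok) next
    if (ts_n(ts) < 2L) note(sprintf("%s: empty or single-sample series", nm))
  }
  want <- list(force = FORCE_CHANNELS, kinematics = KIN_CHANNELS)
  for (nm in names(want)) {
    missing <- setdiff(want[[nm]], colnames(trial[[nm]]$values))
    if (length(missing)) note(sprintf("%s: missing channel %s", nm, paste(missing, collapse = ", ")))
  }
  if (trial$force$rate != FORCE_RATE) {
    note(sprintf("force: rate %g Hz differs from the nominal %d Hz", trial$force$rate, FORCE_RATE))
  }
  if (trial$kinematics$rate != KIN_RATE) {
    note(sprintf("kinematics: rate %g Hz differs from the nominal %d Hz", trial$kinematics$rate, KIN_RATE))
  }
  if (abs(trial$force$t[1L] - trial$kinematics$t[1L]) > 1e-9) {
    note("force and kinematics do not share a time origin")
  }
  if (is.null(trial$subject$body_mass) || !is.finite(trial$subject$body_mass) ||
      trial$subject$body_mass <= 0) {
    note("subject: missing or non-positive body mass")
  }
  if (strict && length(problems)) {
    jw_abort(paste0("invalid trial:\n  - ", paste(problems, collapse = "\n  - ")),
             "jw_format_error")
  }
  problems
}

#' Validate a trial and report violations
#'
#' Reporting variant of the trial invariants: rates, channel presence,
#' monotone uniform time, finite values, shared time origin, subject mass.
#'
#' @param trial a `jw_trial`.
#' @return Character vector of violations (empty when the trial is valid).
#' @export
validate_trial <- function(trial) {
  check_trial(trial, strict = FALSE)
}

fmt_table <- function(df, path) {
  txt <- vapply(df, function(col) sprintf("%.17g", col), character(nrow(df)))
  if (is.null(dim(txt))) txt <- matrix(txt, nrow = nrow(df))
  utils::write.table(
    `colnames<-`(txt, names(df)), path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
}

#' Write a trial to disk
#'
#' Writes the delimited-text + JSON-sidecar trial format described above.
#' Trials failing their invariants (including any non-finite force or
#' kinematic sample) are rejected before anything is written.
#'
#' @param trial a valid `jw_trial`.
#' @param path directory to create/populate.
#' @export
write_trial <- function(trial, path) {
  check_trial(trial, strict = TRUE)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) jw_abort(sprintf("cannot create '%s'", path), "jw_io_error")
  meta <- list(
    format = "jumpwork-trial/1",
    subject = trial$subject[c("subject_id", "sex", "body_mass", "height",
                              "squat_1rm", "rel_strength")],
    jump_type = trial$jump_type,
    drop_height = trial$drop_height,
    force_rate = trial$force$rate,
    kin_rate = trial$kinematics$rate,
    units = list(force = "N", cop = "m", angle = "rad"),
    conventions = list(angles = "flexion-positive (ankle dorsiflexion)",
                       moments = "extensor-positive",
                       cop = "relative to ankle, positive forward"),
    meta = trial$meta,
    has_truth = !is.null(trial$truth),
    truth_events = if (!is.null(trial$truth)) trial$truth$events
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  fmt_table(data.frame(t = trial$force$t, trial$force$values, check.names = FALSE),
            file.path(path, "force.tsv"))
  fmt_table(data.frame(t = trial$kinematics$t, trial$kinematics$values, check.names = FALSE),
            file.path(path, "kinematics.tsv"))
  if (!is.null(trial$truth)) {
    tr <- trial$truth
    df <- data.frame(t = tr$torque$t, tr$torque$values, tr$com$values,
                     tr$state$values, contact = as.numeric(tr$contact),
                     check.names = FALSE)
    fmt_table(df, file.path(path, "truth.tsv"))
  }
  invisible(path)
}

read_tsv_numeric <- function(path, what) {
  if (!file.exists(path)) jw_abort(sprintf("missing %s (%s)", what, path), "jw_format_error")
  df <- utils::read.delim(path, check.names = FALSE)
  for (j in seq_along(df)) df[[j]] <- as.numeric(df[[j]])
  df
}

#' Read a trial from disk
#'
#' Reads the format written by [write_trial()], reconstructing a `jw_trial`
#' that passes all invariants. Violations (missing channels, rate mismatch,
#' non-monotone time, truncated tables) abort with class `jw_format_error`
#' naming the problem.
#'
#' @param path trial directory.
#' @return A `jw_trial`.
#' @export
read_trial <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) jw_abort(sprintf("missing meta.json in '%s'", path), "jw_format_error")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  fdf <- read_tsv_numeric(file.path(path, "force.tsv"), "force table")
  kdf <- read_tsv_numeric(file.path(path, "kinematics.tsv"), "kinematics table")
  for (spec in list(list(df = fdf, rate = meta$force_rate, what = "force"),
                    list(df = kdf, rate = meta$kin_rate, what = "kinematics"))) {
    tt <- spec$df$t
    if (length(tt) < 2L) {
      jw_abort(sprintf("%s table has %d rows (need >= 2)", spec$what, length(tt)),
               "jw_format_error")
    }
    if (any(diff(tt) <= 0) || max(abs(diff(tt) - 1 / spec$rate)) > 1e-9) {
      jw_abort(sprintf("%s table: time column is not a uniform grid at %g Hz",
                       spec$what, spec$rate), "jw_format_error")
    }
  }
  subject <- new_subject(meta$subject$subject_id, meta$subject$sex,
                         meta$subject$body_mass, meta$subject$height,
                         meta$subject$squat_1rm)
  force_ts <- timeseries(as.matrix(fdf[, -1L, drop = FALSE]), rate = meta$force_rate,
                         t0 = fdf$t[1L], units = "N; CoP m")
  kin_ts <- timeseries(as.matrix(kdf[, -1L, drop = FALSE]), rate = meta$kin_rate,
                       t0 = kdf$t[1L], units = "rad")
  truth <- NULL
  tpath <- file.path(path, "truth.tsv")
  if (isTRUE(meta$has_truth) && file.exists(tpath)) {
    tdf <- read_tsv_numeric(tpath, "truth table")
    tq <- c("ankle_l", "knee_l", "hip_l", "ankle_r", "knee_r", "hip_r")
    truth <- list(
      torque = timeseries(as.matrix(tdf[, tq]), rate = meta$force_rate,
                          t0 = tdf$t[1L], units = "N m"),
      com = timeseries(as.matrix(tdf[, c("z", "v", "a")]), rate = meta$force_rate,
                       t0 = tdf$t[1L], units = "m; m/s; m/s^2"),
      state = timeseries(as.matrix(tdf[, c("th1", "th2", "th3", "thd1", "thd2", "thd3")]),
                         rate = meta$force_rate, t0 = tdf$t[1L], units = "rad; rad/s"),
      contact = tdf$contact > 0.5,
      events = meta$truth_events
    )
  }
  trial <- new_trial(subject, meta$jump_type, meta$drop_height,
                     force_ts, kin_ts, truth = truth,
                     meta = as.list(meta$meta))
  check_trial(trial, strict = TRUE)
  trial
}
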
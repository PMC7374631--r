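# End-to-end pipeline: simulate -> preprocess -> analyze -> summarize.

#' Default pipeline configuration
#'
#' Every field can be overridden through [run_pipeline()]'s `config` argument
#' (or the JSON config given to the command-line driver); defaulted fields
#' are recorded in the run log together with the config hash.
#'
#' @return named list of defaults:
#' \describe{
#'   \item{cohort}{`n_men`, `n_women`, `seed` for [generate_cohort()].}
#'   \item{jumps}{jump types to simulate/analyze.}
#'   \item{trial_seed_base}{per-trial seeds are derived from this.}
#'   \item{noise}{`force_sd` (N), `angle_sd` (rad) measurement noise.}
#'   \item{filter}{zero-lag Butterworth `cutoff` (Hz) and effective `order`
#'     for kinematics/force; `NULL` cutoff disables filtering.}
#'   \item{com_filter}{use the filtered force for COM work (the raw force is
#'     always used for impulse checks and event thresholds).}
#'   \item{com_mode}{"total" or "net" force as the COM work-loop drive.}
#'   \item{thresholds}{event detection, see [default_thresholds()].}
#'   \item{anthro_table}{"winter" or "deleva".}
#'   \item{dj_velocity_scale}{drop-height attrition correction on the
#'     touchdown speed (1 = nominal).}
#'   \item{sim_rate}{integrator rate, Hz.}
#'   \item{outdir}{output directory (NULL = no files written).}
#' }
#' @export
default_config <- function() {
  list(
    cohort = list(n_men = 9, n_women = 12, seed = 1),
    jumps = JUMP_TYPES,
    trial_seed_base = 1000,
    noise = list(force_sd = 0, angle_sd = 0),
    filter = list(cutoff = 11, order = 4),
    com_filter = TRUE,
    com_mode = "total",
    thresholds = default_thresholds(),
    anthro_table = "winter",
    dj_velocity_scale = 1.0,
    sim_rate = 1000,
    outdir = NULL
  )
}

merge_config <- function(config) {
  cfg <- utils::modifyList(default_config(), as.list(config))
  if (is.null(cfg$cohort$n_men) && is.null(cfg$trial_dir)) {
    jw_abort("config needs a cohort spec or a trial_dir", "jw_config_error")
  }
  cfg
}

#' Analyze a single trial
#'
#' Runs the full per-trial analysis: event detection, COM kinematics by
#' forward dynamics, COM work decomposition and work loop, planar inverse
#' dynamics, per-joint work with bilateral averaging.
#'
#' @param trial a `jw_trial`.
#' @param config pipeline configuration (see [default_config()]).
#' @return list: `events`, `com` (`state`, `work`, `loop`), `kinetics`,
#'   `joints` (bilaterally averaged `jw_work` per joint), `rows` (data.frame,
#'   one row per measure).
#' @export
analyze_trial <- function(trial, config = list()) {
  cfg <- merge_config(config)
  mass <- trial$subject$body_mass
  events <- detect_events(trial, thresholds = cfg$thresholds)
  fz_raw <- timeseries(total_fz(trial), trial$force$rate, t0 = trial$force$t[1L],
                       units = "N")
  fz_com <- if (cfg$com_filter && !is.null(cfg$filter$cutoff)) {
    lowpass_zero_lag(fz_raw, cfg$filter$cutoff, cfg$filter$order)
  } else {
    fz_raw
  }
  state <- com_kinematics(fz_com, mass, events, trial$jump_type,
                          trial$drop_height, cfg$dj_velocity_scale)
  cwork <- com_work(fz_com, state, events, mass, mode = cfg$com_mode)
  cloop <- com_workloop(fz_com, state, events, mass, mode = cfg$com_mode)
  sp <- segment_parameters(mass, trial$subject$height, cfg$anthro_table)
  kin <- inverse_dynamics_planar(trial, sp, filter_cutoff = cfg$filter$cutoff,
                                 filter_order = cfg$filter$order)
  jw <- joint_work(kin, events)
  joints <- lapply(stats::setNames(JOINTS, JOINTS), function(j) {
    bilateral_average(jw$l[[j]], jw$r[[j]])
  })
  one_row <- function(w, measure) {
    data.frame(subject_id = trial$subject$subject_id, sex = trial$subject$sex,
               jump_type = trial$jump_type, measure = measure,
               W_neg = w$W_neg, W_pos = w$W_pos, W_net = w$W_net,
               ratio = w$ratio, stringsAsFactors = FALSE)
  }
  rows <- rbind(one_row(cwork, "com"), one_row(joints$hip, "hip"),
                one_row(joints$knee, "knee"), one_row(joints$ankle, "ankle"))
  list(events = events, com = list(state = state, work = cwork, loop = cloop),
       kinetics = kin, joints = joints, rows = rows)
}

#' Run the full pipeline
#'
#' Simulates (or reads) a cohort's trials, analyzes every trial, builds the
#' per-trial and group work tables, ensemble COM work loops per group and
#' jump type, and the sex-by-jump and strength-by-jump ANOVAs with Bonferroni
#' post-hoc tests. Deterministic given the config seeds. If `outdir` is set,
#' writes `work_table.csv`, `group_tables.csv`, `ensembles.csv`,
#' `anova.json` and `run_log.json` there.
#'
#' @param config overrides of [default_config()]; alternatively a path to a
#'   JSON file with the same structure.
#' @param progress print one line per trial.
#' @return list: `config`, `cohort`, `groups`, `work` (per-trial rows),
#'   `group_tables` (by sex and by strength tertile), `anova`, `posthoc`,
#'   `ensembles`, `failures`.
#' @export
run_pipeline <- function(config = list(), progress = FALSE) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- merge_config(config)
  trials_on_disk <- !is.null(cfg$trial_dir)
  if (trials_on_disk) {
    paths <- list.dirs(cfg$trial_dir, recursive = FALSE)
    if (!length(paths)) jw_abort("trial_dir contains no trial directories", "jw_config_error")
    trials <- lapply(paths, read_trial)
    subjects <- unique(lapply(trials, `[[`, "subject"))
    cohort <- structure(list(subjects = subjects, profile = NULL, seed = NA),
                        class = "jw_cohort")
  } else {
    cohort <- generate_cohort(cfg$cohort$n_men, cfg$cohort$n_women,
                              seed = cfg$cohort$seed)
  }
  groups <- assign_strength_groups(cohort, policy = "truncate")
  work_rows <- list()
  loops <- list()
  failures <- list()
  trial_idx <- 0L
  run_one <- function(trial) {
    res <- analyze_trial(trial, cfg)
    key <- paste(trial$subject$subject_id, trial$jump_type, sep = ":")
    loops[[key]] <<- res$com$loop
    work_rows[[key]] <<- res$rows
  }
  if (trials_on_disk) {
    for (trial in trials) {
      trial_idx <- trial_idx + 1L
      tryCatch(run_one(trial), jw_error = function(e) {
        failures[[length(failures) + 1L]] <<- list(
          trial = sprintf("%s:%s", trial$subject$subject_id, trial$jump_type),
          stage = "analyze", message = conditionMessage(e))
      })
    }
  } else {
    for (s in cohort$subjects) {
      for (jt in cfg$jumps) {
        trial_idx <- trial_idx + 1L
        seed <- cfg$trial_seed_base + trial_idx
        if (progress) message(sprintf("simulating %s %s", s$subject_id, jt))
        stage <- "simulate"
        tryCatch({
          trial <- simulate_trial(s, jt, sim_rate = cfg$sim_rate, seed = seed)
          if (cfg$noise$force_sd > 0 || cfg$noise$angle_sd > 0) {
            trial <- add_noise(trial, cfg$noise$force_sd, cfg$noise$angle_sd,
                               seed = seed + 1L)
          }
          stage <- "analyze"
          run_one(trial)
        }, jw_error = function(e) {
          failures[[length(failures) + 1L]] <<- list(
            trial = sprintf("%s:%s", s$subject_id, jt),
            stage = stage, message = conditionMessage(e))
        })
      }
    }
  }
  if (!length(work_rows)) jw_abort("no trial analyzed successfully", "jw_pipeline_error")
  work <- do.call(rbind, unname(work_rows))
  rownames(work) <- NULL
  # attach groups; sex comes from the trial itself, strength from the tertile
  # assignment (NA when the cohort cannot be split into tertiles)
  gidx <- match(work$subject_id, groups$subject_id)
  work$sex_group <- work$sex
  work$strength_group <- groups$strength_group[gidx]

  mk_table <- function(group_col) {
    w <- work
    w$group <- w[[group_col]]
    build_group_tables(w)
  }
  group_tables <- list(sex = mk_table("sex_group"),
                       strength = mk_table("strength_group"))

  com_work_tab <- work[work$measure == "com", ]
  try_anova <- function(factor_a) {
    tryCatch(two_way_anova(com_work_tab, "W_net", factor_a, "jump_type"),
             jw_error = function(e) NULL)
  }
  anova <- list(sex = try_anova("sex_group"),
                strength = try_anova("strength_group"))
  posthoc <- list(strength = if (!is.null(anova$strength)) {
    bonferroni_posthoc(anova$strength)
  })

  ensembles <- list()
  key_sub <- sub(":.*", "", names(loops))
  key_jt <- sub(".*:", "", names(loops))
  for (group_col in c("sex_group", "strength_group")) {
    for (g in unique(groups[[group_col]])) {
      members <- groups$subject_id[groups[[group_col]] == g]
      for (jt in unique(key_jt)) {
        sel <- key_sub %in% members & key_jt == jt
        if (any(sel)) {
          ensembles[[paste(g, jt, sep = ":")]] <-
            ensemble_average(loops[sel], group = paste(g, jt))
        }
      }
    }
  }

  out <- list(config = cfg, cohort = cohort, groups = groups, work = work,
              group_tables = group_tables, anova = anova, posthoc = posthoc,
              ensembles = ensembles, failures = failures)
  if (!is.null(cfg$outdir)) write_run_outputs(out, cfg$outdir)
  invisible(out)
}

write_run_outputs <- function(out, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(out$work, file.path(outdir, "work_table.csv"), row.names = FALSE)
  gt <- rbind(cbind(grouping = "sex", out$group_tables$sex),
              cbind(grouping = "strength", out$group_tables$strength))
  utils::write.csv(gt, file.path(outdir, "group_tables.csv"), row.names = FALSE)
  ens <- do.call(rbind, lapply(names(out$ensembles), function(k) {
    e <- out$ensembles[[k]]
    data.frame(group = k, point = seq_along(e$excursion),
               excursion = e$excursion, drive = e$drive,
               excursion_sd = e$excursion_sd, drive_sd = e$drive_sd,
               n = e$n, stringsAsFactors = FALSE)
  }))
  utils::write.csv(ens, file.path(outdir, "ensembles.csv"), row.names = FALSE)
  anova_json <- list(
    sex = out$anova$sex$table,
    strength = out$anova$strength$table,
    posthoc_strength = out$posthoc$strength
  )
  jsonlite::write_json(anova_json, file.path(outdir, "anova.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg_json <- jsonlite::toJSON(out$config, auto_unbox = TRUE, digits = NA,
                               null = "null", force = TRUE)
  log <- list(
    package = "jumpwork",
    version = tryCatch(as.character(utils::packageVersion("jumpwork")),
                       error = function(e) "dev"),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = out$config,
    config_hash = fnv1a32(as.character(cfg_json)),
    n_trials = length(unique(paste(out$work$subject_id, out$work$jump_type))),
    n_failures = length(out$failures),
    failures = out$failures
  )
  jsonlite::write_json(log, file.path(outdir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE, force = TRUE)
  invisible(outdir)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a cohort's trials to disk), `analyze`
#' (per-trial work tables from a trial directory), `all` (full pipeline from
#' a config). Invoke through the installed script
#' `system.file("cli", "jumpwork.R", package = "jumpwork")`:
#' \preformatted{Rscript jumpwork.R all --config cfg.json --out runs/run1}
#'
#' @param args command-line arguments (default `commandArgs(TRUE)`).
#' @return exit status, invisibly.
#' @export
jw_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: jumpwork.R <simulate|analyze|all> [--config cfg.json] [--trials dir] [--out dir] [--quiet]"
  if (!length(args)) {
    message(usage)
    return(invisible(1L))
  }
  cmd <- args[1L]
  rest <- args[-1L]
  opt <- list(config = NULL, trials = NULL, out = NULL, quiet = FALSE)
  i <- 1L
  while (i <= length(rest)) {
    a <- rest[i]
    if (a == "--quiet") {
      opt$quiet <- TRUE
    } else if (a %in% c("--config", "--trials", "--out") && i < length(rest)) {
      opt[[sub("^--", "", a)]] <- rest[i + 1L]
      i <- i + 1L
    } else {
      message("unknown argument: ", a, "\n", usage)
      return(invisible(1L))
    }
    i <- i + 1L
  }
  cfg <- if (!is.null(opt$config)) {
    jsonlite::read_json(opt$config, simplifyVector = TRUE)
  } else {
    list()
  }
  if (!is.null(opt$trials)) cfg$trial_dir <- opt$trials
  if (!is.null(opt$out)) cfg$outdir <- opt$out
  if (cmd == "simulate") {
    mcfg <- merge_config(cfg)
    if (is.null(mcfg$outdir)) {
      message("simulate needs --out")
      return(invisible(1L))
    }
    cohort <- generate_cohort(mcfg$cohort$n_men, mcfg$cohort$n_women,
                              seed = mcfg$cohort$seed)
    idx <- 0L
    for (s in cohort$subjects) {
      for (jt in mcfg$jumps) {
        idx <- idx + 1L
        trial <- simulate_trial(s, jt, sim_rate = mcfg$sim_rate,
                                seed = mcfg$trial_seed_base + idx)
        if (mcfg$noise$force_sd > 0 || mcfg$noise$angle_sd > 0) {
          trial <- add_noise(trial, mcfg$noise$force_sd, mcfg$noise$angle_sd,
                             seed = mcfg$trial_seed_base + idx + 1L)
        }
        write_trial(trial, file.path(mcfg$outdir, sprintf("%s_%s", s$subject_id, jt)))
        if (!opt$quiet) message(sprintf("wrote %s %s", s$subject_id, jt))
      }
    }
  } else if (cmd %in% c("analyze", "all")) {
    out <- run_pipeline(cfg, progress = !opt$quiet)
    if (!opt$quiet) {
      message(sprintf("analyzed %d trials (%d failures)",
                      length(unique(paste(out$work$subject_id, out$work$jump_type))),
                      length(out$failures)))
    }
  } else {
    message(usage)
    return(invisible(1L))
  }
  invisible(0L)
}
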
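# Synthetic cohort generation.

#' Jump type vocabulary
#'
#' The six jump conditions: a countermovement jump and drop jumps from
#' 0.15-0.75 m.
#' @export
JUMP_TYPES <- c("CMJ", "DJ15", "DJ30", "DJ45", "DJ60", "DJ75")

#' Nominal drop height of a jump type
#' @param jump_type one of [JUMP_TYPES].
#' @return drop height in m (0 for CMJ).
#' @export
jump_drop_height <- function(jump_type) {
  jump_type <- match.arg(jump_type, JUMP_TYPES)
  c(CMJ = 0, DJ15 = 0.15, DJ30 = 0.30, DJ45 = 0.45, DJ60 = 0.60, DJ75 = 0.75)[[jump_type]]
}

# Per-sex generation defaults: mean/SD of body mass (kg), height (m) and squat
# one-repetition maximum (kg), as reported for the emulated cohort.
default_strength_profile <- function() {
  list(
    M = list(mass = c(79, 7), height = c(1.77, 0.06), squat_1rm = c(116, 25)),
    W = list(mass = c(63, 11), height = c(1.66, 0.06), squat_1rm = c(66, 22))
  )
}

# Normal draw truncated at +/- 3 SD and at a physiological floor.
rnorm_trunc <- function(n, mean, sd, floor = -Inf) {
  lo <- max(mean - 3 * sd, floor)
  hi <- mean + 3 * sd
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- stats::rnorm(1, mean, sd)
      if (x >= lo && x <= hi) break
    }
    out[i] <- x
  }
  out
}

new_subject <- function(subject_id, sex, body_mass, height, squat_1rm) {
  if (body_mass <= 0 || height <= 0 || squat_1rm < 0) {
    jw_abort("subject anthropometrics out of range", "jw_argument_error")
  }
  structure(
    list(subject_id = subject_id, sex = sex, body_mass = body_mass,
         height = height, squat_1rm = squat_1rm,
         rel_strength = squat_1rm / body_mass),
    class = "jw_subject"
  )
}

#' Generate a synthetic cohort
#'
#' Draws subjects from per-sex normal distributions of body mass, height and
#' squat 1RM, truncated at 3 SD (and at physiological floors), mirroring a
#' 9-men / 12-women recreationally active cohort. Deterministic given `seed`.
#'
#' @param n_men,n_women subject counts (>= 0).
#' @param strength_profile per-sex list of `c(mean, sd)` for `mass`, `height`
#'   and `squat_1rm`; defaults to the emulated cohort's statistics.
#' @param seed integer RNG seed.
#' @return An object of class `jw_cohort`: list with `subjects` (list of
#'   `jw_subject`), the `profile` used and the `seed`.
#' @export
generate_cohort <- function(n_men = 9L, n_women = 12L,
                            strength_profile = default_strength_profile(),
                            seed = 1L) {
  if (length(n_men) != 1L || length(n_women) != 1L || n_men < 0 || n_women < 0) {
    jw_abort("subject counts must be single non-negative numbers", "jw_argument_error")
  }
  for (sx in names(strength_profile)) {
    for (fld in strength_profile[[sx]]) {
      if (length(fld) != 2L || fld[2L] < 0) {
        jw_abort("strength profile entries must be c(mean, sd) with sd >= 0",
                 "jw_argument_error")
      }
    }
  }
  subjects <- with_seed(seed, {
    out <- list()
    sexes <- c(rep("M", n_men), rep("W", n_women))
    for (i in seq_along(sexes)) {
      pf <- strength_profile[[sexes[i]]]
      mass <- rnorm_trunc(1, pf$mass[1L], pf$mass[2L], floor = 40)
      # recreationally active adults squat at least ~half body weight; the
      # normal tail below that is unphysiological
      srm <- rnorm_trunc(1, pf$squat_1rm[1L], pf$squat_1rm[2L],
                         floor = 0.5 * mass)
      out[[i]] <- new_subject(
        subject_id = sprintf("S%02d", i),
        sex = sexes[i],
        body_mass = mass,
        height = rnorm_trunc(1, pf$height[1L], pf$height[2L], floor = 1.40),
        squat_1rm = srm
      )
    }
    out
  })
  structure(list(subjects = subjects, profile = strength_profile, seed = seed),
            class = "jw_cohort")
}

#' @export
print.jw_cohort <- function(x, ...) {
  n <- length(x$subjects)
  sx <- vapply(x$subjects, `[[`, "", "sex")
  cat(sprintf("<jw_cohort> %d subjects (%d M / %d W), seed %d\n",
              n, sum(sx == "M"), sum(sx == "W"), x$seed))
  invisible(x)
}

#' Cohort as a data frame
#' @param cohort a [generate_cohort()] result.
#' @return data.frame with one row per subject.
#' @export
cohort_table <- function(cohort) {
  do.call(rbind, lapply(cohort$subjects, function(s) {
    data.frame(subject_id = s$subject_id, sex = s$sex, body_mass = s$body_mass,
               height = s$height, squat_1rm = s$squat_1rm,
               rel_strength = s$rel_strength, stringsAsFactors = FALSE)
  }))
}
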
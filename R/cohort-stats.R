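# Grouping, ensemble work-loop curves and comparison statistics.

#' Strength-tertile group assignment
#'
#' Ranks subjects by relative strength (squat 1RM / body mass) and splits the
#' cohort into equal thirds: higher (HS), moderate (MS) and lower (LS)
#' strength. Ties at a boundary are broken by subject id (lexicographic), so
#' the partition is deterministic and invariant to subject order.
#'
#' @param cohort a [generate_cohort()] result (size divisible by 3; with the
#'   default 21 subjects the groups are 7/7/7).
#' @param policy what to do when the size is not divisible by 3: `"error"`
#'   (default) or `"truncate"` (drop the weakest remainder before splitting).
#' @return An object of class `jw_groups`: data.frame with `subject_id`,
#'   `sex`, `rel_strength`, `sex_group`, `strength_group`.
#' @export
assign_strength_groups <- function(cohort, policy = c("error", "truncate")) {
  policy <- match.arg(policy)
  tab <- cohort_table(cohort)
  n <- nrow(tab)
  if (n %% 3L != 0L) {
    if (policy == "error") {
      jw_abort(sprintf("cohort size %d is not divisible into three tertiles", n),
               "jw_argument_error")
    }
    ord0 <- order(-tab$rel_strength, tab$subject_id)
    tab <- tab[ord0[seq_len(n - n %% 3L)], ]
    n <- nrow(tab)
  }
  ord <- order(-tab$rel_strength, tab$subject_id)
  tab <- tab[ord, ]
  k <- n %/% 3L
  tab$strength_group <- rep(c("HS", "MS", "LS"), each = k)
  tab$sex_group <- tab$sex
  tab <- tab[order(tab$subject_id), c("subject_id", "sex", "rel_strength",
                                      "sex_group", "strength_group")]
  rownames(tab) <- NULL
  structure(tab, class = c("jw_groups", "data.frame"))
}

#' Ensemble-average work-loop curve
#'
#' Resamples each member loop to 100 points at equal normalized path length
#' (path measured in the range-normalized drive-excursion plane, so the
#' parameterization is scale-free) and averages point-wise. The member curves
#' are closed force-displacement loops rather than time series, hence the
#' fixed 100-point representation.
#'
#' @param loops list of `jw_workloop` objects (>= 1).
#' @param group label carried into the result.
#' @param n_points points per resampled curve (default 100).
#' @return A `jw_ensemble`: `excursion`, `drive` (means), `excursion_sd`,
#'   `drive_sd`, `n`, `group`.
#' @export
ensemble_average <- function(loops, group = "", n_points = 100L) {
  if (!length(loops)) jw_abort("ensemble of an empty group", "jw_argument_error")
  resamp <- lapply(loops, function(lp) {
    x <- lp$excursion; y <- lp$drive
    if (length(x) < 2L) jw_abort("degenerate member loop", "jw_argument_error")
    sx <- diff(range(x)); sy <- diff(range(y))
    if (sx == 0) sx <- 1
    if (sy == 0) sy <- 1
    s <- c(0, cumsum(sqrt((diff(x) / sx)^2 + (diff(y) / sy)^2)))
    if (s[length(s)] == 0) {
      return(cbind(x = rep(x[1L], n_points), y = rep(y[1L], n_points)))
    }
    # collapse zero-length steps so approx() gets strictly increasing knots
    keep <- c(TRUE, diff(s) > 0)
    sg <- seq(0, s[length(s)], length.out = n_points)
    cbind(x = stats::approx(s[keep], x[keep], xout = sg)$y,
          y = stats::approx(s[keep], y[keep], xout = sg)$y)
  })
  X <- vapply(resamp, function(m) m[, "x"], numeric(n_points))
  Y <- vapply(resamp, function(m) m[, "y"], numeric(n_points))
  X <- matrix(X, nrow = n_points); Y <- matrix(Y, nrow = n_points)
  structure(
    list(excursion = rowMeans(X), drive = rowMeans(Y),
         excursion_sd = apply(X, 1L, stats::sd), drive_sd = apply(Y, 1L, stats::sd),
         n = length(loops), group = group),
    class = "jw_ensemble"
  )
}

#' Signed area of an ensemble curve
#' @param ens a `jw_ensemble`.
#' @return area in the drive-excursion units (J/kg for COM loops).
#' @export
ensemble_area <- function(ens) {
  workloop_area(structure(list(excursion = ens$excursion, drive = ens$drive),
                          class = "jw_workloop"))
}

#' Two-way ANOVA (general linear model)
#'
#' Fixed-effects two-way analysis of variance with interaction on a
#' per-subject, per-condition outcome (e.g. net COM work), with marginal
#' (SPSS-style type-III) F tests computed from sum-to-zero contrasts via
#' model comparison.
#'
#' @param data data.frame with the outcome and the two factors.
#' @param outcome name of the outcome column.
#' @param factor_a,factor_b names of the factor columns (e.g. sex or strength
#'   group, and jump type).
#' @return A `jw_anova`: data.frame of terms with `df`, `ss`, `F`, `p`
#'   (p is `NA`-flagged when the outcome is degenerate), plus the model frame.
#' @export
two_way_anova <- function(data, outcome, factor_a, factor_b) {
  for (cl in c(outcome, factor_a, factor_b)) {
    if (!cl %in% names(data)) jw_abort(sprintf("missing column '%s'", cl), "jw_argument_error")
  }
  df <- data.frame(
    y = data[[outcome]],
    A = factor(data[[factor_a]]),
    B = factor(data[[factor_b]])
  )
  df <- df[stats::complete.cases(df), ]
  if (nlevels(droplevels(df$A)) < 2L || nlevels(droplevels(df$B)) < 2L) {
    jw_abort("both factors need at least two levels", "jw_argument_error")
  }
  cells <- table(df$A, df$B)
  if (any(cells == 0L)) {
    bad <- which(cells == 0L, arr.ind = TRUE)[1L, ]
    jw_abort(sprintf("empty cell: %s x %s", rownames(cells)[bad[1L]],
                     colnames(cells)[bad[2L]]), "jw_analysis_error")
  }
  # marginal (type-III) tests with sum-to-zero contrasts: drop each term's
  # columns from the full design and compare residual sums of squares.
  # (Formula arithmetic like `y ~ A*B - A` cannot be used here: R's
  # marginality rules re-absorb the dropped main effect into the interaction.)
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  X_full <- stats::model.matrix(~ A * B, data = df)
  y <- df$y
  rss_of <- function(X) {
    fit <- stats::lm.fit(X, y)
    sum(fit$residuals^2)
  }
  rss_full <- rss_of(X_full)
  df_res <- nrow(X_full) - ncol(X_full)
  patterns <- c("^A[0-9]+$", "^B[0-9]+$", "^A[0-9]+:B[0-9]+$")
  out <- data.frame(term = c(factor_a, factor_b,
                             paste0(factor_a, ":", factor_b)),
                    df = NA_real_, ss = NA_real_, F = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(patterns)) {
    keep <- !grepl(patterns[i], colnames(X_full))
    ss <- rss_of(X_full[, keep, drop = FALSE]) - rss_full
    dfe <- sum(!keep)
    out$df[i] <- dfe
    out$ss[i] <- ss
    if (rss_full > 1e-12 * max(1, sum(y^2)) && dfe > 0 && df_res > 0) {
      out$F[i] <- (ss / dfe) / (rss_full / df_res)
      out$p[i] <- stats::pf(out$F[i], dfe, df_res, lower.tail = FALSE)
    }
  }
  structure(list(table = out, df_residual = df_res, rss = rss_full,
                 data = df, factor_a = factor_a, factor_b = factor_b,
                 alpha = 0.05),
            class = "jw_anova")
}

#' @export
print.jw_anova <- function(x, ...) {
  cat(sprintf("<jw_anova> %s x %s, residual df %d\n", x$factor_a, x$factor_b,
              x$df_residual))
  print(transform(x$table, F = round(F, 3), p = signif(p, 4)))
  invisible(x)
}

#' Bonferroni post-hoc pairwise comparisons
#'
#' Pairwise two-sample t tests between levels of factor A (pooling over
#' factor B), with p values multiplied by the number of pairs and capped at
#' 1. Applied, per the analysis protocol, when the ANOVA main effect is
#' significant at alpha = 0.05 (`gate = TRUE` skips the gate).
#'
#' @param result a [two_way_anova()] object.
#' @param pairs optional list of `c(level1, level2)`; default all pairs.
#' @param gate require a significant main effect of factor A first.
#' @return data.frame: pair, mean difference, t, raw p, adjusted p.
#' @export
bonferroni_posthoc <- function(result, pairs = NULL, gate = TRUE) {
  df <- result$data
  lev <- levels(droplevels(df$A))
  if (is.null(pairs)) {
    pairs <- utils::combn(lev, 2L, simplify = FALSE)
  }
  for (p in pairs) {
    if (!all(p %in% lev)) {
      jw_abort(sprintf("unknown pair: %s-%s", p[1L], p[2L]), "jw_argument_error")
    }
  }
  p_main <- result$table$p[1L]
  if (gate && (is.na(p_main) || p_main > result$alpha)) {
    return(data.frame(pair = character(), diff = numeric(), t = numeric(),
                      p_raw = numeric(), p_adj = numeric(),
                      stringsAsFactors = FALSE))
  }
  m <- length(pairs)
  rows <- lapply(pairs, function(p) {
    y1 <- df$y[df$A == p[1L]]
    y2 <- df$y[df$A == p[2L]]
    tt <- stats::t.test(y1, y2)
    data.frame(pair = paste(p, collapse = "-"),
               diff = mean(y1) - mean(y2),
               t = unname(tt$statistic),
               p_raw = tt$p.value,
               p_adj = min(1, tt$p.value * m),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Group summary tables of work measures
#'
#' Mean +/- SD of negative work, positive work and the negative:positive
#' ratio for the COM and each joint, per group and jump type. Group
#' statistics are means over per-subject values (including the ratios, i.e.
#' mean-of-ratios); the ratio of the group-mean components is also emitted
#' for reference.
#'
#' @param work data.frame of per-subject results as produced by
#'   [run_pipeline()] / [analyze_trial()] rows: columns `subject_id`, `group`,
#'   `jump_type`, `measure` (com/hip/knee/ankle), `W_neg`, `W_pos`, `ratio`.
#' @return data.frame with one row per group x jump type x measure:
#'   n, means, SDs (0-with-flag for singleton groups), mean-of-ratios and
#'   ratio-of-means.
#' @export
build_group_tables <- function(work) {
  need <- c("subject_id", "group", "jump_type", "measure", "W_neg", "W_pos", "ratio")
  miss <- setdiff(need, names(work))
  if (length(miss)) jw_abort(paste("missing columns:", paste(miss, collapse = ", ")),
                             "jw_argument_error")
  sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)
  work <- work[!is.na(work$group), , drop = FALSE]
  if (!nrow(work)) {
    return(data.frame(group = character(), jump_type = character(),
                      measure = character(), n = integer(),
                      W_neg_mean = numeric(), W_neg_sd = numeric(),
                      W_pos_mean = numeric(), W_pos_sd = numeric(),
                      ratio_mean = numeric(), ratio_sd = numeric(),
                      ratio_of_means = numeric(), sd_flagged = logical(),
                      stringsAsFactors = FALSE))
  }
  split_by <- interaction(work$group, work$jump_type, work$measure, drop = TRUE)
  rows <- lapply(split(work, split_by), function(d) {
    data.frame(
      group = d$group[1L], jump_type = d$jump_type[1L], measure = d$measure[1L],
      n = nrow(d),
      W_neg_mean = mean(d$W_neg), W_neg_sd = sd0(d$W_neg),
      W_pos_mean = mean(d$W_pos), W_pos_sd = sd0(d$W_pos),
      ratio_mean = mean(d$ratio, na.rm = TRUE), ratio_sd = sd0(d$ratio[!is.na(d$ratio)]),
      ratio_of_means = neg_pos_ratio(mean(d$W_neg), max(mean(d$W_pos), 0)),
      sd_flagged = nrow(d) < 2L,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$jump_type, out$measure, out$group), ]
}

#' Monte-Carlo null calibration of the two-way ANOVA
#'
#' Simulates the complete null (i.i.d. normal outcome, no effects) at a given
#' design and reports the rejection rate of each term at `alpha`. The design
#' matrices are fixed across replicates, so the replicates reduce to
#' projections; one draw is cross-checked against [two_way_anova()] in the
#' test suite.
#'
#' @param n_a per-level counts for factor A (e.g. `c(9, 12)` subjects).
#' @param k_b number of factor-B levels (e.g. 6 jump types).
#' @param n_reps Monte-Carlo replicates.
#' @param alpha significance level.
#' @param seed RNG seed.
#' @return list: rejection rate per term, `n_reps`, `alpha`.
#' @export
anova_null_calibration <- function(n_a = c(9, 12), k_b = 6, n_reps = 10000,
                                   alpha = 0.05, seed = 1L) {
  A <- factor(rep(rep(seq_along(n_a), n_a), k_b))
  B <- factor(rep(seq_len(k_b), each = sum(n_a)))
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  X_full <- stats::model.matrix(~ A * B)
  drop_cols <- function(pattern) {
    X_full[, !grepl(pattern, colnames(X_full)), drop = FALSE]
  }
  designs <- list(full = X_full,
                  A = drop_cols("^A[0-9]+$"),
                  B = drop_cols("^B[0-9]+$"),
                  AB = drop_cols("^A[0-9]+:B[0-9]+$"))
  Qs <- lapply(designs, function(X) qr.Q(qr(X)))
  n <- nrow(X_full)
  df_res <- n - ncol(X_full)
  rss <- function(Q, y) sum(y^2) - sum(crossprod(Q, y)^2)
  terms <- c("A", "B", "AB")
  dfs <- vapply(designs[terms], function(X) ncol(X_full) - ncol(X), 0)
  rej <- stats::setNames(numeric(3), terms)
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      y <- stats::rnorm(n)
      r_full <- rss(Qs$full, y)
      for (tm in terms) {
        ss <- rss(Qs[[tm]], y) - r_full
        Fv <- (ss / dfs[[tm]]) / (r_full / df_res)
        p <- stats::pf(Fv, dfs[[tm]], df_res, lower.tail = FALSE)
        if (p <= alpha) rej[[tm]] <- rej[[tm]] + 1
      }
    }
  })
  list(rejection_rate = rej / n_reps, n_reps = n_reps, alpha = alpha,
       df = dfs, df_residual = df_res)
}
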
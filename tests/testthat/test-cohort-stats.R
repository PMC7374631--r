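test_that("strength tertiles split 21 subjects 7/7/7, deterministically", {
  coh <- generate_cohort(9, 12, seed = 3)
  g <- assign_strength_groups(coh)
  expect_identical(as.integer(table(g$strength_group)[c("HS", "MS", "LS")]),
                   c(7L, 7L, 7L))
  # permutation invariance: shuffling subject order never changes membership
  shuf <- coh
  set.seed(1)
  shuf$subjects <- sample(shuf$subjects)
  g2 <- assign_strength_groups(shuf)
  expect_identical(g2[order(g2$subject_id), ], g[order(g$subject_id), ])
  # the HS minimum rel-strength is >= the MS maximum, etc.
  byg <- split(g$rel_strength, g$strength_group)
  expect_gte(min(byg$HS), max(byg$MS))
  expect_gte(min(byg$MS), max(byg$LS))

  expect_error(assign_strength_groups(generate_cohort(8, 12, seed = 1)),
               class = "jw_argument_error")

  # boundary ties break by subject id
  tie <- coh
  for (i in seq_along(tie$subjects)) tie$subjects[[i]]$rel_strength <- 1
  gt <- assign_strength_groups(tie)
  expect_identical(gt$strength_group[order(gt$subject_id)],
                   rep(c("HS", "MS", "LS"), each = 7))
})

test_that("ensemble averaging: identity, zero dispersion, and area consistency", {
  th <- seq(0, 2 * pi, length.out = 250)
  mkloop <- function(scale) {
    structure(list(excursion = scale * (1 - cos(th)) / 2,
                   drive = scale * (10 + 3 * sin(th))),
              class = "jw_workloop")
  }
  single <- ensemble_average(list(mkloop(1)), "g")
  expect_length(single$excursion, 100)
  expect_equal(range(single$excursion), range(mkloop(1)$excursion), tolerance = 1e-2)

  twins <- ensemble_average(list(mkloop(1), mkloop(1)), "g")
  expect_equal(max(twins$drive_sd), 0)
  expect_equal(max(twins$excursion_sd), 0)

  # congruent loops: ensemble area within 3% of the mean member area
  loops <- list(mkloop(0.9), mkloop(1), mkloop(1.1))
  areas <- vapply(loops, workloop_area, 0)
  expect_equal(ensemble_area(ensemble_average(loops, "g")), mean(areas),
               tolerance = 0.03)

  expect_error(ensemble_average(list()), class = "jw_argument_error")
})

test_that("two-way ANOVA matches aov on a balanced design and flags degeneracy", {
  set.seed(9)
  d <- data.frame(y = rnorm(120),
                  A = rep(c("M", "W"), each = 60),
                  B = rep(rep(JUMP_TYPES, each = 10), 2))
  ours <- two_way_anova(d, "y", "A", "B")
  ref <- summary(stats::aov(y ~ A * B, data = d))[[1]]
  expect_equal(ours$table$F, ref$`F value`[1:3], tolerance = 1e-10)
  expect_equal(ours$table$p, ref$`Pr(>F)`[1:3], tolerance = 1e-10)

  # constant outcome: zero effect SS, p flagged undefined
  dc <- d
  dc$y <- 1
  res <- two_way_anova(dc, "y", "A", "B")
  expect_equal(res$table$ss, rep(0, 3), tolerance = 1e-20)
  expect_true(all(is.na(res$table$p)))

  # empty cell is named
  de <- d[!(d$A == "W" & d$B == "DJ75"), ]
  err <- tryCatch(two_way_anova(de, "y", "A", "B"), error = function(e) e)
  expect_s3_class(err, "jw_analysis_error")
  expect_match(conditionMessage(err), "W x DJ75")
})

test_that("fast null-calibration path agrees with two_way_anova on one draw", {
  # same design, same draw: F statistics must coincide between the generic
  # model-comparison route and the precomputed-projection route
  n_a <- c(4, 5); k_b <- 3
  A <- factor(rep(rep(c("a", "b"), n_a), k_b))
  B <- factor(rep(seq_len(k_b), each = sum(n_a)))
  set.seed(11)
  y <- rnorm(length(A))
  generic <- two_way_anova(data.frame(y = y, A = A, B = B), "y", "A", "B")

  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  X <- stats::model.matrix(~ A * B)
  rss <- function(Xm) sum(stats::lm.fit(Xm, y)$residuals^2)
  r_full <- rss(X)
  for (i in seq_along(c("^A[0-9]+$", "^B[0-9]+$", "^A[0-9]+:B[0-9]+$"))) {
    pat <- c("^A[0-9]+$", "^B[0-9]+$", "^A[0-9]+:B[0-9]+$")[i]
    keep <- !grepl(pat, colnames(X))
    Fv <- ((rss(X[, keep, drop = FALSE]) - r_full) / sum(!keep)) /
      (r_full / (nrow(X) - ncol(X)))
    expect_equal(generic$table$F[i], Fv, tolerance = 1e-10)
  }
})

test_that("Bonferroni post-hoc combinatorics, capping and gating", {
  set.seed(4)
  d <- data.frame(y = c(rnorm(42), rnorm(42) + 3, rnorm(42)),
                  A = rep(c("HS", "MS", "LS"), each = 42),
                  B = rep(rep(JUMP_TYPES, each = 7), 3))
  res <- two_way_anova(d, "y", "A", "B")
  ph <- bonferroni_posthoc(res)
  expect_identical(nrow(ph), 3L)              # 3 groups -> 3 pairs
  expect_true(all(ph$p_adj >= ph$p_raw))
  expect_true(all(ph$p_adj <= 1))
  expect_equal(ph$p_adj, pmin(1, ph$p_raw * 3))

  expect_error(bonferroni_posthoc(res, pairs = list(c("HS", "XX"))),
               class = "jw_argument_error")

  # no significant main effect -> empty table under the gate
  dn <- d
  set.seed(5)
  dn$y <- rnorm(nrow(dn))
  resn <- two_way_anova(dn, "y", "A", "B")
  if (resn$table$p[1] > 0.05) expect_identical(nrow(bonferroni_posthoc(resn)), 0L)
})

test_that("group tables have the documented shape and both ratio variants", {
  set.seed(2)
  work <- expand.grid(subject_id = sprintf("S%02d", 1:6),
                      jump_type = c("CMJ", "DJ30"),
                      measure = c("com", "hip", "knee", "ankle"),
                      stringsAsFactors = FALSE)
  work$group <- ifelse(work$subject_id <= "S03", "M", "W")
  work$W_neg <- -abs(rnorm(nrow(work)))
  work$W_pos <- abs(rnorm(nrow(work))) + 0.5
  work$ratio <- neg_pos_ratio(work$W_neg, work$W_pos)
  tab <- build_group_tables(work)
  expect_identical(nrow(tab), 2L * 2L * 4L)   # groups x jumps x measures
  # mean-of-ratios differs from ratio-of-means on asymmetric groups
  expect_true(any(abs(tab$ratio_mean - tab$ratio_of_means) > 1e-6))

  solo <- work[work$subject_id == "S01", ]
  solo$group <- "solo"
  tso <- build_group_tables(solo)
  expect_true(all(tso$sd_flagged))
  expect_true(all(tso$W_neg_sd == 0))
})
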
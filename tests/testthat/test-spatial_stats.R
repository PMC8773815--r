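test_that("average gaze table equals a brute-force group-by mean", {
  set.seed(21)
  df <- data.frame(
    participant = sample(c("P1", "P2", "P3", "P4"), 500, replace = TRUE),
    stimulation = sample(c("FEF", "PPC", "SHAM"), 500, replace = TRUE),
    timepoint = sample(c("T0", "T1"), 500, replace = TRUE),
    picture = sample(letters[1:6], 500, replace = TRUE),
    start_ms = runif(500, 0, 6999), duration_ms = 100,
    x_px = runif(500, 0, 1680), y_px = runif(500, 0, 1050))
  tab <- fixation_table(df)
  cells <- average_gaze_table(tab)
  g <- attr(tab, "geometry")
  for (r in sample(nrow(cells), 6)) {
    row <- cells[r, ]
    vals <- c()
    for (i in seq_len(nrow(df))) {
      if (df$participant[i] == row$participant &&
          df$stimulation[i] == row$stimulation &&
          df$timepoint[i] == row$timepoint) {
        vals <- c(vals, df$x_px[i] - g$width_px / 2)
      }
    }
    expect_equal(row$mean_x, mean(vals))
    expect_equal(row$n_fixations, length(vals))
  }
  # two fixations at -10 and +30 average to +10
  small <- fixation_table(data.frame(
    participant = "P1", stimulation = "FEF", timepoint = "T0", picture = "a",
    start_ms = c(1, 2), duration_ms = 100,
    x_px = uncenter_x(c(-10, 30), g), y_px = 1))
  expect_equal(average_gaze_table(small)$mean_x, 10)
})

test_that("uniform fixations give a centred mean and empty cells are flagged", {
  set.seed(22)
  n <- 4000
  df <- data.frame(participant = "P1", stimulation = "FEF", timepoint = "T0",
                   picture = "a", start_ms = seq_len(n), duration_ms = 100,
                   x_px = runif(n, 0, 1680), y_px = 1)
  cells <- average_gaze_table(fixation_table(df))
  se <- 1680 / sqrt(12) / sqrt(n)
  expect_lt(abs(cells$mean_x), 3 * se)

  df2 <- df[1:10, ]
  df2$participant <- c(rep("P1", 5), rep("P2", 5))
  df2$timepoint <- c(rep("T0", 5), rep("T1", 5))
  cells2 <- average_gaze_table(fixation_table(df2))
  miss <- attr(cells2, "missing_cells")
  expect_equal(nrow(miss), 2)  # P1xT1 and P2xT0 absent
})

test_that("noiseless balanced data is recovered exactly by the pre-post model", {
  cellmeans <- matrix(c(-20, 5, 10, -3, 0, 7), nrow = 3,
                      dimnames = list(c("FEF", "PPC", "SHAM"), c("T0", "T1")))
  grid <- expand.grid(participant = sprintf("P%d", 1:6),
                      stimulation = rownames(cellmeans),
                      timepoint = colnames(cellmeans),
                      stringsAsFactors = FALSE)
  grid$mean_x <- cellmeans[cbind(grid$stimulation, grid$timepoint)]
  grid$n_fixations <- 260
  fit <- fit_prepost_model(grid)
  emm <- as.data.frame(emmeans::emmeans(fit$fit, ~ stimulation * timepoint,
                                        lmer.df = "asymptotic"))
  for (i in seq_len(nrow(emm))) {
    expect_equal(emm$emmean[i],
                 cellmeans[as.character(emm$stimulation[i]),
                           as.character(emm$timepoint[i])],
                 tolerance = 1e-6)
  }
  expect_true(any(grepl("n_fixations constant", fit$notes)))
})

test_that("a known interaction shift is recovered without bias", {
  set.seed(23)
  reps <- 30
  est <- numeric(reps)
  for (r in seq_len(reps)) {
    cells <- make_cells(22, shift = list(stimulation = "PPC",
                                         timepoint = "T1", px = -20))
    fit <- fit_prepost_model(cells, include_n_fixations = FALSE)
    ph <- fit$posthoc
    d_ppc <- ph$estimate[ph$stimulation == "PPC" & ph$contrast == "T1 - T0"]
    d_sham <- ph$estimate[ph$stimulation == "SHAM" & ph$contrast == "T1 - T0"]
    est[r] <- d_ppc - d_sham
  }
  expect_lt(abs(mean(est) + 20), 3 * sd(est) / sqrt(reps))
})

test_that("the interaction test holds its nominal size on null data", {
  set.seed(24)
  reps <- 200
  rej <- 0
  for (r in seq_len(reps)) {
    cells <- make_cells(10, subject_sd = 15, noise_sd = 10)
    fit <- fit_prepost_model(cells, include_n_fixations = FALSE)
    p <- fit$anova$p[fit$anova$term == "stimulation:timepoint"]
    rej <- rej + (p < 0.05)
  }
  band <- qnorm(0.995) * sqrt(0.05 * 0.95 / reps)
  expect_gt(rej / reps, 0.05 - band)
  expect_lt(rej / reps, 0.05 + band)
})

test_that("baseline model: identity data gives slope 1 and no stimulation terms", {
  set.seed(30)
  grid <- expand.grid(participant = sprintf("P%d", 1:8),
                      stimulation = c("FEF", "PPC", "SHAM"),
                      timepoint = c("T0", "T1"), stringsAsFactors = FALSE)
  base_val <- rnorm(24, sd = 25)
  key <- paste(grid$participant, grid$stimulation)
  grid$mean_x <- base_val[match(key, unique(key))]  # T1 == T0 exactly
  grid$n_fixations <- 260
  fit <- fit_baseline_model(grid)
  slope <- fit$fixed$estimate[fit$fixed$term == "baseline_x"]
  expect_equal(slope, 1, tolerance = 1e-6)
  others <- fit$fixed$estimate[!fit$fixed$term %in% c("baseline_x")]
  expect_true(all(abs(others) < 1e-6))
})

test_that("baseline slope is recovered and missing baselines are reported", {
  set.seed(25)
  n <- 40
  grid <- expand.grid(participant = sprintf("P%02d", 1:n),
                      stimulation = c("FEF", "PPC", "SHAM"),
                      timepoint = c("T0", "T1"), stringsAsFactors = FALSE)
  t0 <- grid$timepoint == "T0"
  base_val <- rnorm(sum(t0), sd = 30)
  grid$mean_x[t0] <- base_val
  key <- paste(grid$participant, grid$stimulation)
  grid$mean_x[!t0] <- 0.5 * base_val[match(key[!t0], key[t0])] +
    rnorm(sum(!t0), sd = 8)
  grid$n_fixations <- 260
  fit <- fit_baseline_model(grid)
  slope <- fit$fixed$estimate[fit$fixed$term == "baseline_x"]
  se <- fit$fixed$se[fit$fixed$term == "baseline_x"]
  expect_lt(abs(slope - 0.5), 3 * se)

  broken <- grid[!(grid$participant == "P01" & grid$timepoint == "T0"), ]
  expect_error(fit_baseline_model(broken), "P01")
})

test_that("a singular by-stimulation structure triggers the recorded reduction", {
  set.seed(26)
  cells <- make_cells(12, subject_sd = 20, noise_sd = 10)
  fit <- fit_baseline_model(cells, random = "by_stimulation")
  expect_true(fit$reduced)
  expect_true(fit$singular)
  expect_true(any(grepl("refitted with participant-only", fit$notes)))
  expect_false(grepl("participant:stimulation", deparse(fit$formula)))
})

test_that("Bonferroni adjustment caps at one and is identity for m = 1", {
  expect_equal(bonferroni_adjust(0.01, 3), 0.03)
  expect_equal(bonferroni_adjust(0.5, 3), 1)
  expect_equal(bonferroni_adjust(0.2, 1), 0.2)
  expect_equal(bonferroni_adjust(c(0.01, 0.5)), c(0.02, 1))
})

test_that("mixed fixed effects match OLS on balanced data (zero RE variance)", {
  set.seed(27)
  cells <- make_cells(10, subject_sd = 0, noise_sd = 5)
  fit <- fit_prepost_model(cells, include_n_fixations = FALSE,
                           random = "participant")
  df <- gazeclust:::as_model_frame(cells)
  ols <- lm(mean_x ~ stimulation * timepoint, data = df,
            contrasts = gazeclust:::sum_contrasts(df))
  if (inherits(fit$fit, "merMod")) {
    expect_equal(unname(lme4::fixef(fit$fit)), unname(coef(ols)),
                 tolerance = 1e-8)
  } else {
    expect_equal(fit$fixed$estimate, unname(coef(ols)), tolerance = 1e-8)
  }
})

test_that("Satterthwaite df reduces to the classical paired df", {
  set.seed(28)
  n <- 12
  df <- data.frame(participant = rep(sprintf("P%02d", 1:n), 2),
                   timepoint = factor(rep(c("T0", "T1"), each = n)),
                   mean_x = rep(rnorm(n, sd = 25), 2) +
                     rnorm(2 * n, sd = 8))
  fit <- lmerTest::lmer(mean_x ~ timepoint + (1 | participant), data = df)
  an <- as.data.frame(anova(fit, type = 3, ddf = "Satterthwaite"))
  expect_equal(an$DenDF, n - 1, tolerance = 0.05)
})

test_that("adding a constant shifts only the intercept", {
  set.seed(29)
  cells <- make_cells(10)
  f1 <- fit_prepost_model(cells, include_n_fixations = FALSE)
  cells2 <- cells
  cells2$mean_x <- cells2$mean_x + 57
  f2 <- fit_prepost_model(cells2, include_n_fixations = FALSE)
  i1 <- which(f1$fixed$term == "(Intercept)")
  expect_equal(f2$fixed$estimate[i1], f1$fixed$estimate[i1] + 57,
               tolerance = 1e-6)
  expect_equal(f2$fixed$estimate[-i1], f1$fixed$estimate[-i1],
               tolerance = 1e-6)
  expect_equal(f2$anova$F[f2$anova$term == "stimulation:timepoint"],
               f1$anova$F[f1$anova$term == "stimulation:timepoint"],
               tolerance = 1e-4)
})
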
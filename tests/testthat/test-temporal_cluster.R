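test_that("the bin grid and the floor binning rule behave as specified", {
  grid <- bin_grid()
  expect_equal(grid$n_bins, 70)
  expect_error(bin_grid(bin_ms = 130, total_ms = 7000), "multiple")

  g <- screen_geometry()
  df <- data.frame(participant = "P1", stimulation = "FEF", timepoint = "T0",
                   picture = "a",
                   start_ms = c(0, 99.9, 100, 5730, 6999.9, 7000, 7500),
                   duration_ms = 100, x_px = 840, y_px = 1)
  series <- bin_fixations(fixation_table(df), grid)
  expect_equal(series$bin, c(0, 1, 57, 69))
  expect_equal(series$n_fixations, c(2, 1, 1, 1))
  expect_equal(attr(series, "dropped"), 2)
  # a start at 5730 ms falls in the bin covering 5700-5800 ms
  expect_true(57 %in% series$bin)
  # per-bin counts partition the retained fixations
  expect_equal(sum(series$n_fixations), 5)
})

test_that("random fixation sets are partitioned exactly across bins", {
  set.seed(31)
  n <- 2000
  df <- data.frame(
    participant = sample(c("P1", "P2"), n, TRUE),
    stimulation = sample(c("FEF", "SHAM"), n, TRUE),
    timepoint = sample(c("T0", "T1"), n, TRUE),
    picture = sample(letters[1:5], n, TRUE),
    start_ms = runif(n, 0, 7100), duration_ms = 100,
    x_px = runif(n, 0, 1680), y_px = 1)
  series <- bin_fixations(fixation_table(df), bin_grid())
  expect_equal(sum(series$n_fixations) + attr(series, "dropped"), n)
  expect_true(all(series$bin >= 0 & series$bin <= 69))
})

test_that("bin-wise F matches a hand-checked repeated-measures ANOVA", {
  set.seed(32)
  participants <- c("P1", "P2", "P3")
  vals <- array(rnorm(3 * 6 * 2, sd = 20), c(3, 6, 2))
  tab <- make_cell_fixations(participants, c("FEF", "PPC", "SHAM"),
                             c("T0", "T1"), bins = c(10, 42),
                             value_fun = function(pi, ci, b) {
                               vals[pi, ci, ifelse(b == 10, 1, 2)]
                             })
  series <- bin_fixations(tab, bin_grid())
  bt <- binwise_tests(series, term = "interaction")
  expect_equal(sum(bt$testable), 2)

  for (kk in 1:2) {
    b <- c(10, 42)[kk]
    long <- expand.grid(participant = factor(participants),
                        timepoint = factor(c("T0", "T1")),
                        stimulation = factor(c("FEF", "PPC", "SHAM")))
    # cell index in make_cell_fixations runs timepoint-fastest per stimulation
    ci <- (as.integer(long$stimulation) - 1) * 2 + as.integer(long$timepoint)
    long$y <- vals[cbind(as.integer(long$participant), ci, kk)]
    oracle <- summary(stats::aov(
      y ~ stimulation * timepoint + Error(participant / (stimulation * timepoint)),
      data = long))
    otab <- oracle[["Error: participant:stimulation:timepoint"]][[1]]
    expect_equal(bt$F[bt$bin == b], otab$`F value`[1], tolerance = 1e-10)
    expect_equal(bt$p[bt$bin == b], otab$`Pr(>F)`[1], tolerance = 1e-10)
    expect_equal(bt$df1[bt$bin == b], 2)
    expect_equal(bt$df2[bt$bin == b], 4)
  }

  # main effects agree with their own error strata too
  for (term in c("stimulation", "timepoint")) {
    bt2 <- binwise_tests(series, term = term)
    long <- expand.grid(participant = factor(participants),
                        timepoint = factor(c("T0", "T1")),
                        stimulation = factor(c("FEF", "PPC", "SHAM")))
    ci <- (as.integer(long$stimulation) - 1) * 2 + as.integer(long$timepoint)
    long$y <- vals[cbind(as.integer(long$participant), ci, 1)]
    oracle <- summary(stats::aov(
      y ~ stimulation * timepoint + Error(participant / (stimulation * timepoint)),
      data = long))
    otab <- oracle[[paste0("Error: participant:", term)]][[1]]
    expect_equal(bt2$F[bt2$bin == 10], otab$`F value`[1], tolerance = 1e-10)
  }
})

test_that("the per-bin mixed-model route matches a direct lmer fit", {
  set.seed(33)
  vals <- matrix(rnorm(6 * 6, sd = 15), 6, 6)
  tab <- make_cell_fixations(sprintf("P%d", 1:6), c("FEF", "PPC", "SHAM"),
                             c("T0", "T1"), bins = 5,
                             value_fun = function(pi, ci, b) vals[pi, ci])
  series <- bin_fixations(tab, bin_grid())
  m <- binwise_tests(series, method = "lmm")

  long <- expand.grid(participant = factor(sprintf("P%d", 1:6)),
                      timepoint = factor(c("T0", "T1")),
                      stimulation = factor(c("FEF", "PPC", "SHAM")))
  ci <- (as.integer(long$stimulation) - 1) * 2 + as.integer(long$timepoint)
  long$y <- vals[cbind(as.integer(long$participant), ci)]
  fit <- lmerTest::lmer(y ~ stimulation * timepoint + (1 | participant),
                        data = long,
                        contrasts = list(stimulation = contr.sum(3),
                                         timepoint = contr.sum(2)))
  oracle <- as.data.frame(anova(fit, type = 3, ddf = "Satterthwaite"))
  expect_equal(m$F[m$bin == 5],
               oracle["stimulation:timepoint", "F value"], tolerance = 1e-6)
  expect_equal(m$p[m$bin == 5],
               oracle["stimulation:timepoint", "Pr(>F)"], tolerance = 1e-6)
})

test_that("noiseless equal condition means give F = 0", {
  tab <- make_cell_fixations(c("P1", "P2", "P3"), c("FEF", "SHAM"),
                             c("T0", "T1"), bins = 3,
                             value_fun = function(pi, ci, b) pi * 10)
  series <- bin_fixations(tab, bin_grid())
  bt <- binwise_tests(series)
  expect_equal(bt$F[bt$bin == 3], 0)
  expect_equal(bt$p[bt$bin == 3], 1)
})

test_that("cluster formation follows the worked example and breaks on gaps", {
  p <- c(0.20, 0.03, 0.04, 0.60, 0.01)
  f <- c(1.2, 5.0, 4.5, 0.8, 7.1)
  cl <- form_clusters(p, f, alpha = 0.05)
  expect_equal(nrow(cl), 2)
  expect_equal(cl$start_bin, c(1, 4))
  expect_equal(cl$end_bin, c(2, 4))
  expect_equal(cl$mass, c(9.5, 7.1))
  expect_equal(cl$duration_ms, c(200, 100))

  expect_equal(nrow(form_clusters(rep(0.5, 10), rep(1, 10))), 0)
  all_sig <- form_clusters(rep(0.01, 10), rep(2, 10))
  expect_equal(nrow(all_sig), 1)
  expect_equal(all_sig$mass, 20)

  # untestable bins break adjacency
  p2 <- c(0.01, NA, 0.01)
  cl2 <- form_clusters(p2, c(3, NA, 4))
  expect_equal(nrow(cl2), 2)
  expect_error(form_clusters(p, f[1:3]), "aligned")
})

test_that("form_clusters equals an exhaustive scan on 1000 random vectors", {
  set.seed(34)
  for (i in 1:1000) {
    n <- sample(1:70, 1)
    p <- runif(n)
    p[runif(n) < 0.05] <- NA
    f <- rchisq(n, df = 3)
    mine <- form_clusters(p, f, alpha = 0.3)
    oracle <- brute_cluster_scan(p, f, alpha = 0.3)
    expect_equal(nrow(mine), nrow(oracle))
    if (nrow(mine) > 0) {
      expect_equal(mine$start_bin, oracle$start_bin)
      expect_equal(mine$end_bin, oracle$end_bin)
      expect_equal(mine$mass, oracle$mass)
    }
  }
})

test_that("identity relabeling reproduces the observed statistics exactly", {
  set.seed(35)
  cfg <- simulation_config(n_participants = 5, timepoints = c("T0", "T1"),
                           pictures_per_block = 8, seed = 77)
  series <- bin_fixations(simulate_dataset(cfg))
  layout <- gazeclust:::series_layout(series, 2)
  obs <- gazeclust:::layout_binstats(layout, layout$Y2, "interaction")
  n <- layout$n; ncell <- layout$ncell
  identity_idx <- rep(seq_len(n), times = ncell) +
    n * (rep(seq_len(ncell), each = n) - 1L)
  perm <- gazeclust:::layout_binstats(layout,
                                      layout$Y2[identity_idx, , drop = FALSE],
                                      "interaction")
  expect_identical(obs$F, perm$F)
  expect_identical(
    gazeclust:::max_cluster_mass(obs$p, obs$F, 0.05),
    gazeclust:::max_cluster_mass(perm$p, perm$F, 0.05))
  # and the observed path in binwise_tests is the same path
  bt <- binwise_tests(series)
  expect_identical(bt$F, obs$F)
})

test_that("permutation p-values respect their bounds and determinism", {
  # strong constructed effect: FEF/T1 shifted by -120 px in bins 20-24
  set.seed(36)
  tab <- make_cell_fixations(sprintf("P%d", 1:8), c("FEF", "PPC", "SHAM"),
                             c("T0", "T1"), bins = 18:26,
                             value_fun = function(pi, ci, b) {
                               rnorm(1, sd = 10) +
                                 ifelse(ci == 2 && b >= 20 && b <= 24, -120, 0)
                             })
  series <- bin_fixations(tab, bin_grid())
  pn <- permutation_null(series, B = 99, seed = 5)
  expect_length(pn$max_mass, 99)
  expect_true(all(pn$max_mass >= 0))
  expect_true(all(pn$clusters$p_perm >= 1 / 100 & pn$clusters$p_perm <= 1))
  # the dominant injected cluster beats every permuted maximum
  expect_equal(min(pn$clusters$p_perm), 1 / 100)
  # p_perm is monotone non-increasing in mass
  ord <- order(pn$clusters$mass, decreasing = TRUE)
  expect_true(all(diff(pn$clusters$p_perm[ord]) >= 0))

  pn2 <- permutation_null(series, B = 99, seed = 5)
  expect_identical(pn$max_mass, pn2$max_mass)
  expect_identical(pn$clusters$p_perm, pn2$clusters$p_perm)

  expect_error(permutation_null(series, B = 0), "B")
  expect_error(permutation_null(series, scheme = "bogus"), "scheme")
})

test_that("exchange-symmetric data yields a degenerate null", {
  # every condition cell carries identical data for each participant
  tab <- make_cell_fixations(c("P1", "P2", "P3"), c("FEF", "SHAM"),
                             c("T0", "T1"), bins = c(2, 3, 4),
                             value_fun = function(pi, ci, b) pi * 7 + b)
  series <- bin_fixations(tab, bin_grid())
  pn <- permutation_null(series, B = 30, seed = 1)
  expect_equal(nrow(pn$clusters), 0)
  expect_true(all(pn$max_mass == 0))
})

test_that("the window post-hoc recovers a constructed shift exactly", {
  # -40 px confined to FEF x T1 in the 5700-5900 ms window
  tab <- make_cell_fixations(c("P1", "P2", "P3"), c("FEF", "PPC", "SHAM"),
                             c("T0", "T1"), bins = c(57, 58),
                             value_fun = function(pi, ci, b) {
                               (pi - 2) * 5 + ifelse(ci == 2, -40, 0)
                             })
  res <- window_posthoc(tab, c(5700, 5900))
  ph <- res$posthoc
  d <- ph$estimate[ph$stimulation == "FEF" & ph$contrast == "T1 - T0"]
  expect_equal(d, -40, tolerance = 1e-6)
  d_sham <- ph$estimate[ph$stimulation == "SHAM" & ph$contrast == "T1 - T0"]
  expect_equal(d_sham, 0, tolerance = 1e-6)
  expect_equal(res$window, c(5700, 5900))

  expect_error(window_posthoc(tab, c(5700, 8000)), "within")
  expect_error(window_posthoc(tab, c(5710, 5890)), "aligned")
})
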
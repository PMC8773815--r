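#' Time-bin grid for the exploration window
#'
#' @param bin_ms Bin width in ms (default 100).
#' @param total_ms Exploration window in ms (default 7000); must be an
#'   exact multiple of `bin_ms`, giving 70 bins at the defaults.
#' @return An object of class `bin_grid` with `bin_ms`, `total_ms`,
#'   `n_bins`.
#' @export
bin_grid <- function(bin_ms = 100, total_ms = 7000) {
  if (bin_ms <= 0 || total_ms <= 0) stop("grid sizes must be positive", call. = FALSE)
  if (total_ms %% bin_ms != 0) {
    stop("total_ms must be an exact multiple of bin_ms", call. = FALSE)
  }
  structure(list(bin_ms = bin_ms, total_ms = total_ms,
                 n_bins = total_ms %/% bin_ms),
            class = "bin_grid")
}

#' Bin fixations into the 100-ms time grid
#'
#' Each fixation is assigned to the single bin containing its start time
#' (`floor(start_ms / bin_ms)`, 0-based, half-open bins); its centred
#' horizontal position contributes to the unweighted mean over all
#' contributing fixations (pooled across pictures) for its participant,
#' stimulation, timepoint and bin. Cells with no fixation start are absent:
#' gaps are genuine missing data, not zeros. Fixations starting at or after
#' `total_ms` are dropped and counted in the `dropped` attribute.
#'
#' @param table A [fixation_table()].
#' @param grid A [bin_grid()].
#' @return A data frame of class `bin_series` with columns `participant`,
#'   `stimulation`, `timepoint`, `bin` (0-based), `mean_x` (centred px),
#'   `n_fixations`; attributes `grid`, `geometry`, `dropped`.
#' @export
bin_fixations <- function(table, grid = bin_grid()) {
  stopifnot(inherits(table, "fixation_table"), inherits(grid, "bin_grid"))
  g <- attr(table, "geometry")
  dt <- data.table::as.data.table(as.data.frame(table))
  dropped <- sum(dt$start_ms >= grid$total_ms)
  dt <- dt[start_ms < grid$total_ms]
  dt[, bin := as.integer(floor(start_ms / grid$bin_ms))]
  dt[, x_centered := center_x(x_px, g)]
  series <- dt[, list(mean_x = mean(x_centered), n_fixations = .N),
               by = c("participant", "stimulation", "timepoint", "bin")]
  series <- series[order(participant, stimulation, timepoint, bin)]
  structure(data.table::setDF(series),
            class = c("bin_series", "data.frame"),
            grid = grid, geometry = g, dropped = dropped)
}

# ---- fast repeated-measures ANOVA over many bins --------------------------
#
# Y4: complete array (n subjects) x (d2 levels) x (d3 levels) x (K bins).
# Classical fully-within two-factor decomposition with one observation per
# subject-cell: each effect is tested against its interaction with subjects.
# Returns F, df1, df2 vectors of length K for the requested term.
rm_f_multi <- function(Y4, term = c("interaction", "d2", "d3")) {
  term <- match.arg(term)
  dm <- dim(Y4)
  n <- dm[1]; d2 <- dm[2]; d3 <- dm[3]; K <- dm[4]
  M <- colMeans(Y4)                                   # (d2, d3, K) cell means
  gK <- colMeans(matrix(M, d2 * d3, K))               # grand mean per bin
  mj <- rowMeans(aperm(M, c(1, 3, 2)), dims = 2)      # (d2, K)
  ml <- rowMeans(aperm(M, c(2, 3, 1)), dims = 2)      # (d3, K)

  if (term == "interaction") {
    mj_e <- aperm(array(mj, c(d2, K, d3)), c(1, 3, 2))
    ml_e <- aperm(array(ml, c(d3, K, d2)), c(3, 1, 2))
    g_e <- aperm(array(gK, c(K, d2, d3)), c(2, 3, 1))
    D <- M - mj_e - ml_e + g_e
    ss_term <- n * colSums(matrix(D^2, d2 * d3, K))
    df1 <- (d2 - 1) * (d3 - 1)

    mij <- rowMeans(aperm(Y4, c(1, 2, 4, 3)), dims = 3)   # (n, d2, K)
    mil <- rowMeans(aperm(Y4, c(1, 3, 4, 2)), dims = 3)   # (n, d3, K)
    mi <- rowMeans(aperm(Y4, c(1, 4, 2, 3)), dims = 2)    # (n, K)
    mij_e <- aperm(array(mij, c(n, d2, K, d3)), c(1, 2, 4, 3))
    mil_e <- aperm(array(mil, c(n, d3, K, d2)), c(1, 4, 2, 3))
    M_e <- aperm(array(M, c(d2, d3, K, n)), c(4, 1, 2, 3))
    mi_e <- aperm(array(mi, c(n, K, d2, d3)), c(1, 3, 4, 2))
    mj_e4 <- aperm(array(mj, c(d2, K, n, d3)), c(3, 1, 4, 2))
    ml_e4 <- aperm(array(ml, c(d3, K, n, d2)), c(3, 4, 1, 2))
    g_e4 <- aperm(array(gK, c(K, n, d2, d3)), c(2, 3, 4, 1))
    e <- Y4 - mij_e - mil_e - M_e + mi_e + mj_e4 + ml_e4 - g_e4
    ss_err <- colSums(matrix(e^2, n * d2 * d3, K))
    df2 <- (n - 1) * df1
  } else {
    if (term == "d3") {  # symmetry: swap the factor dimensions
      return(rm_f_multi(aperm(Y4, c(1, 3, 2, 4)), term = "d2"))
    }
    mij <- rowMeans(aperm(Y4, c(1, 2, 4, 3)), dims = 3)   # (n, d2, K)
    mi <- rowMeans(aperm(Y4, c(1, 4, 2, 3)), dims = 2)    # (n, K)
    g_e <- aperm(array(gK, c(K, d2)), c(2, 1))
    ss_term <- n * d3 * colSums((mj - g_e)^2)
    df1 <- d2 - 1
    mi_e <- aperm(array(mi, c(n, K, d2)), c(1, 3, 2))
    mj_e <- aperm(array(mj, c(d2, K, n)), c(3, 1, 2))
    g_e3 <- aperm(array(gK, c(K, n, d2)), c(2, 3, 1))
    r <- mij - mi_e - mj_e + g_e3
    ss_err <- d3 * colSums(matrix(r^2, n * d2, K))
    df2 <- (n - 1) * df1
  }

  eps <- .Machine$double.eps
  f <- ifelse(ss_err > eps * pmax(ss_term, 1),
              (ss_term / df1) / (ss_err / df2),
              ifelse(ss_term <= eps, 0, Inf))
  p <- ifelse(is.finite(f), stats::pf(f, df1, df2, lower.tail = FALSE),
              ifelse(f == 0, 1, 0))
  p[f == 0] <- 1
  list(F = f, p = p, df1 = rep(df1, K), df2 = rep(df2, K))
}

# ---- internal layout shared by binwise tests and the permutation null -----
#
# Lays the bin series out as an (n x n_cells x K) array with NA for absent
# cells; cells are ordered timepoint-fastest within stimulation. Bins are
# testable when at least `min_participants` subjects have all cells present;
# testable bins are grouped by their complete-subject mask so the F
# computation can be vectorised per group. Both the observed statistics and
# every permutation go through exactly this path.
series_layout <- function(series, min_participants = 2) {
  stopifnot(inherits(series, "bin_series"))
  grid <- attr(series, "grid")
  K <- grid$n_bins
  participants <- sort(unique(series$participant))
  stims <- intersect(STIMULATION_LEVELS, unique(series$stimulation))
  tps <- intersect(TIMEPOINT_LEVELS, unique(series$timepoint))
  n <- length(participants); n_tp <- length(tps); n_st <- length(stims)
  ncell <- n_tp * n_st
  if (n_st < 2 || n_tp < 2) {
    stop("binwise tests need at least 2 stimulation and 2 timepoint levels",
         call. = FALSE)
  }
  i <- match(series$participant, participants)
  t <- match(series$timepoint, tps)
  s <- match(series$stimulation, stims)
  cell <- t + (s - 1) * n_tp
  k <- series$bin + 1L
  ok <- k >= 1L & k <= K
  Y <- array(NA_real_, c(n, ncell, K))
  Y[cbind(i[ok], cell[ok], k[ok])] <- series$mean_x[ok]
  complete <- matrix(TRUE, n, K)
  for (c_ in seq_len(ncell)) complete <- complete & !is.na(Y[, c_, ])
  n_complete <- colSums(complete)
  testable <- n_complete >= max(2, min_participants)
  mask_key <- apply(complete, 2, function(col) paste(which(col), collapse = ","))
  groups <- list()
  for (k_ in which(testable)) {
    key <- mask_key[k_]
    if (is.null(groups[[key]])) {
      groups[[key]] <- list(subjects = which(complete[, k_]), bins = k_)
    } else {
      groups[[key]]$bins <- c(groups[[key]]$bins, k_)
    }
  }
  list(Y = Y, Y2 = matrix(Y, n * ncell, K), n = n, ncell = ncell, K = K,
       n_tp = n_tp, n_st = n_st, participants = participants,
       stims = stims, tps = tps, groups = groups, testable = testable,
       n_complete = n_complete, grid = grid)
}

# F/p per bin from the (possibly permuted) flat matrix Y2 (n*ncell x K)
layout_binstats <- function(layout, Y2, term) {
  term4 <- switch(term, interaction = "interaction",
                  timepoint = "d2", stimulation = "d3")
  F <- rep(NA_real_, layout$K); p <- rep(NA_real_, layout$K)
  df1 <- rep(NA_real_, layout$K); df2 <- rep(NA_real_, layout$K)
  for (grp in layout$groups) {
    subj <- grp$subjects
    rows <- rep(subj, times = layout$ncell) +
      rep((seq_len(layout$ncell) - 1L) * layout$n, each = length(subj))
    Y4 <- array(Y2[rows, grp$bins, drop = FALSE],
                c(length(subj), layout$n_tp, layout$n_st, length(grp$bins)))
    res <- rm_f_multi(Y4, term = term4)
    F[grp$bins] <- res$F; p[grp$bins] <- res$p
    df1[grp$bins] <- res$df1; df2[grp$bins] <- res$df2
  }
  list(F = F, p = p, df1 = df1, df2 = df2)
}

#' Bin-wise tests of a design term on the gaze position
#'
#' For every testable 100-ms bin, tests whether the requested term
#' (by default the stimulation-by-timepoint interaction) predicts the mean
#' gaze position, treating participant as the random term. The default
#' method is the classical fully-within repeated-measures ANOVA
#' decomposition (each effect tested against its interaction with
#' participants) on the participants with complete condition cells in that
#' bin; `method = "lmm"` instead fits a per-bin linear mixed model with a
#' participant random intercept and Satterthwaite F-tests. The two agree on
#' balanced complete data; the ANOVA route is orders of magnitude faster,
#' which matters inside the permutation null. Bins where fewer than
#' `min_participants` participants are complete are marked untestable
#' (`NA`).
#'
#' @param series A [bin_fixations()] result.
#' @param term `"interaction"`, `"stimulation"` or `"timepoint"`.
#' @param method `"rm_anova"` (default) or `"lmm"`.
#' @param min_participants Minimum complete participants per testable bin.
#' @return Data frame with one row per bin: `bin` (0-based), `F`, `p`,
#'   `df1`, `df2`, `n_complete`, `testable`.
#' @export
binwise_tests <- function(series, term = c("interaction", "stimulation",
                                           "timepoint"),
                          method = c("rm_anova", "lmm"),
                          min_participants = 2) {
  term <- match.arg(term)
  method <- match.arg(method)
  layout <- series_layout(series, min_participants)
  if (!any(layout$testable)) stop("no testable bins", call. = FALSE)
  if (method == "rm_anova") {
    st <- layout_binstats(layout, layout$Y2, term)
  } else {
    st <- lmm_binstats(layout, term)
  }
  data.frame(bin = seq_len(layout$K) - 1L, F = st$F, p = st$p,
             df1 = st$df1, df2 = st$df2,
             n_complete = layout$n_complete, testable = layout$testable)
}

lmm_binstats <- function(layout, term) {
  F <- rep(NA_real_, layout$K); p <- rep(NA_real_, layout$K)
  df1 <- rep(NA_real_, layout$K); df2 <- rep(NA_real_, layout$K)
  term_name <- switch(term, interaction = "stimulation:timepoint",
                      stimulation = "stimulation", timepoint = "timepoint")
  cells <- expand.grid(timepoint = layout$tps, stimulation = layout$stims,
                       stringsAsFactors = FALSE)
  for (k in which(layout$testable)) {
    subj <- which(apply(!is.na(layout$Y[, , k, drop = FALSE]), 1, all))
    df <- do.call(rbind, lapply(subj, function(i) {
      data.frame(participant = layout$participants[i], cells,
                 mean_x = layout$Y[i, , k])
    }))
    df$participant <- factor(df$participant)
    df$stimulation <- factor(df$stimulation, levels = layout$stims)
    df$timepoint <- factor(df$timepoint, levels = layout$tps)
    fitted <- fit_lmm(mean_x ~ stimulation * timepoint + (1 | participant),
                      df, contrasts = sum_contrasts(df))
    an <- anova_table(fitted$fit)
    row <- an[an$term == term_name, , drop = FALSE]
    if (nrow(row) == 1) {
      F[k] <- row$F; p[k] <- row$p; df1[k] <- row$df1; df2[k] <- row$df2
    }
  }
  list(F = F, p = p, df1 = df1, df2 = df2)
}

#' Form clusters of adjacent significant bins
#'
#' Maximal runs of adjacent bins with `p < alpha` form clusters; the F
#' values of member bins are summed into the cluster mass. A single
#' significant bin is a cluster of one. Untestable bins (`NA` p) break
#' adjacency.
#'
#' @param pvals,Fvals Aligned per-bin p and F vectors (NA = untestable).
#' @param alpha Forming threshold (default 0.05).
#' @param bin_ms Bin width used to report cluster times (default 100).
#' @param first_bin 0-based index of the first element of `pvals`.
#' @return Data frame of class `gaze_clusters`: `start_bin`, `end_bin`
#'   (inclusive, 0-based), `n_bins`, `start_ms`, `end_ms`, `duration_ms`,
#'   `mass`.
#' @export
form_clusters <- function(pvals, Fvals, alpha = 0.05, bin_ms = 100,
                          first_bin = 0L) {
  if (length(pvals) != length(Fvals)) {
    stop("pvals and Fvals must be aligned", call. = FALSE)
  }
  sig <- !is.na(pvals) & pvals < alpha
  out <- data.frame(start_bin = integer(), end_bin = integer(),
                    n_bins = integer(), start_ms = numeric(),
                    end_ms = numeric(), duration_ms = numeric(),
                    mass = numeric())
  if (any(sig)) {
    runs <- rle(sig)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    for (r in which(runs$values)) {
      idx <- starts[r]:ends[r]
      b0 <- first_bin + starts[r] - 1L
      b1 <- first_bin + ends[r] - 1L
      out <- rbind(out, data.frame(
        start_bin = b0, end_bin = b1, n_bins = length(idx),
        start_ms = b0 * bin_ms, end_ms = (b1 + 1) * bin_ms,
        duration_ms = length(idx) * bin_ms,
        mass = sum(Fvals[idx])))
    }
  }
  structure(out, class = c("gaze_clusters", "data.frame"), alpha = alpha)
}

max_cluster_mass <- function(pvals, Fvals, alpha) {
  sig <- !is.na(pvals) & pvals < alpha
  if (!any(sig)) return(0)
  runs <- rle(sig)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  max(vapply(which(runs$values),
             function(r) sum(Fvals[starts[r]:ends[r]]), numeric(1)))
}

#' Permutation null distribution of the maximum cluster mass
#'
#' Builds the family-wise corrected cluster p-values: under the null of no
#' effect of the tested term, each participant's set of condition bin
#' series is exchangeable, so every permutation independently re-randomises
#' the stimulation-by-timepoint cell labels within each participant (whole
#' series move together), re-runs the full bin-wise-test-and-clustering
#' chain at the same forming threshold, and records the maximum cluster
#' mass (0 when no cluster forms). Each observed cluster's
#' `p_perm = (1 + #\{max_mass >= mass\}) / (B + 1)`, so `p_perm` is never
#' exactly zero. A fixed seed makes the result bitwise reproducible.
#'
#' @param series A [bin_fixations()] result.
#' @param observed Optional [form_clusters()] result for this series, term
#'   and `alpha`; recomputed when `NULL`.
#' @param B Number of permutations (default 5000).
#' @param seed Integer seed.
#' @param scheme Permutation scheme; only
#'   `"within_participant_cells"` is defined for this single-group
#'   repeated-measures design.
#' @param term,alpha,min_participants As in [binwise_tests()].
#' @return An object of class `permutation_null`: `clusters` (observed
#'   clusters with `p_perm`), `max_mass` (length-B null sample),
#'   `binstats`, `B`, `seed`, `scheme`, `alpha`, `term`.
#' @export
permutation_null <- function(series, observed = NULL, B = 5000, seed = 1,
                             scheme = "within_participant_cells",
                             term = c("interaction", "stimulation",
                                      "timepoint"),
                             alpha = 0.05, min_participants = 2) {
  term <- match.arg(term)
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  if (!identical(scheme, "within_participant_cells")) {
    stop("permutation scheme '", scheme, "' is not defined for this design",
         call. = FALSE)
  }
  layout <- series_layout(series, min_participants)
  if (!any(layout$testable)) stop("no testable bins", call. = FALSE)
  obs <- layout_binstats(layout, layout$Y2, term)
  grid <- layout$grid
  obs_clusters <- form_clusters(obs$p, obs$F, alpha = alpha,
                                bin_ms = grid$bin_ms)
  if (!is.null(observed)) {
    if (nrow(observed) != nrow(obs_clusters) ||
        (nrow(observed) > 0 &&
         !isTRUE(all.equal(observed$mass, obs_clusters$mass)))) {
      stop("`observed` clusters do not match this series/term/alpha",
           call. = FALSE)
    }
  }
  n <- layout$n; ncell <- layout$ncell
  I <- rep(seq_len(n), times = ncell)
  max_mass <- numeric(B)
  with_preserved_rng({
    set.seed(seed)
    for (b_ in seq_len(B)) {
      Pt <- vapply(seq_len(n), function(i) sample.int(ncell), integer(ncell))
      rowidx <- I + n * (as.vector(t(Pt)) - 1L)
      st <- layout_binstats(layout, layout$Y2[rowidx, , drop = FALSE], term)
      max_mass[b_] <- max_cluster_mass(st$p, st$F, alpha)
    }
  })
  if (nrow(obs_clusters) > 0) {
    obs_clusters$p_perm <- vapply(obs_clusters$mass, function(m) {
      (1 + sum(max_mass >= m)) / (B + 1)
    }, numeric(1))
  } else {
    obs_clusters$p_perm <- numeric(0)
  }
  binstats <- data.frame(bin = seq_len(layout$K) - 1L, F = obs$F, p = obs$p,
                         df1 = obs$df1, df2 = obs$df2,
                         n_complete = layout$n_complete,
                         testable = layout$testable)
  structure(list(clusters = obs_clusters, max_mass = max_mass,
                 binstats = binstats, B = B, seed = seed, scheme = scheme,
                 alpha = alpha, term = term, grid = grid),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("<permutation_null> term = %s, B = %d, seed = %d, scheme = %s, alpha = %g\n",
              x$term, x$B, x$seed, x$scheme, x$alpha))
  if (nrow(x$clusters) == 0) {
    cat("no clusters at the forming threshold\n")
  } else {
    print(as.data.frame(x$clusters), digits = 4)
  }
  invisible(x)
}

#' Post-hoc mixed model on a significant time window
#'
#' Averages the centred gaze position over fixations starting within the
#' window (aligned to bin boundaries) for every participant, stimulation
#' and timepoint, then fits the stimulation-by-timepoint mixed model with
#' by-participant random intercepts, Satterthwaite F-tests and
#' Bonferroni-corrected post-hoc contrasts.
#'
#' @param table A [fixation_table()] (bounds-filtered).
#' @param window Length-2 ms interval `c(from, to)`, half-open, aligned to
#'   the grid's bin boundaries.
#' @param grid A [bin_grid()].
#' @param random Random structure passed to [fit_prepost_model()].
#' @return A `gaze_model_result` with the window recorded in `$window`.
#' @export
window_posthoc <- function(table, window, grid = bin_grid(),
                           random = c("participant", "full")) {
  random <- match.arg(random)
  stopifnot(inherits(table, "fixation_table"), length(window) == 2)
  if (window[1] < 0 || window[2] > grid$total_ms || window[1] >= window[2]) {
    stop("window must lie within [0, total_ms) with from < to", call. = FALSE)
  }
  if (window[1] %% grid$bin_ms != 0 || window[2] %% grid$bin_ms != 0) {
    stop("window must be aligned to bin boundaries", call. = FALSE)
  }
  sel <- table$start_ms >= window[1] & table$start_ms < window[2]
  if (!any(sel)) stop("no fixations start within the window", call. = FALSE)
  sub <- fixation_table(as.data.frame(table)[sel, , drop = FALSE],
                        geometry = attr(table, "geometry"),
                        provenance = sprintf("window %g-%g ms",
                                             window[1], window[2]))
  cells <- average_gaze_table(sub)
  res <- fit_prepost_model(cells, include_n_fixations = FALSE,
                           random = if (random == "participant")
                             "participant" else "full")
  res$window <- window
  res$type <- sprintf("window post-hoc (%g-%g ms)", window[1], window[2])
  res
}
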
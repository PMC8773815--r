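#' Left/right saliency ratio of a picture
#'
#' Ratio of the mean saliency of the left half of the matrix to the mean of
#' the right half. For odd column counts the centre column is excluded so
#' the halves stay disjoint.
#'
#' @param m Non-negative numeric matrix of saliency values aligned to the
#'   picture pixels (rows x cols).
#' @return The dimensionless left/right ratio.
#' @export
lr_saliency_ratio <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2) stop("saliency matrix needs at least 2 columns", call. = FALSE)
  if (any(m < 0)) stop("saliency values must be non-negative", call. = FALSE)
  half <- ncol(m) %/% 2
  left <- m[, seq_len(half), drop = FALSE]
  right <- m[, (ncol(m) - half + 1):ncol(m), drop = FALSE]
  mr <- mean(right)
  if (mr == 0) stop("right-half mean saliency is zero; ratio undefined", call. = FALSE)
  mean(left) / mr
}

#' Read a saliency matrix from CSV
#'
#' @param path CSV file of numeric values, no header.
#' @return Numeric matrix.
#' @export
read_saliency_matrix <- function(path) {
  as.matrix(data.table::fread(path, header = FALSE, data.table = FALSE))
}

# one-way ANOVA of values on group, with a guard for the degenerate case of
# zero between-group variability (aov would return 0/0 there)
oneway_balance_test <- function(values, groups) {
  groups <- factor(groups)
  grand <- mean(values)
  means <- tapply(values, groups, mean)
  ns <- tabulate(groups)
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((values - means[groups])^2)
  df1 <- nlevels(groups) - 1
  df2 <- length(values) - nlevels(groups)
  sst <- ssb + ssw
  if (sst <= 0 || ssb <= 1e-12 * sst) {
    return(list(F = 0, p = 1, df1 = df1, df2 = df2))
  }
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, p = stats::pf(f, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2)
}

#' Assign pictures to saliency-balanced blocks
#'
#' Randomly partitions pictures into equally sized blocks and verifies, by
#' one-way ANOVA of the left/right saliency ratio on block, that no
#' significant imbalance was introduced. The balance is enforced by
#' rejection sampling: the assignment is redrawn until the ANOVA p-value
#' exceeds `p_threshold` or `max_tries` is reached (the balance check in the
#' original design is post hoc; the threshold and retry cap are choices of
#' this implementation and are reported in the output).
#'
#' @param ratios Named numeric vector of left/right saliency ratios, one per
#'   picture.
#' @param n_blocks Number of blocks; must divide the number of pictures.
#' @param seed Integer seed; the assignment is fully reproducible.
#' @param p_threshold Minimum acceptable balance p-value (default 0.2).
#' @param max_tries Retry cap (default 1000).
#' @return List with `assignment` (data frame `picture`, `block`),
#'   `F`, `p`, `tries`, `n_blocks`, `seed`, `p_threshold`.
#' @export
assign_balanced_blocks <- function(ratios, n_blocks, seed = 1,
                                   p_threshold = 0.2, max_tries = 1000) {
  if (is.null(names(ratios))) names(ratios) <- as.character(seq_along(ratios))
  n <- length(ratios)
  if (n %% n_blocks != 0) {
    stop("number of pictures (", n, ") is not divisible by n_blocks (",
         n_blocks, ")", call. = FALSE)
  }
  per_block <- n / n_blocks
  best <- NULL
  with_preserved_rng({
    set.seed(seed)
    for (try in seq_len(max_tries)) {
      blocks <- sample(rep(seq_len(n_blocks), each = per_block))
      test <- oneway_balance_test(ratios, blocks)
      cand <- list(assignment = data.frame(picture = names(ratios),
                                           block = blocks),
                   F = test$F, p = test$p, tries = try,
                   n_blocks = n_blocks, seed = seed,
                   p_threshold = p_threshold)
      if (is.null(best) || test$p > best$p) best <- cand
      if (test$p > p_threshold) return(cand)
    }
    stop(structure(class = c("gazeclust_balance_error", "error", "condition"),
                   list(message = sprintf(
                     "no assignment with balance p > %.3g in %d tries (best p = %.3g)",
                     p_threshold, max_tries, best$p),
                     call = NULL, best = best)))
  })
}

#' Mirror coordinates along the vertical midline
#'
#' `mirror_x()` flips a centred horizontal coordinate; `mirror_fixations()`
#' flips every fixation of a table about the screen's vertical midline
#' (uncentred `x_px` becomes `width_px - x_px`); `mirror_saliency()`
#' reverses the columns of a saliency matrix. Used to counterbalance
#' picture content across participants.
#'
#' @param x Centred horizontal coordinate(s) in pixels.
#' @return The mirrored object of the same type.
#' @export
mirror_x <- function(x) -x

#' @rdname mirror_x
#' @param table A [fixation_table()].
#' @export
mirror_fixations <- function(table) {
  stopifnot(inherits(table, "fixation_table"))
  g <- attr(table, "geometry")
  out <- as.data.frame(table)
  out$x_px <- g$width_px - out$x_px
  fixation_table(out, geometry = g,
                 provenance = paste0(attr(table, "provenance"), " (mirrored)"))
}

#' @rdname mirror_x
#' @param m Saliency matrix.
#' @export
mirror_saliency <- function(m) {
  m <- as.matrix(m)
  m[, rev(seq_len(ncol(m))), drop = FALSE]
}
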
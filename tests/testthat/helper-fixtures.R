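# Small builders shared across the suite. Everything is generated in code;
# no fixture files.

# fixation table with one fixation per (participant, stimulation, timepoint,
# bin listed in `bins`), x given in centred px by `value_fun(participant
# index, cell index, bin)`; cell index runs timepoint-fastest.
make_cell_fixations <- function(participants, stimulations, timepoints,
                                bins, value_fun,
                                geometry = screen_geometry(),
                                bin_ms = 100) {
  rows <- list()
  for (pi in seq_along(participants)) {
    ci <- 0
    for (st in stimulations) {
      for (tp in timepoints) {
        ci <- ci + 1
        for (b in bins) {
          rows[[length(rows) + 1]] <- data.frame(
            participant = participants[pi], stimulation = st,
            timepoint = tp, picture = "pic1",
            start_ms = b * bin_ms + bin_ms / 2, duration_ms = 200,
            x_px = uncenter_x(value_fun(pi, ci, b), geometry),
            y_px = geometry$height_px / 2)
        }
      }
    }
  }
  fixation_table(do.call(rbind, rows), geometry = geometry,
                 provenance = "fixture")
}

# simulated gaze cell table (no fixation-level structure) for the spatial
# models: participant intercepts + optional cell shifts + iid noise
make_cells <- function(n, stimulations = c("FEF", "PPC", "SHAM"),
                       timepoints = c("T0", "T1"),
                       subject_sd = 20, noise_sd = 10,
                       shift = NULL, n_fixations = 260) {
  grid <- expand.grid(participant = sprintf("P%02d", seq_len(n)),
                      stimulation = stimulations, timepoint = timepoints,
                      stringsAsFactors = FALSE)
  bias <- rnorm(n, sd = subject_sd)
  grid$mean_x <- bias[match(grid$participant,
                            sprintf("P%02d", seq_len(n)))] +
    rnorm(nrow(grid), sd = noise_sd)
  if (!is.null(shift)) {
    hit <- grid$stimulation == shift$stimulation &
      grid$timepoint == shift$timepoint
    grid$mean_x[hit] <- grid$mean_x[hit] + shift$px
  }
  grid$n_fixations <- n_fixations
  structure(grid, class = c("gaze_cell_table", "data.frame"),
            geometry = screen_geometry())
}

# independent brute-force cluster scan (oracle for form_clusters)
brute_cluster_scan <- function(pvals, Fvals, alpha) {
  sig <- !is.na(pvals) & pvals < alpha
  out <- NULL
  i <- 1
  n <- length(pvals)
  while (i <= n) {
    if (sig[i]) {
      j <- i
      while (j < n && sig[j + 1]) j <- j + 1
      out <- rbind(out, data.frame(start_bin = i - 1, end_bin = j - 1,
                                   mass = sum(Fvals[i:j])))
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (is.null(out)) {
    out <- data.frame(start_bin = integer(), end_bin = integer(),
                      mass = numeric())
  }
  out
}

# reduced-size null simulation config used by the validity checks
null_sim_config <- function(seed) {
  simulation_config(n_participants = 8, timepoints = c("T0", "T1"),
                    pictures_per_block = 12, seed = seed)
}
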
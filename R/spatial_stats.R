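#' Average gaze position per participant, stimulation and timepoint
#'
#' Collapses a (bounds-filtered) fixation table to the mean centred
#' horizontal fixation position per design cell, the dependent variable of
#' the spatial mixed-model analyses. Negative values are left of the
#' picture centre.
#'
#' @param table A [fixation_table()], already filtered with
#'   [filter_out_of_bounds()].
#' @return A data frame of class `gaze_cell_table` with columns
#'   `participant`, `stimulation`, `timepoint`, `mean_x` (centred px) and
#'   `n_fixations`; cells with no fixations are absent and listed in the
#'   `missing_cells` attribute.
#' @export
average_gaze_table <- function(table) {
  stopifnot(inherits(table, "fixation_table"))
  if (nrow(table) == 0) stop("cannot average an empty fixation table", call. = FALSE)
  g <- attr(table, "geometry")
  dt <- data.table::as.data.table(as.data.frame(table))
  dt[, x_centered := center_x(x_px, g)]
  cells <- dt[, list(mean_x = mean(x_centered), n_fixations = .N),
              by = c("participant", "stimulation", "timepoint")]
  cells <- cells[order(participant, stimulation, timepoint)]
  cells <- data.table::setDF(cells)
  full <- expand.grid(participant = unique(cells$participant),
                      stimulation = unique(cells$stimulation),
                      timepoint = unique(cells$timepoint),
                      stringsAsFactors = FALSE)
  key_obs <- with(cells, paste(participant, stimulation, timepoint))
  key_full <- with(full, paste(participant, stimulation, timepoint))
  missing <- full[!key_full %in% key_obs, , drop = FALSE]
  structure(cells, class = c("gaze_cell_table", "data.frame"),
            geometry = g, missing_cells = missing)
}

as_model_frame <- function(cells) {
  df <- as.data.frame(cells)
  df$participant <- factor(df$participant)
  df$stimulation <- factor(df$stimulation,
                           levels = intersect(STIMULATION_LEVELS,
                                              unique(df$stimulation)))
  df$timepoint <- factor(df$timepoint,
                         levels = intersect(TIMEPOINT_LEVELS,
                                            unique(df$timepoint)))
  df
}

sum_contrasts <- function(df, vars = c("stimulation", "timepoint")) {
  out <- list()
  for (v in intersect(vars, names(df))) {
    if (is.factor(df[[v]]) && nlevels(df[[v]]) > 1) {
      out[[v]] <- stats::contr.sum(nlevels(df[[v]]))
    }
  }
  out
}

# Fit an LMM, falling back to OLS when the mixed fit is degenerate
# (e.g. zero residual variance in noiseless constructions). Returns the fit
# plus convergence/singularity bookkeeping; no silent model changes.
fit_lmm <- function(formula, data, contrasts = NULL, relax_checks = FALSE) {
  notes <- character()
  singular <- FALSE
  converged <- TRUE
  control <- if (relax_checks) {
    # permits structures with as many levels as observations, which then
    # surface as boundary (singular) fits instead of hard errors
    lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                      check.nobs.vs.nRE = "ignore")
  } else {
    lme4::lmerControl()
  }
  fit <- withCallingHandlers(
    tryCatch(
      lmerTest::lmer(formula, data = data, REML = TRUE, contrasts = contrasts,
                     control = control),
      error = function(e) e),
    warning = function(w) {
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      notes <<- c(notes, conditionMessage(m))
      invokeRestart("muffleMessage")
    })
  if (inherits(fit, "error")) {
    notes <- c(notes, paste("mixed fit failed, ordinary least squares fallback:",
                            conditionMessage(fit)))
    fixed_formula <- lme4::nobars(formula)
    fit <- stats::lm(fixed_formula, data = data, contrasts = contrasts)
    converged <- FALSE
  } else {
    singular <- lme4::isSingular(fit, tol = 1e-4)
    if (any(grepl("failed to converge", notes))) converged <- FALSE
  }
  list(fit = fit, singular = singular, converged = converged, notes = notes)
}

anova_table <- function(fit) {
  if (inherits(fit, "lmerModLmerTest")) {
    tab <- as.data.frame(stats::anova(fit, type = 3, ddf = "Satterthwaite"))
    data.frame(term = rownames(tab), F = tab$`F value`,
               df1 = tab$NumDF, df2 = tab$DenDF, p = tab$`Pr(>F)`,
               row.names = NULL)
  } else {
    tab <- as.data.frame(car::Anova(fit, type = 3))
    tab <- tab[!rownames(tab) %in% c("(Intercept)", "Residuals"), , drop = FALSE]
    data.frame(term = rownames(tab), F = tab$`F value`,
               df1 = tab$Df, df2 = stats::df.residual(fit),
               p = tab$`Pr(>F)`, row.names = NULL)
  }
}

variance_components <- function(fit) {
  if (!inherits(fit, "merMod")) return(NULL)
  vc <- as.data.frame(lme4::VarCorr(fit))
  data.frame(group = vc$grp, variance = vc$vcov, sd = vc$sdcor)
}

make_model_result <- function(fitted, anova, data, formula, type,
                              posthoc = NULL, extra = list()) {
  fe <- if (inherits(fitted$fit, "merMod")) {
    cf <- as.data.frame(stats::coef(summary(fitted$fit)))
    data.frame(term = rownames(cf), estimate = cf$Estimate,
               se = cf$`Std. Error`, row.names = NULL)
  } else {
    cf <- as.data.frame(stats::coef(summary(fitted$fit)))
    data.frame(term = rownames(cf), estimate = cf$Estimate,
               se = cf$`Std. Error`, row.names = NULL)
  }
  structure(c(list(type = type, fit = fitted$fit, formula = formula,
                   fixed = fe, anova = anova,
                   varcor = variance_components(fitted$fit),
                   singular = fitted$singular, converged = fitted$converged,
                   notes = fitted$notes, posthoc = posthoc, data = data),
              extra),
            class = "gaze_model_result")
}

#' @export
print.gaze_model_result <- function(x, ...) {
  cat(sprintf("<gaze_model_result: %s>\n", x$type))
  cat("  ", deparse(x$formula), "\n")
  if (x$singular) cat("  [singular fit]\n")
  if (!x$converged) cat("  [did not converge / OLS fallback]\n")
  cat("F-tests (Satterthwaite):\n")
  print(x$anova, digits = 4)
  if (!is.null(x$posthoc)) {
    cat("Post-hoc contrasts (Bonferroni):\n")
    print(x$posthoc, digits = 4)
  }
  invisible(x)
}

#' Pre-post linear mixed model of the average gaze position
#'
#' Fits `mean_x ~ stimulation * timepoint (+ n_fixations)` with
#' by-participant random intercepts, optionally augmented by
#' participant-within-stimulation and participant-within-timepoint intercept
#' deviations (the default; a single-group design cannot carry random
#' intercepts for the factors themselves). Fixed effects are tested with
#' type-III F-tests using Satterthwaite denominator degrees of freedom; the
#' stimulation-by-timepoint interaction is decomposed by Bonferroni-corrected
#' post-hoc contrasts.
#'
#' @param cells A [average_gaze_table()] result (or data frame with the same
#'   columns).
#' @param include_n_fixations Include the per-cell fixation count as a
#'   covariate (dropped automatically, with a note, when constant).
#' @param random `"full"` for participant + participant:stimulation +
#'   participant:timepoint intercepts, `"participant"` for participant-only.
#' @param posthoc_family Contrast family for the post-hocs, see
#'   [posthoc_contrasts()].
#' @return A `gaze_model_result`: fixed-effect estimates, F-table, variance
#'   components, singularity/convergence flags and the post-hoc table.
#' @export
fit_prepost_model <- function(cells, include_n_fixations = TRUE,
                              random = c("full", "participant"),
                              posthoc_family = c("timepoint_within_stimulation",
                                                 "cells")) {
  random <- match.arg(random)
  posthoc_family <- match.arg(posthoc_family)
  df <- as_model_frame(cells)
  if (length(unique(df$participant)) < 2) {
    stop("fit_prepost_model needs at least 2 participants", call. = FALSE)
  }
  tab <- table(df$stimulation, df$timepoint)
  if (any(tab == 0)) {
    stop("every stimulation must be observed at every timepoint", call. = FALSE)
  }
  notes0 <- character()
  rhs <- "stimulation * timepoint"
  if (include_n_fixations) {
    if (stats::var(df$n_fixations) > 0) {
      rhs <- paste(rhs, "+ n_fixations")
    } else {
      notes0 <- "n_fixations constant; covariate dropped"
    }
  }
  re <- if (random == "full") {
    "(1 | participant) + (1 | participant:stimulation) + (1 | participant:timepoint)"
  } else {
    "(1 | participant)"
  }
  formula <- stats::as.formula(paste("mean_x ~", rhs, "+", re))
  fitted <- fit_lmm(formula, df, contrasts = sum_contrasts(df))
  fitted$notes <- c(notes0, fitted$notes)
  an <- anova_table(fitted$fit)
  ph <- posthoc_table(fitted$fit, family = posthoc_family)
  make_model_result(fitted, an, df, formula, "pre-post", posthoc = ph,
                    extra = list(random = random))
}

#' Baseline-covariate linear mixed model of the post-stimulation gaze
#' position
#'
#' Models the average gaze position at the post-stimulation timepoint(s) as
#' a function of stimulation and the participant's baseline (T0) gaze
#' position in the same session, with by-participant random intercepts.
#' With a single post timepoint the fixed part is
#' `stimulation * baseline_x`; with several it is
#' `stimulation * timepoint + baseline_x`. Requesting
#' `random = "by_stimulation"` adds participant-within-stimulation
#' intercepts; if any variance component of that richer structure collapses
#' (singular fit) the model is automatically refitted with
#' participant-only intercepts and the event recorded in `notes` and
#' `reduced`.
#'
#' @param cells A [average_gaze_table()] result containing T0 plus at least
#'   one later timepoint for every participant and stimulation.
#' @param random `"participant"` (default) or `"by_stimulation"`.
#' @param singular_tol Variance components below `singular_tol` times the
#'   residual variance count as singular.
#' @return A `gaze_model_result`; `$reduced` is `TRUE` when the richer
#'   random structure was abandoned.
#' @export
fit_baseline_model <- function(cells, random = c("participant", "by_stimulation"),
                               singular_tol = 1e-6) {
  random <- match.arg(random)
  df <- as_model_frame(cells)
  if (!"T0" %in% levels(df$timepoint)) {
    stop("baseline model needs T0 cells", call. = FALSE)
  }
  base <- df[df$timepoint == "T0", c("participant", "stimulation", "mean_x")]
  names(base)[3] <- "baseline_x"
  post <- df[df$timepoint != "T0", , drop = FALSE]
  if (nrow(post) == 0) stop("baseline model needs post-stimulation timepoints",
                            call. = FALSE)
  merged <- merge(post, base, by = c("participant", "stimulation"),
                  all.x = TRUE, sort = TRUE)
  if (anyNA(merged$baseline_x)) {
    offenders <- unique(merged$participant[is.na(merged$baseline_x)])
    stop("missing T0 baseline cell for participant(s): ",
         paste(offenders, collapse = ", "), call. = FALSE)
  }
  merged$timepoint <- droplevels(merged$timepoint)
  fixed <- if (nlevels(merged$timepoint) > 1) {
    "stimulation * timepoint + baseline_x"
  } else {
    "stimulation * baseline_x"
  }
  re <- if (random == "by_stimulation") {
    "(1 | participant) + (1 | participant:stimulation)"
  } else {
    "(1 | participant)"
  }
  formula <- stats::as.formula(paste("mean_x ~", fixed, "+", re))
  fitted <- fit_lmm(formula, merged, contrasts = sum_contrasts(merged),
                    relax_checks = (random == "by_stimulation"))
  reduced <- FALSE
  if (random == "by_stimulation" && inherits(fitted$fit, "merMod")) {
    vc <- variance_components(fitted$fit)
    resid_var <- vc$variance[vc$group == "Residual"]
    re_var <- vc$variance[vc$group != "Residual"]
    if (fitted$singular || !fitted$converged ||
        any(re_var < singular_tol * max(resid_var, .Machine$double.eps))) {
      formula <- stats::as.formula(paste("mean_x ~", fixed, "+ (1 | participant)"))
      refit <- fit_lmm(formula, merged, contrasts = sum_contrasts(merged))
      refit$notes <- c(fitted$notes,
                       "by-stimulation intercept structure degenerate (singular or non-identifiable fit); refitted with participant-only intercepts")
      refit$singular <- TRUE   # records why the reduction happened
      fitted <- refit
      reduced <- TRUE
    }
  }
  an <- anova_table(fitted$fit)
  make_model_result(fitted, an, merged, formula, "baseline",
                    extra = list(random = random, reduced = reduced))
}

posthoc_table <- function(fit, family = c("timepoint_within_stimulation", "cells"),
                          correction = "bonferroni") {
  family <- match.arg(family)
  emm <- try(switch(family,
    timepoint_within_stimulation = {
      e <- emmeans::emmeans(fit, ~ timepoint | stimulation,
                            lmer.df = "satterthwaite")
      emmeans::contrast(e, method = "revpairwise", adjust = "none")
    },
    cells = {
      e <- emmeans::emmeans(fit, ~ stimulation * timepoint,
                            lmer.df = "satterthwaite")
      emmeans::contrast(e, method = "revpairwise", adjust = "none")
    }), silent = TRUE)
  if (inherits(emm, "try-error")) return(NULL)
  tab <- as.data.frame(summary(emm))
  names(tab)[names(tab) == "t.ratio"] <- "t"
  names(tab)[names(tab) == "p.value"] <- "p_raw"
  # Bonferroni over the whole family, not per stratum
  tab$p_adj <- bonferroni_adjust(tab$p_raw, m = nrow(tab))
  tab
}

#' Bonferroni-adjusted p-values
#'
#' @param p Raw p-value(s).
#' @param m Family size; defaults to `length(p)`.
#' @return `pmin(1, m * p)`.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  pmin(1, m * p)
}

#' Post-hoc contrasts for a fitted gaze model
#'
#' Bonferroni-corrected contrasts on the estimated marginal means of a
#' fitted `gaze_model_result`. The default family compares timepoints
#' within each stimulation (the pre-post decomposition); `"cells"` compares
#' all stimulation-by-timepoint cells pairwise.
#'
#' @param model A `gaze_model_result`.
#' @param family `"timepoint_within_stimulation"` or `"cells"`.
#' @param correction Only `"bonferroni"` is implemented.
#' @return Data frame of contrasts with estimates, t-ratios, raw and
#'   adjusted p-values.
#' @export
posthoc_contrasts <- function(model,
                              family = c("timepoint_within_stimulation", "cells"),
                              correction = c("bonferroni")) {
  stopifnot(inherits(model, "gaze_model_result"))
  correction <- match.arg(correction)
  family <- match.arg(family)
  out <- posthoc_table(model$fit, family = family, correction = correction)
  if (is.null(out)) stop("contrast family not available for this model",
                         call. = FALSE)
  out
}
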
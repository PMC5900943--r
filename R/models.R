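#' Pooled-variance two-sample t-test from summary statistics
#'
#' Student's two-sample t-test with pooled variance computed directly from
#' group means, standard deviations and sizes, `df = n1 + n2 - 2`. With
#' zero pooled variance and equal means the statistic is 0 by convention.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @return List with `t`, `df`, `p` (two-tailed).
#' @export
pooled_t_test <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tval <- if (se == 0) {
    if (mean1 == mean2) 0 else Inf * sign(mean1 - mean2)
  } else {
    (mean1 - mean2) / se
  }
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}

# Shared driver for the two ROI mixed models. Fits
#   response ~ group * roi * hemisphere * epoch + (random)
# by REML, with type-III F-tests (Satterthwaite via lmerTest, or fast Wald
# chi-square via car for simulation loops) and emmeans-based group marginal
# means with Bonferroni pairwise contrasts. A singular fit is retained (a
# boundary estimate is a valid REML optimum) with a note; if lmer fails
# entirely, a fixed-effects fallback is fitted and noted.
fit_roi_model <- function(dat, by_cell = FALSE, by_hemisphere = FALSE,
                          means = TRUE,
                          random = c("intercept", "hemisphere"),
                          tests = c("satterthwaite", "wald"),
                          df_method = c("satterthwaite", "asymptotic")) {
  random <- match.arg(random)
  tests <- match.arg(tests)
  df_method <- match.arg(df_method)
  for (g in outcome_groups()) {
    if (!g %in% dat$group) {
      stop("group '", g, "' has no data", call. = FALSE)
    }
  }
  dat$group <- factor(dat$group, levels = outcome_groups())
  dat$roi <- factor(dat$roi)
  dat$hemisphere <- factor(dat$hemisphere)
  dat$epoch <- factor(dat$epoch)
  dat$infant_id <- factor(dat$infant_id)
  notes <- character(0)

  form <- if (random == "hemisphere") {
    response ~ group * roi * hemisphere * epoch + (1 + hemisphere | infant_id)
  } else {
    response ~ group * roi * hemisphere * epoch + (1 | infant_id)
  }
  fit <- tryCatch(
    suppressMessages(lmerTest::lmer(form, data = dat, REML = TRUE)),
    error = function(e) e)
  if (inherits(fit, "error") && random == "hemisphere") {
    notes <- c(notes, paste("hemisphere random slope failed, refit with",
                            "random intercept:", conditionMessage(fit)))
    fit <- tryCatch(
      suppressMessages(lmerTest::lmer(
        response ~ group * roi * hemisphere * epoch + (1 | infant_id),
        data = dat, REML = TRUE)),
      error = function(e) e)
  }
  if (inherits(fit, "error")) {
    notes <- c(notes, paste("random-effects fit failed, fixed-effects",
                            "fallback:", conditionMessage(fit)))
    fit <- stats::lm(response ~ group * roi * hemisphere * epoch, data = dat)
    an <- stats::anova(fit)
  } else {
    if (lme4::isSingular(fit)) {
      notes <- c(notes, "random-effects variance estimated at boundary")
    }
    an <- if (tests == "satterthwaite") {
      stats::anova(fit, type = 3)
    } else {
      car::Anova(fit, type = 3, test.statistic = "Chisq")
    }
  }
  an <- as.data.frame(an)
  an$term <- rownames(an)
  names(an)[names(an) %in% c("Pr(>F)", "Pr(>Chisq)")] <- "p"
  rownames(an) <- NULL

  emm_args <- if (df_method == "asymptotic") list(lmer.df = "asymptotic")
              else list()
  group_means <- NULL
  pw <- NULL
  cell_means <- NULL
  cell_contrasts <- NULL
  hemisphere_means <- NULL
  hemisphere_contrasts <- NULL
  if (means) {
    emm <- suppressMessages(
      do.call(emmeans::emmeans, c(list(fit, ~group), emm_args)))
    group_means <- as.data.frame(emm)
    pw <- as.data.frame(emmeans::contrast(emm, "pairwise",
                                          adjust = "bonferroni"))
  }
  if (by_cell) {
    emm_cell <- suppressMessages(
      do.call(emmeans::emmeans,
              c(list(fit, ~group | hemisphere * epoch), emm_args)))
    cell_means <- as.data.frame(emm_cell)
    cell_contrasts <- as.data.frame(emmeans::contrast(emm_cell, "pairwise",
                                                      adjust = "bonferroni"))
  }
  if (by_hemisphere) {
    emm_hemi <- suppressMessages(
      do.call(emmeans::emmeans, c(list(fit, ~group | hemisphere), emm_args)))
    hemisphere_means <- as.data.frame(emm_hemi)
    hemisphere_contrasts <- as.data.frame(
      emmeans::contrast(emm_hemi, "pairwise", adjust = "bonferroni"))
  }
  structure(list(anova = an, group_means = group_means, pairwise = pw,
                 cell_means = cell_means, cell_contrasts = cell_contrasts,
                 hemisphere_means = hemisphere_means,
                 hemisphere_contrasts = hemisphere_contrasts,
                 model = fit, notes = notes),
            class = "group_result")
}

#' @export
print.group_result <- function(x, ...) {
  cat("Fixed-effect tests:\n")
  print(x$anova, digits = 4)
  if (!is.null(x$group_means)) {
    cat("\nGroup marginal means:\n")
    print(x$group_means, digits = 4)
    cat("\nPairwise comparisons (Bonferroni):\n")
    print(x$pairwise, digits = 4)
  }
  if (length(x$notes)) cat("\nNotes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Mixed model of the visual social response
#'
#' Linear mixed model of outcome group x ROI (IFG, pSTS-TPJ) x hemisphere x
#' time epoch (8--12, 12--16 s) on the ROI-average oxy-haemoglobin response
#' to the visual social condition, with a per-infant random intercept (REML,
#' Satterthwaite F-tests). Marginal group means and Bonferroni-adjusted
#' pairwise group comparisons are returned.
#'
#' @param roi_responses Long table with columns `infant_id`, `group`, `roi`,
#'   `hemisphere`, `condition`, `chromophore`, `epoch`, `value` (stacked
#'   [roi_average()] output across infants joined with phenotype groups).
#' @param rois,epochs Analysis ROIs and epochs.
#' @param ... Passed to the shared model driver (`tests`, `df_method`).
#' @return A `group_result`: `anova`, `group_means`, `pairwise`, `model`,
#'   `notes`.
#' @export
fit_visual_model <- function(roi_responses, rois = c("IFG", "pSTS-TPJ"),
                             epochs = c("8-12", "12-16"), ...) {
  dat <- roi_responses[roi_responses$condition == "V-S" &
                         roi_responses$chromophore == "HbO2" &
                         roi_responses$roi %in% rois &
                         roi_responses$epoch %in% epochs, , drop = FALSE]
  dat$response <- dat$value
  fit_roi_model(dat, by_cell = FALSE, ...)
}

#' Mixed model of the vocal minus non-vocal difference
#'
#' Linear mixed model of outcome group x ROI (aMTG-STG, pSTS-TPJ) x
#' hemisphere x time epoch on the ROI-average vocal minus non-vocal
#' oxy-haemoglobin difference scores, with per-infant random intercept.
#' Besides the overall group means, per-hemisphere-by-epoch group marginal
#' means and Bonferroni pairwise contrasts are returned to expose
#' hemisphere- and time-specific group effects.
#'
#' Vocal selectivity is a lateralized, infant-level trait, so the default
#' random structure adds a per-infant hemisphere slope to the intercept;
#' when that fit fails it falls back to the intercept-only structure with a
#' note.
#'
#' @param differences Long table with columns `infant_id`, `group`, `roi`,
#'   `hemisphere`, `chromophore`, `epoch`, `difference` (stacked
#'   [vocal_contrast()] output joined with phenotype groups).
#' @param rois Analysis ROIs.
#' @param random Random-effects structure (`"hemisphere"` or
#'   `"intercept"`).
#' @param cells Compute per-hemisphere-by-epoch marginal means and
#'   contrasts.
#' @param ... Passed to the shared model driver (`tests`, `df_method`,
#'   `means`).
#' @return A `group_result` with additional `cell_means`, `cell_contrasts`,
#'   `hemisphere_means` and `hemisphere_contrasts` elements.
#' @export
fit_auditory_model <- function(differences, rois = c("aMTG-STG", "pSTS-TPJ"),
                               random = "hemisphere", cells = TRUE, ...) {
  dat <- differences[differences$chromophore == "HbO2" &
                       differences$roi %in% rois, , drop = FALSE]
  dat$response <- dat$difference
  fit_roi_model(dat, by_cell = cells, by_hemisphere = TRUE, random = random,
                ...)
}

#' Correlate brain responses with SRS scores
#'
#' Pearson correlations between per-infant brain response summaries and the
#' Social Responsiveness Scale total, plus partial correlations controlling
#' for outcome group (both variables residualized on group indicator codes;
#' the partial test uses `n - 2 - (g - 1)` degrees of freedom for `g`
#' groups).
#'
#' @param predictors `data.frame` with `infant_id` and one or more numeric
#'   response columns (e.g. `visual`, `auditory`).
#' @param phenotypes Phenotype table with `infant_id`, `group`, `srs_total`.
#' @return Named list (one element per response column) of lists with `n`,
#'   `r`, `df`, `p`, `partial_r`, `partial_df`, `partial_p`. Zero-variance
#'   inputs yield `NA` results.
#' @export
correlate_srs <- function(predictors, phenotypes) {
  ph <- phenotypes[match(predictors$infant_id, phenotypes$infant_id), ]
  vars <- setdiff(names(predictors), "infant_id")
  out <- list()
  for (v in vars) {
    x <- predictors[[v]]
    y <- ph$srs_total
    g <- ph$group
    ok <- stats::complete.cases(x, y, g)
    x <- x[ok]; y <- y[ok]; g <- factor(g[ok])
    n <- length(x)
    if (n < 4L || stats::sd(x) == 0 || stats::sd(y) == 0) {
      out[[v]] <- list(n = n, r = NA_real_, df = NA_real_, p = NA_real_,
                       partial_r = NA_real_, partial_df = NA_real_,
                       partial_p = NA_real_)
      next
    }
    r <- stats::cor(x, y)
    df <- n - 2
    tval <- r * sqrt(df / (1 - r^2))
    p <- 2 * stats::pt(-abs(tval), df)

    if (nlevels(g) > 1L) {
      rx <- stats::resid(stats::lm(x ~ g))
      ry <- stats::resid(stats::lm(y ~ g))
      k <- nlevels(g) - 1L
    } else {
      rx <- x - mean(x); ry <- y - mean(y); k <- 0L
    }
    if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
      pr <- NA_real_; pdf <- NA_real_; pp <- NA_real_
    } else {
      pr <- stats::cor(rx, ry)
      pdf <- n - 2 - k
      pt_ <- pr * sqrt(pdf / (1 - pr^2))
      pp <- 2 * stats::pt(-abs(pt_), pdf)
    }
    out[[v]] <- list(n = n, r = r, df = df, p = p, partial_r = pr,
                     partial_df = pdf, partial_p = pp)
  }
  out
}

#' Per-infant correlation predictors
#'
#' Builds the two dimensional-analysis predictors: the visual-social
#' response averaged across the visual-analysis ROIs, hemispheres and the
#' two analysis epochs, and the left-hemisphere vocal minus non-vocal
#' difference averaged across the auditory-analysis ROIs within the
#' 12--16 s epoch.
#'
#' @param roi_responses Stacked ROI responses across infants (`infant_id`
#'   column required).
#' @param differences Stacked vocal-contrast tables across infants.
#' @return `data.frame` with `infant_id`, `visual`, `auditory` (`NA` where
#'   a summary is unavailable).
#' @export
srs_predictors <- function(roi_responses, differences) {
  vis <- roi_responses[roi_responses$condition == "V-S" &
                         roi_responses$chromophore == "HbO2" &
                         roi_responses$roi %in% c("IFG", "pSTS-TPJ") &
                         roi_responses$epoch %in% c("8-12", "12-16"), ,
                       drop = FALSE]
  aud <- differences[differences$chromophore == "HbO2" &
                       differences$hemisphere == "left" &
                       differences$roi %in% c("aMTG-STG", "pSTS-TPJ") &
                       differences$epoch == "12-16", , drop = FALSE]
  ids <- unique(c(vis$infant_id, aud$infant_id))
  data.frame(
    infant_id = ids,
    visual = vapply(ids, function(id) {
      v <- vis$value[vis$infant_id == id]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1)),
    auditory = vapply(ids, function(id) {
      v <- aud$difference[aud$infant_id == id]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
}
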
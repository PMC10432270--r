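# Test-result container shared by the exposure and T-maze tests.
new_test_result <- function(method, terms, estimate = NA_real_,
                            se = NA_real_, singular = FALSE, note = "") {
  structure(list(method = method, terms = terms, estimate = estimate,
                 se = se, singular = singular, note = note),
            class = "flymag_test")
}

#' @export
print.flymag_test <- function(x, ...) {
  cat(sprintf("<flymag_test> %s%s\n", x$method,
              if (x$singular) " [singular fit]" else ""))
  print(x$terms, row.names = FALSE)
  if (is.finite(x$estimate))
    cat(sprintf("effect estimate: %.4g (s.e. %.4g)\n", x$estimate, x$se))
  if (nzchar(x$note)) cat(x$note, "\n")
  invisible(x)
}

#' Join a track (or ground-truth) table with an experimental design
#'
#' @param table a track table or ground-truth table with a `tube` column.
#' @param design data.frame with `tube`, `id` (independent biological
#'   replicate), `Exposure` (sham/exposed) and optionally `condition`
#'   (field intensity).
#' @return the table with `id`, `Exposure` (and `condition`) attached.
#' @export
join_design <- function(table, design) {
  if (!all(c("tube", "id", "Exposure") %in% names(design)))
    stop("`design` needs columns tube, id, Exposure", call. = FALSE)
  if (anyDuplicated(design$tube))
    stop("`design` maps some tube to several ids", call. = FALSE)
  merge(table, design, by = "tube", all.x = TRUE)
}

#' Per-replicate climber ratios ready for the exposure test
#'
#' @inheritParams climber_proportion
#' @param design see [join_design()].
#' @return data.frame `id`, `Exposure`, (`condition`,) `tube`, `trial`,
#'   `prop`.
#' @export
climber_data <- function(table, design, crit = climber_criterion(),
                         group_size = 10) {
  props <- climber_proportion(table, crit, group_size)
  join_design(props, design)
}

#' Per-frame above-line counts ready for the binomial GLMM
#'
#' Counts of detections at/above the height line per tube x trial x frame,
#' thinned to every `subsample_every`-th frame (per-frame fits at full frame
#' rate are statistically redundant and slow).
#'
#' @inheritParams climber_data
#' @param subsample_every keep every k-th frame within each trial.
#' @return data.frame `id`, `Exposure`, `tube`, `trial`, `frame`,
#'   `time_in_trial_s`, `n_above`, `n_total`.
#' @export
ratio_glmm_data <- function(table, design, crit = climber_criterion(),
                            group_size = 10, subsample_every = 5) {
  cnt <- above_line_counts_raw(table, crit)
  fps <- attr(table, "fps")
  step <- max(1L, as.integer(subsample_every))
  rel <- round(cnt$time_in_trial_s * if (is.null(fps)) 10 else fps)
  cnt <- cnt[rel %% step == 0L, , drop = FALSE]
  cnt$n_above <- pmin(cnt$n_above, group_size)
  cnt$n_total <- group_size
  join_design(cnt, design)
}

#' Exposure effect on the ratio of climbers
#'
#' Two analyses of per-replicate climbing ratios. `"rm_anova"` is the
#' repeated-measures ANOVA of the classical assay: per-replicate climber
#' proportions across trials, with trials as the repeated measure within
#' replicate and Exposure tested against the between-replicate stratum.
#' `"binomial_glmm"` is the mixed-effects binomial model of above-line
#' counts over the whole trial rather than only at the 15-s mark:
#' `cbind(n_above, n_total - n_above) ~ Exposure + (1|id) + (1|trial/frame)`,
#' followed by a type-III Wald chi-square test of Exposure.
#'
#' @param data for `rm_anova`, the output of [climber_data()]; for
#'   `binomial_glmm`, the output of [ratio_glmm_data()].
#' @param method `"rm_anova"` or `"binomial_glmm"`.
#' @return a `flymag_test` with the Exposure term's statistic, df and
#'   p-value; the estimate is the Exposure coefficient (log-odds for the
#'   GLMM, difference in mean proportion for the ANOVA). Singular mixed
#'   fits are flagged, not silenced.
#' @export
test_exposure_ratio <- function(data,
                                method = c("rm_anova", "binomial_glmm")) {
  method <- match.arg(method)
  if (length(unique(data$Exposure)) < 2L)
    stop("need at least two Exposure levels", call. = FALSE)
  data$Exposure <- factor(data$Exposure)
  data$id <- factor(data$id)

  if (method == "rm_anova") {
    fit <- aov(prop ~ Exposure + Error(id), data = data)
    st <- summary(fit)
    tabs <- st[["Error: id"]][[1]]
    rownames(tabs) <- trimws(rownames(tabs))
    terms <- data.frame(term = "Exposure", statistic = "F",
                        value = tabs["Exposure", "F value"],
                        df = tabs["Exposure", "Df"],
                        df_denom = tabs["Residuals", "Df"],
                        p_value = tabs["Exposure", "Pr(>F)"],
                        stringsAsFactors = FALSE)
    means <- tapply(data$prop, data$Exposure, mean)
    return(new_test_result("repeated-measures ANOVA of climber ratios",
                           terms, estimate = unname(diff(means))))
  }

  data$trial <- factor(data$trial)
  data$frame <- factor(data$frame)
  # a single trial degenerates the trial stratum; keep the frame term
  form <- if (nlevels(data$trial) > 1L)
    cbind(n_above, n_total - n_above) ~ Exposure +
      (1 | id) + (1 | trial / frame)
  else
    cbind(n_above, n_total - n_above) ~ Exposure + (1 | id) + (1 | frame)
  fit <- suppressMessages(lme4::glmer(
    form, data = data, family = binomial, na.action = na.exclude))
  singular <- lme4::isSingular(fit)
  an <- car::Anova(fit, type = "III")
  terms <- data.frame(term = "Exposure", statistic = "Chisq",
                      value = an["Exposure", "Chisq"],
                      df = an["Exposure", "Df"], df_denom = NA_real_,
                      p_value = an["Exposure", "Pr(>Chisq)"],
                      stringsAsFactors = FALSE)
  co <- summary(fit)$coefficients
  k <- grep("^Exposure", rownames(co))[1]
  new_test_result("binomial GLMM of above-line counts", terms,
                  estimate = co[k, "Estimate"], se = co[k, "Std. Error"],
                  singular = singular,
                  note = if (singular)
                    "random-effect variance estimated at the boundary" else "")
}

#' Exposure effect on average height climbed (linear mixed model)
#'
#' Fits `Ycm ~ Exposure * condition + (1|id) + (1|trial/frame)` to per-frame
#' tube-average heights (`Ycm`), with random intercepts per biological
#' replicate and per frame nested in trial, and reports type-III
#' Satterthwaite F tests for Exposure, condition and their interaction.
#' When `condition` is absent or has a single level the model reduces to
#' Exposure only.
#'
#' @param data data.frame with `Ycm`, `id`, `trial`, `frame`, `Exposure`
#'   and optionally `condition` — typically [frame_mean_heights()] joined
#'   with the design via [join_design()], subsampled with [subsample_frames()].
#' @return a `flymag_test`; the estimate is the Exposure coefficient (cm).
#' @export
test_exposure_height <- function(data) {
  if (length(unique(data$Exposure)) < 2L)
    stop("need at least two Exposure levels", call. = FALSE)
  data$Exposure <- factor(data$Exposure)
  data$id <- factor(data$id)
  data$trial <- factor(data$trial)
  data$frame <- factor(data$frame)
  has_cond <- "condition" %in% names(data) &&
    length(unique(data$condition)) > 1L
  if (has_cond) data$condition <- factor(data$condition)

  fixed <- if (has_cond) Ycm ~ Exposure * condition else Ycm ~ Exposure
  ran <- if (nlevels(data$trial) > 1L)   # single trial: no trial stratum
    ~ . + (1 | id) + (1 | trial / frame)
  else
    ~ . + (1 | id) + (1 | frame)
  form <- update(fixed, ran)
  fit <- suppressMessages(lmerTest::lmer(form, data = data,
                                         na.action = na.exclude))
  X <- lme4::getME(fit, "X")
  if (qr(X)$rank < ncol(X)) {
    bad <- colnames(X)[qr(X)$pivot[-seq_len(qr(X)$rank)]]
    stop("rank-deficient fixed effects; aliased: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  singular <- lme4::isSingular(fit)
  an <- anova(fit, type = 3)
  terms <- data.frame(term = rownames(an), statistic = "F",
                      value = an[, "F value"], df = an[, "NumDF"],
                      df_denom = an[, "DenDF"], p_value = an[, "Pr(>F)"],
                      stringsAsFactors = FALSE)
  co <- summary(fit)$coefficients
  k <- grep("^Exposure", rownames(co))[1]
  new_test_result("linear mixed model of tube-average height", terms,
                  estimate = co[k, "Estimate"], se = co[k, "Std. Error"],
                  singular = singular,
                  note = if (singular)
                    "random-effect variance estimated at the boundary" else "")
}

#' Thin a per-frame table to every k-th frame within trials
#'
#' @param data data.frame with `time_in_trial_s`.
#' @param every keep every k-th frame.
#' @param fps frames per second (looked up from the table attribute if
#'   absent).
#' @return the thinned data.frame.
#' @export
subsample_frames <- function(data, every = 5, fps = NULL) {
  if (is.null(fps)) fps <- attr(data, "fps")
  if (is.null(fps)) fps <- 10
  step <- max(1L, as.integer(every))
  rel <- round(data$time_in_trial_s * fps)
  data[rel %% step == 0L, , drop = FALSE]
}
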
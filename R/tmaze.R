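#' Preference index of a choice set
#'
#' `PI = 2 * P_M - 1`, where `P_M = n_magnetic / n_total` is the proportion
#' of flies that chose the magnetic arm. 0 means indifference, +1 all flies
#' in the magnetic arm, -1 all flies in the non-magnetic arm.
#'
#' @param n_magnetic count of flies in the magnetic arm (vectorised).
#' @param n_total set size.
#' @return numeric vector of preference indices in `[-1, 1]`.
#' @examples
#' preference_index(58, 100)   # 0.16
#' @export
preference_index <- function(n_magnetic, n_total) {
  if (any(n_total < 1)) stop("`n_total` must be >= 1", call. = FALSE)
  if (any(n_magnetic < 0 | n_magnetic > n_total))
    stop("`n_magnetic` must lie in [0, n_total]", call. = FALSE)
  2 * (n_magnetic / n_total) - 1
}

#' Group test of choice proportions (the set is the replicate)
#'
#' Models per-set counts `(n_magnetic, n_total - n_magnetic)` on the group
#' factor with a binomial-type GLM — the statistically appropriate analysis
#' of group-assay choice data, in which the independent replicate is the set
#' of flies run together, not the individual fly. Overdispersion between
#' sets (flies influencing each other within a run) is absorbed by the
#' quasi-binomial variance (default) or a beta-binomial likelihood.
#'
#' @param sets data.frame with columns `group`, `n_magnetic`, `n_total`
#'   (e.g. from [simulate_tmaze_experiment()], possibly row-bound across
#'   groups).
#' @param dispersion `"quasi"` (quasi-binomial F test, default),
#'   `"binomial"` (likelihood-ratio chi-square; anticonservative under
#'   overdispersion) or `"beta_binomial"` (glmmTMB likelihood-ratio test).
#' @param conf confidence level for per-group proportion intervals.
#' @return a `flymag_test`; `terms` holds the group-effect statistic and
#'   p-value, and the per-group proportion estimates with intervals are
#'   attached as `$group_estimates`. Complete separation is flagged in
#'   `$note`.
#' @export
glm_group_test <- function(sets,
                           dispersion = c("quasi", "binomial",
                                          "beta_binomial"),
                           conf = 0.95) {
  dispersion <- match.arg(dispersion)
  need <- c("group", "n_magnetic", "n_total")
  if (!all(need %in% names(sets)))
    stop("`sets` needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  sets$group <- factor(sets$group)
  if (nlevels(sets$group) < 2L)
    stop("need at least two groups", call. = FALSE)
  if (min(table(sets$group)) < 2L)
    stop("need at least two sets per group", call. = FALSE)
  resp <- cbind(sets$n_magnetic, sets$n_total - sets$n_magnetic)

  if (dispersion == "beta_binomial") {
    fit <- suppressWarnings(glmmTMB::glmmTMB(
      resp ~ group, family = glmmTMB::betabinomial(), data = sets))
    fit0 <- suppressWarnings(glmmTMB::glmmTMB(
      resp ~ 1, family = glmmTMB::betabinomial(), data = sets))
    lrt <- anova(fit0, fit)
    terms <- data.frame(term = "group", statistic = "Chisq",
                        value = lrt$Chisq[2], df = lrt[["Chi Df"]][2],
                        df_denom = NA_real_, p_value = lrt[["Pr(>Chisq)"]][2],
                        stringsAsFactors = FALSE)
    co <- summary(fit)$coefficients$cond
    conv <- isTRUE(fit$fit$convergence == 0) &&
      isTRUE(fit$sdr$pdHess)
    res <- new_test_result("beta-binomial GLM of choice counts", terms,
                           estimate = co[2, "Estimate"],
                           se = co[2, "Std. Error"],
                           note = if (!conv)
                             "beta-binomial fit did not converge cleanly"
                           else "")
    res$group_estimates <- group_prop_estimates(sets, conf)
    return(res)
  }

  fam <- if (dispersion == "quasi") quasibinomial() else binomial()
  fit <- glm(resp ~ group, family = fam, data = sets)
  an <- anova(fit, test = if (dispersion == "quasi") "F" else "Chisq")
  if (dispersion == "quasi") {
    terms <- data.frame(term = "group", statistic = "F",
                        value = an["group", "F"], df = an["group", "Df"],
                        df_denom = an["group", "Resid. Df"],
                        p_value = an["group", "Pr(>F)"],
                        stringsAsFactors = FALSE)
    label <- "quasi-binomial GLM of choice counts"
  } else {
    terms <- data.frame(term = "group", statistic = "Chisq",
                        value = an["group", "Deviance"],
                        df = an["group", "Df"], df_denom = NA_real_,
                        p_value = an["group", "Pr(>Chi)"],
                        stringsAsFactors = FALSE)
    label <- "binomial GLM of choice counts"
  }
  co <- summary(fit)$coefficients
  sep <- any(abs(coef(fit)) > 10)
  res <- new_test_result(label, terms, estimate = co[2, "Estimate"],
                         se = co[2, "Std. Error"],
                         note = if (sep)
                           "possible complete separation (extreme log-odds)"
                         else "")
  res$group_estimates <- group_prop_estimates(sets, conf)
  res
}

group_prop_estimates <- function(sets, conf = 0.95) {
  agg_m <- tapply(sets$n_magnetic, sets$group, sum)
  agg_n <- tapply(sets$n_total, sets$group, sum)
  ci <- wilson_ci(as.vector(agg_m), as.vector(agg_n), conf)
  data.frame(group = names(agg_m), p_magnetic = ci$estimate,
             lower = ci$lower, upper = ci$upper,
             n_sets = as.vector(table(sets$group)),
             stringsAsFactors = FALSE)
}

#' The pseudoreplicated per-fly analysis (for comparison only)
#'
#' Deliberately reproduces the flawed analysis that treats every fly as an
#' independent biological replicate, ignoring that flies tested together in
#' one maze run make correlated choices. With any within-set correlation
#' this inflates significance (pseudoreplication); the function exists so
#' the inflation can be demonstrated against [glm_group_test()], and its
#' output is labelled accordingly. `"per_fly_t"` runs a Welch t-test on the
#' individual 0/1 choices; `"pooled"` runs a two-proportion chi-square test
#' on the pooled counts (no continuity correction).
#'
#' @param sets as in [glm_group_test()] (exactly two groups).
#' @param method `"per_fly_t"` or `"pooled"`.
#' @return a `flymag_test` (method string carries the "for comparison only"
#'   label).
#' @export
pseudoreplicated_test <- function(sets, method = c("per_fly_t", "pooled")) {
  method <- match.arg(method)
  sets$group <- factor(sets$group)
  if (nlevels(sets$group) != 2L)
    stop("pseudoreplicated test expects exactly two groups", call. = FALSE)
  g <- levels(sets$group)
  m <- tapply(sets$n_magnetic, sets$group, sum)
  n <- tapply(sets$n_total, sets$group, sum)

  if (method == "per_fly_t") {
    x1 <- rep(c(1, 0), c(m[1], n[1] - m[1]))
    x2 <- rep(c(1, 0), c(m[2], n[2] - m[2]))
    tt <- t.test(x1, x2)
    terms <- data.frame(term = "group", statistic = "t",
                        value = unname(tt$statistic),
                        df = unname(tt$parameter), df_denom = NA_real_,
                        p_value = tt$p.value, stringsAsFactors = FALSE)
    est <- unname(diff(tt$estimate))
    lab <- "per-fly t-test [pseudoreplicated; for comparison only]"
  } else {
    pt <- prop.test(as.vector(m), as.vector(n), correct = FALSE)
    terms <- data.frame(term = "group", statistic = "Chisq",
                        value = unname(pt$statistic),
                        df = unname(pt$parameter), df_denom = NA_real_,
                        p_value = pt$p.value, stringsAsFactors = FALSE)
    est <- unname(diff(pt$estimate))
    lab <- "pooled two-proportion test [pseudoreplicated; for comparison only]"
  }
  new_test_result(lab, terms, estimate = est)
}
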
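#' Simulate T-maze choice experiments with within-set correlation
#'
#' Generates per-set counts of flies choosing the magnetic arm of a two-arm
#' maze. Flies are tested in sets (typically around 100 per set); choices of
#' flies sharing a maze run are correlated, which is the source of the
#' pseudoreplication problem when flies are treated as independent
#' replicates. The within-set correlation is parameterised as a
#' beta-binomial intraclass correlation: the per-set choice probability is
#' drawn from a Beta distribution with mean `p_magnetic` and variance
#' `icc * p_magnetic * (1 - p_magnetic)`, and counts are binomial given the
#' set probability. `icc = 0` reduces exactly to independent Bernoulli
#' choices.
#'
#' @param n_sets number of independent sets (maze runs) to simulate.
#' @param flies_per_set number of flies per set (default 100).
#' @param p_magnetic marginal probability that a fly chooses the magnetic
#'   arm (0.5 = indifference).
#' @param icc intraclass correlation of choices within a set, in `[0, 1)`.
#' @param group group label attached to every set (e.g. `"trained"`).
#' @param seed optional integer seed; the caller's RNG state is preserved.
#' @return data.frame of class `choice_sets` with columns `set_id`, `group`,
#'   `n_magnetic`, `n_total` and `pi` (the preference index `2 * P_M - 1`).
#' @examples
#' sets <- simulate_tmaze_experiment(10, 100, p_magnetic = 0.5,
#'                                   icc = 0.05, seed = 1)
#' mean(sets$pi)
#' @seealso [preference_index()], [glm_group_test()], [type1_error_study()]
#' @export
simulate_tmaze_experiment <- function(n_sets, flies_per_set = 100,
                                      p_magnetic = 0.5, icc = 0,
                                      group = "group1", seed = NULL) {
  n_sets <- check_count(n_sets, "n_sets")
  flies_per_set <- check_count(flies_per_set, "flies_per_set")
  check_prob(p_magnetic, "p_magnetic")
  if (!is.numeric(icc) || length(icc) != 1L || is.na(icc) || icc < 0 ||
      icc >= 1)
    stop("`icc` must be in [0, 1)", call. = FALSE)

  with_seed(seed, {
    if (icc == 0 || p_magnetic %in% c(0, 1)) {
      p_set <- rep(p_magnetic, n_sets)
    } else {
      # Beta with mean p and variance icc * p * (1 - p):
      # shape1 + shape2 = 1/icc - 1
      nu <- 1 / icc - 1
      p_set <- rbeta(n_sets, p_magnetic * nu, (1 - p_magnetic) * nu)
    }
    n_magnetic <- rbinom(n_sets, flies_per_set, p_set)
    out <- data.frame(set_id = seq_len(n_sets),
                      group = group,
                      n_magnetic = n_magnetic,
                      n_total = flies_per_set,
                      stringsAsFactors = FALSE)
    out$pi <- preference_index(out$n_magnetic, out$n_total)
    class(out) <- c("choice_sets", class(out))
    out
  })
}
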
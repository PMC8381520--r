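#' Expected confidence-interval width at a target at-risk count
#'
#' Reproduces the simulation rationale behind the at-risk thresholds used
#' for reference and comparator eligibility: cohorts are generated with
#' exponential revision times calibrated to a given cumulative failure at
#' the evaluation time and no other censoring before it, with cohort size
#' chosen so that approximately `n_at_risk_target` procedures remain at
#' risk at `t`. The mean full width of the symmetric Greenwood 95\%
#' confidence interval of the 1-Kaplan-Meier failure estimate is the
#' quantity of interest — around 3 percentage points at 1000 at risk and
#' around 5 at 500, for ~5\% cumulative failure.
#'
#' @param n_at_risk_target Desired number still at risk at `t`.
#' @param replicates Number of replicate cohorts (default 200).
#' @param t Evaluation time in years (default 10).
#' @param failure Target cumulative failure at `t` (default 0.05).
#' @param alpha Confidence level complement (default 0.05).
#' @param seed Master seed; each replicate uses a derived substream.
#' @return List with `mean_width` (probability scale), `mean_width_pct`
#'   (percentage points), `widths`, `mean_n_at_risk` and `n_cohort`.
#' @export
ci_width_study <- function(n_at_risk_target, replicates = 200, t = 10,
                           failure = 0.05, alpha = 0.05, seed = 1) {
  stopifnot(n_at_risk_target >= 1, replicates >= 1, t > 0,
            failure > 0, failure < 1)
  lambda <- -log(1 - failure) / t
  n_cohort <- round(n_at_risk_target / (1 - failure))
  sc <- construct_scenario(
    "Design", "cemented", "fixed", "CR", n = n_cohort,
    revision_hazard = lambda, death_hazard = 0,
    enrol_window = c(t + 5, t + 1)  # all follow-up extends past t
  )
  cfg <- registry_config(list(sc), seed = seed)
  widths <- numeric(replicates)
  atrisk <- numeric(replicates)
  for (i in seq_len(replicates)) {
    reg <- generate_registry(cfg, seed = .substream_seed(seed, 100000 + i))
    est <- km_net_failure(as.data.frame(reg), t, alpha = alpha)
    widths[i] <- est$ci_high - est$ci_low
    atrisk[i] <- est$n_at_risk
  }
  list(mean_width = mean(widths), mean_width_pct = 100 * mean(widths),
       widths = widths, mean_n_at_risk = mean(atrisk), n_cohort = n_cohort)
}
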
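# Product-limit estimation of net failure F(t) = 1 - S(t).
#
# Deaths and plain censorings both leave the risk set without contributing
# events; the event of interest is the first revision. Tied times follow the
# usual Kaplan-Meier convention (events precede censorings), which is
# automatic in the product-limit formula: the risk set just before a time
# point contains everyone whose follow-up reaches it.

# Shared worker: event-time table up to and including t.
# Returns d_i (revisions) and n_i (risk set just before t_i) per distinct
# revision time t_i <= t.
.km_table <- function(time, status, t) {
  if (length(time) == 0L) stop("no records: the risk set is empty",
                               call. = FALSE)
  if (any(is.na(time)) || any(time < 0)) {
    stop("follow-up times must be non-negative and non-missing",
         call. = FALSE)
  }
  if (all(time == 0 & status != "revision")) {
    stop("all records censored at time 0: empty risk set", call. = FALSE)
  }
  is_event <- status == "revision"
  ev_times <- sort(unique(time[is_event & time <= t]))
  n_total <- length(time)
  if (length(ev_times) == 0L) {
    return(list(t_i = numeric(0), d_i = integer(0), n_i = integer(0)))
  }
  # risk set just before t_i: follow-up >= t_i
  n_i <- vapply(ev_times, function(ti) sum(time >= ti), integer(1))
  d_i <- vapply(ev_times, function(ti) sum(is_event & time == ti), integer(1))
  list(t_i = ev_times, d_i = d_i, n_i = n_i)
}

#' 1-Kaplan-Meier net failure estimate
#'
#' Estimates the cumulative probability of all-cause revision by time `t`
#' as one minus the Kaplan-Meier survivor function,
#' \deqn{F(t) = 1 - \prod_{t_i \le t} (1 - d_i / n_i),}
#' where \eqn{d_i} is the number of first revisions at the distinct
#' revision time \eqn{t_i} and \eqn{n_i} the risk-set size just before
#' \eqn{t_i}. Deaths are treated as independent censoring, so the estimate
#' is the marginal ("net") failure probability. The Greenwood variance
#' \deqn{\widehat{Var} = S(t)^2 \sum_{t_i \le t} \frac{d_i}{n_i (n_i - d_i)}}
#' and a symmetric normal confidence interval on the failure scale
#' (clipped to \eqn{[0,1]}) are returned alongside the number still at
#' risk at `t`. If the risk set is exhausted by events
#' (\eqn{n_i = d_i} at some time), \eqn{F = 1} and the variance is
#' reported as `NA` with `degenerate = TRUE`: no comparison against such
#' an estimate is meaningful.
#'
#' @param records Data frame with columns `time_years` and `status`
#'   (`revision` / `death` / `censored`), e.g. one construct's rows of a
#'   [tkr_registry()].
#' @param t Evaluation time in years (> 0). Revisions at exactly `t`
#'   count towards `F(t)`.
#' @param alpha Two-sided confidence level complement (default 0.05 for a
#'   95\% interval).
#' @return Object of class `net_failure`: a list with `t`, `failure`,
#'   `variance`, `se`, `n_at_risk`, `ci_low`, `ci_high`, `n`, `events`
#'   and `degenerate`.
#' @seealso [greenwood_variance()], [n_at_risk()], [failure_ci()]
#' @examples
#' rec <- data.frame(time_years = c(1, 2, 3, 4),
#'                   status = c("revision", "censored", "revision", "censored"))
#' km_net_failure(rec, t = 3)$failure  # 0.625
#' @export
km_net_failure <- function(records, t, alpha = 0.05) {
  stopifnot(is.numeric(t), length(t) == 1L, t > 0)
  time <- records$time_years
  status <- records$status
  tab <- .km_table(time, status, t)
  surv <- prod(1 - tab$d_i / tab$n_i)
  failure <- 1 - surv
  exhausted <- any(tab$n_i == tab$d_i)
  variance <- if (exhausted) NA_real_ else {
    surv^2 * sum(tab$d_i / (tab$n_i * (tab$n_i - tab$d_i)))
  }
  est <- structure(list(
    t = t,
    failure = failure,
    variance = variance,
    se = if (is.na(variance)) NA_real_ else sqrt(variance),
    n_at_risk = sum(time >= t),
    n = length(time),
    events = sum(status == "revision" & time <= t),
    degenerate = exhausted,
    alpha = alpha
  ), class = "net_failure")
  ci <- failure_ci(est, alpha = alpha)
  est$ci_low <- ci[[1]]
  est$ci_high <- ci[[2]]
  est
}

#' Greenwood variance of the survivor (and failure) estimate
#'
#' The classical Greenwood variance
#' \eqn{S(t)^2 \sum d_i / (n_i (n_i - d_i))} over revision times up to and
#' including `t`. Because \eqn{F = 1 - S}, it is also the variance of the
#' net-failure estimate. Returns `NA` when the risk set is exhausted by
#' events (an infinite Greenwood term).
#'
#' @inheritParams km_net_failure
#' @return Non-negative variance, or `NA` in the exhausted-risk-set case.
#' @export
greenwood_variance <- function(records, t) {
  km_net_failure(records, t)$variance
}

#' Symmetric confidence interval on the failure scale
#'
#' Plain normal interval \eqn{F \pm z_{1-\alpha/2} \sqrt{Var}}, clipped to
#' \eqn{[0, 1]}. Chosen to mirror the symmetric intervals reported for
#' reference constructs in registry benchmarking reports; no
#' log(-log) transform is applied.
#'
#' @param estimate A `net_failure` object, or any list with `failure` and
#'   `variance` entries.
#' @param alpha Two-sided level complement; default 0.05.
#' @return Numeric vector `c(ci_low, ci_high)`.
#' @export
failure_ci <- function(estimate, alpha = 0.05) {
  f <- estimate$failure
  v <- estimate$variance
  if (is.na(v)) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - alpha / 2)
  half <- z * sqrt(v)
  c(max(0, f - half), min(1, f + half))
}

#' Number still at risk
#'
#' Count of procedures still under observation at `t`: follow-up of at
#' least `t` years and no revision strictly before `t`. Deaths and
#' censorings before `t` remove a procedure from the risk set.
#'
#' @inheritParams km_net_failure
#' @param t Evaluation time in years (>= 0).
#' @return Integer count.
#' @export
n_at_risk <- function(records, t) {
  stopifnot(is.numeric(t), length(t) == 1L, t >= 0)
  sum(records$time_years >= t)
}

#' Prosthesis time incidence rate
#'
#' Revisions per 100 observed component-years: the unadjusted summary rate
#' used in registry annual reports. Included for report parity only; it
#' plays no role in noninferiority classification.
#'
#' @inheritParams km_net_failure
#' @return Rate per 100 component-years.
#' @export
ptir <- function(records) {
  total_years <- sum(records$time_years)
  if (total_years <= 0) stop("zero total follow-up: PTIR undefined",
                             call. = FALSE)
  100 * sum(records$status == "revision") / total_years
}

#' @export
print.net_failure <- function(x, ...) {
  cat(sprintf(
    "Net failure at %g years: %.4f (%d%% CI %.4f-%.4f), %d at risk\n",
    x$t, x$failure, round(100 * (1 - x$alpha)), x$ci_low, x$ci_high,
    x$n_at_risk))
  if (x$degenerate) cat("  [risk set exhausted: variance undefined]\n")
  invisible(x)
}

#' Net-failure estimates for every construct
#'
#' Convenience wrapper: applies [km_net_failure()] to each construct
#' group of a registry at one time point.
#'
#' @param registry A [tkr_registry()].
#' @param t Evaluation time in years.
#' @param alpha Confidence level complement.
#' @return Data frame with one row per construct:
#'   `construct, t_years, n_at_risk, failure, se, ci_low, ci_high`.
#' @export
construct_net_failure <- function(registry, t, alpha = 0.05) {
  groups <- group_by_construct(registry)
  rows <- lapply(names(groups), function(key) {
    est <- km_net_failure(groups[[key]], t, alpha = alpha)
    data.frame(construct = key, t_years = t, n_at_risk = est$n_at_risk,
               failure = est$failure, se = est$se,
               ci_low = est$ci_low, ci_high = est$ci_high,
               variance = est$variance, degenerate = est$degenerate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(construct = character(0), t_years = numeric(0),
                      n_at_risk = integer(0), failure = numeric(0),
                      se = numeric(0), ci_low = numeric(0),
                      ci_high = numeric(0), variance = numeric(0),
                      degenerate = logical(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
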
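# Internal-reference noninferiority benchmarking.
#
# The reference at each time point is the construct with the lowest net
# failure among those with at least `ref_min` still at risk; every other
# construct with at least `comp_min` at risk is compared to it on the
# failure-difference scale with a pooled Greenwood SE, and classified
# against absolute margins equal to 20% and 100% of the reference failure.

.category_levels <- c("inferior_100", "inferior_20", "inconclusive",
                      "noninferior_100", "noninferior_20")

#' Noninferiority margins from the reference failure
#'
#' Converts relative-risk margins into absolute failure-difference
#' margins: `m20 = 0.20 * F_ref` and `m100 = 1.00 * F_ref`. A comparator
#' sitting exactly at the 100\% margin has double the reference's
#' cumulative failure probability.
#'
#' @param reference_failure Reference net failure in `[0, 1]`.
#' @param relative Relative-risk margins; default `c(0.20, 1.00)`.
#' @return List of class `margin_pair` with `m20`, `m100`, and
#'   `degenerate` (`TRUE` when the reference failure is 0, collapsing
#'   both margins to 0).
#' @export
margins_from_reference <- function(reference_failure,
                                   relative = c(0.20, 1.00)) {
  stopifnot(length(reference_failure) == 1L,
            reference_failure >= 0, reference_failure <= 1,
            length(relative) == 2L, all(relative > 0),
            relative[1] < relative[2])
  structure(list(
    m20 = relative[1] * reference_failure,
    m100 = relative[2] * reference_failure,
    relative = relative,
    degenerate = reference_failure == 0
  ), class = "margin_pair")
}

#' Select the internal reference construct
#'
#' The dynamic best-practice benchmark: among constructs with at least
#' `min_at_risk` procedures still at risk at the time point, the one with
#' the lowest net failure. Ties are broken by larger number at risk, then
#' by lexicographic construct label, so the choice is deterministic.
#'
#' @param estimates Data frame as returned by [construct_net_failure()].
#' @param min_at_risk Minimum at-risk count to qualify (default 1000).
#' @return The reference construct label (character scalar).
#' @export
select_reference <- function(estimates, min_at_risk = 1000) {
  ok <- estimates[estimates$n_at_risk >= min_at_risk &
                    !estimates$degenerate, , drop = FALSE]
  if (nrow(ok) == 0L) {
    stop(sprintf("no construct has at least %d at risk: cannot select a reference",
                 min_at_risk), call. = FALSE)
  }
  ord <- order(ok$failure, -ok$n_at_risk, ok$construct)
  ok$construct[ord[1]]
}

#' Eligible comparator constructs
#'
#' All constructs with at least `min_at_risk` still at risk at the time
#' point, excluding the reference itself.
#'
#' @inheritParams select_reference
#' @param reference Reference construct label.
#' @param min_at_risk Minimum at-risk count (default 500).
#' @return Data frame of comparator estimate rows (possibly zero rows).
#' @export
eligible_comparators <- function(estimates, reference, min_at_risk = 500) {
  out <- estimates[estimates$n_at_risk >= min_at_risk &
                     estimates$construct != reference, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Wald comparison of two net-failure estimates
#'
#' Difference in failure probabilities `diff = F_comp - F_ref`, pooled
#' Greenwood standard error `sqrt(Var_comp + Var_ref)`, symmetric normal
#' confidence interval on the difference, Wald statistic `z = diff / se`
#' and two-sided normal p-value. The p-value is descriptive only:
#' classification uses the CI limits.
#'
#' @param comp,ref `net_failure` objects (or lists with `failure` and
#'   `variance`) at the same time point.
#' @param alpha Confidence level complement (default 0.05).
#' @return List with `diff`, `se_diff`, `ci_low`, `ci_high`, `z`, `p`,
#'   and `degenerate` (`TRUE` for a zero SE with a nonzero difference).
#' @export
difference_test <- function(comp, ref, alpha = 0.05) {
  if (is.na(comp$variance) || is.na(ref$variance)) {
    stop("difference test requires finite variances for both estimates",
         call. = FALSE)
  }
  d <- comp$failure - ref$failure
  se <- sqrt(comp$variance + ref$variance)
  if (se == 0) {
    if (d == 0) {
      return(list(diff = 0, se_diff = 0, ci_low = 0, ci_high = 0,
                  z = 0, p = 1, degenerate = FALSE))
    }
    return(list(diff = d, se_diff = 0, ci_low = d, ci_high = d,
                z = NA_real_, p = NA_real_, degenerate = TRUE))
  }
  zq <- stats::qnorm(1 - alpha / 2)
  z <- d / se
  list(diff = d, se_diff = se,
       ci_low = d - zq * se, ci_high = d + zq * se,
       z = z, p = 2 * stats::pnorm(-abs(z)), degenerate = FALSE)
}

#' Five-band noninferiority classification
#'
#' Applies the margin rules to a confidence interval on the failure
#' difference, first match wins:
#' \enumerate{
#'   \item lower limit above `m100` — `inferior_100`;
#'   \item lower limit above `m20` — `inferior_20`;
#'   \item upper limit below `m20` — `noninferior_20`;
#'   \item upper limit below `m100` — `noninferior_100`;
#'   \item otherwise `inconclusive`.
#' }
#' Inferiority rules are evaluated before noninferiority rules, so a
#' narrow interval lying wholly between the margins is called
#' `inferior_20`. Comparisons are strict; exact equality with a margin
#' falls through to the weaker category.
#'
#' @param ci_low,ci_high Confidence limits of the failure difference.
#' @param margins A [margins_from_reference()] result.
#' @return One of `"inferior_100"`, `"inferior_20"`, `"noninferior_20"`,
#'   `"noninferior_100"`, `"inconclusive"`.
#' @export
classify <- function(ci_low, ci_high, margins) {
  stopifnot(inherits(margins, "margin_pair"), ci_low <= ci_high)
  if (ci_low > margins$m100) return("inferior_100")
  if (ci_low > margins$m20) return("inferior_20")
  if (ci_high < margins$m20) return("noninferior_20")
  if (ci_high < margins$m100) return("noninferior_100")
  "inconclusive"
}

# One report: reference + margins + classified comparator rows at (t, stratum).
.benchmark_at <- function(registry, t, stratum = "all", ref_min = 1000,
                          comp_min = 500, alpha = 0.05,
                          margins_relative = c(0.20, 1.00)) {
  groups <- group_by_construct(registry)
  estimates <- construct_net_failure(registry, t, alpha = alpha)
  reference <- select_reference(estimates, min_at_risk = ref_min)
  ref_est <- km_net_failure(groups[[reference]], t, alpha = alpha)
  margins <- margins_from_reference(ref_est$failure, relative = margins_relative)
  comps <- eligible_comparators(estimates, reference, min_at_risk = comp_min)
  n_excluded <- nrow(estimates) - nrow(comps) - 1L

  rows <- lapply(comps$construct, function(key) {
    est <- km_net_failure(groups[[key]], t, alpha = alpha)
    if (is.na(est$variance)) return(NULL)  # exhausted risk set: no comparison
    dt <- difference_test(est, ref_est, alpha = alpha)
    data.frame(
      t_years = t, stratum = stratum, reference = reference,
      ref_failure = ref_est$failure, ref_ci_low = ref_est$ci_low,
      ref_ci_high = ref_est$ci_high, construct = key,
      n_at_risk = est$n_at_risk, failure = est$failure,
      diff = dt$diff, se_diff = dt$se_diff,
      ci_low = dt$ci_low, ci_high = dt$ci_high, z = dt$z, p = dt$p,
      category = classify(dt$ci_low, dt$ci_high, margins),
      stringsAsFactors = FALSE
    )
  })
  rows <- do.call(rbind, rows)
  if (!is.null(rows)) {
    # caterpillar ordering: difference ascending, label as deterministic tie-break
    rows <- rows[order(rows$diff, rows$construct), , drop = FALSE]
    rownames(rows) <- NULL
  }
  structure(list(
    t = t, stratum = stratum, reference = reference,
    reference_estimate = ref_est, margins = margins,
    rows = rows, n_constructs = nrow(estimates),
    n_excluded = n_excluded, alpha = alpha
  ), class = "benchmark_report")
}

#' Benchmark every eligible construct against the internal reference
#'
#' The full analysis pipeline. At each requested time point (and within
#' each gender stratum, if requested) the function estimates per-construct
#' net failure by 1-Kaplan-Meier, selects the reference construct (lowest
#' failure with at least `ref_min` at risk), derives the 20\%/100\%
#' relative-risk margins from the reference's point estimate, runs the
#' pooled-Greenwood Wald comparison for every comparator with at least
#' `comp_min` at risk, and classifies each into the five noninferiority
#' bands. Time points (or strata) where no construct qualifies as a
#' reference are skipped with a message; the run continues.
#'
#' @param registry A [tkr_registry()].
#' @param timepoints Evaluation times in years (default `c(3, 5, 7, 10)`).
#' @param stratify_by `NULL` for a single all-procedures analysis, or
#'   `"gender"` to additionally recompute reference, margins and
#'   eligibility within each gender stratum. Records with unknown gender
#'   are excluded from stratified runs (with a message giving the count).
#' @param ref_min Minimum at-risk count for the reference (default 1000).
#' @param comp_min Minimum at-risk count for comparators (default 500).
#' @param alpha Confidence level complement (default 0.05).
#' @param margins_relative Relative-risk margins (default `c(0.2, 1.0)`).
#' @return Object of class `tkr_benchmark`: a list of `benchmark_report`
#'   objects (one per time point x stratum) plus the call settings.
#'   Skipped analyses are recorded in `$skipped`.
#' @examples
#' cfg <- nzjr_like_scenario(seed = 1)
#' reg <- generate_registry(cfg)
#' fit <- tkr_benchmark(reg, timepoints = c(3, 10))
#' summary(fit)
#' @export
tkr_benchmark <- function(registry, timepoints = c(3, 5, 7, 10),
                          stratify_by = NULL, ref_min = 1000,
                          comp_min = 500, alpha = 0.05,
                          margins_relative = c(0.20, 1.00)) {
  stopifnot(inherits(registry, "tkr_registry"))
  if (nrow(registry) == 0L) stop("registry is empty", call. = FALSE)
  if (!is.null(stratify_by) && !identical(stratify_by, "gender")) {
    stop("stratify_by must be NULL or \"gender\"", call. = FALSE)
  }

  strata <- list(all = registry)
  if (identical(stratify_by, "gender")) {
    known <- registry[registry$gender %in% c("F", "M"), , drop = FALSE]
    n_drop <- nrow(registry) - nrow(known)
    if (n_drop > 0L) {
      message(sprintf("excluding %d record(s) with unknown gender from stratified runs",
                      n_drop))
    }
    for (g in c("F", "M")) {
      sub <- known[known$gender == g, , drop = FALSE]
      class(sub) <- class(registry)
      strata[[g]] <- sub
    }
  }

  reports <- list()
  skipped <- list()
  for (s in names(strata)) {
    for (t in timepoints) {
      key <- sprintf("%s@%gy", s, t)
      rep_t <- tryCatch(
        .benchmark_at(strata[[s]], t, stratum = s, ref_min = ref_min,
                      comp_min = comp_min, alpha = alpha,
                      margins_relative = margins_relative),
        error = function(e) e
      )
      if (inherits(rep_t, "error")) {
        message(sprintf("skipping %s: %s", key, conditionMessage(rep_t)))
        skipped[[key]] <- conditionMessage(rep_t)
      } else {
        reports[[key]] <- rep_t
      }
    }
  }
  if (length(reports) == 0L) {
    stop("no time point produced a report (no qualifying reference anywhere)",
         call. = FALSE)
  }
  structure(list(
    reports = reports, skipped = skipped,
    timepoints = timepoints, stratify_by = stratify_by,
    ref_min = ref_min, comp_min = comp_min, alpha = alpha,
    margins_relative = margins_relative,
    n_records = nrow(registry)
  ), class = "tkr_benchmark")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("Benchmark at %g years (%s stratum)\n", x$t, x$stratum))
  cat(sprintf("  reference: %s, failure %.4f (CI %.4f-%.4f), %d at risk\n",
              x$reference, x$reference_estimate$failure,
              x$reference_estimate$ci_low, x$reference_estimate$ci_high,
              x$reference_estimate$n_at_risk))
  cat(sprintf("  margins: m20 = %.4f, m100 = %.4f\n",
              x$margins$m20, x$margins$m100))
  n_rows <- if (is.null(x$rows)) 0L else nrow(x$rows)
  cat(sprintf("  comparators: %d (of %d constructs)\n", n_rows,
              x$n_constructs))
  if (n_rows > 0L) {
    tab <- table(factor(x$rows$category, levels = .category_levels))
    tab <- tab[tab > 0]
    cat("  categories: ",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
print.tkr_benchmark <- function(x, ...) {
  cat(sprintf("TKR noninferiority benchmark: %d records, %d report(s)\n",
              x$n_records, length(x$reports)))
  for (r in x$reports) print(r)
  if (length(x$skipped) > 0L) {
    cat("skipped:\n")
    for (k in names(x$skipped)) cat(sprintf("  %s: %s\n", k, x$skipped[[k]]))
  }
  invisible(x)
}

#' @export
summary.tkr_benchmark <- function(object, ...) {
  rows <- as.data.frame(object)
  counts <- do.call(rbind, lapply(object$reports, function(r) {
    n_rows <- if (is.null(r$rows)) 0L else nrow(r$rows)
    tab <- table(factor(if (n_rows) r$rows$category else character(0),
                        levels = .category_levels))
    data.frame(t_years = r$t, stratum = r$stratum, reference = r$reference,
               ref_failure = r$reference_estimate$failure,
               n_comparators = n_rows, as.list(tab),
               stringsAsFactors = FALSE)
  }))
  rownames(counts) <- NULL
  structure(list(counts = counts, rows = rows,
                 skipped = object$skipped),
            class = "summary.tkr_benchmark")
}

#' @export
print.summary.tkr_benchmark <- function(x, ...) {
  cat("Category counts per report:\n")
  print(x$counts, row.names = FALSE)
  if (length(x$skipped) > 0L) {
    cat("skipped analyses:", paste(names(x$skipped), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Flatten a benchmark fit to a tidy data frame
#'
#' One row per comparator x time point x stratum, in the benchmark CSV
#' schema.
#'
#' @param x A `tkr_benchmark` object.
#' @param ... Unused.
#' @return Data frame with columns `t_years, stratum, reference,
#'   ref_failure, ref_ci_low, ref_ci_high, construct, n_at_risk, failure,
#'   diff, se_diff, ci_low, ci_high, z, p, category`.
#' @export
as.data.frame.tkr_benchmark <- function(x, ...) {
  rows <- do.call(rbind, lapply(x$reports, function(r) r$rows))
  if (is.null(rows)) {
    rows <- .benchmark_schema_frame()
  }
  rownames(rows) <- NULL
  rows
}

.benchmark_schema_frame <- function() {
  data.frame(t_years = numeric(0), stratum = character(0),
             reference = character(0), ref_failure = numeric(0),
             ref_ci_low = numeric(0), ref_ci_high = numeric(0),
             construct = character(0), n_at_risk = integer(0),
             failure = numeric(0), diff = numeric(0), se_diff = numeric(0),
             ci_low = numeric(0), ci_high = numeric(0), z = numeric(0),
             p = numeric(0), category = character(0),
             stringsAsFactors = FALSE)
}

#' Write benchmark results to CSV
#'
#' Exports the tidy per-comparator table (see
#' [as.data.frame.tkr_benchmark()]). An empty fit writes a header-only
#' file with a warning.
#'
#' @param x A `tkr_benchmark` or `benchmark_report` object.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_benchmark_csv <- function(x, path) {
  rows <- if (inherits(x, "benchmark_report")) {
    if (is.null(x$rows)) .benchmark_schema_frame() else x$rows
  } else {
    as.data.frame(x)
  }
  if (nrow(rows) == 0L) warning("no comparator rows: writing header only")
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
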
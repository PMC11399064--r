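# Control-based PRS deciles and sex-specific lifetime risk per decile.
#
# The central quantity: with L_s the sex-specific lifetime risk of the birth
# cohort (per 100,000), n_{d,s} the cases of sex s falling in decile d, N_s
# the total cases of sex s, and f_d the population fraction of the group
# (0.1 for a decile), the group lifetime risk per 100,000 is
#     risk_{d,s} = L_s * (n_{d,s} / N_s) / f_d
# rendered as "1 in N" with N = round(100,000 / risk).

#' Decile boundaries from the control score distribution
#'
#' Empirical quantiles at 0.1, ..., 0.9 of the control z-scores, using
#' linear interpolation of order statistics (`stats::quantile` type 7).
#'
#' @param control_z Numeric vector of control z-scores (>= 10 distinct
#'   values required).
#' @return Nine strictly ascending cutpoints.
#' @export
decile_boundaries <- function(control_z) {
  control_z <- control_z[is.finite(control_z)]
  if (length(control_z) < 10L || length(unique(control_z)) < 10L)
    stop("insufficient reference: need >= 10 distinct control scores")
  b <- stats::quantile(control_z, probs = seq(0.1, 0.9, by = 0.1),
                       type = 7, names = FALSE)
  if (any(diff(b) <= 0))
    stop("insufficient reference: decile boundaries are not distinct")
  b
}

#' Assign scores to control-based deciles
#'
#' Intervals are half-open on the left, `(b[k-1], b[k]]`: a score exactly on
#' a boundary falls in the lower decile, scores below the first boundary in
#' decile 1, and scores above the ninth boundary (including case scores
#' outside the control range) in decile 10.
#'
#' @param z Numeric scores (all finite).
#' @param boundaries Nine ascending cutpoints from [decile_boundaries()].
#' @return Integer vector of deciles in 1..10, same length as `z`, with the
#'   boundaries kept in attribute `boundaries`.
#' @export
assign_deciles <- function(z, boundaries) {
  if (any(!is.finite(z)))
    stop("invalid input: scores must be finite")
  if (length(boundaries) != 9L || any(diff(boundaries) <= 0))
    stop("invalid input: boundaries must be 9 ascending cutpoints")
  d <- 1L + findInterval(z, boundaries, left.open = TRUE)
  attr(d, "boundaries") <- boundaries
  d
}

#' Lifetime risk per PRS decile
#'
#' Applies the decile lifetime-risk formula `L_s * (n_d / N_s) / f_d` per
#' 100,000 and renders each risk as "1 in N" with `N = round(100,000 /
#' risk)` (nearest integer; exact halves follow R's round-half-to-even).
#' Cells with zero cases get risk 0 and no "1 in N" rendering.
#'
#' @param n_cases Integer vector of case counts, one per group.
#' @param total_cases Total cases of the sex, `N_s` (must be >= sum of
#'   `n_cases`).
#' @param lifetime_risk Sex-specific cohort lifetime risk `L_s` per 100,000.
#' @param fractions Population fraction `f_d` per group; 0.1 for a single
#'   decile, k/10 for a pooled k-decile group. Recycled to the length of
#'   `n_cases`.
#' @return A `data.frame` with `n_cases`, `proportion` (`n_d / N_s`),
#'   `risk_per_100k`, and `one_in_n` (`NA` where the risk is zero).
#' @examples
#' # top-decile women of a cohort with 206 female cases and L = 282/100,000
#' decile_lifetime_risk(79, 206, 282)  # "1 in 92"
#' @export
decile_lifetime_risk <- function(n_cases, total_cases, lifetime_risk,
                                 fractions = 0.1) {
  if (length(total_cases) != 1L || is.na(total_cases) || total_cases <= 0)
    stop("invalid input: total_cases must be a single positive count")
  if (any(n_cases < 0) || sum(n_cases) > total_cases)
    stop("invalid input: case counts must be >= 0 and sum to <= total_cases")
  if (lifetime_risk <= 0)
    stop("invalid input: lifetime_risk must be > 0")
  fractions <- rep_len(fractions, length(n_cases))
  if (any(fractions <= 0 | fractions > 1))
    stop("invalid input: fractions must lie in (0, 1]")
  proportion <- n_cases / total_cases
  risk <- lifetime_risk * proportion / fractions
  one_in_n <- ifelse(risk > 0, round(1e5 / risk), NA_real_)
  data.frame(n_cases = n_cases, proportion = proportion,
             risk_per_100k = risk, one_in_n = one_in_n)
}

#' Lifetime risk for a pooled, contiguous decile range
#'
#' Sums the case counts over the range and applies the decile formula with
#' `f = length(range) / 10`.
#'
#' @param deciles Contiguous integer range of deciles (e.g. `1:3`).
#' @param n_cases_by_decile Case counts for all 10 deciles of the sex.
#' @param total_cases,lifetime_risk As in [decile_lifetime_risk()].
#' @return A one-row `data.frame` as from [decile_lifetime_risk()].
#' @examples
#' pooled_group_risk(1:3, c(3, 3, 2, 8, 15, 25, 22, 30, 19, 79), 206, 282)
#' @export
pooled_group_risk <- function(deciles, n_cases_by_decile, total_cases,
                              lifetime_risk) {
  if (length(deciles) == 0L)
    stop("invalid input: empty decile range")
  deciles <- sort(as.integer(deciles))
  if (any(deciles < 1L | deciles > 10L) ||
      !identical(deciles, seq(min(deciles), max(deciles))))
    stop("invalid input: deciles must be a contiguous range within 1..10")
  if (length(n_cases_by_decile) != 10L)
    stop("invalid input: n_cases_by_decile must have 10 entries")
  decile_lifetime_risk(sum(n_cases_by_decile[deciles]), total_cases,
                       lifetime_risk, fractions = length(deciles) / 10)
}

#' Cohort lifetime risk from case and birth counts
#'
#' @param n_cases Lifetime cases observed in the birth cohort.
#' @param n_births Live births of that sex in the cohort.
#' @return Lifetime risk per 100,000 (unrounded).
#' @examples
#' cohort_lifetime_risk(329, 116745)  # ~282 per 100,000
#' @export
cohort_lifetime_risk <- function(n_cases, n_births) {
  if (n_births <= 0) stop("invalid input: n_births must be > 0")
  if (n_cases < 0) stop("invalid input: n_cases must be >= 0")
  n_cases / n_births * 1e5
}

#' Monte-Carlo population for one risk group
#'
#' Simulates a population of `n_pop` births: the affected count is drawn
#' Binomial(`n_pop`, `risk` / 100,000) and each affected individual receives
#' an onset age resampled from the group's empirical onset distribution.
#'
#' @param n_pop Population size (default 100,000).
#' @param risk Group lifetime risk per 100,000.
#' @param onset_ages Observed onset ages defining the empirical onset
#'   distribution; may be empty only when `risk` is 0.
#' @param seed Optional integer seed.
#' @return A list with `n_pop`, `n_affected`, and `onset_ages` of the
#'   affected individuals.
#' @export
simulate_decile_population <- function(n_pop = 1e5, risk, onset_ages,
                                       seed = NULL) {
  if (risk < 0 || risk > 1e5)
    stop("invalid input: risk must lie in [0, 100000]")
  if (risk > 0 && length(onset_ages) == 0L)
    stop("invalid input: empty onset distribution with positive risk")
  if (!is.null(seed)) set.seed(seed)
  n_aff <- stats::rbinom(1L, as.integer(n_pop), risk / 1e5)
  ages <- if (n_aff > 0L) sample(onset_ages, n_aff, replace = TRUE)
          else numeric(0)
  list(n_pop = as.integer(n_pop), n_affected = n_aff, onset_ages = ages)
}

#' Cumulative risk-by-age curve for a risk group
#'
#' `curve(age) = lifetime_risk * ECDF_onset(age)`: the cumulative risk rises
#' with the group's empirical onset distribution and ends at the group's
#' lifetime risk. The event percentages (`100 * ECDF`) reproduce the
#' "percentage of events per time point" risk-table annotation.
#'
#' @param onset_ages Onset ages of the group's cases.
#' @param lifetime_risk Group lifetime risk per 100,000.
#' @param age_grid Ascending ages (years) at which to evaluate the curve.
#' @return A `data.frame` of class `risk_curve` with `age`,
#'   `cum_risk_per_100k` (nondecreasing), and `pct_events`.
#' @export
cumulative_risk_curve <- function(onset_ages, lifetime_risk, age_grid) {
  if (is.unsorted(age_grid, strictly = FALSE))
    stop("invalid input: age_grid must be ascending")
  e <- if (length(onset_ages)) stats::ecdf(onset_ages)(age_grid)
       else rep(0, length(age_grid))
  out <- data.frame(age = age_grid,
                    cum_risk_per_100k = lifetime_risk * e,
                    pct_events = 100 * e)
  class(out) <- c("risk_curve", "data.frame")
  out
}

#' Ratio of two group lifetime risks
#'
#' @param risk_a,risk_b Risks per 100,000 for the two groups (numerator,
#'   denominator); `risk_b` must be positive.
#' @return The relative risk `risk_a / risk_b`.
#' @export
relative_risk <- function(risk_a, risk_b) {
  if (risk_b <= 0) stop("undefined ratio: denominator risk must be > 0")
  risk_a / risk_b
}

#' Fit the decile lifetime-risk model to a scored cohort
#'
#' The package's core estimator. Decile boundaries are taken from the
#' control z-score distribution; every participant is assigned a decile;
#' per sex, the decile formula converts the case distribution over deciles
#' into absolute lifetime risk per 100,000, together with pooled groups
#' (by default the bottom three deciles and the top decile) and per-cell
#' onset-age summaries.
#'
#' @param z Numeric z-scores, one per participant.
#' @param sex Character vector, `"F"` or `"M"`.
#' @param status Character vector, `"MS"` or `"control"`.
#' @param onset Optional onset ages (NA for controls), used for per-cell
#'   medians/IQRs and the [plot][plot.decile_risk_fit] method.
#' @param lifetime_risk Named per-100,000 risks, `c(F = ..., M = ...)`.
#' @param pooled Named list of contiguous decile ranges to pool.
#' @return An object of class `decile_risk_fit` with elements `boundaries`,
#'   `decile` (per participant), `table` (per sex x decile rows), `pooled`,
#'   and the inputs needed by the methods.
#' @seealso [decile_lifetime_risk()], [pooled_group_risk()],
#'   [cumulative_risk_curve()]
#' @export
fit_decile_risk <- function(z, sex, status, onset = NULL,
                            lifetime_risk = c(F = 282, M = 100),
                            pooled = list("deciles 1-3" = 1:3,
                                          "decile 10" = 10L)) {
  n <- length(z)
  stopifnot(length(sex) == n, length(status) == n)
  if (!all(sex %in% c("F", "M"))) stop("sex must be 'F' or 'M'")
  if (!all(status %in% c("MS", "control")))
    stop("status must be 'MS' or 'control'")
  if (!all(c("F", "M") %in% names(lifetime_risk)))
    stop("lifetime_risk must be named c(F = ..., M = ...)")
  ctrl <- status == "control"
  boundaries <- decile_boundaries(z[ctrl])
  decile <- assign_deciles(z, boundaries)

  per_sex <- lapply(c(F = "F", M = "M"), function(s) {
    case <- status == "MS" & sex == s
    counts <- tabulate(decile[case], nbins = 10L)
    tab <- if (sum(case) > 0L) {
      decile_lifetime_risk(counts, total_cases = sum(case),
                           lifetime_risk = lifetime_risk[[s]],
                           fractions = 0.1)
    } else {
      data.frame(n_cases = counts, proportion = 0, risk_per_100k = 0,
                 one_in_n = NA_real_)
    }
    tab <- cbind(sex = s, decile = 1:10, tab)
    if (!is.null(onset)) {
      tab$onset_median <- tab$onset_iqr <- NA_real_
      for (d in 1:10) {
        a <- onset[case & decile == d]
        a <- a[!is.na(a)]
        if (length(a)) {
          tab$onset_median[d] <- stats::median(a)
          tab$onset_iqr[d] <- stats::IQR(a, type = 7)
        }
      }
    }
    list(table = tab, counts = counts, n_cases = sum(case))
  })
  table <- do.call(rbind, lapply(per_sex, `[[`, "table"))
  rownames(table) <- NULL

  pooled_tab <- do.call(rbind, lapply(names(pooled), function(nm) {
    rng <- pooled[[nm]]
    do.call(rbind, lapply(c("F", "M"), function(s) {
      ps <- per_sex[[s]]
      if (ps$n_cases == 0L) return(NULL)
      row <- pooled_group_risk(rng, ps$counts, ps$n_cases,
                               lifetime_risk[[s]])
      cbind(sex = s, group = nm, row)
    }))
  }))
  if (!is.null(pooled_tab)) rownames(pooled_tab) <- NULL

  structure(list(boundaries = boundaries, decile = decile, table = table,
                 pooled = pooled_tab, lifetime_risk = lifetime_risk,
                 pooled_ranges = pooled,
                 data = data.frame(z = z, sex = sex, status = status,
                                   onset = if (is.null(onset)) NA_real_
                                           else onset,
                                   decile = as.integer(decile))),
            class = "decile_risk_fit")
}

format_one_in_n <- function(x) {
  ifelse(is.na(x), "-", paste("1 in", formatC(x, format = "d", big.mark = ",")))
}

#' @export
print.decile_risk_fit <- function(x, ...) {
  cat("Lifetime risk per PRS decile (control-based deciles)\n\n")
  for (s in c("F", "M")) {
    tab <- x$table[x$table$sex == s, , drop = FALSE]
    cat(sprintf("%s (N cases = %d, cohort lifetime risk %g per 100,000):\n",
                if (s == "F") "Women" else "Men",
                sum(tab$n_cases), x$lifetime_risk[[s]]))
    out <- data.frame(decile = tab$decile, cases = tab$n_cases,
                      pct = sprintf("%.1f", 100 * tab$proportion),
                      risk_per_100k = sprintf("%.1f", tab$risk_per_100k),
                      lifetime_risk = format_one_in_n(tab$one_in_n))
    print(out, row.names = FALSE)
    cat("\n")
  }
  invisible(x)
}

#' @export
summary.decile_risk_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.decile_risk_fit")
}

#' @export
print.summary.decile_risk_fit <- function(x, ...) {
  fit <- x$fit
  print(fit)
  if (!is.null(fit$pooled)) {
    cat("Pooled groups:\n")
    out <- data.frame(sex = fit$pooled$sex, group = fit$pooled$group,
                      cases = fit$pooled$n_cases,
                      risk_per_100k = sprintf("%.2f",
                                              fit$pooled$risk_per_100k),
                      lifetime_risk = format_one_in_n(fit$pooled$one_in_n))
    print(out, row.names = FALSE)
    cat("\n")
    # relative risk of the last pooled group vs the first, per sex
    nms <- unique(fit$pooled$group)
    if (length(nms) >= 2L) {
      for (s in unique(fit$pooled$sex)) {
        a <- fit$pooled$risk_per_100k[fit$pooled$sex == s &
                                        fit$pooled$group == nms[length(nms)]]
        b <- fit$pooled$risk_per_100k[fit$pooled$sex == s &
                                        fit$pooled$group == nms[1L]]
        if (length(a) == 1L && length(b) == 1L && b > 0)
          cat(sprintf("Relative risk (%s), %s vs %s: %.1f\n",
                      s, nms[length(nms)], nms[1L], relative_risk(a, b)))
      }
    }
  }
  invisible(x)
}

#' Plot cumulative lifetime risk by age per decile
#'
#' One line per decile: `risk_d * ECDF(onset ages in decile d)` over the age
#' grid, for the requested sex. Requires onset ages in the fit.
#'
#' @param x A `decile_risk_fit`.
#' @param sex `"F"` or `"M"`.
#' @param age_grid Ages at which to evaluate the curves.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, the matrix of curves (age x decile).
#' @export
plot.decile_risk_fit <- function(x, sex = "F", age_grid = 0:60, ...) {
  d <- x$data
  if (all(is.na(d$onset)))
    stop("fit has no onset ages; refit with onset = ...")
  tab <- x$table[x$table$sex == sex, , drop = FALSE]
  curves <- sapply(1:10, function(dd) {
    ages <- d$onset[d$status == "MS" & d$sex == sex & d$decile == dd]
    ages <- ages[!is.na(ages)]
    cumulative_risk_curve(ages, tab$risk_per_100k[dd],
                          age_grid)$cum_risk_per_100k
  })
  graphics::matplot(age_grid, curves, type = "s", lty = 1, col = 1:10,
                    xlab = "Age at onset (years)",
                    ylab = "Cumulative lifetime risk per 100,000",
                    main = sprintf("Lifetime MS risk by PRS decile (%s)",
                                   if (sex == "F") "women" else "men"), ...)
  graphics::legend("topleft", legend = paste("decile", 1:10), col = 1:10,
                   lty = 1, cex = 0.7, bty = "n")
  invisible(curves)
}
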
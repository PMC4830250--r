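# Accuracy scoring of the estimator family against planimetry:
# absolute percentage deviations and their bins, per-case closest-value
# tallies, Levene-gated independent t-tests and Bland-Altman limits of
# agreement, assembled into a per-variation summary table.

#' Absolute percentage deviation from a reference
#'
#' `|estimate - reference| / reference * 100`. Deviations are reported
#' unsigned: the study's printed deviation ranges are non-negative,
#' which fixes the absolute-value convention.
#'
#' @param estimate,reference volumes in mL (vectorised); `reference`
#'   must be positive.
#' @return percentage deviation(s).
#' @export
percentage_deviation <- function(estimate, reference) {
  if (any(reference <= 0) || anyNA(reference))
    stop("`reference` must be positive")
  abs(estimate - reference) / reference * 100
}

#' Closest-value counts across variations
#'
#' For each case, the variation whose estimate is nearest (smallest
#' absolute difference) to the reference earns one win. Differences
#' within `tie_tol` mL of the case minimum are treated as tied; ties go
#' to the earliest-listed tied variation under the default policy
#' (`"first"`), to the last under `"last"`, or to a seeded random pick
#' under `"random"`. Counts always sum to the number of cases.
#'
#' @param estimates matrix or data frame, one column per variation (the
#'   column order defines the listing order used by the tie policy).
#' @param references numeric vector of reference volumes, one per row.
#' @param tie_policy `"first"` (default), `"last"` or `"random"`.
#' @param tie_tol absolute tolerance in mL for detecting ties; defaults
#'   to 1e-8, which absorbs last-ulp noise in text-parsed tables.
#' @param seed used only by the `"random"` policy.
#' @return list of class `closest_value_counts`: `counts` (named integer
#'   vector), `tie_policy`, `n_tied_cases`.
#' @export
closest_value_counts <- function(estimates, references,
                                 tie_policy = c("first", "last", "random"),
                                 tie_tol = 1e-8, seed = 0L) {
  tie_policy <- match.arg(tie_policy)
  est <- as.matrix(estimates)
  if (!nrow(est) || !ncol(est)) stop("`estimates` must be non-empty")
  if (nrow(est) != length(references))
    stop("`estimates` rows and `references` length differ")
  d <- abs(est - references)
  dmin <- do.call(pmin, as.data.frame(d))
  tied <- d <= dmin + tie_tol
  n_tied <- sum(rowSums(tied) > 1L)
  pick_one <- function(i) {
    cand <- which(tied[i, ])
    switch(tie_policy,
           first = cand[1L],
           last = cand[length(cand)],
           random = if (length(cand) == 1L) cand else
             .with_seed(seed + i, function() sample(cand, 1L)))
  }
  win <- vapply(seq_len(nrow(est)), pick_one, integer(1))
  nm <- colnames(est)
  if (is.null(nm)) nm <- as.character(seq_len(ncol(est)))
  counts <- table(factor(nm[win], levels = nm))
  structure(list(counts = stats::setNames(as.integer(counts), nm),
                 tie_policy = tie_policy, n_tied_cases = n_tied),
            class = "closest_value_counts")
}

#' @export
print.closest_value_counts <- function(x, ...) {
  cat(sprintf("<closest_value_counts> policy '%s', %d tied case(s)\n",
              x$tie_policy, x$n_tied_cases))
  print(x$counts)
  invisible(x)
}

#' Bin percentage deviations at 10% and 20%
#'
#' Boundaries follow the study's table convention: "<10%" is strict, so
#' a deviation of exactly 10 or 20 falls in the middle "10-20%" bin.
#'
#' @param deviations non-negative percentage deviations.
#' @return named integer vector `lt10`, `b10_20`, `gt20`.
#' @export
deviation_bins <- function(deviations) {
  if (!length(deviations)) stop("`deviations` must be non-empty")
  if (any(deviations < 0) || anyNA(deviations))
    stop("`deviations` must be non-negative")
  c(lt10 = sum(deviations < 10),
    b10_20 = sum(deviations >= 10 & deviations <= 20),
    gt20 = sum(deviations > 20))
}

# Levene's test with center = mean for two samples: the classic one-way
# ANOVA on absolute deviations from the group mean.
.levene_p <- function(a, b) {
  z <- c(abs(a - mean(a)), abs(b - mean(b)))
  g <- factor(rep(1:2, c(length(a), length(b))))
  if (stats::sd(z) == 0) return(1)
  stats::oneway.test(z ~ g, var.equal = TRUE)$p.value
}

#' Compare estimate and reference means (Levene-gated t-test)
#'
#' Levene's test (center = mean) screens the two samples for equal
#' variances; when its p-value exceeds `alpha` the pooled-variance
#' independent two-sample t-test is used, otherwise Welch's. Both tests
#' are two-sided and unpaired.
#'
#' @param estimates,references numeric vectors (each >= 2 values).
#' @param alpha variance-homogeneity gate, default 0.05.
#' @return list `levene_p`, `t_p`, `variant_used` (`"pooled"` or
#'   `"welch"`).
#' @export
compare_means <- function(estimates, references, alpha = 0.05) {
  if (length(estimates) < 2L || length(references) < 2L)
    stop("both samples need at least 2 values")
  if (stats::sd(estimates) == 0 && stats::sd(references) == 0) {
    if (isTRUE(all.equal(mean(estimates), mean(references))))
      return(list(levene_p = 1, t_p = 1, variant_used = "pooled"))
    stop("both samples are constant with different means: t-test undefined")
  }
  lev <- .levene_p(estimates, references)
  pooled <- lev > alpha
  tt <- stats::t.test(estimates, references, var.equal = pooled)
  list(levene_p = lev, t_p = tt$p.value,
       variant_used = if (pooled) "pooled" else "welch")
}

#' Bland-Altman agreement statistics
#'
#' Differences `estimate - reference`: their mean (bias), sample SD,
#' limits of agreement mean +/- 1.96 SD, the proportion of cases inside
#' the limits, and the plotting payload (pair mean vs difference).
#'
#' @param estimates,references numeric vectors of equal length >= 2.
#' @return An object of class `agreement_stats`: `mean_difference_mL`,
#'   `sd_difference_mL`, `loa_low_mL`, `loa_high_mL`,
#'   `proportion_within_loa`, `payload` (data frame `mean_pair`,
#'   `difference`).
#' @export
bland_altman <- function(estimates, references) {
  if (length(estimates) != length(references))
    stop("`estimates` and `references` must have equal length")
  if (length(estimates) < 2L) stop("at least 2 pairs are required")
  d <- estimates - references
  m <- mean(d); s <- stats::sd(d)
  lo <- m - 1.96 * s; hi <- m + 1.96 * s
  structure(list(mean_difference_mL = m, sd_difference_mL = s,
                 loa_low_mL = lo, loa_high_mL = hi,
                 proportion_within_loa = mean(d >= lo & d <= hi),
                 payload = data.frame(mean_pair = (estimates + references) / 2,
                                      difference = d)),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("<agreement_stats> bias %.2f mL, LoA [%.2f, %.2f], %.0f%% within\n",
              x$mean_difference_mL, x$loa_low_mL, x$loa_high_mL,
              100 * x$proportion_within_loa))
  invisible(x)
}

#' Plot a Bland-Altman payload
#'
#' @param stats an [bland_altman()] result.
#' @param main plot title.
#' @return the input, invisibly. Draws on the active graphics device.
#' @export
plot_bland_altman <- function(stats, main = "Bland-Altman") {
  stopifnot(inherits(stats, "agreement_stats"))
  p <- stats$payload
  plot(p$mean_pair, p$difference, xlab = "Mean of methods (mL)",
       ylab = "Difference (mL)", main = main, pch = 19)
  graphics::abline(h = c(stats$loa_low_mL, stats$mean_difference_mL,
                         stats$loa_high_mL),
                   lty = c(2, 1, 2))
  invisible(stats)
}

#' Summarise estimator accuracy over a cohort
#'
#' Builds the per-variation summary table: mean, SD and range of the
#' estimates; Levene-gated t-test against planimetry; closest-value
#' counts at intra-group scope (each group separately) and overall
#' scope (all variations together); deviation mean/SD/range and bins;
#' Bland-Altman agreement.
#'
#' @param table cohort data frame with a `planimetry` column and one
#'   column per variation estimate, or a list of `case_record`s (see
#'   [cases_to_table()]).
#' @param variations character vector naming the estimate columns, in
#'   listing order; defaults to every `v`-prefixed column.
#' @param groups named list partitioning `variations` for the
#'   intra-group closest scope; defaults to the traditional/new split
#'   when the default eight columns are present, otherwise one group.
#' @param tie_policy,tie_tol forwarded to [closest_value_counts()].
#' @return An object of class `evaluation_summary`: `table` (one row per
#'   variation), `agreement` (named list of [bland_altman()] results),
#'   `closest_overall`, `closest_intra`, `n`, `tie_policy`.
#' @export
summarize_cohort <- function(table, variations = NULL, groups = NULL,
                             tie_policy = "first", tie_tol = 1e-8) {
  if (is.list(table) && !is.data.frame(table) &&
      all(vapply(table, inherits, logical(1), "case_record")))
    table <- cases_to_table(table)
  if (!is.data.frame(table) || !"planimetry" %in% names(table))
    stop("`table` must be a data frame with a `planimetry` column")
  if (nrow(table) < 3L) stop("at least 3 cases are required")
  if (is.null(variations))
    variations <- grep("^v", names(table), value = TRUE)
  if (!length(variations) || !all(variations %in% names(table)))
    stop("estimate columns not found")
  if (is.null(groups)) {
    std <- c("v1", "v2", "v3", "v4"); new <- c("v1p", "v2p", "v3p", "v4p")
    groups <- if (all(c(std, new) %in% variations))
      list(traditional = std, new = new) else list(all = variations)
  }
  ref <- table$planimetry
  est <- as.matrix(table[variations])
  overall <- closest_value_counts(est, ref, tie_policy, tie_tol)
  intra <- stats::setNames(numeric(length(variations)), variations)
  intra_by_group <- lapply(groups, function(g)
    closest_value_counts(est[, g, drop = FALSE], ref, tie_policy, tie_tol))
  for (g in intra_by_group) intra[names(g$counts)] <- g$counts
  rows <- lapply(variations, function(v) {
    x <- table[[v]]
    dev <- percentage_deviation(x, ref)
    bins <- deviation_bins(dev)
    cm <- compare_means(x, ref)
    data.frame(variation = v, n = length(x),
               mean_mL = mean(x), sd_mL = stats::sd(x),
               min_mL = min(x), max_mL = max(x),
               levene_p = cm$levene_p, t_p = cm$t_p,
               t_variant = cm$variant_used,
               closest_intra = intra[[v]],
               closest_overall = overall$counts[[v]],
               dev_mean_pct = mean(dev), dev_sd_pct = stats::sd(dev),
               dev_min_pct = min(dev), dev_max_pct = max(dev),
               n_lt10 = bins[["lt10"]], n_10_20 = bins[["b10_20"]],
               n_gt20 = bins[["gt20"]],
               pct_lt10 = 100 * bins[["lt10"]] / length(x),
               pct_10_20 = 100 * bins[["b10_20"]] / length(x),
               pct_gt20 = 100 * bins[["gt20"]] / length(x),
               stringsAsFactors = FALSE)
  })
  agreement <- lapply(stats::setNames(variations, variations),
                      function(v) bland_altman(table[[v]], ref))
  structure(list(table = do.call(rbind, rows),
                 agreement = agreement,
                 closest_overall = overall,
                 closest_intra = intra_by_group,
                 n = nrow(table), tie_policy = tie_policy),
            class = "evaluation_summary")
}

#' @export
print.evaluation_summary <- function(x, ...) {
  cat(sprintf("<evaluation_summary> %d cases, tie policy '%s'\n",
              x$n, x$tie_policy))
  d <- x$table
  out <- data.frame(variation = d$variation,
                    estimate = sprintf("%.2f ± %.2f", d$mean_mL, d$sd_mL),
                    p = signif(d$t_p, 2),
                    closest = sprintf("%d/%d | %d/%d", d$closest_intra, d$n,
                                      d$closest_overall, d$n),
                    dev_pct = sprintf("%.2f ± %.2f", d$dev_mean_pct,
                                      d$dev_sd_pct),
                    lt10 = d$n_lt10, b10_20 = d$n_10_20, gt20 = d$n_gt20)
  print(out, row.names = FALSE)
  invisible(x)
}

#' Convert case records to a cohort table
#'
#' One row per [case_record()], with planimetry, measured lengths,
#' products and per-variation estimate columns (`v` + variation name).
#'
#' @param records list of `case_record` objects.
#' @return data frame.
#' @export
cases_to_table <- function(records) {
  if (!length(records)) stop("`records` must be non-empty")
  do.call(rbind, lapply(records, as.data.frame))
}
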
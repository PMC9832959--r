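#' Welch two-sample t-test (unequal variances)
#'
#' `t = (m_a - m_b) / sqrt(s2_a/n_a + s2_b/n_b)` with Welch-Satterthwaite
#' degrees of freedom and a two-sided p from the t distribution. Also
#' accepts the summary form via [welch_t_from_summary()]. When both groups
#' have zero variance and equal means, p = 1 by convention.
#'
#' @param group_a,group_b numeric vectors (each n >= 2).
#' @return list: `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
welch_t_test <- function(group_a, group_b) {
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs n >= 2 finite values")
  welch_t_from_summary(mean(group_a), sd(group_a), length(group_a),
                       mean(group_b), sd(group_b), length(group_b))
}

#' Welch t-test from group summaries
#'
#' @param mean_a,mean_b group means.
#' @param spread_a,spread_b group SD (default) or SEM per `spread_type`;
#'   SEM is converted with `sd = sem * sqrt(n)`.
#' @param n_a,n_b group sizes (>= 2).
#' @param spread_type `"sd"` or `"sem"`.
#' @return list: `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
welch_t_from_summary <- function(mean_a, spread_a, n_a, mean_b, spread_b, n_b,
                                 spread_type = c("sd", "sem")) {
  spread_type <- match.arg(spread_type)
  if (n_a < 2 || n_b < 2) stop("each group needs n >= 2")
  sd_a <- if (spread_type == "sem") spread_a * sqrt(n_a) else spread_a
  sd_b <- if (spread_type == "sem") spread_b * sqrt(n_b) else spread_b
  va <- sd_a^2 / n_a; vb <- sd_b^2 / n_b
  if (va + vb == 0) {
    if (mean_a == mean_b) return(list(t = 0, df = NA_real_, p = 1,
                                      mean_a = mean_a, mean_b = mean_b))
    stop("both variances are zero with unequal means: t undefined")
  }
  t <- (mean_a - mean_b) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
       mean_a = mean_a, mean_b = mean_b)
}

#' Per-timepoint Welch comparison of two growth curves
#'
#' Runs [welch_t_test()] on replicate counts at every shared timepoint and
#' flags significance at 0.05 and 0.01. No multiplicity correction is
#' applied (and the output says so), matching the assay's per-timepoint
#' reporting.
#'
#' @param curve_a,curve_b `growth_curves` rows for a single condition each
#'   (data.frames with `day`, `count`).
#' @return data.frame: `day`, `mean_a`, `mean_b`, `t`, `df`, `p`,
#'   `sig_05`, `sig_01`; attribute `multiplicity_correction = "none"`.
#' @export
compare_growth_curves <- function(curve_a, curve_b) {
  days <- intersect(unique(curve_a$day), unique(curve_b$day))
  if (!length(days)) stop("curves share no timepoints")
  rows <- lapply(sort(days), function(d) {
    w <- welch_t_test(curve_a$count[curve_a$day == d],
                      curve_b$count[curve_b$day == d])
    data.frame(day = d, mean_a = w$mean_a, mean_b = w$mean_b,
               t = w$t, df = w$df, p = w$p,
               sig_05 = w$p < 0.05, sig_01 = w$p < 0.01)
  })
  out <- do.call(rbind, rows)
  attr(out, "multiplicity_correction") <- "none"
  out
}

#' Monotone association between growth rate and nuclear size
#'
#' Spearman correlation between the per-interval growth rate (log count
#' ratio per day, from replicate-mean counts) and the mean nuclear area at
#' the interval start. A negative coefficient is the expected
#' differentiation signature: proliferation slows as nuclei enlarge towards
#' the plateau.
#'
#' @param curve `growth_curves` rows for one condition (columns `day`,
#'   `count`, `mean_area`), >= 3 timepoints.
#' @return list: `rho`, `direction` (`"negative"`/`"positive"`/`"none"`),
#'   `n_intervals`; `rho` is `NA` (direction `"none"`) for constant series.
#' @export
size_growth_correlation <- function(curve) {
  days <- sort(unique(curve$day))
  if (length(days) < 3) stop("need >= 3 timepoints")
  mc <- vapply(days, function(d) mean(curve$count[curve$day == d]), numeric(1))
  ma <- vapply(days, function(d) mean(curve$mean_area[curve$day == d]), numeric(1))
  k <- length(days) - 1
  rate <- (log(mc[-1]) - log(mc[-length(mc)])) / diff(days)
  size0 <- ma[-length(ma)]
  if (sd(rate) == 0 || sd(size0) == 0)
    return(list(rho = NA_real_, direction = "none", n_intervals = k))
  rho <- stats::cor(rate, size0, method = "spearman")
  list(rho = rho,
       direction = if (rho < 0) "negative" else if (rho > 0) "positive" else "none",
       n_intervals = k)
}

#' Relative expression by the delta-delta-Ct method
#'
#' Per sample: `dCt = Ct_target - Ct_reference` (normalisation to the
#' housekeeping gene); `ddCt = dCt - mean(dCt of the calibrator group)` per
#' gene; relative expression `= 2^(-ddCt)`. The calibrator aggregation is
#' the arithmetic mean of dCt, i.e. the geometric mean of calibrator folds
#' is 1 by construction. Samples missing either Ct are dropped and logged.
#'
#' @param records a `qpcr_records` data.frame (`sample`, `group`, `gene`,
#'   `ct_target`, `ct_reference`).
#' @param calibrator_group label of the calibrator group (must be present
#'   for every gene).
#' @return list: `samples` (per-sample `dct`, `ddct`, `rel_expr`) and
#'   `summary` (per gene x group: mean, sd, sem, n of relative expression).
#' @export
delta_delta_ct <- function(records, calibrator_group) {
  stopifnot(all(c("sample", "group", "gene", "ct_target", "ct_reference")
                %in% names(records)))
  ok <- is.finite(records$ct_target) & is.finite(records$ct_reference)
  if (any(!ok)) message(sum(!ok), " sample(s) missing a Ct value; dropped")
  rec <- records[ok, , drop = FALSE]
  if (!any(rec$group == calibrator_group))
    stop("calibrator group '", calibrator_group, "' is empty")
  rec$dct <- rec$ct_target - rec$ct_reference
  rec$ddct <- NA_real_
  for (g in unique(rec$gene)) {
    cal <- rec$gene == g & rec$group == calibrator_group
    if (!any(cal)) stop("calibrator group missing for gene ", g)
    rec$ddct[rec$gene == g] <- rec$dct[rec$gene == g] - mean(rec$dct[cal])
  }
  rec$rel_expr <- 2^(-rec$ddct)
  grp <- interaction(rec$gene, rec$group, drop = TRUE)
  summary <- data.frame(
    gene = tapply(rec$gene, grp, `[`, 1),
    group = tapply(rec$group, grp, `[`, 1),
    n = as.integer(tapply(rec$rel_expr, grp, length)),
    mean_fold = as.numeric(tapply(rec$rel_expr, grp, mean)),
    sd_fold = as.numeric(tapply(rec$rel_expr, grp, sd)),
    stringsAsFactors = FALSE)
  summary$sem_fold <- summary$sd_fold / sqrt(summary$n)
  summary <- summary[order(summary$gene, summary$group != calibrator_group), ]
  rownames(summary) <- NULL
  list(samples = rec, summary = summary)
}
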
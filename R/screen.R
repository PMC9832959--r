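#' Plate median and raw MAD of well counts
#'
#' The screen's dispersion statistic: the sample median of per-well counts
#' and the median of absolute deviations from it. The MAD is deliberately
#' left UNSCALED (no 1.4826 normal-consistency factor) — the hit band is
#' defined directly in raw MAD units.
#'
#' @param counts numeric vector of per-well cell counts (>= 2 finite values).
#' @return list: `median`, `mad`, `n`, `degenerate` (TRUE when mad == 0).
#' @examples
#' plate_mad(c(10, 12, 14, 100))  # median 13, mad 2
#' @export
plate_mad <- function(counts) {
  counts <- counts[is.finite(counts)]
  if (length(counts) < 2) stop("plate_mad needs >= 2 finite values")
  med <- stats::median(counts)
  m <- stats::median(abs(counts - med))
  list(median = med, mad = m, n = length(counts), degenerate = m == 0)
}

plate_stats_table <- function(measurements, include_controls = TRUE) {
  use <- measurements$role == "compound" |
    (include_controls & measurements$role == "control")
  dat <- measurements[use, , drop = FALSE]
  groups <- unique(dat[, c("plate_id", "sex")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    sel <- dat$plate_id == groups$plate_id[i] & dat$sex == groups$sex[i]
    pm <- plate_mad(dat$cell_count[sel])
    sa <- dat$mean_nuclear_area[sel]
    sa <- sa[is.finite(sa)]
    sm <- if (length(sa) >= 2) plate_mad(sa) else list(median = NA_real_, mad = NA_real_)
    data.frame(plate_id = groups$plate_id[i], sex = groups$sex[i],
               median_count = pm$median, mad_count = pm$mad,
               n_wells_used = pm$n, degenerate = pm$degenerate,
               median_area = sm$median, mad_area = sm$mad,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Call hyper/hypo hits per plate per sex
#'
#' Each assay plate (one per sex) is analysed independently: (median, MAD)
#' of the per-well cell count is computed over all measured compound wells
#' (plus control wells unless `include_controls = FALSE`); a compound whose
#' replicate-mean count lies `k` MAD or more above (below) the plate median
#' is a hyperhit (hypohit). The band is inclusive by default
#' (`mean >= median + k*mad`); `inclusive = FALSE` uses a strict inequality.
#' Degenerate plates (MAD = 0) yield no calls and a loud warning.
#'
#' @param measurements a `well_measurements` table.
#' @param layout optional `plate_layout`, validated against the measurements.
#' @param k MAD multiplier (default 3, must be > 0).
#' @param include_controls include control wells in the plate statistics.
#' @param inclusive hit at exactly `k` MAD counts as a hit (default TRUE).
#' @return list of class `hit_calls`: `calls` (one row per compound per sex:
#'   `compound_id`, `sex`, `plate_id`, `n_replicates`, `mean_count`,
#'   `deviation_mads`, `direction`, `mean_area`), `plate_stats`, and the
#'   thresholds used.
#' @export
call_hits <- function(measurements, layout = NULL, k = 3,
                      include_controls = TRUE, inclusive = TRUE) {
  if (!is.numeric(k) || k <= 0) stop("k must be a positive MAD multiplier")
  if (!is.null(layout)) validate_layout(layout)
  cp <- unique(measurements[measurements$role == "compound",
                            c("compound_id", "plate_id")])
  if (anyDuplicated(cp$compound_id))
    stop("configuration error: compound(s) measured on more than one plate: ",
         paste(head(unique(cp$compound_id[duplicated(cp$compound_id)])), collapse = ", "))
  ps <- plate_stats_table(measurements, include_controls)
  deg <- ps[ps$degenerate, ]
  if (nrow(deg))
    warning("degenerate plate(s) with MAD = 0 emit no hit calls: ",
            paste(paste(deg$plate_id, deg$sex), collapse = ", "))
  cmp <- measurements[measurements$role == "compound", , drop = FALSE]
  keygrp <- interaction(cmp$compound_id, cmp$sex, drop = TRUE)
  agg <- data.frame(
    compound_id = tapply(cmp$compound_id, keygrp, `[`, 1),
    sex = tapply(cmp$sex, keygrp, `[`, 1),
    plate_id = tapply(cmp$plate_id, keygrp, `[`, 1),
    n_replicates = as.integer(tapply(cmp$cell_count, keygrp, length)),
    mean_count = as.numeric(tapply(cmp$cell_count, keygrp, mean)),
    mean_area = as.numeric(tapply(cmp$mean_nuclear_area, keygrp,
                                  function(x) mean(x, na.rm = TRUE))),
    stringsAsFactors = FALSE)
  i <- match(paste(agg$plate_id, agg$sex), paste(ps$plate_id, ps$sex))
  med <- ps$median_count[i]; mad <- ps$mad_count[i]
  agg$deviation_mads <- ifelse(mad > 0, (agg$mean_count - med) / mad, NA_real_)
  ge <- if (inclusive) `>=` else `>`
  le <- if (inclusive) `<=` else `<`
  agg$direction <- "none"
  agg$direction[mad > 0 & ge(agg$mean_count, med + k * mad)] <- "hyper"
  agg$direction[mad > 0 & le(agg$mean_count, med - k * mad)] <- "hypo"
  agg <- agg[order(agg$compound_id, agg$sex), ]
  rownames(agg) <- NULL
  structure(list(calls = agg, plate_stats = ps, k = k,
                 include_controls = include_controls, inclusive = inclusive),
            class = "hit_calls")
}

#' Negative-control false discovery rate
#'
#' Tests every control WELL (not replicate-averaged — the intentional
#' asymmetry with compound calls) against its own plate's hit band and
#' reports the flagged fraction as a percentage, separately for hyper and
#' hypo. Zero flagged wells is reported as 0% with the zero shown.
#'
#' @inheritParams call_hits
#' @return list: `fdr_hyper_percent`, `fdr_hypo_percent`, `n_controls`,
#'   `n_flagged_hyper`, `n_flagged_hypo`, `flagged_hyper`, `flagged_hypo`
#'   (data.frames of flagged wells).
#' @examples
#' # 7 of 160 control wells flagged -> 4.375 percent
#' @export
control_fdr <- function(measurements, layout = NULL, k = 3,
                        include_controls = TRUE, inclusive = TRUE) {
  if (!is.numeric(k) || k <= 0) stop("k must be a positive MAD multiplier")
  ctrl <- measurements[measurements$role == "control", , drop = FALSE]
  if (!nrow(ctrl)) stop("no control wells in measurements")
  ps <- plate_stats_table(measurements, include_controls)
  i <- match(paste(ctrl$plate_id, ctrl$sex), paste(ps$plate_id, ps$sex))
  med <- ps$median_count[i]; mad <- ps$mad_count[i]
  ge <- if (inclusive) `>=` else `>`
  le <- if (inclusive) `<=` else `<`
  hyper <- mad > 0 & ge(ctrl$cell_count, med + k * mad)
  hypo <- mad > 0 & le(ctrl$cell_count, med - k * mad)
  list(fdr_hyper_percent = 100 * sum(hyper) / nrow(ctrl),
       fdr_hypo_percent = 100 * sum(hypo) / nrow(ctrl),
       n_controls = nrow(ctrl),
       n_flagged_hyper = sum(hyper), n_flagged_hypo = sum(hypo),
       flagged_hyper = ctrl[hyper, c("plate_id", "sex", "well", "cell_count")],
       flagged_hypo = ctrl[hypo, c("plate_id", "sex", "well", "cell_count")])
}

#' Categorise hits on the cell-count vs nuclear-size plane
#'
#' The nuclear-size shift of a hit is its replicate-mean nuclear area
#' expressed in per-plate MAD units of the area distribution; shrinkage is a
#' shift of `-size_k` MAD or beyond. Categories: C1 = hypohit with
#' shrinkage (cytotoxic signature), C2 = hyperhit with shrinkage, C3 = any
#' hit without shrinkage (minimal nuclear-morphology impact); size-ENLARGED
#' hits fall in C3 and carry `enlarged = TRUE`. Non-hits get `not_a_hit`;
#' hits with missing size statistics are left `NA` and logged.
#'
#' @param hits a `hit_calls` object from [call_hits()].
#' @param size_k MAD multiplier on nuclear area (default 3).
#' @return the `hit_calls` object with `nuclear_size_shift`, `category` and
#'   `enlarged` columns added to `$calls`.
#' @export
categorize_hits <- function(hits, size_k = 3) {
  stopifnot(inherits(hits, "hit_calls"), size_k > 0)
  calls <- hits$calls
  ps <- hits$plate_stats
  i <- match(paste(calls$plate_id, calls$sex), paste(ps$plate_id, ps$sex))
  smed <- ps$median_area[i]; smad <- ps$mad_area[i]
  shift <- ifelse(is.finite(smad) & smad > 0,
                  (calls$mean_area - smed) / smad, NA_real_)
  calls$nuclear_size_shift <- shift
  is_hit <- calls$direction != "none"
  shrink <- is.finite(shift) & shift <= -size_k
  calls$enlarged <- is_hit & is.finite(shift) & shift >= size_k
  calls$category <- "not_a_hit"
  calls$category[is_hit & calls$direction == "hypo" & shrink] <- "C1"
  calls$category[is_hit & calls$direction == "hyper" & shrink] <- "C2"
  calls$category[is_hit & !shrink] <- "C3"
  undet <- is_hit & !is.finite(shift)
  if (any(undet)) {
    calls$category[undet] <- NA_character_
    message(sum(undet), " hit(s) lack size statistics; category undetermined")
  }
  hits$calls <- calls
  hits$size_k <- size_k
  hits
}

#' Partition hit compounds by sex
#'
#' Exact set algebra on the per-sex hit sets: compounds hit in the male
#' screen only, the female screen only, or both.
#'
#' @param hits_male,hits_female character vectors of hit compound ids.
#' @return list: `male_only`, `female_only`, `both`, and `sizes`.
#' @export
venn_partition <- function(hits_male, hits_female) {
  hits_male <- unique(hits_male); hits_female <- unique(hits_female)
  out <- list(male_only = sort(setdiff(hits_male, hits_female)),
              female_only = sort(setdiff(hits_female, hits_male)),
              both = sort(intersect(hits_male, hits_female)))
  out$sizes <- lengths(out[1:3])
  # invariant: disjoint cover of the union
  stopifnot(!anyDuplicated(c(out$male_only, out$female_only, out$both)),
            setequal(c(out$male_only, out$female_only, out$both),
                     union(hits_male, hits_female)))
  out
}

direction_set <- function(calls, compound) {
  d <- calls$direction[calls$compound_id == compound]
  unique(d[d != "none"])
}

#' Cross-screen concordance of hit directions
#'
#' A compound "repeats" between a reference and a confirmation screen when
#' its effect direction (hyper/hypo, in any sex) matches. Compounds absent
#' from either screen are excluded and logged.
#'
#' @param hits_ref,hits_test `hit_calls` objects for the two screens.
#' @param compounds compound ids to compare (default: reference hits).
#' @return list: `n_repeated`, `n_tested`, `excluded`, and a per-compound
#'   `table` with both screens' direction sets and the agreement flag.
#' @export
concordance <- function(hits_ref, hits_test, compounds = NULL) {
  stopifnot(inherits(hits_ref, "hit_calls"), inherits(hits_test, "hit_calls"))
  if (is.null(compounds)) {
    compounds <- unique(hits_ref$calls$compound_id[hits_ref$calls$direction != "none"])
  }
  present <- compounds %in% hits_ref$calls$compound_id &
    compounds %in% hits_test$calls$compound_id
  excluded <- compounds[!present]
  if (length(excluded))
    message(length(excluded), " compound(s) absent from a screen; excluded")
  compounds <- compounds[present]
  rows <- lapply(compounds, function(cp) {
    dr <- direction_set(hits_ref$calls, cp)
    dt <- direction_set(hits_test$calls, cp)
    data.frame(compound_id = cp,
               ref_direction = paste(sort(dr), collapse = "/"),
               test_direction = paste(sort(dt), collapse = "/"),
               repeated = length(intersect(dr, dt)) > 0,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  list(n_repeated = if (is.null(tab)) 0L else sum(tab$repeated),
       n_tested = length(compounds), excluded = excluded, table = tab)
}
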
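#' Configuration for a full synthetic screen run
#'
#' One serialisable object holding every knob of the compound-screen
#' workflow: library/plate geometry, planted effects, growth and imaging
#' parameters, hit-calling thresholds, and the top-level seed all
#' randomness flows from. Defaults reproduce the study conditions of the
#' emulated screen: a 438-compound library, 80 compounds per plate in
#' technical quadruplets at 250 nM, 32 DMSO controls per plate, 6 days of
#' growth.
#'
#' @param seed top-level integer seed.
#' @param n_compounds,compounds_per_plate,replicates,controls_per_plate,plate_format
#'   screen geometry (see [generate_plate_layout()]).
#' @param days screen duration, days.
#' @param k,size_k MAD multipliers for count hits and size shrinkage.
#' @param include_controls,inclusive hit-band policy (see [call_hits()]).
#' @param growth a [growth_params()].
#' @param n_hypo,n_hyper,effect_hypo,effect_hyper planted truth
#'   (see [plant_effects()]).
#' @param use_imaging render and re-segment field images instead of using
#'   simulated counts directly (slow; only sensible for small layouts whose
#'   expected counts fit the field at the configured nuclear radius).
#' @param imaging an [image_params()].
#' @param out_dir optional output directory for artifacts.
#' @param workflow label recorded in reports.
#' @return list of class `screen_config`.
#' @export
screen_config <- function(seed = 1, n_compounds = 438, compounds_per_plate = 80,
                          replicates = 4, controls_per_plate = 32,
                          plate_format = 384, days = 6, k = 3, size_k = 3,
                          include_controls = TRUE, inclusive = TRUE,
                          growth = growth_params(), n_hypo = 60, n_hyper = 20,
                          effect_hypo = 0.3, effect_hyper = 1.8,
                          use_imaging = FALSE, imaging = image_params(),
                          out_dir = NULL, workflow = "compound_screen") {
  if (!is.numeric(k) || k <= 0) stop("config error: k must be > 0")
  if (!is.numeric(size_k) || size_k <= 0) stop("config error: size_k must be > 0")
  if (days < 0) stop("config error: days must be >= 0")
  structure(as.list(environment()), class = "screen_config")
}

config_hash <- function(config) {
  s <- paste(deparse(unclass(config)), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}

# Write a CSV and validate the round trip (schema + row count).
write_validated_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  back <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(back), names(df)) || nrow(back) != nrow(df))
    stop("round-trip validation failed for ", path)
  invisible(path)
}

#' Run the compound-screen workflow end to end
#'
#' synthdata -> (optional imaging) -> hit calling -> report: generates the
#' layout and planted effects, simulates (or renders and re-segments)
#' per-well measurements, calls and categorises hits per sex, estimates the
#' negative-control FDR, partitions hits by sex, tests kinase-family
#' enrichment, and scores recovery of the planted truth. The Venn
#' partition (disjoint cover) and the one-category-per-hit invariant are
#' asserted on every run.
#'
#' @param config a [screen_config()].
#' @return list of class `screen_report`.
#' @export
run_screen <- function(config = screen_config()) {
  stopifnot(inherits(config, "screen_config"))
  layout <- generate_plate_layout(config$n_compounds, config$compounds_per_plate,
                                  config$replicates, config$controls_per_plate,
                                  config$plate_format, seed = config$seed)
  compounds <- sort(unique(layout$compound_id[layout$role == "compound"]))
  effects <- plant_effects(compounds, n_hypo = config$n_hypo,
                           n_hyper = config$n_hyper,
                           effect_hypo = config$effect_hypo,
                           effect_hyper = config$effect_hyper,
                           seed = config$seed)
  measurements <- simulate_screen_counts(layout, effects, config$growth,
                                         days = config$days, seed = config$seed)
  if (isTRUE(config$use_imaging)) {
    measurements <- reimage_measurements(measurements, config)
  }
  hits <- call_hits(measurements, layout, k = config$k,
                    include_controls = config$include_controls,
                    inclusive = config$inclusive)
  hits <- categorize_hits(hits, size_k = config$size_k)
  fdr <- control_fdr(measurements, layout, k = config$k,
                     include_controls = config$include_controls,
                     inclusive = config$inclusive)
  calls <- hits$calls
  hit_rows <- calls[calls$direction != "none", , drop = FALSE]
  venn <- venn_partition(hit_rows$compound_id[hit_rows$sex == "male"],
                         hit_rows$compound_id[hit_rows$sex == "female"])
  hit_compounds <- sort(unique(hit_rows$compound_id))
  # invariant: every categorised hit carries exactly one of C1/C2/C3
  cat_ok <- hit_rows$category %in% c("C1", "C2", "C3") | is.na(hit_rows$category)
  stopifnot(all(cat_ok),
            all(calls$category[calls$direction == "none"] == "not_a_hit"))
  enrichment <- family_enrichment(hit_compounds,
                                  effects[, c("compound_id", "family")])
  recovery <- score_recovery(calls, effects)
  report <- structure(list(
    workflow = config$workflow, config = config,
    config_hash = config_hash(config),
    thresholds = list(k = config$k, size_k = config$size_k,
                      inclusive = config$inclusive,
                      include_controls = config$include_controls),
    layout = layout, effects = effects, measurements = measurements,
    plate_stats = hits$plate_stats, calls = calls,
    hit_compounds = hit_compounds, venn = venn, fdr = fdr,
    enrichment = enrichment, recovery = recovery), class = "screen_report")
  if (!is.null(config$out_dir)) write_screen_report(report, config$out_dir)
  report
}

# Render field images for every measured well and replace counts/areas by
# the segmented readout (the imaging-in-the-loop path).
reimage_measurements <- function(measurements, config) {
  ip <- config$imaging
  out <- NULL
  for (s in unique(measurements$sex)) {
    ms <- measurements[measurements$sex == s, , drop = FALSE]
    wc <- data.frame(plate_id = ms$plate_id, well = ms$well, count = ms$cell_count)
    dir <- file.path(tempdir(), paste0("gtscreen_fields_", s, "_",
                                       config$seed))
    unlink(dir, recursive = TRUE)
    render_field_images(ip, wc, seed = substream_seed(config$seed, s), dir = dir)
    lay <- ms; lay$role[is.na(lay$role)] <- "compound"
    meas <- measure_plate(dir, lay, fields_per_well = ip$fields_per_well,
                          maxval = ip$maxval)
    unlink(dir, recursive = TRUE)
    out <- rbind(out, meas)
  }
  class(out) <- c("well_measurements", "data.frame")
  out
}

score_recovery <- function(calls, effects) {
  eff <- pmin(effects$effect_male, effects$effect_female)
  truth <- ifelse(effects$effect_male > 1 | effects$effect_female > 1, "hyper",
                  ifelse(effects$effect_male < 1 | effects$effect_female < 1,
                         "hypo", "none"))
  names(truth) <- effects$compound_id
  found <- function(cp, dir) any(calls$direction[calls$compound_id == cp] == dir)
  hypo_cp <- names(truth)[truth == "hypo"]
  hyper_cp <- names(truth)[truth == "hyper"]
  null_cp <- names(truth)[truth == "none"]
  list(
    sensitivity_hypo = if (length(hypo_cp))
      mean(vapply(hypo_cp, found, logical(1), dir = "hypo")) else NA_real_,
    sensitivity_hyper = if (length(hyper_cp))
      mean(vapply(hyper_cp, found, logical(1), dir = "hyper")) else NA_real_,
    null_flagged_fraction = if (length(null_cp))
      mean(vapply(null_cp, function(cp)
        any(calls$direction[calls$compound_id == cp] != "none"),
        logical(1))) else NA_real_,
    n_hypo_planted = length(hypo_cp), n_hyper_planted = length(hyper_cp),
    n_null = length(null_cp))
}

#' Write screen-report artifacts to disk
#'
#' Emits `layout.csv`, `measurements.csv`, `hits.csv`, `plate_stats.csv`,
#' `enrichment.csv` and a composite `report.json` (config, thresholds,
#' plate stats, Venn, FDRs, enrichment, recovery). Every CSV is re-read and
#' schema-validated on write.
#'
#' @param report a `screen_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_screen_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_validated_csv(as.data.frame(report$layout), file.path(dir, "layout.csv"))
  write_validated_csv(as.data.frame(report$measurements),
                      file.path(dir, "measurements.csv"))
  write_validated_csv(report$calls, file.path(dir, "hits.csv"))
  write_validated_csv(report$plate_stats, file.path(dir, "plate_stats.csv"))
  write_validated_csv(report$enrichment, file.path(dir, "enrichment.csv"))
  json <- list(workflow = report$workflow, config_hash = report$config_hash,
               seed = report$config$seed, thresholds = report$thresholds,
               n_hits = length(report$hit_compounds),
               venn = report$venn[c("male_only", "female_only", "both")],
               fdr = report$fdr[c("fdr_hyper_percent", "fdr_hypo_percent",
                                  "n_controls", "n_flagged_hyper",
                                  "n_flagged_hypo")],
               plate_stats = report$plate_stats,
               enrichment = report$enrichment, recovery = report$recovery)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.screen_report <- function(x, ...) {
  cat("Synthetic GTme compound screen (", x$workflow, ")\n", sep = "")
  cat("  seed ", x$config$seed, ", config hash ", x$config_hash, "\n", sep = "")
  cat("  compounds:", x$config$n_compounds, " plates/sex:",
      length(unique(x$layout$plate_id)), "\n")
  cat("  hits:", length(x$hit_compounds),
      sprintf("(male-only %d, female-only %d, both %d)\n",
              x$venn$sizes[["male_only"]], x$venn$sizes[["female_only"]],
              x$venn$sizes[["both"]]))
  cat(sprintf("  control FDR: hyper %.3f%%, hypo %.3f%% (n = %d)\n",
              x$fdr$fdr_hyper_percent, x$fdr$fdr_hypo_percent,
              x$fdr$n_controls))
  cat(sprintf("  planted-truth recovery: sens(hypo) %.3f, sens(hyper) %.3f, null flagged %.4f\n",
              x$recovery$sensitivity_hypo, x$recovery$sensitivity_hyper,
              x$recovery$null_flagged_fraction))
  invisible(x)
}

#' Run the siRNA proliferation-assay workflow
#'
#' Emulates the gene-silencing variant of the screen: per gene and sex, a
#' growth course is simulated at the assay timepoints with the planted
#' knockdown effect on the growth rate, compared to the mock-transfected
#' course of the same sex by per-timepoint Welch tests; knockdown of each
#' target is confirmed by a planted-fold qPCR table analysed with
#' [delta_delta_ct()]. Missing timepoints yield a partial report with a
#' warning.
#'
#' @param genes character vector of silenced genes.
#' @param knockdown_growth named list: gene -> c(male =, female =) rate
#'   multipliers (the phenotypic effect of silencing).
#' @param knockdown_fold named numeric: gene -> residual expression fold
#'   after silencing (qPCR confirmation).
#' @param timepoints assay days (default 1, 3, 6).
#' @param growth a [growth_params()].
#' @param replicates wells per set.
#' @param noise_sd_ct qPCR Ct noise, cycles.
#' @param seed integer seed.
#' @return list of class `sirna_report`: `curves`, `tests` (per gene/sex
#'   per-timepoint Welch table), `knockdown` (ddCt summary), `config`.
#' @export
run_sirna_assay <- function(genes = c("Ar", "Gli3", "Mafb"),
                            knockdown_growth = list(
                              Ar = c(male = 0.85, female = 1.00),
                              Gli3 = c(male = 0.87, female = 1.00),
                              Mafb = c(male = 0.90, female = 0.92)),
                            knockdown_fold = setNames(rep(0.2, length(genes)), genes),
                            timepoints = c(1, 3, 6),
                            growth = growth_params(), replicates = 4,
                            noise_sd_ct = 0.1, seed = 1) {
  if (length(timepoints) < length(c(1, 3, 6)))
    warning("partial assay: fewer than the standard three timepoints")
  conds <- list()
  overrides <- list()
  for (s in c("male", "female")) {
    conds[[paste0(s, "+mock")]] <- list(sex = s, modulators = character())
    for (g in genes) {
      lab <- paste0(s, "+si", g)
      conds[[lab]] <- list(sex = s, modulators = character())
      overrides[[lab]] <- unname(knockdown_growth[[g]][s])
    }
  }
  # condition labels must match simulate_growth_course's sex+modulator labels;
  # encode the siRNA as a rate override keyed by the bare sex label instead
  curves <- NULL
  for (nm in names(conds)) {
    cond <- conds[[nm]]
    mult <- overrides[[nm]] %||% 1
    cc <- simulate_growth_course(list(cond), timepoints, growth, replicates,
                                 rate_overrides = setNames(list(mult), cond$sex),
                                 seed = substream_seed(seed, nm))
    cc$condition <- nm
    curves <- rbind(curves, cc)
  }
  tests <- list()
  for (s in c("male", "female")) {
    mock <- curves[curves$condition == paste0(s, "+mock"), ]
    for (g in genes) {
      lab <- paste0(s, "+si", g)
      tests[[lab]] <- compare_growth_curves(curves[curves$condition == lab, ], mock)
    }
  }
  qpcr <- simulate_qpcr(genes, knockdown_fold, noise_sd = noise_sd_ct,
                        replicates = replicates,
                        groups = c("mock", "siRNA"), seed = seed)
  kd <- delta_delta_ct(qpcr, calibrator_group = "mock")
  structure(list(curves = curves, tests = tests, knockdown = kd$summary,
                 config = list(genes = genes,
                               knockdown_growth = knockdown_growth,
                               knockdown_fold = as.list(knockdown_fold),
                               timepoints = timepoints,
                               replicates = replicates, seed = seed)),
            class = "sirna_report")
}
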
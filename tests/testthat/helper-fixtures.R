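# Hand-built measurement tables with known plate statistics.

# compounds: named list compound_id -> replicate count vector
# controls: vector of control-well counts
# areas: optional named list compound_id -> replicate area vector, and
# control_areas for control wells (defaults 100 everywhere).
manual_measurements <- function(compounds, controls = numeric(0),
                                areas = NULL, control_areas = NULL,
                                plate_id = "plate01", sex = "male") {
  rows <- list()
  w <- 0L
  for (cp in names(compounds)) {
    cnt <- compounds[[cp]]
    ar <- if (!is.null(areas[[cp]])) areas[[cp]] else rep(100, length(cnt))
    for (j in seq_along(cnt)) {
      w <- w + 1L
      rows[[w]] <- data.frame(plate_id = plate_id, sex = sex,
                              well = sprintf("A%d", w), role = "compound",
                              compound_id = cp, replicate_index = j,
                              cell_count = cnt[j], mean_nuclear_area = ar[j],
                              n_fields = 4L, stringsAsFactors = FALSE)
    }
  }
  if (length(controls)) {
    ca <- if (!is.null(control_areas)) control_areas else rep(100, length(controls))
    for (j in seq_along(controls)) {
      w <- w + 1L
      rows[[w]] <- data.frame(plate_id = plate_id, sex = sex,
                              well = sprintf("B%d", j), role = "control",
                              compound_id = NA_character_,
                              replicate_index = NA_integer_,
                              cell_count = controls[j],
                              mean_nuclear_area = ca[j],
                              n_fields = 4L, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("well_measurements", "data.frame")
  out
}

# Noiseless, fixed-radius rendering parameters for exact imaging fixtures.
noiseless_params <- function(...) {
  image_params(noise_sd = 0, radius_sd = 0, ...)
}

# A plate whose count median is 13 and raw MAD is 2 (band [7, 19] at k = 3)
# over ALL wells including the appended test compounds: the 21 control wells
# (ten 11s, one 13, ten 15s) anchor the statistics so that quadruplets at
# 20, 6, 13 and 19 leave median and MAD unchanged (verified by enumeration).
band13_measurements <- function(extra = list()) {
  manual_measurements(extra, controls = c(rep(11, 10), 13, rep(15, 10)))
}
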
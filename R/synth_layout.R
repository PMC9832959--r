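#' Generate a screening plate layout
#'
#' Lays out an `n_compounds`-member library over 384-well (or 96-well) assay
#' plates, `compounds_per_plate` compounds per library plate in technical
#' replicate wells, plus DMSO negative-control wells; each library plate is
#' stamped into one assay plate per sex, at identical well positions. Well
#' positions within a plate are randomised under `seed`.
#'
#' @param n_compounds number of unique compounds in the library.
#' @param compounds_per_plate compounds per library plate (default 80).
#' @param replicates technical replicate wells per compound (default 4).
#' @param controls_per_plate DMSO control wells per plate (default 32).
#' @param plate_format wells per plate (384 default; 96 supported).
#' @param sexes character vector of screened sexes.
#' @param seed integer seed; layouts are deterministic given the seed.
#' @return a `data.frame` with class `plate_layout`: columns `plate_id`,
#'   `sex`, `well`, `role` (`compound`/`control`/`empty`), `compound_id`
#'   (`NA` unless `role == "compound"`), `replicate_index`.
#' @examples
#' lay <- generate_plate_layout(438, seed = 1)
#' table(lay$plate_id, lay$role)[, c("compound", "control", "empty")] / 2
#' @export
generate_plate_layout <- function(n_compounds, compounds_per_plate = 80,
                                  replicates = 4, controls_per_plate = 32,
                                  plate_format = 384,
                                  sexes = c("male", "female"), seed = 1) {
  stopifnot(n_compounds >= 1, compounds_per_plate >= 1, replicates >= 1,
            controls_per_plate >= 0)
  need <- replicates * compounds_per_plate + controls_per_plate
  if (need > plate_format) {
    stop("plate capacity exceeded: ", compounds_per_plate, " compounds x ",
         replicates, " replicates + ", controls_per_plate, " controls = ",
         need, " wells > ", plate_format, "-well format")
  }
  compounds <- sprintf("CPD%03d", seq_len(n_compounds))
  n_plates <- ceiling(n_compounds / compounds_per_plate)
  wells <- well_names(plate_format)

  layout <- with_substream(seed, "layout", {
    per_plate <- lapply(seq_len(n_plates), function(i) {
      idx <- ((i - 1) * compounds_per_plate + 1):min(i * compounds_per_plate, n_compounds)
      cpds <- compounds[idx]
      shuffled <- sample(wells)
      n_cw <- length(cpds) * replicates
      role <- rep("empty", plate_format)
      compound_id <- rep(NA_character_, plate_format)
      rep_idx <- rep(NA_integer_, plate_format)
      cw <- shuffled[seq_len(n_cw)]
      pos <- match(cw, wells)
      role[pos] <- "compound"
      compound_id[pos] <- rep(cpds, each = replicates)
      rep_idx[pos] <- rep(seq_len(replicates), times = length(cpds))
      if (controls_per_plate > 0) {
        ctrl <- shuffled[n_cw + seq_len(controls_per_plate)]
        role[match(ctrl, wells)] <- "control"
      }
      data.frame(plate_id = sprintf("plate%02d", i), well = wells, role = role,
                 compound_id = compound_id, replicate_index = rep_idx,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, per_plate)
  })

  out <- do.call(rbind, lapply(sexes, function(s) cbind(layout, sex = s)))
  out <- out[, c("plate_id", "sex", "well", "role", "compound_id", "replicate_index")]
  rownames(out) <- NULL
  class(out) <- c("plate_layout", "data.frame")
  out
}

validate_layout <- function(layout) {
  stopifnot(is.data.frame(layout),
            all(c("plate_id", "sex", "well", "role", "compound_id") %in% names(layout)))
  stopifnot(all(layout$role %in% c("compound", "control", "empty")))
  cp <- unique(layout[layout$role == "compound", c("compound_id", "plate_id")])
  if (anyDuplicated(cp$compound_id)) {
    stop("configuration error: compound(s) split across plates: ",
         paste(unique(cp$compound_id[duplicated(cp$compound_id)]), collapse = ", "))
  }
  invisible(layout)
}

#' Write / read a plate layout CSV
#'
#' @param layout a `plate_layout` data frame.
#' @param path file path.
#' @return `read_layout_csv` returns a `plate_layout`; `write_layout_csv`
#'   returns `path` invisibly.
#' @export
write_layout_csv <- function(layout, path) {
  utils::write.csv(as.data.frame(layout), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_layout_csv
#' @export
read_layout_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$compound_id[out$compound_id %in% c("", "NA")] <- NA_character_
  class(out) <- c("plate_layout", "data.frame")
  validate_layout(out)
  out
}
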
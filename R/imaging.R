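#' Segment nuclei in a grayscale field image
#'
#' Re-implements the screen's per-field readout: rolling-ball-style
#' background subtraction (morphological opening with a disc), a global
#' threshold (Otsu by default, or fixed), connected-component labelling,
#' optional distance-transform watershed splitting of oversized blobs, and
#' an area filter.
#'
#' Objects smaller than `min_area` are always dropped. `max_area` acts as
#' the splitting trigger: when `split_touching` is `TRUE`, any blob larger
#' than `max_area` is re-segmented at the distance-transform ridge; blobs
#' that remain (or are left) above `max_area` are kept and flagged
#' `oversize` rather than discarded, so merged nuclei are still counted
#' (once) when splitting is off.
#'
#' Blank fields are legal: under Otsu a field whose dynamic range after
#' background subtraction is below `dynamic_floor` returns zero objects; a
#' strictly constant image under Otsu is a degenerate-image error.
#'
#' @param field_image 2-D numeric matrix of grey levels.
#' @param min_area,max_area object-area filter band, pixel^2.
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param split_touching split oversized blobs by watershed (default TRUE).
#' @param fixed_threshold grey-level threshold applied to the
#'   background-subtracted image when `threshold_method = "fixed"`.
#' @param bg_radius disc radius (pixels) of the opening used as background
#'   estimate.
#' @param maxval full-scale grey level of the input (default 65535).
#' @param dynamic_floor minimum post-subtraction dynamic range (fraction of
#'   `maxval`) for Otsu to see signal.
#' @param watershed_tolerance minimum object-height separation for the
#'   watershed split.
#' @return list of class `segmented_field`: `label_map` (integer matrix,
#'   labels contiguous from 1), `objects` (data.frame: `label`, `area`,
#'   `centroid_row`, `centroid_col`, `oversize`), `params_used`.
#' @export
segment_nuclei <- function(field_image, min_area = 20, max_area = Inf,
                           threshold_method = c("otsu", "fixed"),
                           split_touching = TRUE, fixed_threshold = NULL,
                           bg_radius = 15, maxval = 65535,
                           dynamic_floor = 0.03, watershed_tolerance = 1) {
  threshold_method <- match.arg(threshold_method)
  if (!is.matrix(field_image) || !is.numeric(field_image))
    stop("field_image must be a 2-D numeric matrix")
  if (any(!is.finite(field_image))) stop("field_image contains non-finite values")
  params_used <- list(min_area = min_area, max_area = max_area,
                      threshold_method = threshold_method,
                      split_touching = split_touching,
                      fixed_threshold = fixed_threshold,
                      bg_radius = bg_radius, maxval = maxval,
                      dynamic_floor = dynamic_floor,
                      watershed_tolerance = watershed_tolerance)
  empty <- function() {
    structure(list(label_map = matrix(0L, nrow(field_image), ncol(field_image)),
                   objects = data.frame(label = integer(0), area = numeric(0),
                                        centroid_row = numeric(0),
                                        centroid_col = numeric(0),
                                        oversize = logical(0)),
                   params_used = params_used),
              class = "segmented_field")
  }
  if (diff(range(field_image)) == 0) {
    if (threshold_method == "otsu")
      stop("degenerate image: constant-valued field under otsu thresholding")
  }
  brush <- EBImage::makeBrush(2 * bg_radius + 1, shape = "disc")
  bg <- EBImage::opening(field_image, brush)
  sub <- pmax(field_image - bg, 0)

  if (threshold_method == "otsu") {
    if (diff(range(sub)) < dynamic_floor * maxval) return(empty())
    th <- EBImage::otsu(EBImage::Image(sub / maxval), range = c(0, 1)) * maxval
  } else {
    if (is.null(fixed_threshold)) stop("fixed_threshold required for threshold_method = 'fixed'")
    th <- fixed_threshold
  }
  mask <- sub > th
  if (!any(mask)) return(empty())

  lab <- EBImage::bwlabel(mask)
  areas <- tabulate(lab[lab > 0])

  if (split_touching && is.finite(max_area) && any(areas > max_area)) {
    big <- which(areas > max_area)
    bigmask <- matrix(lab %in% big, nrow(lab), ncol(lab))
    ws <- EBImage::watershed(EBImage::distmap(bigmask),
                             tolerance = watershed_tolerance, ext = 1)
    lab[bigmask] <- 0L
    lab2 <- as.integer(lab)
    off <- max(lab2)
    lab2[as.vector(bigmask)] <- as.integer(ws)[as.vector(bigmask)] + off
    lab <- matrix(lab2, nrow(lab), ncol(lab))
    areas <- tabulate(lab[lab > 0])
  }

  keep <- which(areas >= min_area)
  if (!length(keep)) return(empty())
  # relabel contiguous from 1, deterministic (by old label order)
  newlab <- integer(length(areas))
  newlab[keep] <- seq_along(keep)
  m <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab > 0
  m[nz] <- newlab[lab[nz]]

  idx <- which(m > 0, arr.ind = TRUE)
  labs <- m[m > 0]
  area <- as.numeric(tabulate(labs, nbins = length(keep)))
  crow <- as.numeric(tapply(idx[, 1], labs, mean))
  ccol <- as.numeric(tapply(idx[, 2], labs, mean))
  objects <- data.frame(label = seq_along(keep), area = area,
                        centroid_row = crow, centroid_col = ccol,
                        oversize = area > max_area)
  structure(list(label_map = m, objects = objects, params_used = params_used),
            class = "segmented_field")
}

#' Aggregate segmented fields into one per-well measurement
#'
#' Sums object counts over fields and pools all object areas for the
#' unweighted mean nuclear area. An empty pool yields count 0 with the mean
#' area flagged missing (`NA`).
#'
#' @param fields list of `segmented_field` objects (>= 1).
#' @param plate_id,well,sex identifiers copied to the output row.
#' @return one-row data.frame of class `well_measurements`.
#' @export
summarize_well <- function(fields, plate_id, well, sex = NA_character_) {
  stopifnot(length(fields) >= 1)
  stopifnot(all(vapply(fields, inherits, logical(1), "segmented_field")))
  shapes <- vapply(fields, function(f) paste(dim(f$label_map), collapse = "x"), "")
  if (length(unique(shapes)) > 1)
    warning("mixed field shapes in well ", well, " (areas are shape-independent)")
  areas <- unlist(lapply(fields, function(f) f$objects$area))
  count <- length(areas)
  out <- data.frame(plate_id = plate_id, sex = sex, well = well,
                    role = NA_character_, compound_id = NA_character_,
                    replicate_index = NA_integer_,
                    cell_count = as.integer(count),
                    mean_nuclear_area = if (count > 0) mean(areas) else NA_real_,
                    n_fields = length(fields), stringsAsFactors = FALSE)
  class(out) <- c("well_measurements", "data.frame")
  out
}

#' Measure every well of a plate from its field images
#'
#' Batch driver over a directory of per-field TIFFs named
#' `{plate}_{well}_f{k}.tif`. Each non-empty layout well must have
#' `fields_per_well` images; wells with missing images are excluded and
#' logged, per-well segmentation failures are collected, not fatal. Results
#' are independent of file enumeration order.
#'
#' @param image_dir directory of field TIFFs.
#' @param layout a `plate_layout` whose (plate_id, well) pairs are unique
#'   (single-sex, or distinct plate ids per sex).
#' @param fields_per_well expected images per well.
#' @param maxval full-scale grey level the TIFFs are rescaled to.
#' @param ... further arguments passed to [segment_nuclei()].
#' @return a `well_measurements` data.frame (one row per measured well),
#'   with attributes `qc_log` (character) and `params_used`.
#' @export
measure_plate <- function(image_dir, layout, fields_per_well = 4,
                          maxval = 65535, ...) {
  files <- sort(list.files(image_dir, pattern = "\\.tif$"))
  if (!length(files)) stop("no .tif images found in ", image_dir)
  m <- regmatches(files, regexec("^(.*)_([A-Z][0-9]+)_f([0-9]+)\\.tif$", files))
  ok <- lengths(m) == 4
  inv <- data.frame(file = files[ok],
                    plate_id = vapply(m[ok], `[`, "", 2),
                    well = vapply(m[ok], `[`, "", 3),
                    field = as.integer(vapply(m[ok], `[`, "", 4)),
                    stringsAsFactors = FALSE)
  wells <- unique(layout[layout$role != "empty",
                         c("plate_id", "sex", "well", "role", "compound_id",
                           "replicate_index")])
  if (anyDuplicated(wells[, c("plate_id", "well")]))
    stop("layout has duplicate (plate_id, well) pairs; use distinct plate ids per sex")
  log <- c(sprintf("image_dir=%s files=%d wells_expected=%d fields_per_well=%d",
                   image_dir, length(files), nrow(wells), fields_per_well))
  rows <- list()
  for (i in seq_len(nrow(wells))) {
    sel <- inv$plate_id == wells$plate_id[i] & inv$well == wells$well[i]
    if (sum(sel) != fields_per_well) {
      log <- c(log, sprintf("excluded %s %s: %d of %d field images found",
                            wells$plate_id[i], wells$well[i], sum(sel),
                            fields_per_well))
      next
    }
    fi <- inv[sel, ][order(inv$field[sel]), ]
    segs <- tryCatch(lapply(fi$file, function(f) {
      img <- tiff::readTIFF(file.path(image_dir, f)) * maxval
      segment_nuclei(img, maxval = maxval, ...)
    }), error = function(e) e)
    if (inherits(segs, "error")) {
      log <- c(log, sprintf("failed %s %s: %s", wells$plate_id[i],
                            wells$well[i], conditionMessage(segs)))
      next
    }
    row <- summarize_well(segs, wells$plate_id[i], wells$well[i], wells$sex[i])
    row$role <- wells$role[i]
    row$compound_id <- wells$compound_id[i]
    row$replicate_index <- wells$replicate_index[i]
    rows[[length(rows) + 1]] <- row
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no wells could be measured from ", image_dir)
  rownames(out) <- NULL
  class(out) <- c("well_measurements", "data.frame")
  attr(out, "qc_log") <- log
  attr(out, "params_used") <- c(list(fields_per_well = fields_per_well,
                                     maxval = maxval), list(...))
  out
}
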
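#' Rendering parameters for synthetic nuclei field images
#'
#' Fields emulate a 10x Hoechst/DAPI acquisition: dark background plus
#' bright nuclei rendered as radially decaying blobs (flat core with a
#' Gaussian edge whose half-maximum sits exactly at the drawn nuclear
#' radius), with additive Gaussian read noise. Four fields are imaged per
#' well by default.
#'
#' @param field_shape c(height, width) in pixels.
#' @param nuclei_per_field expected nuclei per field (used when rendering
#'   fields without an explicit per-well count).
#' @param radius_mean,radius_sd nuclear radius distribution, pixels
#'   (`radius_mean > radius_sd >= 0`).
#' @param peak_intensity,background,noise_sd grey levels; must fit the bit
#'   depth.
#' @param overlap_allowed allow touching/overlapping nuclei (default FALSE:
#'   hard-disk placement by rejection sampling).
#' @param placement_margin minimum clearance (pixels) between nucleus edges
#'   under hard-disk placement, so intensity skirts of neighbours do not
#'   bridge.
#' @param fields_per_well images per well (default 4).
#' @param bit_depth image bit depth (default 16).
#' @return list of class `image_params`.
#' @export
image_params <- function(field_shape = c(256L, 256L), nuclei_per_field = 40,
                         radius_mean = 6, radius_sd = 0.8,
                         peak_intensity = 20000, background = 500,
                         noise_sd = 100, overlap_allowed = FALSE,
                         placement_margin = 3, fields_per_well = 4L,
                         bit_depth = 16L) {
  maxval <- 2^bit_depth - 1
  stopifnot(radius_mean > radius_sd, radius_sd >= 0, fields_per_well >= 1,
            peak_intensity + background <= maxval, background >= 0,
            noise_sd >= 0, all(field_shape >= 16))
  structure(list(field_shape = as.integer(field_shape),
                 nuclei_per_field = nuclei_per_field,
                 radius_mean = radius_mean, radius_sd = radius_sd,
                 peak_intensity = peak_intensity, background = background,
                 noise_sd = noise_sd, overlap_allowed = overlap_allowed,
                 placement_margin = placement_margin,
                 fields_per_well = as.integer(fields_per_well),
                 bit_depth = as.integer(bit_depth), maxval = maxval),
            class = "image_params")
}

# Draw hard-disk (or free) nucleus centers and radii for one field.
place_nuclei <- function(n, params, max_attempts = 200 * max(n, 1)) {
  if (n == 0) return(data.frame(row = numeric(0), col = numeric(0), radius = numeric(0)))
  h <- params$field_shape[1]; w <- params$field_shape[2]
  rows <- cols <- rad <- numeric(n)
  placed <- 0L; attempts <- 0L
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("could not place ", n, " nuclei of radius ~", params$radius_mean,
           " in a ", h, "x", w, " field after ", max_attempts,
           " attempts; lower the density or set overlap_allowed = TRUE")
    }
    r <- max(1.5, rnorm(1, params$radius_mean, params$radius_sd))
    cr <- runif(1, r + 1, h - r)
    cc <- runif(1, r + 1, w - r)
    if (!params$overlap_allowed && placed > 0) {
      d2 <- (rows[seq_len(placed)] - cr)^2 + (cols[seq_len(placed)] - cc)^2
      if (any(d2 < (rad[seq_len(placed)] + r + params$placement_margin)^2)) next
    }
    placed <- placed + 1L
    rows[placed] <- cr; cols[placed] <- cc; rad[placed] <- r
  }
  data.frame(row = rows, col = cols, radius = rad)
}

#' Render one field image from explicit nucleus positions
#'
#' Each nucleus adds a flat-core profile with a narrow Gaussian edge whose
#' half-maximum sits at its radius, so any mid-range threshold recovers a
#' disk of close to the drawn radius; read noise and clipping to the bit
#' depth follow. Useful for constructing exact fixtures (e.g. deliberately
#' overlapping nuclei).
#'
#' @param nuclei data.frame with columns `row`, `col`, `radius` (pixels).
#' @param params an `image_params`.
#' @param noise_sd override for the read-noise level (default from params).
#' @return numeric matrix (grey levels, integers in `[0, 2^bit_depth - 1]`).
#' @export
render_field <- function(nuclei, params = image_params(),
                         noise_sd = params$noise_sd) {
  h <- params$field_shape[1]; w <- params$field_shape[2]
  img <- matrix(params$background, h, w)
  sigma_edge <- 1 / sqrt(2 * log(2))       # half-maximum one pixel past the core
  for (i in seq_len(nrow(nuclei))) {
    r <- nuclei$radius[i]
    ext <- ceiling(r + 4)
    rr <- max(1, floor(nuclei$row[i] - ext)):min(h, ceiling(nuclei$row[i] + ext))
    cc <- max(1, floor(nuclei$col[i] - ext)):min(w, ceiling(nuclei$col[i] + ext))
    d <- sqrt(outer((rr - nuclei$row[i])^2, (cc - nuclei$col[i])^2, "+"))
    prof <- ifelse(d <= r - 1, 1, exp(-(d - (r - 1))^2 / (2 * sigma_edge^2)))
    img[rr, cc] <- img[rr, cc] + params$peak_intensity * prof
  }
  if (noise_sd > 0) img <- img + rnorm(length(img), 0, noise_sd)
  matrix(as.numeric(round(pmin(pmax(img, 0), params$maxval))), h, w)
}

#' Render field images for a set of wells, with ground truth
#'
#' Splits each well's assigned nucleus count across `fields_per_well` fields
#' (multinomially, as evenly as randomness allows), places nuclei by
#' hard-disk rejection sampling, renders each field, and records the exact
#' centers and intended areas (`pi * r^2`) as ground truth.
#'
#' @param params an `image_params`.
#' @param well_counts data.frame with columns `plate_id`, `well`, `count`
#'   (or a named vector of counts, taken as plate "plate01").
#' @param seed integer seed.
#' @param dir optional directory: writes one 16-bit grayscale TIFF per field
#'   named `{plate}_{well}_f{k}.tif` plus a `truth.csv` sidecar.
#' @return list with `images` (named list of matrices, `{plate}_{well}_f{k}`),
#'   `truth` (per-field data.frame: `plate_id`, `well`, `field`, `count`),
#'   and `objects` (per-nucleus data.frame with centers, radii, areas).
#' @export
render_field_images <- function(params, well_counts, seed = 1, dir = NULL) {
  if (!is.data.frame(well_counts)) {
    well_counts <- data.frame(plate_id = "plate01", well = names(well_counts),
                              count = as.integer(well_counts),
                              stringsAsFactors = FALSE)
  }
  stopifnot(all(c("plate_id", "well", "count") %in% names(well_counts)),
            all(well_counts$count >= 0))
  k <- params$fields_per_well
  res <- with_substream(seed, "images", {
    images <- list()
    truth <- list()
    objects <- list()
    for (i in seq_len(nrow(well_counts))) {
      split <- as.vector(rmultinom(1, well_counts$count[i], rep(1 / k, k)))
      for (f in seq_len(k)) {
        nuc <- place_nuclei(split[f], params)
        key <- sprintf("%s_%s_f%d", well_counts$plate_id[i], well_counts$well[i], f)
        images[[key]] <- render_field(nuc, params)
        truth[[key]] <- data.frame(plate_id = well_counts$plate_id[i],
                                   well = well_counts$well[i], field = f,
                                   count = nrow(nuc), stringsAsFactors = FALSE)
        if (nrow(nuc)) {
          objects[[key]] <- cbind(truth[[key]][rep(1, nrow(nuc)), 1:3],
                                  nuc, area = pi * nuc$radius^2)
        }
      }
    }
    list(images = images,
         truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
         objects = if (length(objects))
           do.call(rbind, c(objects, list(make.row.names = FALSE)))
         else NULL)
  })
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (key in names(res$images)) {
      tiff::writeTIFF(res$images[[key]] / params$maxval,
                      file.path(dir, paste0(key, ".tif")),
                      bits.per.sample = 16L, compression = "none")
    }
    utils::write.csv(res$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  res
}
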
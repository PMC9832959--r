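#' Simulate a qPCR Ct table with planted fold changes
#'
#' For each gene, a "calibrator" group is generated at a baseline target Ct
#' and a "treatment" group whose target Ct is shifted by `-log2(fold)`; the
#' reference (housekeeping, Rpl7-style) Ct is constant up to noise. A
#' delta-delta-Ct analysis of the output recovers the planted folds within
#' noise (exactly at `noise_sd = 0`).
#'
#' @param genes character vector of target genes.
#' @param fold_changes named numeric: gene -> planted fold change of the
#'   treatment group relative to the calibrator group (> 0).
#' @param ct_ref_level reference-gene Ct, cycles (default 18).
#' @param ct_target_base calibrator-group target Ct, cycles (default 25);
#'   recycled over genes.
#' @param noise_sd Gaussian Ct noise, cycles.
#' @param replicates samples per group per gene.
#' @param groups labels for (calibrator, treatment).
#' @param seed integer seed.
#' @return data.frame of class `qpcr_records`: `sample`, `group`, `gene`,
#'   `ct_target`, `ct_reference`.
#' @export
simulate_qpcr <- function(genes, fold_changes, ct_ref_level = 18,
                          ct_target_base = 25, noise_sd = 0, replicates = 3,
                          groups = c("calibrator", "treatment"), seed = 1) {
  stopifnot(length(groups) == 2, replicates >= 1)
  fold_changes <- fold_changes[genes]
  if (any(!is.finite(unlist(fold_changes))) || any(unlist(fold_changes) <= 0))
    stop("fold changes must be positive and given for every gene")
  base <- rep_len(ct_target_base, length(genes))
  with_substream(seed, "qpcr", {
    rows <- lapply(seq_along(genes), function(g) {
      fold <- as.numeric(fold_changes[[genes[g]]])
      do.call(rbind, lapply(1:2, function(k) {
        shift <- if (k == 2) -log2(fold) else 0
        data.frame(
          sample = sprintf("%s_%s_%d", genes[g], groups[k], seq_len(replicates)),
          group = groups[k], gene = genes[g],
          ct_target = base[g] + shift + rnorm(replicates, 0, noise_sd),
          ct_reference = ct_ref_level + rnorm(replicates, 0, noise_sd),
          stringsAsFactors = FALSE)
      }))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("qpcr_records", "data.frame")
    out
  })
}

#' Simulate BrdU-positive points in a region of interest
#'
#' Plants `round(density * area)` points uniformly inside a simple polygon
#' (rejection sampling in the bounding box).
#'
#' @param density BrdU+ cells per pixel^2.
#' @param roi n x 2 polygon matrix, pixel coordinates.
#' @param label region label (e.g. "corpus body", "prepuce").
#' @param seed integer seed.
#' @return list of class `brdu_roi`: `roi`, `points` (m x 2 matrix),
#'   `label`.
#' @export
simulate_brdu_roi <- function(density, roi, label = "roi", seed = 1) {
  stopifnot(density >= 0)
  roi <- validate_polygon(roi)
  n <- round(density * polygon_area(roi))
  pts <- with_substream(seed, "brdu", {
    out <- matrix(numeric(0), ncol = 2)
    bb <- apply(roi, 2, range)
    while (nrow(out) < n) {
      m <- max(32, 2 * (n - nrow(out)))
      cand <- cbind(runif(m, bb[1, 1], bb[2, 1]), runif(m, bb[1, 2], bb[2, 2]))
      keep <- cand[points_in_polygon(cand, roi), , drop = FALSE]
      out <- rbind(out, keep)
    }
    out[seq_len(n), , drop = FALSE]
  })
  colnames(pts) <- c("x", "y")
  structure(list(roi = roi, points = pts, label = label), class = "brdu_roi")
}
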
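#' Two-sided Fisher exact test for a 2x2 table
#'
#' With margins fixed, enumerates the hypergeometric distribution over all
#' feasible tables and sums the probabilities of those no more probable than
#' the observed table (two-sided by the probability-ordering rule).
#' Probabilities are computed from log binomial coefficients; the tie
#' comparison uses a 1e-7 relative tolerance so floating-point ties at the
#' observed probability are included.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return two-sided p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(3, 0, 0, 3), 2))  # 0.1
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("need a 2x2 table")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be nonnegative integers")
  r1 <- sum(table[1, ]); r2 <- sum(table[2, ])
  c1 <- sum(table[, 1]); n <- r1 + r2
  if (n == 0) stop("empty table")
  xs <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, xs) + lchoose(r2, c1 - xs) - lchoose(n, c1)
  p <- exp(logp)
  p_obs <- p[match(table[1, 1], xs)]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

#' Kinase-family enrichment among screen hits
#'
#' For each family f the 2x2 table
#' `[[hits in f, hits not in f], [non-hits in f, non-hits not in f]]` is
#' tested with [fisher_exact_2x2()]. A family is labelled `enriched` when
#' its hit fraction strictly exceeds the overall hit fraction, else
#' `disenriched`; families are ranked by p within each label. Unannotated
#' compounds fall into an `other` family (logged).
#'
#' @param hits character vector of hit compound ids.
#' @param library_annotation data.frame with `compound_id` and `family`
#'   covering the screened library.
#' @return data.frame ranked per label: `family`, `n_family`, `n_hits`,
#'   `hit_fraction`, `overall_hit_fraction`, `odds_direction`, `p`, `label`.
#' @export
family_enrichment <- function(hits, library_annotation) {
  stopifnot(is.data.frame(library_annotation),
            all(c("compound_id", "family") %in% names(library_annotation)))
  ann <- library_annotation[!duplicated(library_annotation$compound_id), ]
  if (!nrow(ann)) stop("empty compound library annotation")
  una <- is.na(ann$family) | ann$family == ""
  if (any(una)) {
    message(sum(una), " unannotated compound(s) assigned family 'other'")
    ann$family[una] <- "other"
  }
  missing_hits <- setdiff(hits, ann$compound_id)
  if (length(missing_hits)) {
    message(length(missing_hits), " hit(s) absent from annotation; added as 'other'")
    ann <- rbind(ann[, c("compound_id", "family")],
                 data.frame(compound_id = missing_hits, family = "other"))
  }
  is_hit <- ann$compound_id %in% hits
  total <- nrow(ann)
  overall <- sum(is_hit) / total
  fams <- sort(unique(ann$family))
  rows <- lapply(fams, function(f) {
    inf <- ann$family == f
    a <- sum(is_hit & inf); b <- sum(is_hit & !inf)
    c <- sum(!is_hit & inf); d <- sum(!is_hit & !inf)
    frac <- a / (a + c)
    data.frame(family = f, n_family = a + c, n_hits = a, hit_fraction = frac,
               overall_hit_fraction = overall,
               odds_direction = ifelse(frac > overall, 1, -1),
               p = fisher_exact_2x2(matrix(c(a, c, b, d), 2)),
               label = ifelse(frac > overall, "enriched", "disenriched"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$label != "enriched", out$p, out$family), ]
  rownames(out) <- NULL
  out
}
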
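test_that("plate median and raw MAD match hand enumeration", {
  expect_equal(plate_mad(c(10, 12, 14, 100)),
               list(median = 13, mad = 2, n = 4, degenerate = FALSE))
  expect_equal(plate_mad(c(5, 7, 9))[c("median", "mad")],
               list(median = 7, mad = 2))
  const <- plate_mad(rep(42, 10))
  expect_equal(const$mad, 0)
  expect_true(const$degenerate)
  expect_error(plate_mad(7), ">= 2")
  expect_error(plate_mad(c(1, NA)), ">= 2")
})

test_that("plate_mad equals a sort-based oracle on random plates", {
  # independent oracle: medians from sorted vectors, no stats::median
  sort_median <- function(x) {
    s <- sort(x); n <- length(s)
    if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  }
  set.seed(42)
  for (i in 1:200) {
    x <- round(rnorm(sample(3:96, 1), 1000, 300))
    pm <- plate_mad(x)
    med <- sort_median(x)
    expect_identical(pm$median, med)
    expect_identical(pm$mad, sort_median(abs(x - med)))
  }
})

test_that("hit calls follow the inclusive 3-MAD band on replicate means", {
  m <- band13_measurements(list(hi = rep(20, 4), lo = rep(6, 4),
                                mid = rep(13, 4), edge = rep(19, 4)))
  hits <- call_hits(m, k = 3)
  ps <- hits$plate_stats
  expect_equal(ps$median_count, 13)
  expect_equal(ps$mad_count, 2)
  calls <- hits$calls
  dir <- setNames(calls$direction, calls$compound_id)
  dev <- setNames(calls$deviation_mads, calls$compound_id)
  expect_equal(dir[["hi"]], "hyper")
  expect_equal(dev[["hi"]], 3.5)
  expect_equal(dir[["lo"]], "hypo")
  expect_equal(dir[["mid"]], "none")
  # boundary: exactly median + 3 MAD is a hit under the inclusive rule only
  expect_equal(dir[["edge"]], "hyper")
  strict <- call_hits(m, k = 3, inclusive = FALSE)
  expect_equal(strict$calls$direction[strict$calls$compound_id == "edge"], "none")
})

test_that("degenerate plates warn and emit no calls", {
  m <- manual_measurements(list(a = rep(50, 4), b = rep(50, 4)),
                           controls = rep(50, 8))
  expect_warning(h <- call_hits(m), "degenerate")
  expect_true(all(h$calls$direction == "none"))
  expect_true(all(is.na(h$calls$deviation_mads)))
})

test_that("a compound measured on two plates is a configuration error", {
  m1 <- manual_measurements(list(a = rep(10, 4)), controls = rep(10, 4),
                            plate_id = "plate01")
  m2 <- manual_measurements(list(a = rep(10, 4)), controls = rep(10, 4),
                            plate_id = "plate02")
  m <- rbind(m1, m2)
  class(m) <- c("well_measurements", "data.frame")
  expect_error(call_hits(m), "more than one plate")
  expect_error(call_hits(band13_measurements(list(a = rep(12, 4))), k = 0), "positive")
})

test_that("control FDR counts per-well outliers against the plate band", {
  # 8 controls, one pushed far above the band -> 12.5% hyper, 0% hypo
  m <- manual_measurements(
    list(a = c(100, 102, 98, 101), b = c(99, 103, 100, 97),
         c = c(101, 99, 102, 100), d = c(98, 100, 101, 99)),
    controls = c(100, 99, 101, 102, 98, 100, 101, 500))
  f <- control_fdr(m, k = 3)
  expect_equal(f$fdr_hyper_percent, 12.5)
  expect_equal(f$fdr_hypo_percent, 0)
  expect_equal(f$n_controls, 8)
  expect_equal(f$flagged_hyper$cell_count, 500)
  no_ctrl <- manual_measurements(list(a = c(1, 2, 3, 4)))
  expect_error(control_fdr(no_ctrl), "no control wells")
})

test_that("hit categories follow the count/size rules", {
  # 101 control wells anchor both statistics against the 16 compound wells:
  # counts 11 x50 / 13 / 15 x50 -> median 13, MAD 2 (hit band [7, 19]);
  # areas 95 x50 / 100 / 105 x50 -> median 100, MAD 5 (verified by hand
  # enumeration over all 117 wells including the compounds below)
  m <- manual_measurements(
    list(c1 = rep(6, 4), c2 = rep(20, 4), c3lo = rep(5, 4), big = rep(21, 4)),
    controls = c(rep(11, 50), 13, rep(15, 50)),
    areas = list(c1 = rep(70, 4),    # shift (70-100)/5  = -6.0 -> shrinkage
                 c2 = rep(76, 4),    # shift -4.8 -> shrinkage
                 c3lo = rep(100, 4), # shift 0
                 big = rep(130, 4)), # shift +6 -> enlarged
    control_areas = c(rep(95, 50), 100, rep(105, 50)))
  h <- categorize_hits(call_hits(m, k = 3), size_k = 3)
  expect_equal(h$plate_stats$median_area, 100)
  expect_equal(h$plate_stats$mad_area, 5)
  cat <- setNames(h$calls$category, h$calls$compound_id)
  expect_equal(cat[["c1"]], "C1")
  expect_equal(cat[["c2"]], "C2")
  expect_equal(cat[["c3lo"]], "C3")
  expect_equal(cat[["big"]], "C3")
  expect_true(h$calls$enlarged[h$calls$compound_id == "big"])
  shift <- setNames(h$calls$nuclear_size_shift, h$calls$compound_id)
  expect_equal(shift[["c1"]], -6)
})

test_that("venn partition is exact set algebra and a disjoint cover", {
  v <- venn_partition(c("A", "B", "C"), c("B", "D"))
  expect_equal(v$male_only, c("A", "C"))
  expect_equal(v$female_only, "D")
  expect_equal(v$both, "B")
  x <- c("p", "q")
  v2 <- venn_partition(x, x)
  expect_equal(v2$both, sort(x))
  expect_length(v2$male_only, 0)
  v3 <- venn_partition(x, character(0))
  expect_equal(v3$male_only, sort(x))
})

test_that("cross-screen concordance matches directions per compound", {
  m <- band13_measurements(list(up = rep(25, 4), dn = rep(5, 4)))
  h <- call_hits(m)
  expect_equal(concordance(h, h)$n_repeated, 2)
  # a screen with the opposite directions repeats nothing
  m_op <- band13_measurements(list(up = rep(5, 4), dn = rep(25, 4)))
  h_op <- call_hits(m_op)
  cc <- concordance(h, h_op)
  expect_equal(cc$n_repeated, 0)
  expect_equal(cc$n_tested, 2)
  # unknown compound is excluded with a message
  expect_message(cc2 <- concordance(h, h_op, c("up", "dn", "ghost")), "absent")
  expect_equal(cc2$n_tested, 2)
  expect_equal(cc2$excluded, "ghost")
})

test_that("hit directions are invariant to count shifts and scalings", {
  set.seed(99)
  for (i in 1:30) {
    n_cpd <- sample(10:30, 1)
    counts <- lapply(seq_len(n_cpd), function(j)
      round(rnorm(4, 1000, 150) * sample(c(0.3, 1, 1, 1, 1.8), 1)))
    names(counts) <- sprintf("c%02d", seq_len(n_cpd))
    m <- manual_measurements(counts, controls = round(rnorm(8, 1000, 150)))
    base <- call_hits(m)$calls
    cshift <- sample(50:500, 1); mscale <- runif(1, 0.2, 5)
    m_sh <- m; m_sh$cell_count <- m$cell_count + cshift
    m_sc <- m; m_sc$cell_count <- m$cell_count * mscale
    expect_equal(call_hits(m_sh)$calls$direction, base$direction)
    expect_equal(call_hits(m_sc)$calls$direction, base$direction)
  }
})

test_that("hit calls are independent of well ordering", {
  lay <- generate_plate_layout(40, 40, 4, 16, 384, seed = 2)
  m <- simulate_screen_counts(lay, plant_effects(sprintf("CPD%03d", 1:40),
                                                 n_hypo = 5, n_hyper = 3, seed = 2),
                              growth_params(), seed = 2)
  h1 <- call_hits(m)
  set.seed(1)
  h2 <- call_hits(m[sample(nrow(m)), ])
  expect_equal(h1$calls, h2$calls)
})

test_that("exact test matches closed cases and the base-R implementation", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2)), 1.0)
  expect_equal(fisher_exact_2x2(matrix(c(3, 0, 0, 3), 2)), 0.1)
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "nonnegative")
  expect_error(fisher_exact_2x2(matrix(0, 2, 2)), "empty")
  set.seed(7)
  for (i in 1:100) {
    tb <- matrix(rpois(4, sample(1:8, 1)), 2)
    if (sum(tb) == 0) next
    expect_equal(fisher_exact_2x2(tb),
                 stats::fisher.test(tb)$p.value, tolerance = 1e-12)
  }
})

test_that("family enrichment recovers a planted all-hypo family", {
  cpds <- sprintf("CPD%03d", 1:120)
  fam <- rep(c("F", "G", "H", "I"), each = 30)
  ann <- data.frame(compound_id = cpds, family = fam)
  hits <- c(cpds[fam == "F"], cpds[fam == "G"][1:3])
  e <- family_enrichment(hits, ann)
  expect_equal(e$family[1], "F")
  expect_equal(e$label[1], "enriched")
  expect_lt(e$p[1], 1e-6)
  # EGFR-like family with no hits ranks disenriched
  expect_true(all(e$label[e$family %in% c("H", "I")] == "disenriched"))
  # single-family library: no contrast, p = 1
  e1 <- family_enrichment(cpds[1:5], data.frame(compound_id = cpds,
                                                family = "only"))
  expect_equal(e1$p, 1)
  # boundary: family hit fraction equal to global is labelled disenriched
  ann2 <- data.frame(compound_id = cpds[1:20], family = rep(c("x", "y"), each = 10))
  e2 <- family_enrichment(c(cpds[1:5], cpds[11:15]), ann2)
  expect_true(all(e2$label == "disenriched"))
  expect_error(family_enrichment("a", data.frame(compound_id = character(0),
                                                 family = character(0))),
               "empty")
})
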
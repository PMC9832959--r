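test_that("screen layout partitions wells and conserves replicate counts", {
  lay <- generate_plate_layout(438, 80, 4, 32, 384, seed = 1)
  for (s in c("male", "female")) {
    sub <- lay[lay$sex == s, ]
    expect_equal(length(unique(sub$plate_id)), 6)
    tab <- table(sub$plate_id, sub$role)
    expect_true(all(tab[1:5, "compound"] == 320))
    expect_true(all(tab[1:5, "control"] == 32))
    expect_true(all(tab[1:5, "empty"] == 32))
    expect_equal(unname(tab["plate06", c("compound", "control", "empty")]),
                 c(152, 32, 200))
    # every compound: exactly 4 wells on exactly one plate
    cw <- sub[sub$role == "compound", ]
    expect_true(all(table(cw$compound_id) == 4))
    expect_true(all(tapply(cw$plate_id, cw$compound_id,
                           function(x) length(unique(x))) == 1))
    expect_setequal(unique(cw$replicate_index), 1:4)
  }
  # wells partition exactly into the three roles
  expect_equal(nrow(lay), 384 * 6 * 2)
  expect_setequal(unique(lay$role), c("compound", "control", "empty"))
})

test_that("layout handles the minimal case and rejects overflow", {
  lay <- generate_plate_layout(1, 1, 4, 0, 384, seed = 1)
  sub <- lay[lay$sex == "male", ]
  expect_equal(sum(sub$role == "compound"), 4)
  expect_equal(sum(sub$role == "empty"), 380)
  expect_error(generate_plate_layout(100, 80, 4, 100, 384, seed = 1),
               "capacity exceeded")
})

test_that("layouts and measurements are deterministic for a fixed seed", {
  expect_identical(generate_plate_layout(90, seed = 11),
                   generate_plate_layout(90, seed = 11))
  lay <- generate_plate_layout(10, 10, 4, 8, 96, seed = 3)
  m1 <- simulate_screen_counts(lay, growth = growth_params(), seed = 5)
  m2 <- simulate_screen_counts(lay, growth = growth_params(), seed = 5)
  expect_identical(m1, m2)
  m3 <- simulate_screen_counts(lay, growth = growth_params(), seed = 6)
  expect_false(identical(m1$cell_count, m3$cell_count))
})

test_that("zero-noise counts and sizes equal their closed forms", {
  g <- growth_params(rate_male = 1.3, rate_female = 1.3,
                     n0_range = c(400, 400), count_cv = 0, size_cv = 0)
  lay <- generate_plate_layout(1, 1, 4, 0, 384, seed = 1)
  m <- simulate_screen_counts(lay, growth = g, days = 6, seed = 1)
  expect_true(all(m$cell_count == round(400 * 1.3^6)))   # 1931
  expect_equal(unique(m$mean_nuclear_area),
               g$size_plateau - (g$size_plateau - g$size0) * (1 - g$size_rate)^6)
  # identity at t = 0
  m0 <- simulate_screen_counts(lay, growth = g, days = 0, seed = 1)
  expect_true(all(m0$cell_count == 400))
  expect_true(all(m0$mean_nuclear_area == g$size0))
})

test_that("growth-course constructions are monotone in their modulators", {
  g <- growth_params(count_cv = 0, size_cv = 0)
  gc <- simulate_growth_course(c("female", "female+MT", "male", "male+FLUT"),
                               1:5, g, seed = 1)
  final <- function(cond) mean(gc$count[gc$condition == cond & gc$day == 5])
  expect_gt(final("female+MT"), final("female"))
  expect_lt(final("male+FLUT"), final("male"))
  expect_error(simulate_growth_course("male", numeric(0)), "non-empty")
  expect_error(simulate_growth_course("male", c(3, 1)), "sorted")
})

test_that("male growth advantage at day 5 is near-universal across seeds", {
  g <- growth_params(count_cv = 0.05)
  wins <- vapply(1:200, function(s) {
    gc <- simulate_growth_course(c("male", "female"), 1:5, g, seed = s)
    d5 <- gc[gc$day == 5, ]
    mean(d5$count[d5$sex == "male"]) > mean(d5$count[d5$sex == "female"])
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("qPCR generator plants folds recoverable by delta-delta-Ct", {
  q <- simulate_qpcr(c("a", "b", "c"), c(a = 1, b = 4, c = 0.33),
                     noise_sd = 0, seed = 1)
  # fold 4 -> target Ct two cycles below calibrator
  cal <- q$ct_target[q$gene == "b" & q$group == "calibrator"]
  trt <- q$ct_target[q$gene == "b" & q$group == "treatment"]
  expect_equal(unique(cal) - unique(trt), 2)
  dd <- delta_delta_ct(q, "calibrator")
  got <- dd$summary$mean_fold[dd$summary$group == "treatment"]
  expect_equal(got, c(1, 4, 0.33)[match(dd$summary$gene[dd$summary$group == "treatment"], c("a", "b", "c"))])
  expect_error(simulate_qpcr("a", c(a = -1)), "positive")
})

test_that("BrdU point planting matches density times area", {
  rect <- matrix(c(0, 0, 100, 0, 100, 500, 0, 500), ncol = 2, byrow = TRUE)
  b <- simulate_brdu_roi(0.001, rect, seed = 2)
  expect_equal(nrow(b$points), 50)
  expect_true(all(points_in_polygon(b$points, rect)))
  b0 <- simulate_brdu_roi(0, rect, seed = 2)
  expect_equal(nrow(b0$points), 0)
  bowtie <- matrix(c(0, 0, 10, 10, 10, 0, 0, 10), ncol = 2, byrow = TRUE)
  expect_error(simulate_brdu_roi(0.01, bowtie), "degenerate")
  expect_error(simulate_brdu_roi(0.01, matrix(c(0, 0, 1, 1, 2, 2), ncol = 2, byrow = TRUE)),
               "degenerate")
})

test_that("field rendering respects ground truth and packing limits", {
  ip <- noiseless_params(field_shape = c(128L, 128L), fields_per_well = 4L)
  wells <- data.frame(plate_id = "p1", well = c("A1", "A2"), count = c(40, 0))
  r <- render_field_images(ip, wells, seed = 4)
  # ground-truth consistency: field counts sum to the assigned well count
  sums <- tapply(r$truth$count, r$truth$well, sum)
  expect_equal(as.vector(sums[c("A1", "A2")]), c(40, 0))
  expect_equal(length(r$images), 8)
  # empty field is pure background
  blank <- r$images[["p1_A2_f1"]]
  expect_true(all(blank == ip$background))
  # determinism: byte-identical images for the same seed
  r2 <- render_field_images(ip, wells, seed = 4)
  expect_identical(r$images, r2$images)
  # infeasible packing errors out with advice
  big <- image_params(field_shape = c(512L, 512L), radius_mean = 40,
                      radius_sd = 0, fields_per_well = 1L)
  expect_error(render_field_images(big, data.frame(plate_id = "p", well = "A1",
                                                   count = 300), seed = 1),
               "overlap_allowed")
  ok <- image_params(field_shape = c(512L, 512L), radius_mean = 5,
                     radius_sd = 0, fields_per_well = 1L)
  rok <- render_field_images(ok, data.frame(plate_id = "p", well = "A1",
                                            count = 300), seed = 1)
  expect_equal(rok$truth$count, 300)
})

test_that("planted effects map is consistent and errors on bad input", {
  cpds <- sprintf("CPD%03d", 1:100)
  eff <- plant_effects(cpds, n_hypo = 10, n_hyper = 5, seed = 2)
  expect_equal(sum(eff$effect_male < 1), 10)
  expect_equal(sum(eff$effect_male > 1), 5)
  expect_true(all(eff$effect_male > 0))
  expect_error(plant_effects(cpds, n_hypo = 90, n_hyper = 20), "<=")
  # unknown compounds in layout get effect 1.0 with a log message
  lay <- generate_plate_layout(3, 3, 2, 0, 96, seed = 1)
  eff2 <- plant_effects("CPD001", n_hypo = 0, n_hyper = 0)
  expect_message(simulate_screen_counts(lay, eff2, growth_params(), seed = 1),
                 "missing from effect map")
})
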
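test_that("Welch t-test matches the hand formula and frozen case", {
  w <- welch_t_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(w$t, -sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(w$df, 4, tolerance = 1e-12)
  expect_equal(w$p, 0.2878641, tolerance = 1e-6)
  same <- welch_t_test(c(5, 6, 7), c(5, 6, 7))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # antisymmetry
  sw <- welch_t_test(c(2, 3, 4), c(1, 2, 3))
  expect_equal(sw$t, -w$t)
  expect_equal(sw$p, w$p)
  expect_error(welch_t_test(1, c(1, 2)), "n >= 2")
  # zero-variance conventions
  expect_equal(welch_t_test(c(1, 1), c(1, 1))$p, 1)
  expect_error(welch_t_from_summary(1, 0, 3, 2, 0, 3), "undefined")
})

test_that("Welch t-test equals the reference implementation on random cases", {
  set.seed(123)
  for (i in 1:1000) {
    a <- rnorm(sample(2:12, 1), 0, runif(1, 0.5, 3))
    b <- rnorm(sample(2:12, 1), runif(1, -2, 2), runif(1, 0.5, 3))
    w <- welch_t_test(a, b)
    ref <- stats::t.test(a, b)
    expect_equal(w$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(w$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(w$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("summary-form Welch with SEM input reproduces the vector form", {
  a <- c(3.2, 4.1, 2.8, 3.9); b <- c(5.0, 4.4, 6.1, 5.2)
  w <- welch_t_test(a, b)
  ws <- welch_t_from_summary(mean(a), sd(a) / sqrt(4), 4,
                             mean(b), sd(b) / sqrt(4), 4, spread_type = "sem")
  expect_equal(ws[c("t", "df", "p")], w[c("t", "df", "p")])
})

test_that("growth-curve comparison flags per-timepoint significance", {
  g <- growth_params(count_cv = 0.05)
  gc <- simulate_growth_course(c("male", "female"), 1:5, g, seed = 3)
  male <- gc[gc$condition == "male", ]
  female <- gc[gc$condition == "female", ]
  tab <- compare_growth_curves(male, female)
  expect_equal(tab$day, 1:5)
  expect_equal(tab$sig_05, tab$p < 0.05)
  expect_equal(attr(tab, "multiplicity_correction"), "none")
  self <- compare_growth_curves(male, male)
  expect_true(all(self$p == 1))
  female_off <- female; female_off$day <- female_off$day + 100
  expect_error(compare_growth_curves(male, female_off), "no timepoints")
})

test_that("size-growth correlation detects the coupled slowdown", {
  g <- growth_params(couple_size_growth = TRUE, count_cv = 0.02)
  gc <- simulate_growth_course("male", 1:6, g, seed = 8)
  res <- size_growth_correlation(gc)
  expect_equal(res$direction, "negative")
  expect_lt(res$rho, 0)
  # perfectly opposed monotone series -> rho exactly -1
  toy <- data.frame(day = rep(1:4, each = 2),
                    count = rep(c(100, 180, 240, 280), each = 2),
                    mean_area = rep(c(50, 70, 90, 110), each = 2))
  expect_equal(size_growth_correlation(toy)$rho, -1)
  # constant mean counts -> zero-variance growth path is flagged
  flat <- data.frame(day = rep(1:4, each = 2), count = 100,
                     mean_area = rep(c(50, 70, 90, 110), each = 2))
  res_flat <- size_growth_correlation(flat)
  expect_true(is.na(res_flat$rho))
  expect_equal(res_flat$direction, "none")
  expect_error(size_growth_correlation(toy[toy$day < 3, ]), ">= 3")
})

test_that("delta-delta-Ct has the right conventions and invariances", {
  q <- simulate_qpcr("g", c(g = 0.33), noise_sd = 0, replicates = 4, seed = 1)
  dd <- delta_delta_ct(q, "calibrator")
  expect_equal(dd$summary$mean_fold[dd$summary$group == "treatment"], 0.33)
  # calibrator geometric mean fold is exactly 1
  cal_folds <- dd$samples$rel_expr[dd$samples$group == "calibrator"]
  expect_equal(exp(mean(log(cal_folds))), 1)
  # one cycle above the calibrator mean dCt -> fold 0.5
  rec <- data.frame(sample = c("a", "b"), group = c("cal", "trt"),
                    gene = "g", ct_target = c(25, 26), ct_reference = 18)
  expect_equal(delta_delta_ct(rec, "cal")$samples$rel_expr, c(1, 0.5))
  # invariant to adding a constant to both Cts of one sample
  rec2 <- rec; rec2$ct_target[2] <- rec2$ct_target[2] + 3
  rec2$ct_reference[2] <- rec2$ct_reference[2] + 3
  expect_equal(delta_delta_ct(rec2, "cal")$samples$rel_expr,
               delta_delta_ct(rec, "cal")$samples$rel_expr)
  # enhanced expression <=> fold > 1 <=> lower ddCt
  rec3 <- rec; rec3$ct_target[2] <- 23
  out <- delta_delta_ct(rec3, "cal")$samples
  expect_gt(out$rel_expr[2], 1)
  expect_lt(out$ddct[2], 0)
  # missing reference Ct drops the sample with a message
  rec4 <- rbind(rec, data.frame(sample = "c", group = "trt", gene = "g",
                                ct_target = 24, ct_reference = NA))
  expect_message(dd4 <- delta_delta_ct(rec4, "cal"), "dropped")
  expect_equal(nrow(dd4$samples), 2)
  expect_error(delta_delta_ct(rec, "nope"), "empty")
})

test_that("BrdU density is a boundary-inclusive count over shoelace area", {
  rect <- matrix(c(0, 0, 100, 0, 100, 500, 0, 500), ncol = 2, byrow = TRUE)
  set.seed(4)
  pts <- cbind(runif(50, 0, 100), runif(50, 0, 500))
  d <- brdu_density(list(roi = rect, points = pts, label = "CB"))
  expect_equal(d$density, 0.001)
  expect_equal(d$area, 50000)
  expect_equal(brdu_density(list(roi = rect, points = NULL))$density, 0)
  # boundary point counts; outside point goes to QC
  d2 <- brdu_density(list(roi = rect, points = rbind(c(0, 0), c(101, 5))))
  expect_equal(d2$n_inside, 1)
  expect_equal(d2$n_outside, 1)
  # rigid motion of polygon + points together leaves density unchanged
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  d3 <- brdu_density(list(roi = rect %*% R + 13, points = pts %*% R + 13))
  expect_equal(d3$density, d$density)
  # generator round trip
  b <- simulate_brdu_roi(0.001079, matrix(c(0, 0, 1000, 0, 1000, 1000, 0, 1000),
                                          ncol = 2, byrow = TRUE), seed = 5)
  expect_equal(nrow(b$points), 1079)
  expect_equal(brdu_density(b)$density, 1079 / 1e6)
})

test_that("BrdU group comparison reports dual spreads and round-trips", {
  a <- c(0.0010, 0.0011, 0.0012, 0.0010)
  cmp <- brdu_group_compare(a, a * 3)
  expect_lt(cmp$p, 0.05)
  parsed <- parse_brdu_summary(cmp$group_a$format)
  expect_equal(parsed$mean, cmp$group_a$mean, tolerance = 1e-3)
  expect_equal(parsed$n, 4)
  eq <- brdu_group_compare(a, a)
  expect_equal(eq$p, 1)
  # planted 3x difference detected in most seeds
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    x <- 0.001 * exp(rnorm(4, 0, 0.1)); y <- 0.003 * exp(rnorm(4, 0, 0.1))
    brdu_group_compare(x, y)$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
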
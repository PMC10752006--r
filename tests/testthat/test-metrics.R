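test_that("ROI means average valid voxels and flag invalid ones", {
  map <- array(0.5, c(3, 3, 1))
  roi_all <- roi_spec(array(1L, c(3, 3, 1)), 0.01, "metric_roi")
  expect_equal(roi_mean(map, roi_all), 0.5)
  map2 <- array(c(0.10, 0.14), c(2, 1, 1))
  expect_equal(roi_mean(map2, roi_spec(array(1L, c(2, 1, 1)), 0.01,
                                       "metric_roi")), 0.12)
  # one invalid voxel is dropped with a warning; mean recomputed directly
  map3 <- array(seq_len(9) / 10, c(3, 3, 1))
  map3[2, 2, 1] <- NA
  expect_warning(m <- roi_mean(map3, roi_all), "1 invalid voxel")
  expect_equal(m, mean(map3[!is.na(map3)]))
  # degenerate ROIs are errors
  expect_error(roi_mean(map, roi_spec(matrix(numeric(0), 0, 3), 0.01,
                                      "metric_roi")), "empty ROI")
  expect_error(roi_mean(array(NA_real_, c(1, 1, 1)),
                        roi_spec(array(1L, c(1, 1, 1)), 0.01, "metric_roi")),
               "invalid")
  expect_error(roi_mean(map, roi_spec(matrix(c(5, 0, 0), 1), 0.01,
                                      "metric_roi")), "bounds")
  expect_error(roi_mean(map, roi_spec(array(1L, c(3, 3, 1)), 0.01,
                                      "whole_nerve_roi")), "metric_roi")
})

test_that("nerve volume is voxel count times voxel volume", {
  roi10 <- roi_spec(cbind(0:9, 0, 0), 0.01, "whole_nerve_roi")
  expect_equal(nerve_volume(roi10), 0.10)
  vox <- prod(c(0.0586, 0.0586, 1))
  roi41 <- roi_spec(cbind(0:40, 0, 0), vox, "whole_nerve_roi")
  expect_equal(nerve_volume(roi41), 41 * vox)
  expect_equal(nerve_volume(roi41), 0.1406, tolerance = 2e-3)
  expect_error(nerve_volume(roi_spec(matrix(numeric(0), 0, 3), 0.01,
                                     "whole_nerve_roi")), "empty")
  expect_error(nerve_volume(roi_spec(cbind(0, 0, 0), 0.01, "metric_roi")),
               "whole_nerve_roi")
})

test_that("axon volume is the exact product and monotone in both factors", {
  expect_equal(axon_volume(0.15, 0.76), 0.114)
  expect_equal(axon_volume(0.14, 0.81), 0.1134)
  expect_equal(axon_volume(0.2, 0), 0)
  v <- seq(0, 0.3, 0.05); f <- seq(0, 1, 0.2)
  expect_true(all(diff(axon_volume(v, 0.7)) >= 0))
  expect_true(all(diff(axon_volume(0.14, f)) >= 0))
  expect_true(all(axon_volume(v, 0.7) <= v))
  expect_error(axon_volume(0.1, 1.2), "fiber_fraction")
  expect_error(axon_volume(-0.1, 0.5), "nerve_volume")
})

test_that("percent change honors the explicit denominator convention", {
  expect_equal(percent_change(0.03, 0.12, "reference"), 300)
  expect_equal(percent_change(1, 1, "reference"), 0)
  expect_equal(percent_change(1.89, 1.47, "reference"), -22.2, tolerance = 0.05)
  # denominator choice is not symmetric, matching the two published usages
  expect_equal(percent_change(0.10, 0.19, "comparison"), 47.4, tolerance = 0.05)
  expect_false(isTRUE(all.equal(percent_change(0.10, 0.19, "reference"),
                                percent_change(0.10, 0.19, "comparison"))))
  expect_equal(percent_change(0.12, 0.10, "larger"),
               percent_change(0.12, 0.10, "reference"))
  expect_error(percent_change(0, 0.1, "reference"), "zero")
})

test_that("Pearson r matches a direct covariance-formula oracle", {
  expect_equal(pearson_r2(1:5, 2 * (1:5) + 3)$r2, 1)
  expect_equal(pearson_r2(c(0, 1, 2), c(0, 1, 0))$r, 0)
  set.seed(13)
  x <- rnorm(10); y <- 0.8 * x + rnorm(10, 0, 0.5)
  out <- pearson_r2(x, y)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_direct <- r_direct * sqrt(8 / (1 - r_direct^2))
  p_direct <- 2 * pt(-abs(t_direct), df = 8)
  expect_equal(out$r, r_direct, tolerance = 1e-12)
  expect_equal(out$r2, r_direct^2, tolerance = 1e-12)
  expect_equal(out$p, p_direct, tolerance = 1e-12)
  expect_error(pearson_r2(rep(1, 5), rnorm(5)), "constant")
  expect_error(pearson_r2(1:2, 1:2), "3 complete pairs")
})

test_that("two-way ANOVA matches manual sums of squares on a balanced toy", {
  toy <- data.frame(
    group = rep(c("sham", "TBI"), each = 4),
    day = rep(rep(c(1, 3), each = 2), 2),
    metric = "m",
    value = c(1.0, 1.2, 2.0, 2.2, 1.5, 1.7, 3.1, 3.3))
  out <- two_way_anova(toy, "m")
  # manual two-way decomposition (balanced, so Type II = textbook SS)
  y <- toy$value
  gm <- mean(y)
  mg <- tapply(y, toy$group, mean); md <- tapply(y, toy$day, mean)
  mc <- tapply(y, interaction(toy$group, toy$day), mean)
  ss_g <- 4 * sum((mg - gm)^2)
  ss_d <- 4 * sum((md - gm)^2)
  ss_cells <- 2 * sum((mc - gm)^2)
  ss_gd <- ss_cells - ss_g - ss_d
  ss_e <- sum((y - rep(mc[interaction(toy$group, toy$day)], 1))^2)
  ms_e <- ss_e / 4
  expect_equal(out$F, c(ss_g / 1, ss_d / 1, ss_gd / 1) / ms_e,
               tolerance = 1e-10)
  expect_equal(out$p[1], 1 - pf(out$F[1], 1, 4), tolerance = 1e-12)
})

test_that("ANOVA detects a 3-SD group shift and not a null one", {
  set.seed(21)
  base <- expand.grid(group = c("sham", "TBI"), day = c(1, 3, 7, 30),
                      rep = 1:10)
  null_tab <- data.frame(base[c("group", "day")], metric = "m",
                         value = rnorm(nrow(base), 1, 0.1))
  out0 <- two_way_anova(null_tab, "m")
  expect_gt(out0$p[1], 0.05)
  shift_tab <- null_tab
  shift_tab$value <- shift_tab$value + ifelse(shift_tab$group == "TBI", 0.3, 0)
  out1 <- two_way_anova(shift_tab, "m")
  expect_lt(out1$p[1], 0.001)
  # identical groups: F ~ 0, p ~ 1
  dup <- null_tab[null_tab$group == "sham", ]
  dup$group <- "TBI"
  out2 <- two_way_anova(rbind(null_tab[null_tab$group == "sham", ], dup), "m")
  expect_lt(out2$F[1], 1e-10)
  expect_gt(out2$p[1], 0.999)
  # empty / underfilled cells are named
  expect_error(two_way_anova(null_tab[!(null_tab$group == "TBI" &
                                          null_tab$day == 7), ], "m"),
               "TBI:7")
  expect_error(two_way_anova(null_tab, "absent"), "no records")
})

test_that("group summaries aggregate per group, day and metric", {
  tab <- data.frame(animal = rep(c("a", "b"), each = 2),
                    group = rep(c("sham", "TBI"), each = 2),
                    eye = c("L", "R", "L", "R"), day = 3, metric = "m",
                    value = c(1, 3, 5, 9))
  gs <- group_summary(tab)
  expect_equal(gs$mean[gs$group == "sham"], 2)
  expect_equal(gs$mean[gs$group == "TBI"], 7)
  expect_equal(gs$sd[gs$group == "TBI"], sd(c(5, 9)))
  expect_equal(gs$n, c(2, 2))
})
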
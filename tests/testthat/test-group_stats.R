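make_records <- function(values_by_animal, groups, cells = NULL) {
  recs <- list()
  for (a in seq_along(values_by_animal)) {
    v <- values_by_animal[[a]]
    recs[[a]] <- data.frame(animal_id = sprintf("a%02d", a),
                            group = groups[a],
                            cell_id = sprintf("a%02d_c%02d", a, seq_along(v)),
                            value = v)
  }
  do.call(rbind, recs)
}

test_that("percent change arithmetic matches its definition", {
  expect_equal(round(percent_change(0.89, 0.62)), 30)
  expect_equal(round(percent_change(36.0, 24.7)), 31)
  expect_equal(percent_change(5, 5), 0)
  # exact identity: percent_change(a, a (1 - q/100)) = q
  for (q in c(-50, 0, 12.5, 99)) expect_equal(percent_change(4, 4 * (1 - q / 100)), q)
  expect_error(percent_change(0, 1), class = "nc_validation_error")
  expect_error(percent_change(-2, 1), class = "nc_validation_error")
})

test_that("identical values give zero difference and p ~ 1", {
  recs <- make_records(rep(list(rep(3.5, 4)), 4),
                       c("control", "control", "disease", "disease"))
  cmp <- compare_groups(recs, "value")
  expect_equal(cmp$estimate, 0)
  expect_equal(cmp$p_value, 1)
  expect_true(cmp$degenerate)
})

test_that("comparison is invariant to row and animal ordering", {
  set.seed(42)
  recs <- make_records(lapply(1:6, function(i) rnorm(5, 10 + (i > 3))),
                       rep(c("control", "disease"), each = 3))
  recs$value <- recs$value
  a <- compare_groups(recs, "value")
  b <- compare_groups(recs[sample(nrow(recs)), ], "value")
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$estimate, b$estimate)
})

test_that("design prerequisites are enforced", {
  recs <- make_records(list(rnorm(3), rnorm(3), rnorm(3)),
                       c("control", "disease", "disease"))
  expect_error(compare_groups(recs, "value"), class = "nc_inference_error")
  expect_error(compare_groups(recs, "missing_metric"),
               class = "nc_validation_error")
})

test_that("with one cell per animal the mixed model agrees with the t-test", {
  set.seed(101)
  for (rep in 1:5) {
    vals <- lapply(1:10, function(i) rnorm(1, mean = 10 + 0.4 * (i > 5)))
    recs <- make_records(vals, rep(c("control", "disease"), each = 5))
    cmp <- compare_groups(recs, "value")
    tt <- t.test(value ~ group, data = recs, var.equal = TRUE)
    expect_equal(cmp$p_value, tt$p.value, tolerance = 0.02)
    expect_equal(cmp$estimate,
                 -unname(diff(rev(tt$estimate))), tolerance = 1e-6)
  }
})

test_that("type-I error of the nested comparison is nominal under the null", {
  set.seed(2024)
  n_rep <- 200
  rejections <- 0
  for (r in seq_len(n_rep)) {
    animal_means <- rnorm(10, 10, 0.5) # shared animal-level variation
    vals <- lapply(seq_len(10), function(a) rnorm(6, animal_means[a], 1))
    recs <- make_records(vals, rep(c("control", "disease"), each = 5))
    p <- compare_groups(recs, "value")$p_value
    if (p <= 0.05) rejections <- rejections + 1
  }
  # binomial 95% band around 0.05 with 200 replicates: [0.02, 0.081]
  expect_gte(rejections / n_rep, 0.02)
  expect_lte(rejections / n_rep, 0.081)
})

test_that("nested comparison is robust to pseudo-replication", {
  # strong animal effects, no group effect: a naive cell-level t-test
  # rejects far too often; the mixed model must not follow it
  set.seed(7)
  n_rep <- 60
  naive <- mixed <- 0
  for (r in seq_len(n_rep)) {
    animal_means <- rnorm(4, 10, 1.5)
    vals <- lapply(1:4, function(a) rnorm(12, animal_means[a], 0.3))
    recs <- make_records(vals, rep(c("control", "disease"), each = 2))
    if (t.test(value ~ group, data = recs)$p.value <= 0.05) naive <- naive + 1
    if (compare_groups(recs, "value")$p_value <= 0.05) mixed <- mixed + 1
  }
  expect_gt(naive, mixed)
  expect_lte(mixed / n_rep, 0.15)
})

test_that("densitometry comparison normalizes, collapses replicates, then tests", {
  tab <- data.frame(
    sample_id = rep(c("c1", "c2", "c3", "d1", "d2", "d3"), each = 3),
    group = rep(c("control", "disease"), each = 9),
    target_band_intensity = rep(c(8.9, 9.2, 8.6, 6.1, 6.3, 6.2), each = 3) *
      rep(c(1, 1.05, 0.95), times = 6),
    loading_control_band_intensity = 10)
  cmp <- densitometry_compare(tab)
  expect_equal(unname(cmp$control["n"]), 3)
  expect_s3_class(cmp, "group_comparison")
  # means constructed to sit at 0.89 vs 0.62 -> ~30% reduction
  expect_equal(unname(cmp$control["mean"]), 0.89, tolerance = 1e-9)
  expect_equal(unname(cmp$disease["mean"]), 0.62, tolerance = 1e-9)
  expect_equal(round(unname(cmp$percent_change), 1), 30.3)

  # identical groups: zero difference, p = 1
  same <- data.frame(sample_id = c("c1", "c2", "d1", "d2"),
                     group = rep(c("control", "disease"), each = 2),
                     target_band_intensity = 5,
                     loading_control_band_intensity = 10)
  cmp0 <- densitometry_compare(same)
  expect_equal(cmp0$estimate, 0)
  expect_equal(cmp0$p_value, 1)

  expect_error(densitometry_compare(same[c(1, 3, 4), ]),
               class = "nc_inference_error")
  bad <- same; bad$target_band_intensity[1] <- -1
  expect_error(densitometry_compare(bad), class = "nc_validation_error")
})

test_that("densitometry recovers a known expression ratio from lognormal bands", {
  set.seed(31)
  ratios <- replicate(50, {
    ctrl <- exp(rnorm(4, log(1.0), 0.15))
    dis <- exp(rnorm(4, log(0.7), 0.15))
    tab <- data.frame(sample_id = c(sprintf("c%d", 1:4), sprintf("d%d", 1:4)),
                      group = rep(c("control", "disease"), each = 4),
                      target_band_intensity = c(ctrl, dis) * 50,
                      loading_control_band_intensity = 50)
    cmp <- densitometry_compare(tab)
    unname(cmp$disease["mean"] / cmp$control["mean"])
  })
  se <- sd(ratios) / sqrt(length(ratios))
  # Jensen bias of a ratio of sample means is O(cv^2/n) ~ 0.004 here
  expect_lt(abs(mean(ratios) - 0.7), 3 * se + 0.01)
})
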
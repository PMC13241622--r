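test_that("scene simulation honours trivial configurations", {
  base <- scene_config(frame_size_nm = c(1500, 1500), soma_radius_nm = 650,
                       nucleus_radius_nm = 250)
  empty_cfg <- base; empty_cfg$n_clusters <- 0L
  expect_length(simulate_scene(empty_cfg, seed = 1)$clusters, 0)

  # constant-1 size law: geometric with mean 1 is degenerate at 1 channel
  one_cfg <- scene_config(frame_size_nm = c(1500, 1500), soma_radius_nm = 650,
                          nucleus_radius_nm = 250, mean_channels = 1,
                          n_clusters = 10)
  scene <- simulate_scene(one_cfg, seed = 2)
  tr <- scene_truth(scene)
  expect_equal(tr$n_channels, rep(1L, 10))
  expect_equal(tr$true_area_nm2, rep(900, 10))
})

test_that("channels-per-cluster law realizes its configured mean", {
  # scaled down from the 10k-cluster statement: 1500 clusters, same 2-SE check
  cfg <- scene_config(frame_size_nm = c(20000, 20000), soma_radius_nm = 9500,
                      nucleus_radius_nm = 550, n_clusters = 1500,
                      mean_channels = 15)
  tr <- scene_truth(simulate_scene(cfg, seed = 9))
  se <- sqrt(15 * 14) / sqrt(1500) # geometric(mean m): var = m(m-1)
  expect_lt(abs(mean(tr$n_channels) - 15), 2 * se)
})

test_that("placement respects ROI geometry and the minimum edge gap", {
  cfg <- scene_config(frame_size_nm = c(2000, 2000), soma_radius_nm = 900,
                      nucleus_radius_nm = 350, n_clusters = 15)
  scene <- simulate_scene(cfg, seed = 4)
  centre <- scene$soma_centre_nm
  for (cl in scene$clusters) {
    d <- sqrt(colSums((t(cl$channels_xy) - centre)^2))
    expect_true(all(d <= cfg$soma_radius_nm))
    expect_true(all(d >= cfg$nucleus_radius_nm - sqrt(450))) # centre can graze
  }
  # bounding circles honour the configured gap
  ctr <- t(vapply(scene$clusters, `[[`, numeric(2), "centre"))
  rad <- vapply(scene$clusters, `[[`, 0, "radius")
  for (a in 1:14) for (b in (a + 1):15) {
    gap <- sqrt(sum((ctr[a, ] - ctr[b, ])^2)) - rad[a] - rad[b]
    expect_gte(gap, cfg$min_edge_gap_nm - 1e-9)
  }
  # impossible demand fails loudly
  tight <- scene_config(frame_size_nm = c(1200, 1200), soma_radius_nm = 500,
                        nucleus_radius_nm = 200, n_clusters = 200)
  expect_error(simulate_scene(tight, seed = 1, max_tries = 50),
               class = "nc_placement_error")
})

test_that("localization simulation follows the emission hierarchy", {
  cfg <- scene_config(frame_size_nm = c(1500, 1500), soma_radius_nm = 650,
                      nucleus_radius_nm = 250, n_clusters = 5)
  scene <- simulate_scene(cfg, seed = 5)
  # no labels, no background -> empty table
  em0 <- emission_config(labeling_efficiency = 0, background_rate_um2 = 0)
  expect_equal(nrow(simulate_localizations(scene, em0, seed = 1)), 0)

  # sigma = 0, one blink, full labeling -> events exactly at channel sites
  one <- scene_config(frame_size_nm = c(1500, 1500), soma_radius_nm = 650,
                      nucleus_radius_nm = 250, mean_channels = 1, n_clusters = 1)
  sc1 <- simulate_scene(one, seed = 6)
  em1 <- emission_config(labeling_efficiency = 1, mean_blinks = 1,
                         localization_precision_nm = 0, background_rate_um2 = 0)
  locs <- simulate_localizations(sc1, em1, seed = 2)
  expect_equal(nrow(locs), 1)
  expect_equal(c(locs$x_nm, locs$y_nm), as.numeric(sc1$clusters[[1]]$channels_xy))

  # expectation check: total rows ~ n_channels * efficiency * mean_blinks
  big <- scene_config(frame_size_nm = c(8000, 8000), soma_radius_nm = 3800,
                      nucleus_radius_nm = 550, n_clusters = 80,
                      mean_channels = 13)
  scb <- simulate_scene(big, seed = 7)
  nch <- sum(scene_truth(scb)$n_channels)
  em <- emission_config(labeling_efficiency = 0.9, mean_blinks = 5,
                        background_rate_um2 = 0)
  got <- nrow(simulate_localizations(scb, em, seed = 8))
  mu <- nch * 0.9 * 5
  # per-channel count variance: E[L]Var(B) + Var(L)E[B]^2 (B = 1+Pois(4))
  se <- sqrt(nch * (0.9 * 4 + 0.09 * 25))
  expect_lt(abs(got - mu), 2 * se)
})

test_that("rendering deposits and conserves event weight", {
  # nearest-pixel binning: one event, one pixel, exact weight
  locs <- data.frame(x_nm = 12.5, y_nm = 27.5, frame = 1L, weight = 3)
  img <- render(locs, pixel_size_nm = 5, frame_size_nm = c(100, 100),
                sigma_render_nm = 0)
  expect_equal(sum(img$pixels > 0), 1)
  expect_equal(img$pixels[6, 3], 3) # row = y/5 rounded up, col = x/5
  expect_equal(sum(img$pixels), 3)

  # conservation for events well inside the frame
  set.seed(12)
  n <- 400
  locs <- data.frame(x_nm = runif(n, 150, 850), y_nm = runif(n, 150, 850),
                     frame = 1L, weight = 1)
  img <- render(locs, 5, c(1000, 1000), sigma_render_nm = 12)
  expect_equal(sum(img$pixels), n, tolerance = 1e-3)

  # event at an interior pixel corner: exact 4-fold symmetric deposition,
  # each quadrant matching the analytic per-pixel kernel integral
  img <- render(data.frame(x_nm = 50, y_nm = 50, weight = 1), 5,
                c(100, 100), sigma_render_nm = 4)
  q <- img$pixels[10:11, 10:11]
  expect_equal(q[1, 1], q[1, 2])
  expect_equal(q[1, 1], q[2, 1])
  expect_equal(q[1, 1], q[2, 2])
  anl <- (pnorm(5, 0, 4) - pnorm(0, 0, 4))^2
  expect_equal(q[1, 1], anl, tolerance = 1e-6)

  expect_error(render(locs, pixel_size_nm = 0, frame_size_nm = c(100, 100)),
               class = "nc_validation_error")
})

test_that("identical seeds reproduce scenes, tables and images bit-for-bit", {
  cfg <- scene_config(frame_size_nm = c(1500, 1500), soma_radius_nm = 650,
                      nucleus_radius_nm = 250)
  a <- simulate_cell(cfg, seed = 33)
  b <- simulate_cell(cfg, seed = 33)
  c <- simulate_cell(cfg, seed = 34)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(as.data.frame(a$locs), as.data.frame(b$locs))
  expect_identical(scene_truth(a$scene), scene_truth(b$scene))
  expect_false(identical(a$image$pixels, c$image$pixels))
})

test_that("two-group designs apply the group effect and nesting", {
  cfg <- scene_config(frame_size_nm = c(1500, 1500), soma_radius_nm = 650,
                      nucleus_radius_nm = 250)
  # minimal design: one animal, one cell per group
  ds <- make_two_group_dataset(cfg, n_animals_per_group = 1,
                               cells_per_animal = 1, animal_sd = 0,
                               seed = 1)
  expect_length(ds, 2)
  expect_setequal(vapply(ds, `[[`, "", "group"), c("control", "disease"))
  # with animal_sd = 0 the configured law means are exact
  mu <- vapply(ds, `[[`, 0, "true_mean_channels")
  grp <- vapply(ds, `[[`, "", "group")
  expect_equal(unname(mu[grp == "disease"] / mu[grp == "control"]), 0.79)

  # realized ground-truth group means track the 0.79 effect
  ds2 <- make_two_group_dataset(cfg, n_animals_per_group = 2,
                                cells_per_animal = 4, animal_sd = 0,
                                seed = 2,
                                cell_fun = function(image, roi, scene) NULL)
  truth <- data.table::rbindlist(lapply(ds2, function(r)
    data.table::data.table(group = r$group, area = r$truth$true_area_nm2)))
  ratio <- mean(truth$area[truth$group == "disease"]) /
    mean(truth$area[truth$group == "control"])
  n_d <- sum(truth$group == "disease")
  # geometric law: sd ~ mean, so the ratio has relative SE ~ sqrt(2/n)
  expect_lt(abs(ratio - 0.79), 2 * 0.79 * sqrt(2 / n_d))
})

test_that("with no group effect and no animal effect the groups are exchangeable", {
  # 100 replicates; per replicate a two-sample t-test on per-cell true
  # mean areas should stay non-significant ~95% of the time
  # modest density: a tiny ROI at the default 10/um^2 can jam placement
  cfg <- scene_config(frame_size_nm = c(1600, 1600), soma_radius_nm = 700,
                      nucleus_radius_nm = 260, group_effect = 1,
                      cluster_density_um2 = 6)
  reject <- 0L
  for (r in 1:100) {
    ds <- make_two_group_dataset(cfg, n_animals_per_group = 2,
                                 cells_per_animal = 2, animal_sd = 0,
                                 seed = 60000 + r,
                                 cell_fun = function(image, roi, scene) NULL)
    v <- vapply(ds, function(x) mean(x$truth$true_area_nm2), 0)
    g <- vapply(ds, `[[`, "", "group")
    if (t.test(v[g == "control"], v[g == "disease"])$p.value <= 0.05)
      reject <- reject + 1L
  }
  expect_gte(100L - reject, 94L)
})
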
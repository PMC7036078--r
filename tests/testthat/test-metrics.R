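test_that("scalar metrics match brute-force formulas on random maps", {
  set.seed(77)
  for (rep in 1:25) {
    m <- random_label_mesh(sample(30:120, 1))
    map <- random_map(m)
    t <- map$times
    lv <- m$chamber %in% c("LV", "SEPTUM")
    rv <- m$chamber == "RV"
    lv_epi <- m$chamber == "LV" & m$surface == "EPI"
    expect_equal(compute_vvtat(map), max(t) - min(t), tolerance = 1e-12)
    expect_equal(compute_lvtat(map), max(t[lv]) - min(t[lv]), tolerance = 1e-12)
    expect_equal(compute_vvsync(map), abs(mean(t[lv]) - mean(t[rv])),
      tolerance = 1e-12
    )
    if (sum(lv_epi) >= 2) {
      expect_equal(compute_lvdisp(map), oracle_pop_sd(t[lv_epi]),
        tolerance = 1e-12
      )
    }
    expect_lte(compute_lvtat(map), compute_vvtat(map))
  }
})

test_that("metric edge cases behave as defined", {
  m <- random_label_mesh(40)
  uniform <- activation_map(m, rep(40, 40))
  expect_equal(compute_vvtat(uniform), 0)
  expect_equal(compute_lvdisp(uniform), 0)
  # LV constant, RV varying: LVtat 0
  t <- rep(25, 40)
  t[m$chamber == "RV"] <- stats::runif(sum(m$chamber == "RV"), 0, 90)
  expect_equal(compute_lvtat(activation_map(m, t)), 0)
  # two-point population SD
  m2 <- random_label_mesh(8)
  m2$chamber[] <- "LV"
  m2$surface[] <- "ENDO_LV"
  m2$chamber[3] <- "RV"
  m2$surface[c(1, 2)] <- "EPI"
  t2 <- rep(4, 8)
  t2[c(1, 2)] <- c(0, 10)
  expect_equal(compute_lvdisp(activation_map(m2, t2)), 5)
  # chamber mean difference on block-constant map
  t3 <- ifelse(m$chamber == "RV", 20, 60)
  expect_equal(compute_vvsync(activation_map(m, t3)), 40)
  expect_equal(
    compute_vvsync(activation_map(m, t3), signed = TRUE), 40
  )
})

test_that("isochrone bands partition reached vertices into 30 equal widths", {
  m <- random_label_mesh(60)
  t <- stats::runif(60, 10, 100)
  t[1] <- 10
  t[2] <- 100 # pin the range to 90 ms
  map <- activation_map(m, t)
  iso <- build_isochrones(map)
  expect_equal(iso$n_bands, 30L)
  expect_equal(diff(iso$band_edges)[1], 3, tolerance = 1e-12) # 90/30 ms
  expect_equal(iso$band_index[2], 30L) # max goes in the last band
  counts <- table(iso$band_index)
  expect_equal(sum(counts), 60)
  # constant map: everything in band 1
  iso0 <- build_isochrones(activation_map(m, rep(7, 60)))
  expect_true(all(iso0$band_index == 1L))
  expect_error(build_isochrones(map, 0), "at least one")
})

test_that("final segments report every segment touched by the last band", {
  m <- test_mesh()
  seg <- assign_aha_segments(m)
  fc <- mesh_frame_coords(m)
  # craft a map whose last band straddles segments 5 and 11
  t <- stats::runif(nrow(m$vertices), 0, 50)
  pick5 <- which(seg == 5)[1]
  pick11 <- which(seg == 11)[1]
  t[c(pick5, pick11)] <- 100
  map <- activation_map(m, t)
  expect_equal(final_segments(map, seg), c(5L, 11L))
  # single-segment case
  t[pick11] <- 50
  expect_equal(final_segments(map = activation_map(m, t), seg), 5L)
  # RV-only last band falls back to the latest LV band, with a message
  t2 <- stats::runif(nrow(m$vertices), 0, 50)
  t2[which(m$chamber == "RV")[1]] <- 200
  t2[pick5] <- 49.9999
  expect_message(
    fs <- final_segments(activation_map(m, t2), seg),
    "falling back"
  )
  expect_true(5L %in% fs)
})

test_that("wave-front angle recovers constructed isochrone orientations", {
  m <- test_mesh()
  proj <- lao_cranial_projection(m)
  h <- proj$coords[, 1]
  v <- proj$coords[, 2]
  ang_dist <- function(a, b) min(abs(a - b) %% 180, 180 - abs(a - b) %% 180)
  # planar wave sweeping vertically: bands are horizontal lines -> 0 degrees
  map_h <- activation_map(m, v - min(v))
  expect_lt(ang_dist(wavefront_angle(map_h, proj), 0), 2)
  # wave along the +45 degree diagonal: isochrone lines at 135 degrees
  map_d <- activation_map(m, (h + v) / sqrt(2) - min((h + v) / sqrt(2)))
  expect_lt(ang_dist(wavefront_angle(map_d, proj), 135), 2)
  # equivariance: rotating projected coordinates rotates the angle
  a0 <- wavefront_angle(map_d, proj, iso_index = 15)
  rot <- pi / 6
  proj_rot <- proj
  proj_rot$coords <- proj$coords %*%
    rbind(c(cos(rot), sin(rot)), c(-sin(rot), cos(rot)))
  a1 <- wavefront_angle(map_d, proj_rot, iso_index = 15)
  expect_equal((a1 - a0) %% 180, 30, tolerance = 1e-6)
})

test_that("latest-region centroid is the mean of the latest masked band", {
  set.seed(11)
  m <- random_label_mesh(80)
  map <- random_map(m)
  iso <- build_isochrones(map)
  mask <- which(m$chamber == "LV")
  ctr <- latest_region_centroid(map, iso, mask)
  band <- iso$band_index[mask]
  sel <- mask[band == max(band)]
  expect_equal(ctr, colMeans(m$vertices[sel, , drop = FALSE]),
    tolerance = 1e-12
  )
  # degenerate one- and two-vertex regions
  t <- rep(1, 80)
  t[mask[1]] <- 99
  expect_equal(
    latest_region_centroid(activation_map(m, t), mask = mask),
    m$vertices[mask[1], ]
  )
  t[mask[2]] <- 99
  expect_equal(
    latest_region_centroid(activation_map(m, t), mask = mask),
    colMeans(m$vertices[mask[1:2], ])
  )
  expect_error(latest_region_centroid(map, iso, integer()), "empty mask")
})

test_that("scenario comparison matches brute-force normalization and Pearson", {
  set.seed(5)
  m <- test_mesh()
  proj <- lao_cranial_projection(m)
  map_a <- random_map(m)
  map_b <- random_map(m)
  cmp <- compare_scenarios(map_a, map_b, proj)
  na <- (map_a$times - min(map_a$times)) / (max(map_a$times) - min(map_a$times))
  nb <- (map_b$times - min(map_b$times)) / (max(map_b$times) - min(map_b$times))
  r_oracle <- sum((na - mean(na)) * (nb - mean(nb))) /
    sqrt(sum((na - mean(na))^2) * sum((nb - mean(nb))^2))
  expect_equal(cmp$pearson_r, r_oracle, tolerance = 1e-12)
  # self-comparison: r = 1, no shift, no rotation
  self <- compare_scenarios(map_a, map_a, proj)
  expect_equal(self$pearson_r, 1, tolerance = 1e-12)
  expect_equal(self$latest_region_shift, 0)
  expect_equal(self$wfa_delta, 0)
  # affine invariance of r
  map_c <- activation_map(m, 12 + 3.5 * map_a$times)
  expect_equal(compare_scenarios(map_a, map_c, proj)$pearson_r, 1,
    tolerance = 1e-12
  )
  expect_error(
    compare_scenarios(map_a, activation_map(m, rep(3, nrow(m$vertices))), proj),
    "zero-variance"
  )
})

test_that("metrics are time-shift invariant and time-scale covariant", {
  set.seed(9)
  m <- test_mesh()
  seg <- assign_aha_segments(m)
  proj <- lao_cranial_projection(m)
  map <- simulate_activation(
    m, conduction_model(), make_scenario("LBBB", m)
  )
  ms0 <- compute_metrics(map, seg, proj)
  shifted <- activation_map(m, map$times + 17.3, map$scenario)
  ms_shift <- compute_metrics(shifted, seg, proj)
  for (f in c("vvtat", "vvsync", "lvtat", "lvdisp", "wfa")) {
    expect_equal(ms_shift[[f]], ms0[[f]], tolerance = 1e-9, info = f)
  }
  expect_identical(ms_shift$final_segments, ms0$final_segments)
  cc <- 2.4
  scaled <- activation_map(m, map$times * cc, map$scenario)
  ms_scale <- compute_metrics(scaled, seg, proj)
  for (f in c("vvtat", "vvsync", "lvtat", "lvdisp")) {
    expect_equal(ms_scale[[f]], cc * ms0[[f]], tolerance = 1e-9, info = f)
  }
  expect_equal(ms_scale$wfa, ms0$wfa, tolerance = 1e-9)
  expect_identical(ms_scale$final_segments, ms0$final_segments)
  expect_equal(
    compare_scenarios(map, scaled, proj)$pearson_r, 1,
    tolerance = 1e-12
  )
  # dispersion of a bounded variable is at most half its range
  expect_lte(ms0$lvdisp, compute_lvtat(map) / 2)
})
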
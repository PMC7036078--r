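test_that("default mesh satisfies its structural invariants", {
  m <- test_mesh()
  n <- nrow(m$vertices)
  expect_true(all(m$triangles >= 1 & m$triangles <= n))
  expect_true(all(m$chamber %in% c("LV", "RV", "SEPTUM")))
  expect_true(all(m$surface %in% c("EPI", "ENDO_LV", "ENDO_RV")))
  # long-axis extent matches the 90 mm parameter
  z <- as.numeric(sweep(m$vertices, 2, m$base_point) %*% m$long_axis)
  expect_gte(max(z) - min(z), 85)
  expect_lte(max(z) - min(z), 95)
  # every endocardial vertex takes part in a transmural link
  linked <- unique(as.vector(m$transmural))
  endo <- which(m$surface != "EPI")
  expect_true(all(endo %in% linked))
  # apex-base direction is the long axis
  expect_equal(
    (m$apex_point - m$base_point) / sqrt(sum((m$apex_point - m$base_point)^2)),
    m$long_axis,
    tolerance = 1e-12
  )
})

test_that("each surface layer is edge-connected", {
  m <- test_mesh()
  tri <- m$triangles
  edges <- unique(rbind(tri[, 1:2], tri[, 2:3], tri[, c(1, 3)]))
  for (lay in c("EPI", "ENDO_LV", "ENDO_RV")) {
    ids <- which(m$surface == lay)
    keep <- m$surface[edges[, 1]] == lay & m$surface[edges[, 2]] == lay
    g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
    g <- igraph::add_edges(g, t(matrix(match(edges[keep, ], ids), ncol = 2)))
    expect_equal(igraph::count_components(g), 1, info = lay)
  }
})

test_that("mesh generation is deterministic and rejects bad parameters", {
  a <- biv_mesh(n_theta = 12, n_z = 6)
  b <- biv_mesh(n_theta = 12, n_z = 6)
  expect_identical(a$vertices, b$vertices)
  expect_identical(a$triangles, b$triangles)
  expect_error(biv_mesh(long_axis_mm = -5), "positive")
  expect_error(biv_mesh(long_axis_mm = 30, lv_epi_radius_mm = 35), "exceed")
})

test_that("AHA segmentation partitions the LV into the 16 standard segments", {
  m <- test_mesh()
  seg <- assign_aha_segments(m)
  lv <- m$chamber %in% c("LV", "SEPTUM")
  expect_setequal(unique(seg[lv]), 1:16)
  expect_true(all(is.na(seg[!lv])))
  expect_equal(sum(!is.na(seg)), sum(lv)) # a partition of LV vertices
  expect_identical(unclass(seg), unclass(assign_aha_segments(m))) # idempotent
  # a basal vertex on the inferolateral sector falls in segment 5
  fc <- mesh_frame_coords(m)
  pick <- which(lv & abs(fc$f - 0.1) < 0.05 &
    fc$theta_deg > -170 & fc$theta_deg < -130)
  expect_true(length(pick) > 0)
  expect_true(all(seg[pick] == 5))
})

test_that("AHA segment regions are edge-connected", {
  m <- test_mesh()
  seg <- assign_aha_segments(m)
  tri <- m$triangles
  edges <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(1, 3)], m$transmural)
  for (s in 1:16) {
    ids <- which(!is.na(seg) & seg == s)
    keep <- !is.na(seg[edges[, 1]]) & !is.na(seg[edges[, 2]]) &
      seg[edges[, 1]] == s & seg[edges[, 2]] == s
    g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
    g <- igraph::add_edges(g, t(matrix(match(edges[keep, ], ids), ncol = 2)))
    expect_equal(igraph::count_components(g), 1, info = paste("segment", s))
  }
})

test_that("named sites are on the RV cavity lining, disjoint, and placed", {
  m <- test_mesh()
  sites <- lapply(
    c(
      "RV_APEX_ANTERIOR", "RV_APEX_MID", "RV_APEX_POSTERIOR",
      "RV_MID_SEPTUM", "RV_ANTERIOR_FREE_WALL_ENDO"
    ),
    locate_site,
    mesh = m
  )
  for (st in sites) {
    expect_gt(length(st$vertex_ids), 0)
    expect_true(all(m$surface[st$vertex_ids] == "ENDO_RV"))
    d <- sqrt(colSums((t(m$vertices[st$vertex_ids, , drop = FALSE]) -
      st$center)^2))
    expect_true(all(d <= 5))
  }
  for (i in 1:4) {
    for (j in (i + 1):5) {
      expect_length(intersect(sites[[i]]$vertex_ids, sites[[j]]$vertex_ids), 0)
    }
  }
  fc <- mesh_frame_coords(m)
  septal <- sites[[4]]
  expect_true(all(fc$f[septal$vertex_ids] >= 0.4 &
    fc$f[septal$vertex_ids] <= 0.6))
  expect_true(all(m$chamber[septal$vertex_ids] == "SEPTUM"))
  expect_error(locate_site(m, "NOT_A_SITE"), "unknown")
  expect_error(locate_site(m, "RV_APEX_MID", radius_mm = 0.01), "empty")
})

test_that("site location is rotation-equivariant", {
  m <- biv_mesh(n_theta = 16, n_z = 8)
  R <- rotation_matrix(c(1, 2, 0.5), 0.8)
  mr <- rotate_mesh(m, R, translation = c(5, -3, 10))
  for (nm in c("RV_APEX_MID", "RV_MID_SEPTUM")) {
    s0 <- locate_site(m, nm, radius_mm = 8)
    s1 <- locate_site(mr, nm, radius_mm = 8)
    expect_identical(s0$vertex_ids, s1$vertex_ids)
    c0 <- colMeans(m$vertices[s0$vertex_ids, , drop = FALSE])
    c1 <- colMeans(mr$vertices[s1$vertex_ids, , drop = FALSE])
    expect_equal(as.numeric(R %*% c0 + c(5, -3, 10)), c1, tolerance = 1e-9)
  }
})

test_that("LAO-cranial projection preserves the long axis and distances", {
  m <- test_mesh()
  p <- lao_cranial_projection(m)
  # base-apex distance unforeshortened
  d3 <- sqrt(sum((m$apex_point - m$base_point)^2))
  rel <- sweep(rbind(m$base_point, m$apex_point), 2, m$base_point)
  p2 <- rel %*% t(p$basis)
  expect_equal(sqrt(sum((p2[2, ] - p2[1, ])^2)), d3, tolerance = 1e-6)
  # apex below base (orientation convention)
  expect_lt(p2[2, 2], p2[1, 2])
  # in-plane distances preserved: points sharing the view axis coordinate
  w <- cross3_test(p$basis[1, ], p$basis[2, ])
  depth <- as.numeric(m$vertices %*% w)
  same_depth <- which(abs(depth - depth[1]) < 1e-9)
  if (length(same_depth) >= 2) {
    i <- same_depth[1]
    j <- same_depth[2]
    d3ij <- sqrt(sum((m$vertices[i, ] - m$vertices[j, ])^2))
    d2ij <- sqrt(sum((p$coords[i, ] - p$coords[j, ])^2))
    expect_equal(d2ij, d3ij, tolerance = 1e-6)
  }
})

test_that("projection is equivariant under rigid motion of the mesh", {
  m <- biv_mesh(n_theta = 16, n_z = 8)
  p0 <- lao_cranial_projection(m)
  R <- rotation_matrix(c(0.3, 1, 2), -1.1)
  p1 <- lao_cranial_projection(rotate_mesh(m, R, translation = c(1, 2, 3)))
  expect_equal(p0$coords, p1$coords, tolerance = 1e-9)
})
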
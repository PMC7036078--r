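test_that("a uniform chain activates at distance over velocity", {
  # 3 collinear vertices 10 mm apart, cv 1 mm/ms, source at one end
  m <- as_biv_mesh(
    vertices = rbind(c(0, 0, 0), c(10, 0, 0), c(20, 0, 0)),
    triangles = rbind(c(1, 2, 3)),
    chamber = c("RV", "RV", "RV"),
    surface = c("ENDO_RV", "ENDO_RV", "ENDO_RV"),
    base_point = c(0, 0, 0), apex_point = c(0, 0, 1),
    long_axis = c(0, 0, 1), septal_axis = c(1, 0, 0)
  )
  cm <- conduction_model(base_cv = 1, rv_endo_fast_factor = 1, transmural_cv = 1)
  map <- simulate_activation(m, cm, raw_scenario(list(1L)))
  # direct edge 1-3 exists in the triangle but costs 20 ms, same as the chain
  expect_equal(map$times, c(0, 10, 20))
})

test_that("simulator equals the brute-force shortest-path oracle", {
  set.seed(421)
  for (rep in 1:6) {
    m <- random_small_mesh()
    expect_lte(nrow(m$vertices), 500)
    cv <- stats::runif(3, 0.3, 1.2)
    cm <- conduction_model(
      base_cv = c(EPI = cv[1], ENDO_LV = cv[2], ENDO_RV = cv[3]),
      rv_endo_fast_factor = stats::runif(1, 1, 5),
      transmural_cv = stats::runif(1, 0.3, 1.2)
    )
    if (rep %% 2 == 0) {
      cm <- add_scar(cm, sample.int(nrow(m$vertices), 30), 0.4)
    }
    srcs <- sample.int(nrow(m$vertices), 3)
    onsets <- stats::runif(3, 0, 15)
    fast <- rep %% 3 == 0
    sc <- raw_scenario(as.list(srcs), onsets = as.list(onsets), fast_layer = fast)
    map <- simulate_activation(m, cm, sc)
    oracle <- oracle_activation_times(m, cm, srcs, onsets, fast)
    expect_equal(map$times, oracle, tolerance = 1e-12)
  }
})

test_that("activation time at each source equals its onset", {
  m <- biv_mesh(n_theta = 16, n_z = 8)
  cm <- conduction_model()
  sc <- raw_scenario(list(5L, 40L), onsets = list(3, 11))
  map <- simulate_activation(m, cm, sc)
  expect_equal(map$times[5], 3)
  expect_lte(map$times[40], 11)
  expect_true(all(map$times >= 0))
})

test_that("scaling every velocity by c divides activation times by c", {
  m <- biv_mesh(n_theta = 16, n_z = 8)
  sc <- raw_scenario(list(10L))
  cm1 <- conduction_model(
    base_cv = c(EPI = 0.5, ENDO_LV = 0.7, ENDO_RV = 0.9),
    rv_endo_fast_factor = 3, transmural_cv = 0.4
  )
  cm3 <- conduction_model(
    base_cv = cm1$base_cv * 3, rv_endo_fast_factor = 3,
    transmural_cv = cm1$transmural_cv * 3
  )
  t1 <- simulate_activation(m, cm1, sc)$times
  t3 <- simulate_activation(m, cm3, sc)$times
  expect_equal(t1 / 3, t3, tolerance = 1e-10)
})

test_that("a faster RV endocardial layer never delays RV endocardium", {
  m <- biv_mesh(n_theta = 16, n_z = 8)
  sc_fast <- make_scenario("LBBB", m, radius_mm = 8)
  sc_slow <- make_scenario("LBBB", m, radius_mm = 8, fast_layer = FALSE)
  cm <- conduction_model(rv_endo_fast_factor = 4)
  t_fast <- simulate_activation(m, cm, sc_fast)$times
  t_slow <- simulate_activation(m, cm, sc_slow)$times
  rv_endo <- m$surface == "ENDO_RV"
  expect_true(all(t_fast[rv_endo] <= t_slow[rv_endo] + 1e-12))
  expect_true(all(t_fast <= t_slow + 1e-12))
})

test_that("named scenarios use the expected sources", {
  m <- test_mesh()
  sc <- make_scenario("LBBB", m)
  ids <- sc$sources[[1]]$site$vertex_ids
  expect_true(all(m$surface[ids] == "ENDO_RV"))
  expect_true(sc$fast_layer)
  fc <- mesh_frame_coords(m)
  rvsp <- make_scenario("RVSP", m)
  expect_false(rvsp$fast_layer)
  expect_true(all(fc$f[rvsp$sources[[1]]$site$vertex_ids] >= 0.4 &
    fc$f[rvsp$sources[[1]]$site$vertex_ids] <= 0.6))
  all_sources <- lapply(
    c("LBBB", "RVAP_ANTERIOR", "RVAP_MID", "RVAP_POSTERIOR", "RVSP"),
    function(nm) sort(make_scenario(nm, m)$sources[[1]]$site$vertex_ids)
  )
  expect_equal(length(unique(all_sources)), 5)
  expect_error(make_scenario("LV_PACE", m), "unknown")
})

test_that("scar regions slow or block conduction", {
  m <- biv_mesh(n_theta = 16, n_z = 8)
  sc <- raw_scenario(list(1L))
  cm <- conduction_model()
  t0 <- simulate_activation(m, cm, sc)$times
  # slowing scar: every activation time is >= the scar-free one
  fc <- mesh_frame_coords(m)
  region <- which(fc$f > 0.3 & fc$f < 0.7 & m$chamber == "LV")
  cm_slow <- add_scar(cm, region, 0.25)
  t_slow <- simulate_activation(m, cm_slow, sc)$times
  expect_true(all(t_slow >= t0 - 1e-12))
  expect_gt(max(t_slow - t0), 1)
  # an edge inside the region costs exactly 4x its unscarred traversal time
  ea0 <- pacesim:::activation_edges(m, cm, FALSE)
  ea1 <- pacesim:::activation_edges(m, cm_slow, FALSE)
  inside <- ea0$edges[, 1] %in% region & ea0$edges[, 2] %in% region
  expect_equal(ea1$weights[inside], 4 * ea0$weights[inside], tolerance = 1e-12)
  # empty region leaves the model unchanged
  expect_identical(add_scar(cm, integer(), 0.5), cm)
  expect_error(add_scar(cm, 1:5, 1), "multiplier")
  # a fully blocking ring leaves the enclosed apex unreached
  ring <- which(fc$f > 0.55 & fc$f < 0.75)
  cm_block <- add_scar(cm, ring, 0)
  expect_message(
    map_b <- simulate_activation(m, cm_block, sc),
    "unreached"
  )
  expect_gt(sum(map_b$unreached), 0)
  apex_id <- which.max(fc$f)
  expect_true(map_b$unreached[apex_id])
})

test_that("all sources inside a blocking scar is an error", {
  m <- biv_mesh(n_theta = 16, n_z = 8)
  cm <- add_scar(conduction_model(), c(7L, 8L), 0)
  expect_error(
    simulate_activation(m, cm, raw_scenario(list(7L))),
    "blocking scar"
  )
})
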
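# Graph-eikonal activation simulator.
#
# Activation spreads over the mesh edge graph: an edge (a, b) costs
# |a - b| / cv_edge where cv_edge is the harmonic mean of the endpoint
# velocities (surface-layer conduction velocity, optionally boosted on the
# fast RV endocardial layer, and scaled down inside scar regions).
# Transmural endo-epi links conduct at the transmural velocity. Activation
# time at a vertex is the minimum over sources of onset + geodesic traversal
# time — the exact multi-source shortest-path solution.

#' Conduction model for the activation simulator
#'
#' @param base_cv named conduction velocities (mm/ms) per surface layer
#'   (`EPI`, `ENDO_LV`, `ENDO_RV`).
#' @param rv_endo_fast_factor multiplier >= 1 applied to the RV endocardial
#'   layer when the fast layer is enabled (Purkinje-like rapid conduction).
#' @param transmural_cv velocity (mm/ms) of endo-epi transmural links.
#' @param scars list of scar regions, each `list(region =, multiplier =)`;
#'   normally populated via [add_scar()].
#' @return object of class `conduction_model`.
#' @export
conduction_model <- function(base_cv = c(EPI = 0.6, ENDO_LV = 0.6, ENDO_RV = 0.6),
                             rv_endo_fast_factor = 4,
                             transmural_cv = 0.6,
                             scars = list()) {
  if (length(base_cv) == 1 && is.null(names(base_cv))) {
    base_cv <- c(EPI = base_cv, ENDO_LV = base_cv, ENDO_RV = base_cv)
  }
  if (!all(SURFACES %in% names(base_cv))) {
    stop("base_cv must name velocities for ", paste(SURFACES, collapse = ", "))
  }
  if (any(base_cv <= 0) || transmural_cv <= 0) {
    stop("conduction velocities must be positive")
  }
  if (rv_endo_fast_factor < 1) stop("rv_endo_fast_factor must be >= 1")
  structure(
    list(
      base_cv = base_cv[SURFACES], rv_endo_fast_factor = rv_endo_fast_factor,
      transmural_cv = transmural_cv, scars = scars
    ),
    class = "conduction_model"
  )
}

#' Add a scar region to a conduction model
#'
#' Vertices inside the region have their local conduction velocity multiplied
#' by `multiplier`; edges with both endpoints inside are therefore slowed by
#' exactly `1/multiplier`, and `multiplier = 0` blocks conduction through the
#' region entirely.
#'
#' @param cm a `conduction_model`.
#' @param region integer vector of vertex ids.
#' @param multiplier velocity multiplier in `[0, 1)`.
#' @return a new `conduction_model`.
#' @export
add_scar <- function(cm, region, multiplier) {
  stopifnot(inherits(cm, "conduction_model"))
  if (multiplier < 0 || multiplier >= 1) stop("scar multiplier must be in [0, 1)")
  region <- unique(as.integer(region))
  if (length(region) == 0) {
    return(cm)
  }
  cm$scars <- c(cm$scars, list(list(region = region, multiplier = multiplier)))
  cm
}

#' Pacing / intrinsic activation scenario
#'
#' Builds the named scenario on a mesh. Intrinsic LBBB is modelled as RV
#' breakthrough at the anterior endocardial free wall with the fast RV
#' endocardial layer enabled; the paced scenarios stimulate the corresponding
#' apical or septal site with the fast layer disabled (a paced wavefront
#' spreads through working myocardium).
#'
#' @param name one of `LBBB`, `RVAP_ANTERIOR`, `RVAP_MID`, `RVAP_POSTERIOR`,
#'   `RVSP`.
#' @param mesh a `biv_mesh`.
#' @param radius_mm site capture radius passed to [locate_site()].
#' @param fast_layer override the scenario's default fast-layer flag.
#' @return object of class `pacing_scenario`: list with `name`, `sources`
#'   (list of `list(site =, onset =)`) and `fast_layer`.
#' @export
make_scenario <- function(name, mesh, radius_mm = 5, fast_layer = NULL) {
  site_of <- c(
    LBBB = "RV_ANTERIOR_FREE_WALL_ENDO",
    RVAP_ANTERIOR = "RV_APEX_ANTERIOR",
    RVAP_MID = "RV_APEX_MID",
    RVAP_POSTERIOR = "RV_APEX_POSTERIOR",
    RVSP = "RV_MID_SEPTUM"
  )
  if (!name %in% names(site_of)) stop("unknown scenario name: ", name)
  if (is.null(fast_layer)) fast_layer <- identical(name, "LBBB")
  site <- locate_site(mesh, site_of[[name]], radius_mm = radius_mm)
  structure(
    list(
      name = name,
      sources = list(list(site = site, onset = 0)),
      fast_layer = fast_layer
    ),
    class = "pacing_scenario"
  )
}

#' Per-vertex conduction velocities under a model
#' @keywords internal
vertex_velocities <- function(mesh, cm, fast_layer) {
  v <- unname(cm$base_cv[mesh$surface])
  if (fast_layer) {
    v[mesh$surface == "ENDO_RV"] <- v[mesh$surface == "ENDO_RV"] *
      cm$rv_endo_fast_factor
  }
  vt <- rep(cm$transmural_cv, nrow(mesh$vertices))
  for (sc in cm$scars) {
    v[sc$region] <- v[sc$region] * sc$multiplier
    vt[sc$region] <- vt[sc$region] * sc$multiplier
  }
  list(surface = v, transmural = vt)
}

#' Weighted edge list of the activation graph
#'
#' Surface edges from the triangulation plus transmural links, with traversal
#' times (ms) as weights. Fully blocked edges (harmonic-mean velocity zero)
#' are dropped.
#' @keywords internal
activation_edges <- function(mesh, cm, fast_layer) {
  tri <- mesh$triangles
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  vel <- vertex_velocities(mesh, cm, fast_layer)
  harm <- function(a, b) ifelse(a <= 0 | b <= 0, 0, 2 * a * b / (a + b))
  len <- function(pairs) {
    d <- mesh$vertices[pairs[, 1], , drop = FALSE] -
      mesh$vertices[pairs[, 2], , drop = FALSE]
    sqrt(rowSums(d^2))
  }
  w_surf <- ifelse(harm(vel$surface[e[, 1]], vel$surface[e[, 2]]) > 0,
    len(e) / harm(vel$surface[e[, 1]], vel$surface[e[, 2]]), Inf
  )
  tm <- mesh$transmural
  if (nrow(tm) > 0) {
    cvt <- harm(vel$transmural[tm[, 1]], vel$transmural[tm[, 2]])
    w_tm <- ifelse(cvt > 0, len(tm) / cvt, Inf)
  } else {
    w_tm <- numeric()
  }
  edges <- rbind(e, tm)
  w <- c(w_surf, w_tm)
  keep <- is.finite(w)
  list(edges = edges[keep, , drop = FALSE], weights = w[keep])
}

#' Simulate the spread of activation
#'
#' Exact multi-source shortest-path (graph-eikonal) activation times on the
#' mesh edge graph under a conduction model. Vertices unreachable because of
#' a fully blocking scar are flagged unreached (`NA` time) with a message;
#' unreachable vertices with no block present indicate a malformed mesh and
#' raise an error.
#'
#' @param mesh a `biv_mesh`.
#' @param cm a `conduction_model`.
#' @param scenario a `pacing_scenario`.
#' @return object of class `activation_map`: list with `times` (ms, `NA` when
#'   unreached), `scenario`, `fast_layer`, `unreached` and the `mesh`.
#' @export
simulate_activation <- function(mesh, cm, scenario) {
  stopifnot(
    inherits(mesh, "biv_mesh"), inherits(cm, "conduction_model"),
    inherits(scenario, "pacing_scenario")
  )
  n <- nrow(mesh$vertices)
  src_ids <- integer()
  onsets <- numeric()
  for (s in scenario$sources) {
    ids <- s$site$vertex_ids
    if (any(ids < 1 | ids > n)) stop("scenario site indexes outside the mesh")
    src_ids <- c(src_ids, ids)
    onsets <- c(onsets, rep(s$onset, length(ids)))
  }
  if (any(onsets < 0)) stop("source onsets must be >= 0")
  ea <- activation_edges(mesh, cm, scenario$fast_layer)
  blocked <- any(vapply(cm$scars, function(s) s$multiplier == 0, logical(1)))
  vel <- vertex_velocities(mesh, cm, scenario$fast_layer)
  live_src <- vel$surface[src_ids] > 0
  if (!any(live_src)) stop("all scenario sources are inside a blocking scar")
  src_ids <- src_ids[live_src]
  onsets <- onsets[live_src]
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, t(ea$edges), weight = ea$weights)
  d <- igraph::distances(g, v = src_ids, algorithm = "dijkstra")
  times <- do.call(pmin, c(
    lapply(seq_along(src_ids), function(i) onsets[i] + d[i, ]),
    list(na.rm = FALSE)
  ))
  unreached <- !is.finite(times)
  if (any(unreached)) {
    if (!blocked) {
      stop("internal error: unreachable vertices with no conduction block")
    }
    message(sum(unreached), " vertices unreached (scar block); flagged NA")
    times[unreached] <- NA_real_
  }
  structure(
    list(
      times = as.numeric(times), scenario = scenario$name,
      fast_layer = scenario$fast_layer, unreached = unreached, mesh = mesh
    ),
    class = "activation_map"
  )
}

#' @export
print.activation_map <- function(x, ...) {
  t <- x$times[!x$unreached]
  cat(
    "activation_map [", x$scenario, "]: ", length(x$times), " vertices, ",
    sum(x$unreached), " unreached, times ",
    sprintf("%.1f-%.1f ms\n", min(t), max(t)),
    sep = ""
  )
  invisible(x)
}

#' Construct an activation map from per-vertex times
#'
#' Wraps externally computed (or synthetic) per-vertex activation times into
#' the `activation_map` container used by the metrics functions.
#'
#' @param mesh a `biv_mesh`.
#' @param times numeric vector of activation times (ms), `NA` = unreached.
#' @param scenario scenario name to record.
#' @return an `activation_map`.
#' @export
activation_map <- function(mesh, times, scenario = "external") {
  stopifnot(inherits(mesh, "biv_mesh"), length(times) == nrow(mesh$vertices))
  structure(
    list(
      times = as.numeric(times), scenario = scenario, fast_layer = NA,
      unreached = !is.finite(times), mesh = mesh
    ),
    class = "activation_map"
  )
}
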
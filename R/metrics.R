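# Activation metrics on epicardial/endocardial activation maps.
#
# Four scalar metrics summarize one map: VVtat (range of activation over both
# ventricles), LVtat (range over the LV, septum included), VVsync (absolute
# difference of the LV and RV mean activation times, the "ventricular
# electrical uncoupling"), LVdisp (population SD of LV epicardial times).
# Maps are additionally divided into 30 equal-width isochrone bands; the AHA
# segments containing the last band are the terminal segments, and the
# orientation of a chosen band in the LAO-cranial projection is the
# wave-front angle. Unreached (scar-blocked) vertices are excluded
# everywhere.

lv_chambers <- function(include_septum = TRUE) {
  if (include_septum) c("LV", "SEPTUM") else "LV"
}

reached_times <- function(map, mask = NULL) {
  t <- map$times
  ok <- !map$unreached
  if (!is.null(mask)) ok <- ok & mask
  t[ok]
}

#' Biventricular total activation time (VVtat)
#'
#' Range (max minus min, ms) of activation times over all reached ventricular
#' vertices.
#'
#' @param map an `activation_map`.
#' @return VVtat in ms.
#' @export
compute_vvtat <- function(map) {
  t <- reached_times(map)
  if (length(t) == 0) stop("empty activation map")
  max(t) - min(t)
}

#' Left ventricular total activation time (LVtat)
#'
#' Range (ms) of activation over reached LV vertices; septal vertices count
#' toward the LV by default.
#'
#' @param map an `activation_map`.
#' @param include_septum count septal vertices as LV (default `TRUE`).
#' @return LVtat in ms.
#' @export
compute_lvtat <- function(map, include_septum = TRUE) {
  mask <- map$mesh$chamber %in% lv_chambers(include_septum)
  t <- reached_times(map, mask)
  if (length(t) == 0) stop("no LV vertices in map")
  max(t) - min(t)
}

#' Interventricular electrical synchrony (VVsync)
#'
#' Absolute difference (ms) between the unweighted mean LV and mean RV
#' activation times ("ventricular electrical uncoupling"). Set
#' `signed = TRUE` for the signed LV-minus-RV variant.
#'
#' @param map an `activation_map`.
#' @param include_septum count septal vertices as LV (default `TRUE`).
#' @param signed return the signed LV minus RV difference.
#' @return VVsync in ms.
#' @export
compute_vvsync <- function(map, include_septum = TRUE, signed = FALSE) {
  lv <- reached_times(map, map$mesh$chamber %in% lv_chambers(include_septum))
  rv <- reached_times(map, map$mesh$chamber == "RV")
  if (length(lv) == 0 || length(rv) == 0) stop("a chamber is empty")
  d <- mean(lv) - mean(rv)
  if (signed) d else abs(d)
}

#' Dispersion of LV activation (LVdisp)
#'
#' Population standard deviation (divide-by-N, ms) of the LV epicardial
#' activation times.
#'
#' @param map an `activation_map`.
#' @return LVdisp in ms.
#' @export
compute_lvdisp <- function(map) {
  mask <- map$mesh$chamber == "LV" & map$mesh$surface == "EPI"
  t <- reached_times(map, mask)
  if (length(t) < 2) stop("need >= 2 LV epicardial vertices")
  sqrt(mean((t - mean(t))^2))
}

#' Divide an activation map into equal-width isochrone bands
#'
#' Partitions `[min, max]` of the reached activation times into `n` bands of
#' equal width; the vertex at the maximum falls in the last band, and a
#' constant map puts every vertex in band 1.
#'
#' @param map an `activation_map`.
#' @param n number of bands (default 30).
#' @return object of class `isochrone_set`: list with `n_bands`, `band_edges`
#'   (ms, length n + 1) and per-vertex `band_index` (1..n, `NA` unreached).
#' @export
build_isochrones <- function(map, n = 30) {
  if (n < 1) stop("need at least one isochrone band")
  t <- map$times
  ok <- !map$unreached
  if (!any(ok)) stop("empty activation map")
  lo <- min(t[ok])
  hi <- max(t[ok])
  width <- (hi - lo) / n
  idx <- rep(NA_integer_, length(t))
  if (width == 0) {
    idx[ok] <- 1L
  } else {
    idx[ok] <- pmin(as.integer(floor((t[ok] - lo) / width)) + 1L, as.integer(n))
  }
  structure(
    list(
      n_bands = as.integer(n),
      band_edges = lo + width * 0:n,
      band_index = idx
    ),
    class = "isochrone_set"
  )
}

#' Terminal AHA segments of an activation map
#'
#' The set of AHA segments containing at least one LV vertex in the final
#' isochrone band; more than one segment qualifies when the last band
#' straddles a segment boundary. If the final band holds no LV vertex (an
#' RV-only last band), the latest band occupied by the LV is used instead and
#' a message is logged.
#'
#' @param map an `activation_map`.
#' @param seg an `aha_segmentation` of the map's mesh.
#' @param iso an `isochrone_set` built from `map` (default built here, 30
#'   bands).
#' @return sorted integer vector of AHA segment ids.
#' @export
final_segments <- function(map, seg, iso = build_isochrones(map)) {
  stopifnot(inherits(iso, "isochrone_set"))
  lv <- !is.na(unclass(seg))
  band <- iso$band_index
  target <- iso$n_bands
  in_last <- lv & !is.na(band) & band == target
  if (!any(in_last)) {
    target <- max(band[lv & !is.na(band)])
    message(
      "final isochrone holds no LV vertex; falling back to LV band ", target
    )
    in_last <- lv & !is.na(band) & band == target
  }
  sort(unique(unclass(seg)[in_last]))
}

#' Wave-front angle of an isochrone band
#'
#' Fits a total-least-squares line through the projected 2D positions of the
#' vertices in the chosen isochrone band and returns its orientation in
#' degrees within `[0, 180)`, measured anticlockwise from the projection's
#' horizontal axis. The default band is the one containing the median
#' activation time, standing in for the manually selected "most prominent"
#' isochrone; the same index must be used when comparing two maps.
#'
#' @param map an `activation_map`.
#' @param proj a `planar_projection` of the map's mesh.
#' @param iso an `isochrone_set` built from `map`.
#' @param iso_index band to fit; default the band containing the median time.
#' @return angle in degrees, `[0, 180)`.
#' @export
wavefront_angle <- function(map, proj, iso = build_isochrones(map),
                            iso_index = NULL) {
  stopifnot(inherits(proj, "planar_projection"))
  if (is.null(iso_index)) iso_index <- median_band(map, iso)
  sel <- !is.na(iso$band_index) & iso$band_index == iso_index
  pts <- proj$coords[sel, , drop = FALSE]
  if (nrow(unique(pts)) < 2) {
    stop("isochrone band has fewer than 2 distinct points")
  }
  ctr <- colMeans(pts)
  cc <- crossprod(sweep(pts, 2, ctr)) / nrow(pts)
  ev <- eigen(cc, symmetric = TRUE)$vectors[, 1]
  ang <- atan2(ev[2], ev[1]) * 180 / pi
  ang %% 180
}

#' Index of the band containing the median activation time
#' @keywords internal
median_band <- function(map, iso = build_isochrones(map)) {
  t <- reached_times(map)
  m <- stats::median(t)
  lo <- iso$band_edges[1]
  width <- (iso$band_edges[iso$n_bands + 1] - lo) / iso$n_bands
  if (width == 0) {
    return(1L)
  }
  min(as.integer(floor((m - lo) / width)) + 1L, iso$n_bands)
}

#' Default LV free-wall mask for latest-region analysis
#'
#' LV epicardium excluding the septum (which carries no epicardial surface in
#' the idealized geometry).
#'
#' @param mesh a `biv_mesh`.
#' @return logical vertex mask.
#' @export
lv_free_wall_mask <- function(mesh) {
  mesh$chamber == "LV" & mesh$surface == "EPI"
}

#' Centroid of the latest-activated region within a mask
#'
#' Unweighted centroid (mm) of the masked vertices lying in the latest
#' isochrone band occupied within the mask.
#'
#' @param map an `activation_map`.
#' @param iso an `isochrone_set` built from `map`.
#' @param mask logical or integer vertex mask (default the LV free wall).
#' @return length-3 numeric centroid (mm).
#' @export
latest_region_centroid <- function(map, iso = build_isochrones(map),
                                   mask = lv_free_wall_mask(map$mesh)) {
  if (is.logical(mask)) mask <- which(mask)
  if (length(mask) == 0) stop("empty mask")
  band <- iso$band_index[mask]
  if (all(is.na(band))) stop("mask contains no reached vertices")
  sel <- mask[!is.na(band) & band == max(band, na.rm = TRUE)]
  colMeans(map$mesh$vertices[sel, , drop = FALSE])
}

#' Full metric set for one activation map
#'
#' @param map an `activation_map`.
#' @param seg an `aha_segmentation` (default computed from the map's mesh).
#' @param proj a `planar_projection` (default LAO-cranial of the map's mesh).
#' @param n_bands number of isochrone bands (default 30).
#' @param iso_index wave-front-angle band (default median-time band).
#' @return object of class `metric_set`: list with `vvtat`, `vvsync`,
#'   `lvtat`, `lvdisp`, `wfa`, `final_segments`, `scenario`.
#' @export
compute_metrics <- function(map, seg = assign_aha_segments(map$mesh),
                            proj = lao_cranial_projection(map$mesh),
                            n_bands = 30, iso_index = NULL) {
  iso <- build_isochrones(map, n_bands)
  structure(
    list(
      vvtat = compute_vvtat(map),
      vvsync = compute_vvsync(map),
      lvtat = compute_lvtat(map),
      lvdisp = compute_lvdisp(map),
      wfa = wavefront_angle(map, proj, iso, iso_index),
      final_segments = final_segments(map, seg, iso),
      scenario = map$scenario
    ),
    class = "metric_set"
  )
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf(
    "metric_set [%s]: VVtat %.1f  VVsync %.1f  LVtat %.1f  LVdisp %.1f ms; WFA %.1f deg; final segments {%s}\n",
    x$scenario, x$vvtat, x$vvsync, x$lvtat, x$lvdisp, x$wfa,
    paste(x$final_segments, collapse = ",")
  ))
  invisible(x)
}

signed_angle_diff <- function(a, b) {
  ((a - b + 90) %% 180) - 90
}

#' Compare two activation maps of the same mesh
#'
#' Pearson correlation of per-vertex activation times after each map is
#' shifted to start at zero and normalized by its own VVtat; Euclidean shift
#' (mm) between the latest-activated-region centroids within the LV free
#' wall; and the signed wave-front-angle difference using the same isochrone
#' band index in both maps.
#'
#' @param map_a,map_b `activation_map`s on the same mesh (`map_a` is the
#'   reference, e.g. intrinsic LBBB).
#' @param proj shared `planar_projection` (default LAO-cranial).
#' @param mask latest-region mask (default the LV free wall).
#' @param iso_index shared wave-front band (default `map_a`'s median band).
#' @param n_bands isochrone bands per map (default 30).
#' @return object of class `scenario_comparison`: list with `pearson_r`,
#'   `latest_region_shift` (mm), `wfa_delta` (degrees, b minus a, in
#'   (-90, 90]), and the scenario names.
#' @export
compare_scenarios <- function(map_a, map_b,
                              proj = lao_cranial_projection(map_a$mesh),
                              mask = lv_free_wall_mask(map_a$mesh),
                              iso_index = NULL, n_bands = 30) {
  if (nrow(map_a$mesh$vertices) != nrow(map_b$mesh$vertices) ||
    max(abs(map_a$mesh$vertices - map_b$mesh$vertices)) > 1e-9) {
    stop("maps are not on the same mesh")
  }
  ok <- !map_a$unreached & !map_b$unreached
  norm_times <- function(map) {
    tat <- compute_vvtat(map)
    if (tat == 0) stop("zero-variance activation map")
    (map$times - min(map$times, na.rm = TRUE)) / tat
  }
  r <- stats::cor(norm_times(map_a)[ok], norm_times(map_b)[ok])
  iso_a <- build_isochrones(map_a, n_bands)
  iso_b <- build_isochrones(map_b, n_bands)
  ca <- latest_region_centroid(map_a, iso_a, mask)
  cb <- latest_region_centroid(map_b, iso_b, mask)
  if (is.null(iso_index)) iso_index <- median_band(map_a, iso_a)
  wa <- wavefront_angle(map_a, proj, iso_a, iso_index)
  wb <- wavefront_angle(map_b, proj, iso_b, iso_index)
  structure(
    list(
      pearson_r = r,
      latest_region_shift = sqrt(sum((ca - cb)^2)),
      wfa_delta = signed_angle_diff(wb, wa),
      scenario_a = map_a$scenario, scenario_b = map_b$scenario
    ),
    class = "scenario_comparison"
  )
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat(sprintf(
    "scenario_comparison [%s vs %s]: r = %.3f, latest-region shift = %.1f mm, WFA delta = %.1f deg\n",
    x$scenario_a, x$scenario_b, x$pearson_r, x$latest_region_shift, x$wfa_delta
  ))
  invisible(x)
}
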
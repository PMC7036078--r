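# Plain-text interchange: PLY (ASCII) and VTK legacy ASCII meshes with
# per-vertex integer labels, activation-map CSV, metric-set JSON. File
# vertex indices are 0-based (as the formats require); in-memory objects are
# 1-based R indices.

CHAMBER_CODE <- c(LV = 0L, RV = 1L, SEPTUM = 2L)
SURFACE_CODE <- c(EPI = 0L, ENDO_LV = 1L, ENDO_RV = 2L)

#' Write a biventricular mesh as ASCII PLY
#'
#' Vertices carry integer properties `chamber_label` (LV=0, RV=1, SEPTUM=2)
#' and `surface_label` (EPI=0, ENDO_LV=1, ENDO_RV=2), plus `segment_id` when
#' a segmentation is supplied (-1 outside the LV). Transmural links are
#' stored as an `edge` element; the anatomical frame and landmarks ride in
#' comment lines so that [read_mesh_ply()] can reconstruct the full object.
#'
#' @param mesh a `biv_mesh`.
#' @param path output file.
#' @param segments optional `aha_segmentation`.
#' @return `path`, invisibly.
#' @export
write_mesh_ply <- function(mesh, path, segments = NULL) {
  stopifnot(inherits(mesh, "biv_mesh"))
  n <- nrow(mesh$vertices)
  num <- function(v) paste(format(v, digits = 10, trim = TRUE), collapse = " ")
  header <- c(
    "ply", "format ascii 1.0",
    "comment pacesim biventricular mesh",
    paste("comment frame base_point", num(mesh$base_point)),
    paste("comment frame apex_point", num(mesh$apex_point)),
    paste("comment frame long_axis", num(mesh$long_axis)),
    paste("comment frame septal_axis", num(mesh$septal_axis)),
    vapply(
      names(mesh$landmarks),
      function(nm) paste("comment landmark", nm, num(mesh$landmarks[[nm]])),
      character(1)
    ),
    paste("element vertex", n),
    "property float x", "property float y", "property float z",
    "property int chamber_label", "property int surface_label",
    if (!is.null(segments)) "property int segment_id",
    paste("element face", nrow(mesh$triangles)),
    "property list uchar int vertex_indices",
    paste("element edge", nrow(mesh$transmural)),
    "property int vertex1", "property int vertex2",
    "end_header"
  )
  vmat <- cbind(
    format(mesh$vertices, digits = 10, trim = TRUE),
    CHAMBER_CODE[mesh$chamber], SURFACE_CODE[mesh$surface]
  )
  if (!is.null(segments)) {
    sid <- unclass(segments)
    sid[is.na(sid)] <- -1L
    vmat <- cbind(vmat, sid)
  }
  lines <- c(
    header,
    apply(vmat, 1, paste, collapse = " "),
    apply(mesh$triangles - 1L, 1, function(tr) paste(c(3L, tr), collapse = " ")),
    apply(mesh$transmural - 1L, 1, paste, collapse = " ")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read an ASCII PLY biventricular mesh
#'
#' Expects the element layout written by [write_mesh_ply()] (vertex
#' coordinates with chamber/surface label properties, triangular faces, an
#' optional edge element with the transmural links, and frame/landmark
#' comments).
#'
#' @param path PLY file.
#' @return a `biv_mesh`; any `segment_id` property is attached as attribute
#'   `segments`.
#' @export
read_mesh_ply <- function(path) {
  lines <- readLines(path)
  end <- match("end_header", lines)
  if (is.na(end)) stop("not a valid ASCII PLY file (no end_header)")
  header <- lines[seq_len(end)]
  counts <- list(vertex = 0L, face = 0L, edge = 0L)
  vprops <- character()
  current <- ""
  frame <- list()
  landmarks <- list()
  for (ln in header) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 0) next
    if (tok[1] == "element") {
      current <- tok[2]
      counts[[current]] <- as.integer(tok[3])
    } else if (tok[1] == "property" && current == "vertex") {
      vprops <- c(vprops, tok[length(tok)])
    } else if (tok[1] == "comment" && length(tok) >= 5 && tok[2] == "frame") {
      frame[[tok[3]]] <- as.numeric(tok[4:6])
    } else if (tok[1] == "comment" && length(tok) >= 6 && tok[2] == "landmark") {
      landmarks[[tok[3]]] <- as.numeric(tok[4:6])
    }
  }
  body <- lines[(end + 1):length(lines)]
  vl <- body[seq_len(counts$vertex)]
  vdat <- matrix(
    as.numeric(unlist(strsplit(trimws(vl), "\\s+"))),
    nrow = counts$vertex, byrow = TRUE
  )
  colnames(vdat) <- vprops
  tri <- matrix(integer(), 0, 3)
  if (counts$face > 0) {
    fl <- body[counts$vertex + seq_len(counts$face)]
    fdat <- matrix(
      as.integer(unlist(strsplit(trimws(fl), "\\s+"))),
      nrow = counts$face, byrow = TRUE
    )
    tri <- fdat[, 2:4, drop = FALSE] + 1L
  }
  links <- matrix(integer(), 0, 2)
  if (counts$edge > 0) {
    el <- body[counts$vertex + counts$face + seq_len(counts$edge)]
    links <- matrix(
      as.integer(unlist(strsplit(trimws(el), "\\s+"))),
      nrow = counts$edge, byrow = TRUE
    ) + 1L
  }
  chamber <- names(CHAMBER_CODE)[match(vdat[, "chamber_label"], CHAMBER_CODE)]
  surface <- names(SURFACE_CODE)[match(vdat[, "surface_label"], SURFACE_CODE)]
  mesh <- as_biv_mesh(
    vertices = vdat[, c("x", "y", "z")], triangles = tri,
    chamber = chamber, surface = surface, transmural = links,
    base_point = frame$base_point, apex_point = frame$apex_point,
    long_axis = frame$long_axis, septal_axis = frame$septal_axis,
    landmarks = landmarks
  )
  if ("segment_id" %in% vprops) {
    sid <- as.integer(vdat[, "segment_id"])
    sid[sid < 0] <- NA_integer_
    attr(mesh, "segments") <- structure(sid, class = "aha_segmentation")
  }
  mesh
}

#' Write a mesh as VTK legacy ASCII polydata
#'
#' Chamber and surface label codes are always attached as point data;
#' additional per-vertex scalar arrays (e.g. activation times) can be passed
#' in `point_data`.
#'
#' @param mesh a `biv_mesh`.
#' @param path output file.
#' @param point_data named list of per-vertex numeric vectors.
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path, point_data = list()) {
  stopifnot(inherits(mesh, "biv_mesh"))
  n <- nrow(mesh$vertices)
  m <- nrow(mesh$triangles)
  arrays <- c(
    list(
      chamber_label = as.numeric(CHAMBER_CODE[mesh$chamber]),
      surface_label = as.numeric(SURFACE_CODE[mesh$surface])
    ),
    point_data
  )
  lines <- c(
    "# vtk DataFile Version 3.0",
    "pacesim biventricular mesh", "ASCII", "DATASET POLYDATA",
    paste("POINTS", n, "float"),
    apply(mesh$vertices, 1, function(p) {
      paste(format(p, digits = 10, trim = TRUE), collapse = " ")
    }),
    paste("POLYGONS", m, 4 * m),
    apply(mesh$triangles - 1L, 1, function(tr) paste(c(3L, tr), collapse = " ")),
    paste("POINT_DATA", n)
  )
  for (nm in names(arrays)) {
    lines <- c(
      lines,
      paste("SCALARS", nm, "float 1"), "LOOKUP_TABLE default",
      format(arrays[[nm]], digits = 10, trim = TRUE)
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write / read an activation map as CSV
#'
#' Columns `vertex_id` (0-based), `activation_time_ms` (empty when
#' unreached) and `scenario`.
#'
#' @param map an `activation_map`.
#' @param path CSV file.
#' @param mesh the `biv_mesh` the map belongs to (reader only).
#' @return `read_map_csv` returns an `activation_map`.
#' @export
write_map_csv <- function(map, path) {
  stopifnot(inherits(map, "activation_map"))
  utils::write.csv(
    data.frame(
      vertex_id = seq_along(map$times) - 1L,
      activation_time_ms = map$times,
      scenario = map$scenario
    ),
    path,
    row.names = FALSE, na = ""
  )
  invisible(path)
}

#' @rdname write_map_csv
#' @export
read_map_csv <- function(path, mesh) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d <- d[order(d$vertex_id), ]
  activation_map(mesh, d$activation_time_ms, scenario = d$scenario[1])
}

#' Write metric sets as JSON
#'
#' @param metrics a `metric_set` or named list of them.
#' @param path JSON file.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(metrics, path) {
  if (inherits(metrics, "metric_set")) metrics <- list(metrics)
  payload <- lapply(metrics, function(m) {
    list(
      scenario = m$scenario, vvtat_ms = m$vvtat, vvsync_ms = m$vvsync,
      lvtat_ms = m$lvtat, lvdisp_ms = m$lvdisp, wfa_deg = m$wfa,
      final_segments = m$final_segments
    )
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
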
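# Idealized biventricular surface geometry.
#
# Canonical frame: long axis = +z, base plane at z = 0, apex at z = L (mm).
# Circumferential angle theta = 0 at the mid-septum, increasing toward the
# anterior wall. The LV is a two-layer truncated half-ellipsoid of revolution
# (epicardium + endocardium); the RV free wall is a two-layer crescent bulge
# welded onto the septal arc of the LV epicardial shell, so that the outer LV
# shell under the bulge becomes the RV-facing septal surface (surface label
# ENDO_RV, chamber SEPTUM). All lengths mm, all times ms.

CHAMBERS <- c("LV", "RV", "SEPTUM")
SURFACES <- c("EPI", "ENDO_LV", "ENDO_RV")
SITE_NAMES <- c(
  "RV_APEX_ANTERIOR", "RV_APEX_MID", "RV_APEX_POSTERIOR",
  "RV_MID_SEPTUM", "RV_ANTERIOR_FREE_WALL_ENDO"
)

cross3 <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

unit3 <- function(v) v / sqrt(sum(v^2))

#' Construct a biventricular mesh object from its parts
#'
#' Low-level constructor used by [biv_mesh()] and the PLY/VTK readers. Checks
#' the structural invariants (valid triangle indices, one chamber and one
#' surface label per vertex, apex-base direction equal to the long axis).
#'
#' @param vertices numeric n x 3 matrix of coordinates (mm).
#' @param triangles integer m x 3 matrix of 1-based vertex indices.
#' @param chamber character vector, one of `"LV"`, `"RV"`, `"SEPTUM"` per vertex.
#' @param surface character vector, one of `"EPI"`, `"ENDO_LV"`, `"ENDO_RV"`.
#' @param transmural integer t x 2 matrix of endo-epi link vertex pairs.
#' @param base_point,apex_point 3-vectors (mm).
#' @param long_axis unit 3-vector, base to apex.
#' @param septal_axis unit 3-vector perpendicular to `long_axis`, pointing at
#'   the mid-septum (circumferential angle zero).
#' @param landmarks named list of 3-vector anatomical landmark coordinates.
#' @param params list of generation parameters (kept for provenance).
#' @return an object of class `biv_mesh`.
#' @export
as_biv_mesh <- function(vertices, triangles, chamber, surface,
                        transmural = matrix(integer(), ncol = 2),
                        base_point, apex_point, long_axis, septal_axis,
                        landmarks = list(), params = list()) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  transmural <- as.matrix(transmural)
  storage.mode(transmural) <- "integer"
  dimnames(vertices) <- dimnames(triangles) <- dimnames(transmural) <- NULL
  n <- nrow(vertices)
  stopifnot(ncol(vertices) == 3, ncol(triangles) == 3)
  if (nrow(triangles) > 0 && (min(triangles) < 1 || max(triangles) > n)) {
    stop("triangles index vertices outside 1..n")
  }
  if (nrow(transmural) > 0 && (min(transmural) < 1 || max(transmural) > n)) {
    stop("transmural links index vertices outside 1..n")
  }
  if (length(chamber) != n || length(surface) != n) {
    stop("chamber/surface labels must have one entry per vertex")
  }
  if (!all(chamber %in% CHAMBERS)) stop("unknown chamber label")
  if (!all(surface %in% SURFACES)) stop("unknown surface label")
  long_axis <- unit3(as.numeric(long_axis))
  septal_axis <- unit3(as.numeric(septal_axis))
  ab <- as.numeric(apex_point) - as.numeric(base_point)
  if (sqrt(sum(ab^2)) > 0 && max(abs(unit3(ab) - long_axis)) > 1e-8) {
    stop("apex_point - base_point direction must equal long_axis")
  }
  structure(
    list(
      vertices = vertices, triangles = triangles,
      chamber = as.character(chamber), surface = as.character(surface),
      transmural = transmural,
      base_point = as.numeric(base_point), apex_point = as.numeric(apex_point),
      long_axis = long_axis, septal_axis = septal_axis,
      landmarks = landmarks, params = params
    ),
    class = "biv_mesh"
  )
}

#' @export
print.biv_mesh <- function(x, ...) {
  cat(
    "biv_mesh:", nrow(x$vertices), "vertices,", nrow(x$triangles),
    "triangles,", nrow(x$transmural), "transmural links\n"
  )
  cat("  chambers:", paste(sprintf(
    "%s=%d", names(table(x$chamber)),
    as.integer(table(x$chamber))
  ), collapse = " "), "\n")
  cat("  surfaces:", paste(sprintf(
    "%s=%d", names(table(x$surface)),
    as.integer(table(x$surface))
  ), collapse = " "), "\n")
  invisible(x)
}

#' Build the idealized biventricular surface mesh
#'
#' Generates a two-layer truncated-ellipsoid left ventricle with an attached
#' two-layer right-ventricular free-wall crescent sharing the septal wall,
#' labelled per vertex with chamber (`LV`/`RV`/`SEPTUM`) and surface
#' (`EPI`/`ENDO_LV`/`ENDO_RV`), with transmural endo-epi links and named
#' anatomical landmarks for pacing-site definition. Deterministic for fixed
#' parameters. Default dimensions approximate an adult dilated LV
#' (90 mm long axis, 35 mm epicardial short-axis radius).
#'
#' @param long_axis_mm base-to-apex length of the LV epicardium (mm).
#' @param lv_epi_radius_mm LV epicardial short-axis radius at the base (mm).
#' @param lv_wall_mm LV wall thickness at the base (mm).
#' @param rv_bulge_mm maximal height of the RV free-wall epicardial bulge
#'   above the septal surface (mm).
#' @param rv_wall_mm maximal RV free-wall thickness (mm).
#' @param rv_extent apical extent of the RV as a fraction of `long_axis_mm`.
#' @param septal_half_angle_deg circumferential half-angle of the septal arc
#'   covered by the RV (degrees).
#' @param n_theta,n_z circumferential / longitudinal grid resolution.
#' @return a [as_biv_mesh()] object in the canonical frame.
#' @examples
#' m <- biv_mesh(n_theta = 16, n_z = 8)
#' table(m$chamber, m$surface)
#' @export
biv_mesh <- function(long_axis_mm = 90, lv_epi_radius_mm = 35,
                     lv_wall_mm = 10, rv_bulge_mm = 16, rv_wall_mm = 5,
                     rv_extent = 0.78, septal_half_angle_deg = 60,
                     n_theta = 40, n_z = 20) {
  if (long_axis_mm <= 0 || lv_epi_radius_mm <= 0 || lv_wall_mm <= 0 ||
    rv_bulge_mm <= 0 || rv_wall_mm <= 0 || rv_extent <= 0 ||
    septal_half_angle_deg <= 0 || n_theta < 8 || n_z < 4) {
    stop("biv_mesh: all dimensions must be positive (n_theta >= 8, n_z >= 4)")
  }
  if (long_axis_mm <= lv_epi_radius_mm) {
    stop("biv_mesh: long axis must exceed the LV short-axis radius")
  }
  if (rv_wall_mm >= rv_bulge_mm) {
    stop("biv_mesh: RV wall must be thinner than the RV bulge")
  }
  L <- long_axis_mm
  a_epi <- lv_epi_radius_mm
  a_endo <- a_epi - lv_wall_mm
  L_endo <- L - 0.8 * lv_wall_mm
  if (a_endo <= 0) stop("biv_mesh: LV wall thicker than LV radius")
  z_rv <- rv_extent * L
  th_ins <- septal_half_angle_deg * pi / 180
  H_epi <- rv_bulge_mm
  H_endo <- rv_bulge_mm - rv_wall_mm
  eps_h <- 0.5 # mm; below this a bulge grid node welds onto the LV shell

  theta <- -pi + 2 * pi * (seq_len(n_theta) - 1) / n_theta
  f <- (seq_len(n_z) - 1) / n_z # ring long-axis fractions, base ring f = 0

  # endocardial crescent footprint sits strictly inside the epicardial one so
  # that its rim welds onto the RV-facing septal surface (keeping the RV
  # cavity lining edge-connected), not onto the epicardium.
  th_ins_endo <- 0.8 * th_ins
  z_rv_endo <- 0.9 * z_rv
  bulge <- function(H, th, z, th_lim = th_ins, z_lim = z_rv) {
    h <- H * cos(pi * th / (2 * th_lim)) * cos(pi * z / (2 * z_lim))
    h[abs(th) >= th_lim | z >= z_lim] <- 0
    h
  }
  bulge_endo <- function(H, th, z) bulge(H, th, z, th_ins_endo, z_rv_endo)

  verts <- list()
  chamber <- character()
  surface <- character()
  nv <- 0L
  add_vertex <- function(p, ch, su) {
    nv <<- nv + 1L
    verts[[nv]] <<- p
    chamber[nv] <<- ch
    surface[nv] <<- su
    nv
  }

  # outer LV shell (epicardium / RV-facing septal surface)
  z_epi <- f * L
  r_epi <- a_epi * sqrt(pmax(0, 1 - f^2))
  h_epi <- outer(z_epi, theta, function(z, th) bulge(H_epi, th, z))
  shell_id <- matrix(0L, n_z, n_theta)
  for (k in seq_len(n_z)) {
    for (j in seq_len(n_theta)) {
      septal <- h_epi[k, j] > eps_h
      shell_id[k, j] <- add_vertex(
        c(r_epi[k] * cos(theta[j]), r_epi[k] * sin(theta[j]), z_epi[k]),
        if (septal) "SEPTUM" else "LV",
        if (septal) "ENDO_RV" else "EPI"
      )
    }
  }
  apex_epi <- add_vertex(c(0, 0, L), "LV", "EPI")

  # inner LV shell (LV endocardium / LV-facing septal surface)
  z_endo <- f * L_endo
  r_endo <- a_endo * sqrt(pmax(0, 1 - f^2))
  endo_id <- matrix(0L, n_z, n_theta)
  for (k in seq_len(n_z)) {
    for (j in seq_len(n_theta)) {
      septal <- h_epi[k, j] > eps_h
      endo_id[k, j] <- add_vertex(
        c(r_endo[k] * cos(theta[j]), r_endo[k] * sin(theta[j]), z_endo[k]),
        if (septal) "SEPTUM" else "LV", "ENDO_LV"
      )
    }
  }
  apex_endo <- add_vertex(c(0, 0, L_endo), "LV", "ENDO_LV")

  # RV free wall layers: grid nodes with bulge height > eps get new vertices,
  # the rest weld onto the outer LV shell so the crescent is stitched on.
  rv_layer <- function(H, surf, bulge_fun = bulge) {
    id <- shell_id
    for (k in seq_len(n_z)) {
      for (j in seq_len(n_theta)) {
        h <- bulge_fun(H, theta[j], z_epi[k])
        if (h > eps_h) {
          r <- r_epi[k] + h
          id[k, j] <- add_vertex(
            c(r * cos(theta[j]), r * sin(theta[j]), z_epi[k]), "RV", surf
          )
        }
      }
    }
    id
  }
  rvepi_id <- rv_layer(H_epi, "EPI")
  rvendo_id <- rv_layer(H_endo, "ENDO_RV", bulge_endo)

  vertices <- do.call(rbind, verts)

  # triangulation: quad grids split into triangles; layers sharing welded
  # vertices are stitched automatically.
  tris <- list()
  nt <- 0L
  # quad diagonals alternate with (ring + column) parity: for even n_theta
  # this makes the lattice exactly mirror-symmetric about the mid-septal
  # meridian and removes the directional bias a uniform diagonal would
  # imprint on geodesic wavefronts.
  add_quad <- function(c00, c01, c10, c11, flip) {
    if (flip) {
      nt <<- nt + 1L
      tris[[nt]] <<- c(c00, c01, c10)
      nt <<- nt + 1L
      tris[[nt]] <<- c(c01, c11, c10)
    } else {
      nt <<- nt + 1L
      tris[[nt]] <<- c(c00, c01, c11)
      nt <<- nt + 1L
      tris[[nt]] <<- c(c00, c11, c10)
    }
  }
  jnext <- c(seq_len(n_theta)[-1], 1L)
  for (k in seq_len(n_z - 1)) {
    for (j in seq_len(n_theta)) {
      jn <- jnext[j]
      flip <- (k + j) %% 2 == 0
      add_quad(
        shell_id[k, j], shell_id[k, jn], shell_id[k + 1, j],
        shell_id[k + 1, jn], flip
      )
      add_quad(
        endo_id[k, j], endo_id[k, jn], endo_id[k + 1, j],
        endo_id[k + 1, jn], flip
      )
      for (id in list(rvepi_id, rvendo_id)) {
        corners <- c(id[k, j], id[k, jn], id[k + 1, j], id[k + 1, jn])
        if (any(corners > apex_endo)) { # at least one true RV vertex
          add_quad(corners[1], corners[2], corners[3], corners[4], flip)
        }
      }
    }
  }
  for (j in seq_len(n_theta)) { # apex fans
    jn <- jnext[j]
    nt <- nt + 1L
    tris[[nt]] <- c(shell_id[n_z, j], shell_id[n_z, jn], apex_epi)
    nt <- nt + 1L
    tris[[nt]] <- c(endo_id[n_z, j], endo_id[n_z, jn], apex_endo)
  }
  triangles <- do.call(rbind, tris)

  # transmural links: LV endo <-> outer shell at matching grid nodes (these
  # double as septal LV-face <-> RV-face links), RV endo <-> RV epi.
  links <- rbind(
    cbind(as.vector(endo_id), as.vector(shell_id)),
    c(apex_endo, apex_epi)
  )
  rv_links <- cbind(as.vector(rvendo_id), as.vector(rvepi_id))
  rv_links <- rv_links[rv_links[, 1] != rv_links[, 2], , drop = FALSE]
  links <- rbind(links, rv_links)
  links <- t(apply(links, 1, sort))
  links <- unique(links)

  # anatomical landmarks (canonical frame); RV tip = deepest endocardial
  # extent of the free-wall crescent on the mid-septal meridian.
  # apex landmark depth: where the endocardial crescent is ~2 mm proud of the
  # septal surface, so nearby grid vertices exist at any supported resolution
  z_tip <- (2 * z_rv_endo / pi) * acos(min(1, 2 / H_endo))
  on_rv_endo <- function(th_deg, z) {
    th <- th_deg * pi / 180
    r <- a_epi * sqrt(max(0, 1 - (z / L)^2)) + bulge_endo(H_endo, th, z)
    c(r * cos(th), r * sin(th), z)
  }
  on_septal_face <- function(th_deg, z) {
    th <- th_deg * pi / 180
    r <- a_epi * sqrt(max(0, 1 - (z / L)^2))
    c(r * cos(th), r * sin(th), z)
  }
  landmarks <- list(
    RV_APEX_MID = on_rv_endo(0, z_tip),
    RV_APEX_ANTERIOR = on_rv_endo(30, 0.8 * z_rv_endo),
    RV_APEX_POSTERIOR = on_rv_endo(-30, 0.8 * z_rv_endo),
    RV_MID_SEPTUM = on_septal_face(0, 0.5 * L),
    RV_ANTERIOR_FREE_WALL_ENDO = on_rv_endo(40, 0.30 * L)
  )

  as_biv_mesh(
    vertices = vertices, triangles = triangles,
    chamber = chamber, surface = surface, transmural = links,
    base_point = c(0, 0, 0), apex_point = c(0, 0, L),
    long_axis = c(0, 0, 1), septal_axis = c(1, 0, 0),
    landmarks = landmarks,
    params = list(
      long_axis_mm = L, lv_epi_radius_mm = a_epi, lv_wall_mm = lv_wall_mm,
      rv_bulge_mm = rv_bulge_mm, rv_wall_mm = rv_wall_mm,
      rv_extent = rv_extent, septal_half_angle_deg = septal_half_angle_deg,
      n_theta = n_theta, n_z = n_z
    )
  )
}

#' Rigidly transform a mesh
#'
#' Applies a rotation (and optional translation) to vertices, frame axes and
#' landmarks alike, so that anatomy-derived quantities are equivariant.
#'
#' @param mesh a `biv_mesh`.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 offset (mm).
#' @return the transformed `biv_mesh`.
#' @export
rotate_mesh <- function(mesh, rotation, translation = c(0, 0, 0)) {
  stopifnot(inherits(mesh, "biv_mesh"))
  rotation <- as.matrix(rotation)
  rot <- function(p) as.numeric(rotation %*% as.numeric(p)) + translation
  mesh$vertices <- t(apply(mesh$vertices, 1, function(p) {
    as.numeric(rotation %*% p)
  }))
  mesh$vertices <- sweep(mesh$vertices, 2, -translation)
  mesh$base_point <- rot(mesh$base_point)
  mesh$apex_point <- rot(mesh$apex_point)
  mesh$long_axis <- as.numeric(rotation %*% mesh$long_axis)
  mesh$septal_axis <- as.numeric(rotation %*% mesh$septal_axis)
  mesh$landmarks <- lapply(mesh$landmarks, rot)
  mesh
}

#' Long-axis fractions and circumferential angles of mesh vertices
#'
#' @param mesh a `biv_mesh`.
#' @return list with per-vertex `f` (long-axis fraction, 0 base to 1 apex),
#'   `theta_deg` (degrees in (-180, 180], 0 at mid-septum, positive toward
#'   anterior) and `z` (mm along the long axis).
#' @export
mesh_frame_coords <- function(mesh) {
  stopifnot(inherits(mesh, "biv_mesh"))
  rel <- sweep(mesh$vertices, 2, mesh$base_point)
  L <- sum((mesh$apex_point - mesh$base_point) * mesh$long_axis)
  z <- as.numeric(rel %*% mesh$long_axis)
  ant <- cross3(mesh$long_axis, mesh$septal_axis)
  xs <- as.numeric(rel %*% mesh$septal_axis)
  ya <- as.numeric(rel %*% ant)
  list(f = z / L, theta_deg = atan2(ya, xs) * 180 / pi, z = z)
}

#' Assign the 16-segment AHA model to the left ventricle
#'
#' Divides LV vertices (septal vertices included, as they count toward the LV)
#' into basal / mid / apical thirds by long-axis fraction and into the standard
#' circumferential sectors (6 of 60 degrees for the basal and mid rings, 4 of
#' 90 degrees for the apical ring). Segment 1 is the basal anterior wall;
#' numbering follows the American Heart Association convention. The 17th
#' (apex cap) segment is not used: apical vertices map to segments 13-16.
#'
#' @param mesh a `biv_mesh`.
#' @return integer vector (class `aha_segmentation`), segment id 1-16 per LV
#'   or septal vertex, `NA` for RV vertices.
#' @export
assign_aha_segments <- function(mesh) {
  stopifnot(inherits(mesh, "biv_mesh"))
  if (is.null(mesh$long_axis)) stop("mesh has no long_axis")
  lv <- mesh$chamber %in% c("LV", "SEPTUM")
  if (!any(lv)) stop("mesh has no LV vertices")
  fc <- mesh_frame_coords(mesh)
  seg <- rep(NA_integer_, nrow(mesh$vertices))
  ring <- ifelse(fc$f < 1 / 3, 0L, ifelse(fc$f < 2 / 3, 1L, 2L))
  th <- fc$theta_deg
  sector6 <- function(t) {
    # 1 anterior (60,120], 2 anteroseptal (0,60], 3 inferoseptal (-60,0],
    # 4 inferior (-120,-60], 5 inferolateral (-180,-120], 6 anterolateral else
    ifelse(t > 60 & t <= 120, 1L,
      ifelse(t > 0 & t <= 60, 2L,
        ifelse(t > -60 & t <= 0, 3L,
          ifelse(t > -120 & t <= -60, 4L,
            ifelse(t <= -120, 5L, 6L)
          )
        )
      )
    )
  }
  sector4 <- function(t) {
    # 13 anterior (45,135], 14 septal (-45,45], 15 inferior (-135,-45],
    # 16 lateral otherwise
    ifelse(t > 45 & t <= 135, 13L,
      ifelse(t > -45 & t <= 45, 14L,
        ifelse(t > -135 & t <= -45, 15L, 16L)
      )
    )
  }
  basal <- lv & ring == 0L
  mid <- lv & ring == 1L
  apical <- lv & ring == 2L
  seg[basal] <- sector6(th[basal])
  seg[mid] <- sector6(th[mid]) + 6L
  seg[apical] <- sector4(th[apical])
  structure(seg, class = "aha_segmentation")
}

#' Names of the 16 AHA segments
#' @return character vector of length 16, indexed by segment id.
#' @export
aha_segment_names <- function() {
  c(
    "basal anterior", "basal anteroseptal", "basal inferoseptal",
    "basal inferior", "basal inferolateral", "basal anterolateral",
    "mid anterior", "mid anteroseptal", "mid inferoseptal",
    "mid inferior", "mid inferolateral", "mid anterolateral",
    "apical anterior", "apical septal", "apical inferior", "apical lateral"
  )
}

#' Locate a named anatomical pacing/initiation site
#'
#' Returns the mesh vertices of the RV cavity lining (surface `ENDO_RV`,
#' which includes the RV face of the septum) within `radius_mm` of the named
#' landmark. Apical and free-wall sites are restricted to the RV free wall
#' (chamber `RV`); the mid-septal site lies on the RV face of the septum.
#'
#' @param mesh a `biv_mesh` with landmarks (as built by [biv_mesh()]).
#' @param name one of `RV_APEX_ANTERIOR`, `RV_APEX_MID`, `RV_APEX_POSTERIOR`,
#'   `RV_MID_SEPTUM`, `RV_ANTERIOR_FREE_WALL_ENDO`.
#' @param radius_mm site capture radius (mm), default 5.
#' @return object of class `anatomical_site`: list with `name`, `vertex_ids`,
#'   `center`.
#' @export
locate_site <- function(mesh, name, radius_mm = 5) {
  stopifnot(inherits(mesh, "biv_mesh"))
  if (!name %in% SITE_NAMES) stop("unknown site name: ", name)
  center <- mesh$landmarks[[name]]
  if (is.null(center)) stop("mesh carries no landmark for site ", name)
  cand <- mesh$surface == "ENDO_RV"
  cand <- cand & mesh$chamber ==
    if (name == "RV_MID_SEPTUM") "SEPTUM" else "RV"
  d <- sqrt(colSums((t(mesh$vertices) - center)^2))
  ids <- which(cand & d <= radius_mm)
  if (length(ids) == 0) {
    stop("site ", name, " is empty at radius ", radius_mm, " mm")
  }
  structure(
    list(name = name, vertex_ids = ids, center = center),
    class = "anatomical_site"
  )
}

#' Left anterior oblique cranial planar projection
#'
#' Orthographic projection onto the plane spanned by the anterior direction
#' (horizontal) and the negated long axis (vertical), i.e. the view in which
#' the projected base-to-apex distance is maximal, with the base up. A rigid
#' rotation followed by dropping the view axis: in-plane distances are
#' preserved exactly.
#'
#' @param mesh a `biv_mesh`.
#' @return object of class `planar_projection`: list with `view`, n x 2
#'   `coords` (mm) and the 2 x 3 in-plane `basis`.
#' @export
lao_cranial_projection <- function(mesh) {
  stopifnot(inherits(mesh, "biv_mesh"))
  if (is.null(mesh$long_axis)) stop("mesh has no long_axis")
  sv <- svd(scale(mesh$vertices, scale = FALSE))$d
  if (sum(sv > 1e-9) < 2) stop("degenerate mesh: vertices are collinear")
  u <- cross3(mesh$long_axis, mesh$septal_axis) # anterior, horizontal
  v <- -mesh$long_axis # vertical, base up
  rel <- sweep(mesh$vertices, 2, mesh$base_point)
  coords <- cbind(as.numeric(rel %*% u), as.numeric(rel %*% v))
  colnames(coords) <- c("h", "v")
  structure(
    list(view = "LAO_CRANIAL", coords = coords, basis = rbind(u, v)),
    class = "planar_projection"
  )
}
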
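# Synthetic paired cohorts.
#
# Two independent generator paths: (a) a metric-level generator drawing
# paired (intrinsic, paced) per-patient metric values from bivariate normals
# with the published subgroup means/SDs, so the statistics stage can be
# tested against known parameters; and (b) a map-level generator running the
# activation simulator per synthetic patient with jittered conduction,
# optional ischemic scar and additive measurement noise, exercising the whole
# chain end-to-end.

COHORT_METRICS <- c("vvsync", "vvtat", "lvtat", "lvdisp", "wfa")

#' Default per-subgroup cohort parameters
#'
#' Intrinsic (LBBB) and paced means/SDs per metric and lead-position
#' subgroup, as published for a 14-patient CRT cohort (9 apical, 5 septal):
#' VVsync, VVtat, LVtat, LVdisp in ms, WFA in degrees.
#'
#' @return data.frame with columns `metric`, `group`, `intrinsic_mean`,
#'   `intrinsic_sd`, `paced_mean`, `paced_sd`.
#' @export
cohort_default_params <- function() {
  data.frame(
    metric = rep(COHORT_METRICS, times = 2),
    group = rep(c("apical", "septal"), each = 5),
    intrinsic_mean = c(
      38.2, 89.9, 82.0, 25.7, 76.7,
      57.6, 120.2, 97.0, 31.2, 93.0
    ),
    intrinsic_sd = c(
      14.5, 20.6, 20.0, 6.0, 28.9,
      24.6, 8.7, 21.5, 7.6, 13.5
    ),
    paced_mean = c(
      27.8, 107.4, 103.3, 33.3, 50.0,
      50.4, 118.4, 101.8, 33.4, 84.0
    ),
    paced_sd = c(
      11.3, 24.0, 23.8, 6.9, 27.6,
      16.8, 10.5, 10.6, 4.2, 28.4
    ),
    stringsAsFactors = FALSE
  )
}

#' Specification of a synthetic paired cohort
#'
#' @param n_apical,n_septal patients per lead-position subgroup (defaults
#'   9 and 5, the published split).
#' @param params per-subgroup metric means/SDs, see [cohort_default_params()].
#' @param rho within-patient correlation between the intrinsic and paced
#'   draw of each metric, in `[0, 1)` (default 0.7; the publication reports
#'   only group summaries, so pairing strength is a free parameter).
#' @param ischemic_fraction fraction of patients flagged ischemic (default
#'   8/14 as published).
#' @param map_noise_sd additive measurement noise on map-path activation
#'   times (ms, default 3).
#' @param cv_jitter_sdlog lognormal SD of the per-patient conduction-velocity
#'   multiplier on the map path (default 0.1).
#' @param scar_multiplier,scar_radius_mm ischemic-scar slowing factor and
#'   patch radius for map-path ischemic patients.
#' @param site_radius_mm pacing-site capture radius for map-path scenarios
#'   (mm; enlarge on coarse meshes).
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_apical = 9, n_septal = 5,
                        params = cohort_default_params(), rho = 0.7,
                        ischemic_fraction = 8 / 14, map_noise_sd = 3,
                        cv_jitter_sdlog = 0.1, scar_multiplier = 0.3,
                        scar_radius_mm = 12, site_radius_mm = 5) {
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  if (any(params$intrinsic_sd < 0) || any(params$paced_sd < 0)) {
    stop("SDs must be >= 0")
  }
  if (map_noise_sd < 0 || cv_jitter_sdlog < 0) stop("noise SDs must be >= 0")
  stopifnot(n_apical >= 0, n_septal >= 0, n_apical + n_septal > 0)
  structure(
    list(
      n_apical = n_apical, n_septal = n_septal,
      n_patients = n_apical + n_septal, params = params, rho = rho,
      ischemic_fraction = ischemic_fraction, map_noise_sd = map_noise_sd,
      cv_jitter_sdlog = cv_jitter_sdlog, scar_multiplier = scar_multiplier,
      scar_radius_mm = scar_radius_mm, site_radius_mm = site_radius_mm
    ),
    class = "cohort_spec"
  )
}

assign_ischemic <- function(spec) {
  n <- spec$n_patients
  k <- round(spec$ischemic_fraction * n)
  flags <- rep(FALSE, n)
  if (k > 0) flags[sample.int(n, min(k, n))] <- TRUE
  flags
}

#' Generate a paired metric-level cohort
#'
#' Per patient and metric, draws a bivariate-normal (intrinsic, paced) pair
#' with the subgroup's means/SDs and within-patient correlation `rho`.
#' Reproducible under a fixed seed (uses the R RNG stream).
#'
#' @param spec a [cohort_spec()].
#' @return `cohort_table`: long data.frame with two rows per patient
#'   (`state` intrinsic / paced) and columns `patient_id`, `lead_position`,
#'   `ischemic`, `state`, `vvsync_ms`, `vvtat_ms`, `lvtat_ms`, `lvdisp_ms`,
#'   `wfa_deg`.
#' @export
generate_metric_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  lead <- rep(c("apical", "septal"), c(spec$n_apical, spec$n_septal))
  n <- spec$n_patients
  ischemic <- assign_ischemic(spec)
  rho <- spec$rho
  cols <- paste0(COHORT_METRICS, c(rep("_ms", 4), "_deg"))
  intr <- matrix(NA_real_, n, 5, dimnames = list(NULL, cols))
  paced <- intr
  for (i in seq_len(n)) {
    p <- spec$params[spec$params$group == lead[i], ]
    p <- p[match(COHORT_METRICS, p$metric), ]
    z1 <- stats::rnorm(5)
    z2 <- stats::rnorm(5)
    intr[i, ] <- p$intrinsic_mean + p$intrinsic_sd * z1
    paced[i, ] <- p$paced_mean + p$paced_sd * (rho * z1 + sqrt(1 - rho^2) * z2)
  }
  out <- data.frame(
    patient_id = rep(seq_len(n), each = 2),
    lead_position = rep(lead, each = 2),
    ischemic = rep(ischemic, each = 2),
    state = rep(c("intrinsic", "paced"), n),
    stringsAsFactors = FALSE
  )
  vals <- matrix(NA_real_, 2 * n, 5, dimnames = list(NULL, cols))
  vals[seq(1, 2 * n, by = 2), ] <- intr
  vals[seq(2, 2 * n, by = 2), ] <- paced
  out <- cbind(out, as.data.frame(vals))
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Generate a simulator-based map-level cohort
#'
#' Per synthetic patient: conduction velocities jittered by a shared
#' lognormal multiplier, an ischemic scar patch for ischemic patients, one
#' intrinsic LBBB map plus one paced map (RV apical-mid or septal pacing per
#' lead assignment) and additive Gaussian measurement noise on the activation
#' times.
#'
#' @param spec a [cohort_spec()].
#' @param mesh a `biv_mesh` shared by the cohort.
#' @param cm baseline `conduction_model`.
#' @return list of per-patient lists with `intrinsic` and `paced`
#'   `activation_map`s, `lead_position` and `ischemic`.
#' @export
generate_map_cohort <- function(spec, mesh, cm = conduction_model()) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(mesh, "biv_mesh"))
  lead <- rep(c("apical", "septal"), c(spec$n_apical, spec$n_septal))
  ischemic <- assign_ischemic(spec)
  lv_epi <- which(lv_free_wall_mask(mesh))
  lapply(seq_len(spec$n_patients), function(i) {
    mult <- stats::rlnorm(1, 0, spec$cv_jitter_sdlog)
    cmi <- conduction_model(
      base_cv = cm$base_cv * mult,
      rv_endo_fast_factor = cm$rv_endo_fast_factor,
      transmural_cv = cm$transmural_cv * mult
    )
    if (ischemic[i]) {
      center <- mesh$vertices[sample(lv_epi, 1), ]
      d <- sqrt(colSums((t(mesh$vertices) - center)^2))
      cmi <- add_scar(
        cmi, which(d <= spec$scar_radius_mm), spec$scar_multiplier
      )
    }
    paced_name <- if (lead[i] == "apical") "RVAP_MID" else "RVSP"
    noisy <- function(map) {
      if (spec$map_noise_sd > 0) {
        map$times <- map$times + stats::rnorm(length(map$times), 0, spec$map_noise_sd)
      }
      map
    }
    r <- spec$site_radius_mm
    list(
      intrinsic = noisy(simulate_activation(
        mesh, cmi, make_scenario("LBBB", mesh, radius_mm = r)
      )),
      paced = noisy(simulate_activation(
        mesh, cmi, make_scenario(paced_name, mesh, radius_mm = r)
      )),
      lead_position = lead[i], ischemic = ischemic[i]
    )
  })
}

#' Metric-set cohort table from a map-level cohort
#'
#' Computes the full metric set for every map in a map-level cohort and
#' assembles the same long `cohort_table` layout as the metric-level
#' generator.
#'
#' @param maps output of [generate_map_cohort()].
#' @param seg,proj shared segmentation / projection of the cohort mesh
#'   (defaults computed from the first map).
#' @return a `cohort_table` data.frame.
#' @export
map_cohort_metrics <- function(maps,
                               seg = assign_aha_segments(maps[[1]]$intrinsic$mesh),
                               proj = lao_cranial_projection(maps[[1]]$intrinsic$mesh)) {
  rows <- lapply(seq_along(maps), function(i) {
    pt <- maps[[i]]
    one <- function(map, state) {
      ms <- compute_metrics(map, seg, proj)
      data.frame(
        patient_id = i, lead_position = pt$lead_position,
        ischemic = pt$ischemic, state = state,
        vvsync_ms = ms$vvsync, vvtat_ms = ms$vvtat, lvtat_ms = ms$lvtat,
        lvdisp_ms = ms$lvdisp, wfa_deg = ms$wfa, stringsAsFactors = FALSE
      )
    }
    rbind(one(pt$intrinsic, "intrinsic"), one(pt$paced, "paced"))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Write / read a cohort table as CSV
#' @param cohort a `cohort_table`.
#' @param path file path.
#' @return `read_cohort_csv` returns a `cohort_table`.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("cohort_table", "data.frame")
  out
}
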
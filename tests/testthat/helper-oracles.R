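# Independent brute-force oracles, kept free of the package's own
# computational paths.

# O(V^2) single-pass multi-source Dijkstra on an explicit edge list.
oracle_shortest_times <- function(n, edges, weights, sources, onsets) {
  dist <- rep(Inf, n)
  dist[sources] <- pmin(dist[sources], onsets)
  adj <- vector("list", n)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]
    b <- edges[i, 2]
    adj[[a]] <- rbind(adj[[a]], c(b, weights[i]))
    adj[[b]] <- rbind(adj[[b]], c(a, weights[i]))
  }
  done <- rep(FALSE, n)
  for (iter in seq_len(n)) {
    u <- which(!done)[which.min(dist[!done])]
    if (length(u) == 0 || !is.finite(dist[u])) break
    done[u] <- TRUE
    nb <- adj[[u]]
    if (!is.null(nb)) {
      for (r in seq_len(nrow(nb))) {
        v <- nb[r, 1]
        w <- dist[u] + nb[r, 2]
        if (w < dist[v]) dist[v] <- w
      }
    }
  }
  dist
}

# Independent edge-weight construction from first principles: triangle edges
# at the harmonic-mean layer velocity, transmural links at the transmural
# velocity, per-vertex scar multipliers.
oracle_edge_weights <- function(mesh, base_cv, fast_factor, transmural_cv,
                                fast_on, scars = list()) {
  vel <- numeric(nrow(mesh$vertices))
  for (i in seq_len(nrow(mesh$vertices))) {
    vel[i] <- base_cv[[mesh$surface[i]]]
    if (fast_on && mesh$surface[i] == "ENDO_RV") vel[i] <- vel[i] * fast_factor
  }
  velt <- rep(transmural_cv, nrow(mesh$vertices))
  for (sc in scars) {
    vel[sc$region] <- vel[sc$region] * sc$multiplier
    velt[sc$region] <- velt[sc$region] * sc$multiplier
  }
  seen <- new.env()
  edges <- list()
  weights <- numeric()
  push <- function(a, b, v1, v2) {
    key <- paste(min(a, b), max(a, b))
    if (!is.null(seen[[key]])) {
      return()
    }
    seen[[key]] <- TRUE
    if (v1 <= 0 || v2 <= 0) {
      return()
    }
    cv <- 2 * v1 * v2 / (v1 + v2)
    d <- sqrt(sum((mesh$vertices[a, ] - mesh$vertices[b, ])^2))
    edges[[length(edges) + 1]] <<- c(a, b)
    weights[length(weights) + 1] <<- d / cv
  }
  for (i in seq_len(nrow(mesh$triangles))) {
    tr <- mesh$triangles[i, ]
    for (pr in list(c(1, 2), c(2, 3), c(1, 3))) {
      a <- tr[pr[1]]
      b <- tr[pr[2]]
      push(a, b, vel[a], vel[b])
    }
  }
  for (i in seq_len(nrow(mesh$transmural))) {
    a <- mesh$transmural[i, 1]
    b <- mesh$transmural[i, 2]
    push(a, b, velt[a], velt[b])
  }
  list(edges = do.call(rbind, edges), weights = weights)
}

oracle_activation_times <- function(mesh, cm, sources, onsets, fast_on) {
  ew <- oracle_edge_weights(
    mesh, cm$base_cv, cm$rv_endo_fast_factor, cm$transmural_cv,
    fast_on, cm$scars
  )
  oracle_shortest_times(
    nrow(mesh$vertices), ew$edges, ew$weights, sources, onsets
  )
}

# population SD, written out
oracle_pop_sd <- function(x) sqrt(sum((x - sum(x) / length(x))^2) / length(x))

# two-sided exact Mann-Whitney p by complete rank enumeration (no ties)
oracle_mwu_exact <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  ranks <- rank(c(a, b))
  u <- sum(ranks[seq_len(na)]) - na * (na + 1) / 2
  idx <- utils::combn(na + nb, na)
  allv <- seq_len(na + nb)
  us <- apply(idx, 2, function(s) sum(allv[s]) - na * (na + 1) / 2)
  ge <- mean(us >= u)
  le <- mean(us <= u)
  p <- if (u > na * nb / 2) 2 * ge else 2 * le
  list(u = u, p = min(1, p))
}

# minimal labelled point-set "mesh" for metric-formula tests (no surface
# needed by the scalar metrics)
random_label_mesh <- function(n, seed_chambers = TRUE) {
  stopifnot(n >= 8)
  v <- matrix(stats::runif(3 * n, -40, 40), ncol = 3)
  chamber <- sample(c("LV", "RV", "SEPTUM"), n, replace = TRUE)
  chamber[1:3] <- c("LV", "RV", "SEPTUM") # guarantee presence
  surface <- ifelse(chamber == "RV", "ENDO_RV",
    sample(c("EPI", "ENDO_LV"), n, replace = TRUE)
  )
  lv_epi <- which(chamber == "LV")
  surface[lv_epi[1:min(2, length(lv_epi))]] <- "EPI" # >= 2 LV epicardial
  as_biv_mesh(
    vertices = v, triangles = matrix(integer(), 0, 3),
    chamber = chamber, surface = surface,
    base_point = c(0, 0, 0), apex_point = c(0, 0, 90),
    long_axis = c(0, 0, 1), septal_axis = c(1, 0, 0)
  )
}

random_map <- function(mesh, tmax = 150) {
  activation_map(mesh, stats::runif(nrow(mesh$vertices), 0, tmax))
}

cross3_test <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(
    0, -axis[3], axis[2],
    axis[3], 0, -axis[1],
    -axis[2], axis[1], 0
  ), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}
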
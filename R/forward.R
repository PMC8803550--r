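#' Spherical conductor model
#'
#' The volume-conductor model used by the simulator and the beamformer: a
#' homogeneous conducting sphere. It preserves every algebraic property the
#' pipelines exercise (radial silence, linearity, externally vanishing volume
#' currents) without requiring anatomy.
#'
#' @param centre sphere centre, 3-vector in metres (head frame).
#' @param radius sphere radius in metres (default 0.09, an adult head).
#' @return an object of class `opm_sphere`.
#' @export
sphere_model <- function(centre = c(0, 0, 0), radius = 0.09) {
  stopifnot(length(centre) == 3, radius > 0)
  structure(list(centre = as.numeric(centre), radius = radius),
            class = "opm_sphere")
}

#' Build a synthetic scalp array geometry
#'
#' Places `n_sensors` OPMs on a Fibonacci lattice over the upper hemisphere
#' at `head_radius + scalp_offset` from the origin. Each sensor gets a radial
#' sensitive axis pointing outward plus one (`dual`) or two (`triaxial`)
#' orthonormal tangential axes. Channels are named `S##-RAD`, `S##-TAN`
#' (and `S##-TAN2` for triaxial).
#'
#' @param n_sensors number of sensor sites (>= 4).
#' @param axes `"dual"` (radial + one tangential channel per site) or
#'   `"triaxial"` (full 3D field vector).
#' @param head_radius scalp sphere radius in metres (default 0.09).
#' @param scalp_offset sensor cell standoff from the scalp in metres
#'   (default 0.01, typical for a rigid scanner-cast).
#' @return a channel table (data.frame) of scalp channels, usable directly
#'   as the `channels` slot of a recording.
#' @export
build_array_geometry <- function(n_sensors, axes = c("dual", "triaxial"),
                                 head_radius = 0.09, scalp_offset = 0.01) {
  axes <- match.arg(axes)
  if (n_sensors < 4) stop("n_sensors must be at least 4")
  r <- head_radius + scalp_offset
  i <- seq_len(n_sensors) - 1
  # upper hemisphere: z in (0, 1], golden-angle azimuth
  z <- (i + 0.5) / n_sensors
  phi <- i * pi * (3 - sqrt(5))
  s <- sqrt(1 - z^2)
  pos <- r * cbind(s * cos(phi), s * sin(phi), z)
  rows <- list()
  for (k in seq_len(n_sensors)) {
    rad <- pos[k, ] / sqrt(sum(pos[k, ]^2))
    # tangential basis: project global x (or y near the poles) onto the
    # tangent plane
    seed <- if (abs(rad[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    t1 <- seed - sum(seed * rad) * rad
    t1 <- t1 / sqrt(sum(t1^2))
    t2 <- c(rad[2] * t1[3] - rad[3] * t1[2],
            rad[3] * t1[1] - rad[1] * t1[3],
            rad[1] * t1[2] - rad[2] * t1[1])
    nm <- sprintf("S%02d", k)
    ax <- list(RAD = rad, TAN = t1)
    if (axes == "triaxial") ax$TAN2 <- t2
    for (a in names(ax))
      rows[[length(rows) + 1]] <- data.frame(
        name = paste0(nm, "-", a), kind = "scalp", axis = a,
        pos_x = pos[k, 1], pos_y = pos[k, 2], pos_z = pos[k, 3],
        ori_x = ax[[a]][1], ori_y = ax[[a]][2], ori_z = ax[[a]][3],
        stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reference sensor channels
#'
#' Static off-head reference OPMs (dual axis) for synthetic gradiometry.
#'
#' @param positions matrix (n x 3) of reference sensor positions in metres;
#'   defaults to two sensors well away from the head, placed and oriented so
#'   that the four sensitive axes span all three field components (a
#'   mirror-symmetric pair would be blind to one direction of a homogeneous
#'   field).
#' @return a channel table of `reference` channels named `N#-RAD` / `N#-TAN`.
#' @export
build_reference_channels <- function(positions = rbind(c(0.35, 0.25, 0.15),
                                                       c(-0.25, 0.30, 0.40))) {
  positions <- as.matrix(positions)
  rows <- list()
  for (k in seq_len(nrow(positions))) {
    p <- positions[k, ]
    rad <- p / sqrt(sum(p^2))
    seed <- if (k %% 2 == 1) c(1, 0, 0) else c(0, 1, 0)
    if (abs(sum(seed * rad)) > 0.95) seed <- c(0, 0, 1)
    t1 <- seed - sum(seed * rad) * rad
    t1 <- t1 / sqrt(sum(t1^2))
    nm <- sprintf("N%d", k - 1)
    for (a in c("RAD", "TAN")) {
      o <- if (a == "RAD") rad else t1
      rows[[length(rows) + 1]] <- data.frame(
        name = paste0(nm, "-", a), kind = "reference", axis = a,
        pos_x = p[1], pos_y = p[2], pos_z = p[3],
        ori_x = o[1], ori_y = o[2], ori_z = o[3],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

trigger_channel_row <- function(name = "NI-TRIG") {
  data.frame(name = name, kind = "trigger", axis = NA_character_,
             pos_x = NA_real_, pos_y = NA_real_, pos_z = NA_real_,
             ori_x = NA_real_, ori_y = NA_real_, ori_z = NA_real_,
             stringsAsFactors = FALSE)
}

#' Current-dipole lead field in a conducting sphere
#'
#' Analytic magnetic field of a current dipole inside a homogeneous
#' conducting sphere (volume currents included; they cancel in the radial
#' component and vanish outside the sphere), evaluated at each sensor and
#' projected onto each channel's sensitive axis. Linear in the dipole moment.
#'
#' @param geom channel table of scalp channels (from
#'   [build_array_geometry()]).
#' @param sphere an `opm_sphere`.
#' @param source dipole position, 3-vector in metres; must lie strictly
#'   inside the sphere and off centre.
#' @return matrix (n_channels x 3) in tesla per ampere-metre; column j is the
#'   channel response to a unit dipole moment along axis j.
#' @export
sarvas_leadfield <- function(geom, sphere, source) {
  stopifnot(inherits(sphere, "opm_sphere"), length(source) == 3)
  r0 <- as.numeric(source) - sphere$centre
  d0 <- sqrt(sum(r0^2))
  if (d0 >= sphere$radius)
    stop("source must lie strictly inside the sphere")
  if (d0 < 1e-6)
    stop("source at the sphere centre: tangential basis is degenerate")
  pos <- position_matrix(geom)
  ori <- orientation_matrix(geom)
  rel <- sweep(pos, 2, sphere$centre)
  rs <- sqrt(rowSums(rel^2))
  if (any(rs <= sphere$radius))
    stop("sensor position(s) inside the sphere")
  mu0_4pi <- 1e-7
  n <- nrow(pos)
  L <- matrix(0, n, 3)
  for (j in 1:3) {
    Q <- c(0, 0, 0); Q[j] <- 1
    Qxr0 <- c(Q[2] * r0[3] - Q[3] * r0[2],
              Q[3] * r0[1] - Q[1] * r0[3],
              Q[1] * r0[2] - Q[2] * r0[1])
    a_vec <- rel - matrix(r0, n, 3, byrow = TRUE)
    a <- sqrt(rowSums(a_vec^2))
    ar <- rowSums(a_vec * rel)            # a . r
    r0r <- as.numeric(rel %*% r0)         # r0 . r
    F_ <- a * (rs * a + rs^2 - r0r)
    gF_r <- a^2 / rs + ar / a + 2 * a + 2 * rs
    gF_r0 <- a + 2 * rs + ar / a
    gradF <- rel * gF_r - matrix(r0, n, 3, byrow = TRUE) * gF_r0
    Qxr0_r <- as.numeric(rel %*% Qxr0)
    B <- (matrix(Qxr0, n, 3, byrow = TRUE) * F_ - gradF * Qxr0_r) *
      (mu0_4pi / F_^2)
    L[, j] <- rowSums(B * ori)
  }
  rownames(L) <- geom$name
  L
}

#' Lead field for a multi-source model
#'
#' Column-wise concatenation of per-source lead fields: with
#' `reduce_rank = FALSE`, columns 1-3 are source 1 (x, y, z moment),
#' columns 4-6 source 2, and so on. In a spherical conductor the radial
#' moment is externally silent, so each source's 3-column block has rank 2;
#' the default `reduce_rank = TRUE` keeps only the two effective (tangential)
#' moment directions per source, which a unit-gain beamformer constraint
#' requires.
#'
#' @param geom scalp channel table.
#' @param sphere an `opm_sphere`.
#' @param sources list of dipole positions (3-vectors, metres).
#' @param reduce_rank drop each source's silent radial direction (default
#'   `TRUE`).
#' @return matrix (n_channels x n_ori * n_sources) with `n_ori` 2 (reduced)
#'   or 3; attribute `n_ori` records the block size, `moment_basis` the
#'   per-source moment directions spanning each block.
#' @export
dual_source_leadfield <- function(geom, sphere, sources,
                                  reduce_rank = TRUE) {
  stopifnot(length(sources) >= 1)
  blocks <- lapply(sources, function(s) {
    L <- sarvas_leadfield(geom, sphere, s)
    if (!reduce_rank) return(list(L = L, basis = diag(3)))
    sv <- svd(L)
    list(L = L %*% sv$v[, 1:2, drop = FALSE],
         basis = sv$v[, 1:2, drop = FALSE])
  })
  out <- do.call(cbind, lapply(blocks, `[[`, "L"))
  attr(out, "n_ori") <- if (reduce_rank) 2L else 3L
  attr(out, "moment_basis") <- lapply(blocks, `[[`, "basis")
  out
}

#' Preset bilateral "auditory cortex" source positions
#'
#' A fixed convention, not anatomy: bilateral temporal-lobe-like positions in
#' the sphere frame, scaled from canonical auditory-cortex coordinates to fit
#' inside the default sphere.
#'
#' @return list of two 3-vectors (metres).
#' @export
auditory_sources <- function() {
  list(c(-0.054, -0.022, 0.004), c(0.054, -0.022, 0.004))
}

#' Preset left "sensorimotor" source position
#' @return a 3-vector (metres): left hemisphere, superior.
#' @export
sensorimotor_source <- function() c(-0.042, -0.008, 0.058)
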
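#' Digital resolution phantom: parallel tubes in a bright bath
#'
#' Emulates a line-pair resolution phantom built from sealed cylindrical
#' tubes immersed in a homogeneous contrast-agent bath: the bath is bright
#' and each tube (wall plus trapped air, i.e. the full outer diameter) is a
#' signal void. Tube centers are coplanar and spaced so the gap between
#' adjacent outer walls equals `tube_separation` (center-to-center distance
#' `tube_outer_diameter + tube_separation`). Voxels straddling a cylinder
#' wall get a partial-volume intensity from `supersample`^3 subvoxel
#' membership averaging, mimicking the scanner's intrinsic partial-volume
#' effect; a hard binary mask would alias and contaminate edge-width
#' measurements downstream.
#'
#' The default geometry is five tubes of 0.5 mm inner / 0.7 mm outer
#' diameter separated by 0.7 mm, on a 26 mm field of view sampled at
#' 128^3 (0.203 mm isotropic).
#'
#' With `orientation = c(0, 0)` the tube long axes lie along y and the
#' row of tubes runs along x. `orientation = c(angle_xy, angle_yz)` first
#' rotates the tube frame by `angle_xy` degrees in the x-y plane, then by
#' `angle_yz` degrees in the y-z plane, giving obliquely oriented tubes
#' (the worst case for through-plane partial-volume averaging).
#'
#' @param grid_shape Voxels per axis (length 3 or scalar).
#' @param spacing Isotropic voxel size, mm.
#' @param n_tubes Number of tubes (>= 0); 0 gives a uniform bath.
#' @param tube_inner_diameter,tube_outer_diameter Tube bore / outer wall
#'   diameter, mm. The full outer diameter is rendered as void.
#' @param tube_separation Gap between adjacent outer walls, mm.
#' @param tube_length Tube length, mm (`Inf` = tubes span the volume).
#' @param orientation Numeric `c(angle_xy_deg, angle_yz_deg)`.
#' @param background_intensity,void_intensity Bath / tube intensities.
#' @param supersample Subvoxel grid per axis for partial-volume averaging.
#'
#' @return An [srr_volume()] whose `meta` records the construction
#'   (tube centers, axis, separation) and a ready-made line-profile
#'   segment crossing all tube centers perpendicular to the tube axis.
#' @export
make_resolution_phantom <- function(grid_shape = c(128, 128, 128),
                                    spacing = 26 / 128,
                                    n_tubes = 5,
                                    tube_inner_diameter = 0.5,
                                    tube_outer_diameter = 0.7,
                                    tube_separation = 0.7,
                                    tube_length = Inf,
                                    orientation = c(0, 0),
                                    background_intensity = 100,
                                    void_intensity = 0,
                                    supersample = 3) {
  if (length(grid_shape) == 1L) grid_shape <- rep(grid_shape, 3L)
  grid_shape <- as.integer(grid_shape)
  if (tube_outer_diameter < tube_inner_diameter || tube_inner_diameter <= 0)
    stop("need tube_outer_diameter >= tube_inner_diameter > 0")
  if (tube_separation <= 0) stop("tube_separation must be > 0")
  if (n_tubes < 0) stop("n_tubes must be >= 0")

  origin <- -(grid_shape - 1) / 2 * spacing
  data <- array(background_intensity, dim = grid_shape)

  # Tube frame: the long axis u starts along y and is tilted by the
  # orientation angles; the tube row w is laid along the default
  # slice-select axis (z) -- slabs thicker than the tube gap then cut
  # across the row, the configuration whose through-plane resolution the
  # phantom probes. For tilted u the row is the z component orthogonal
  # to u (rows stay as close to the slice axis as rigidity allows).
  rot <- orientation_matrix(orientation[1], orientation[2])
  u <- as.numeric(rot %*% c(0, 1, 0))
  zhat <- c(0, 0, 1)
  w <- zhat - sum(zhat * u) * u
  if (sqrt(sum(w^2)) < 1e-6) w <- c(1, 0, 0) - sum(c(1, 0, 0) * u) * u
  w <- w / sqrt(sum(w^2))

  cc <- tube_outer_diameter + tube_separation  # center-to-center
  centers <- NULL
  if (n_tubes > 0) {
    offs <- (seq_len(n_tubes) - (n_tubes + 1) / 2) * cc
    centers <- t(vapply(offs, function(o) o * w, numeric(3)))
    half_fov <- grid_shape * spacing / 2
    # radial extent per axis: the tube's own axis direction is unbounded
    radial <- tube_outer_diameter / 2 * sqrt(pmax(0, 1 - u^2))
    for (j in seq_len(n_tubes)) {
      if (any(abs(centers[j, ]) + radial > half_fov))
        stop(sprintf("tube %d exceeds the field of view", j))
    }
    frac <- cpp_cylinder_fraction(
      grid_shape, rep(spacing, 3), origin, centers, u,
      tube_outer_diameter / 2, tube_length / 2, as.integer(supersample)
    )
    data <- data + array(frac, dim = grid_shape) *
      (void_intensity - background_intensity)
  }

  prof <- NULL
  if (n_tubes > 0) {
    ext <- (n_tubes / 2 + 1) * cc
    prof <- list(start = -ext * w, end = ext * w)
  }

  srr_volume(
    data, spacing = spacing, origin = origin,
    meta = list(
      kind = "resolution",
      background = background_intensity,
      void = void_intensity,
      tube_axis = u,
      tube_row_direction = w,
      tube_centers = centers,
      tube_outer_diameter = tube_outer_diameter,
      center_spacing = cc,
      n_tubes = n_tubes,
      tube_profile = prof,
      intensity_range = sort(c(void_intensity, background_intensity))
    )
  )
}

# rotation by a degrees in the x-y plane then b degrees in the y-z plane
orientation_matrix <- function(angle_xy_deg, angle_yz_deg) {
  a <- angle_xy_deg * pi / 180
  b <- angle_yz_deg * pi / 180
  rxy <- rbind(c(cos(a), -sin(a), 0),
               c(sin(a),  cos(a), 0),
               c(0,       0,      1))
  ryz <- rbind(c(1, 0,      0),
               c(0, cos(b), -sin(b)),
               c(0, sin(b),  cos(b)))
  ryz %*% rxy
}

#' Digital biological phantom: nested smoothed ellipsoids
#'
#' A fully synthetic stand-in for an ex vivo embryo specimen, built from
#' nested ellipsoids rather than an atlas so that region homogeneity, edge
#' sharpness, and measurement-site placement are exactly controllable. It
#' contains (a) two large homogeneous regions of distinct mean intensity
#' ("tissue" and "liver"), each comfortably hosting 9 x 9 x 9 voxel ROIs;
#' (b) a smooth closed high-contrast liver boundary crossed by 20
#' boundary-normal line-profile segments; (c) three fine bright rods 2-3
#' voxels wide; and (d) a dark surround (the susceptibility-matched bath
#' analogue) used as the noise ROI. Partial-volume intensities at all
#' boundaries come from 3^3 subvoxel membership averaging.
#'
#' The seed perturbs ellipsoid centers and semi-axes by a few percent so
#' replicate phantoms are anatomically distinct; the ROI and edge-profile
#' placements in `meta` are recomputed from the perturbed construction, so
#' they stay valid for every seed. Output is bit-reproducible for a fixed
#' seed.
#'
#' @param grid_shape Voxels per axis (length 3 or scalar); each >= 96
#'   (the design is scale-relative, so below 96 voxels the 9 x 9 x 9
#'   background noise ROI no longer clears the body ellipsoid).
#' @param spacing Isotropic voxel size, mm.
#' @param seed Integer seed for the anatomical jitter.
#' @param supersample Subvoxel grid per axis for partial-volume averaging.
#' @return An [srr_volume()]; `meta$rois` is a tibble of named 9^3 box
#'   ROIs (signal, noise, high, low), `meta$edge_profiles` a tibble of 20
#'   boundary-normal segments (start/end in mm) across the liver boundary.
#' @export
make_biological_phantom <- function(grid_shape = c(128, 128, 128),
                                    spacing = 0.05,
                                    seed = 1,
                                    supersample = 3) {
  if (length(grid_shape) == 1L) grid_shape <- rep(grid_shape, 3L)
  grid_shape <- as.integer(grid_shape)
  if (any(grid_shape < 96))
    stop("grid too small: need >= 96 voxels per axis to host the 9x9x9 ROIs and edge profiles")
  spacing <- rep(as.numeric(spacing), length.out = 3L)[1]
  sp3 <- rep(spacing, 3)
  origin <- -(grid_shape - 1) / 2 * spacing
  E <- grid_shape * spacing / 2  # half field of view per axis

  # a few percent of anatomical jitter per seed
  jit <- with_local_seed(seed, list(
    ax = runif(3, -0.03, 0.03),
    ctr = runif(3, -0.015, 0.015),
    lax = runif(3, -0.03, 0.03),
    lctr = runif(3, -0.01, 0.01)
  ))

  i_bg <- 5; i_body <- 90; i_liver <- 55; i_rod <- 100

  body_ax <- c(0.81, 0.72, 0.78) * E * (1 + jit$ax)
  body_ctr <- jit$ctr * E
  liver_ax <- c(0.375, 0.344, 0.359) * E * (1 + jit$lax)
  liver_ctr <- c(0.094, -0.078, 0.0625) * E + jit$lctr * E

  ss <- as.integer(supersample)
  data <- array(i_bg, dim = grid_shape)
  paint <- function(data, frac, value) data + frac * (value - data)

  f_body <- array(cpp_ellipsoid_fraction(grid_shape, sp3, origin,
                                         body_ctr, body_ax, ss), grid_shape)
  data <- paint(data, f_body, i_body)
  f_liver <- array(cpp_ellipsoid_fraction(grid_shape, sp3, origin,
                                          liver_ctr, liver_ax, ss), grid_shape)
  data <- paint(data, f_liver, i_liver)

  # fine structures: three bright rods along y, 3 voxels across
  rod_x <- -0.625 * E[1]
  rod_z <- c(-0.156, 0, 0.156) * E[3]
  rod_centers <- cbind(rod_x, 0, rod_z)
  f_rod <- array(cpp_cylinder_fraction(grid_shape, sp3, origin, rod_centers,
                                       c(0, 1, 0), 1.5 * spacing,
                                       0.3 * E[2], ss), grid_shape)
  data <- paint(data, f_rod, i_rod)

  # 9^3 box ROIs, voxel indices of the low corner
  roi_half <- 4L
  roi_corner <- function(p_mm) {
    ctr <- round((p_mm - origin) / spacing) + 1
    as.integer(ctr - roi_half)
  }
  # tissue ROI in the -x octant: clear of the liver (and the edge-profile
  # corridor around it) and of the rods at x = -0.625 E
  tissue_roi <- c(-0.469, -0.281, 0.281) * E
  rois <- tibble::tibble(
    name = c("signal", "noise", "high", "low"),
    corner = list(
      roi_corner(tissue_roi),
      roi_corner(c(0, 0.89 * E[2], 0)),
      roi_corner(tissue_roi),
      roi_corner(liver_ctr)
    ),
    size = list(rep(9L, 3), rep(9L, 3), rep(9L, 3), rep(9L, 3))
  )

  # 20 boundary-normal edge profiles across the liver surface
  dirs <- fibonacci_directions(20)
  half_len <- 0.19 * min(E)
  prof <- purrr::map_dfr(seq_len(nrow(dirs)), function(i) {
    d <- dirs[i, ]
    t_surf <- 1 / sqrt(sum((d / liver_ax)^2))
    p <- liver_ctr + t_surf * d
    nrm <- (p - liver_ctr) / liver_ax^2
    nrm <- nrm / sqrt(sum(nrm^2))
    tibble::tibble(
      id = i,
      sx = p[1] - half_len * nrm[1], sy = p[2] - half_len * nrm[2],
      sz = p[3] - half_len * nrm[3],
      ex = p[1] + half_len * nrm[1], ey = p[2] + half_len * nrm[2],
      ez = p[3] + half_len * nrm[3]
    )
  })

  srr_volume(
    data, spacing = spacing, origin = origin,
    meta = list(
      kind = "biological",
      background = i_bg,
      intensity_range = c(0, 100),
      intensities = list(background = i_bg, body = i_body,
                         liver = i_liver, rod = i_rod),
      rois = rois,
      edge_profiles = prof,
      liver_center = liver_ctr,
      liver_semiaxes = liver_ax,
      seed = seed
    )
  )
}

# n roughly uniform directions on the sphere (spherical Fibonacci lattice)
fibonacci_directions <- function(n) {
  i <- seq_len(n)
  z <- (2 * i - 1) / n - 1
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}
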
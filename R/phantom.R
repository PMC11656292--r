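#' Progression parameters for a synthetic head-and-neck patient
#'
#' Parameterizes the interfractional anatomy change of one phantom patient:
#' linear per-day volume loss of the primary (high-risk), nodal and elective
#' target regions, total-course volume loss and medial drift of the salivary
#' glands, total thyroid loss, lateral neck contraction, and the amplitude of
#' random small nonrigid variations (sNRV).  Defaults are the cohort means of
#' the emulated population: CTV losses 1.5/2.3/0.3 % per treatment day,
#' parotid loss 28.6 % with 2.3 mm medial shift, submandibular loss 26.6 %,
#' thyroid loss 12.3 %.
#'
#' @param ctv_high_loss_per_day,ctv_node_loss_per_day,ctv_elective_loss_per_day
#'   fractional volume loss per treatment day (5 fractions/week, week w is day
#'   5w), each in [0, 1).
#' @param parotid_total_loss,submandibular_total_loss,thyroid_total_loss
#'   fractional volume loss reached at week 6, each in [0, 1).
#' @param parotid_medial_shift medial centroid drift of each parotid reached
#'   at week 6 (mm, >= 0).
#' @param neck_contraction inward displacement of the neck surface reached at
#'   week 6 (mm, >= 0).
#' @param snrv_sigma RMS amplitude of the weekly random smooth perturbation
#'   field (mm, >= 0).
#' @param seed integer seed; the same seed reproduces the patient bit-exactly.
#' @return An object of class \code{progression_params}.
#' @export
progression_params <- function(ctv_high_loss_per_day = 0.015,
                               ctv_node_loss_per_day = 0.023,
                               ctv_elective_loss_per_day = 0.003,
                               parotid_total_loss = 0.286,
                               parotid_medial_shift = 2.3,
                               submandibular_total_loss = 0.266,
                               thyroid_total_loss = 0.123,
                               neck_contraction = 3.0,
                               snrv_sigma = 1.0,
                               seed = 1L) {
  p <- list(ctv_high_loss_per_day = ctv_high_loss_per_day,
            ctv_node_loss_per_day = ctv_node_loss_per_day,
            ctv_elective_loss_per_day = ctv_elective_loss_per_day,
            parotid_total_loss = parotid_total_loss,
            parotid_medial_shift = parotid_medial_shift,
            submandibular_total_loss = submandibular_total_loss,
            thyroid_total_loss = thyroid_total_loss,
            neck_contraction = neck_contraction,
            snrv_sigma = snrv_sigma,
            seed = as.integer(seed))
  losses <- c("parotid_total_loss", "submandibular_total_loss", "thyroid_total_loss")
  for (nm in losses)
    if (p[[nm]] < 0 || p[[nm]] >= 1)
      stop("`", nm, "` must lie in [0, 1)")
  rates <- c("ctv_high_loss_per_day", "ctv_node_loss_per_day", "ctv_elective_loss_per_day")
  for (nm in rates)
    if (p[[nm]] < 0 || p[[nm]] >= 1)
      stop("`", nm, "` must lie in [0, 1)")
  if (p$parotid_medial_shift < 0 || p$neck_contraction < 0 || p$snrv_sigma < 0)
    stop("shifts and snrv_sigma must be >= 0")
  structure(p, class = "progression_params")
}

#' Default grid specification for phantom patients
#' @param dim grid dimensions (voxels).
#' @param spacing isotropic voxel spacing (mm).
#' @export
grid_spec <- function(dim = c(64L, 64L, 48L), spacing = 3) {
  stopifnot(length(dim) == 3L, all(dim >= 2), length(spacing) == 1L, spacing > 0)
  list(dim = as.integer(dim), spacing = rep(as.numeric(spacing), 3),
       origin = c(0, 0, 0))
}

# ---------------------------------------------------------------------------
# Analytic phantom geometry (world mm).  Idealized axial head-and-neck:
# elliptical body tapering to the neck, central high-risk CTV sphere slightly
# left of midline, an elective/nodal collar ring around the neck axis,
# bilateral parotids and submandibular glands, posterior pharyngeal
# constrictor slabs, anterior oral cavity, brainstem/cord posterior, thyroid
# inferior.  RSP tissue classes: air 0.001, water 1.0, bone 1.5 (vertebral
# column annulus).

.anat_cache <- new.env(parent = emptyenv())

# voxel-center matrix for a grid spec, cached per session
cached_centers <- function(gs) {
  key <- paste("pts", paste(c(gs$dim, gs$spacing, gs$origin), collapse = "_"))
  p <- .anat_cache[[key]]
  if (is.null(p)) {
    p <- grid_centers(voxel_grid(array(0, gs$dim), gs$spacing, gs$origin))
    .anat_cache[[key]] <- p
  }
  p
}

phantom_geometry <- function() {
  cx <- 96
  body_pars <- function(z) {
    t <- pmin(pmax((z - 60) / 24, 0), 1)
    list(cy = 98 - 6 * t, rx = 56 + 16 * t, ry = 52 + 10 * t)
  }
  ellipsoid <- function(c0, semi) {
    force(c0); force(semi)
    function(p) ((p[, 1] - c0[1]) / semi[1])^2 + ((p[, 2] - c0[2]) / semi[2])^2 +
      ((p[, 3] - c0[3]) / semi[3])^2 <= 1
  }
  body <- function(p) {
    bp <- body_pars(p[, 3])
    ((p[, 1] - cx) / bp$rx)^2 + ((p[, 2] - bp$cy) / bp$ry)^2 <= 1 &
      p[, 3] >= 3 & p[, 3] <= 141
  }
  ctv_high_c <- c(102, 86, 96); ctv_high_r <- 20
  ctv_high <- function(p)
    (p[, 1] - ctv_high_c[1])^2 + (p[, 2] - ctv_high_c[2])^2 + (p[, 3] - ctv_high_c[3])^2 <= ctv_high_r^2
  ring_c <- c(96, 92); ring_rmid <- 39; ring_halfw <- 7; ring_zc <- 72; ring_halfz <- 15
  # the elective collar spares an anterior (submental/laryngeal) wedge, which
  # also keeps the nodal contraction field away from the submandibular glands
  ring_wedge <- function(p, rho) (ring_c[2] - p[, 2]) - 0.45 * rho
  ctv_low <- function(p) {
    rho <- sqrt((p[, 1] - ring_c[1])^2 + (p[, 2] - ring_c[2])^2)
    bp <- body_pars(p[, 3])
    inside_margin <- ((p[, 1] - cx) / (bp$rx - 6))^2 + ((p[, 2] - bp$cy) / (bp$ry - 6))^2 <= 1
    d2ctv <- (p[, 1] - ctv_high_c[1])^2 + (p[, 2] - ctv_high_c[2])^2 + (p[, 3] - ctv_high_c[3])^2
    d2cord <- (p[, 1] - 96)^2 + (p[, 2] - 118)^2
    abs(rho - ring_rmid) <= ring_halfw & abs(p[, 3] - ring_zc) <= ring_halfz &
      inside_margin & d2ctv > (ctv_high_r + 6)^2 & ring_wedge(p, rho) < 0 &
      d2cord > 16^2
  }
  cyl <- function(cxy, r, z0, z1) {
    force(cxy); force(r); force(z0); force(z1)
    function(p) (p[, 1] - cxy[1])^2 + (p[, 2] - cxy[2])^2 <= r^2 & p[, 3] >= z0 & p[, 3] <= z1
  }
  slab <- function(xr, yr, zr) {
    force(xr); force(yr); force(zr)
    function(p) abs(p[, 1] - 96) <= xr & p[, 2] >= yr[1] & p[, 2] <= yr[2] &
      p[, 3] >= zr[1] & p[, 3] < zr[2]
  }
  shapes <- list(
    ctv_high = ctv_high,
    ctv_low = ctv_low,
    parotid_l = ellipsoid(c(142, 96, 105), c(10, 13, 16)),
    parotid_r = ellipsoid(c(50, 96, 105), c(10, 13, 16)),
    submandibular_l = ellipsoid(c(122, 70, 75), c(8, 8, 8)),
    submandibular_r = ellipsoid(c(70, 70, 75), c(8, 8, 8)),
    pcm_sup = slab(18, c(104, 112), c(90, 105)),
    pcm_med = slab(18, c(104, 112), c(75, 90)),
    pcm_inf = slab(18, c(104, 112), c(60, 75)),
    oral_cavity = ellipsoid(c(96, 56, 90), c(22, 16, 14)),
    brainstem = cyl(c(96, 112), 8, 108, 141),
    spinal_cord = cyl(c(96, 118), 5, 6, 108),
    thyroid = function(p)
      ellipsoid(c(110, 66, 48), c(7, 6, 10))(p) | ellipsoid(c(82, 66, 48), c(7, 6, 10))(p)
  )
  bone <- function(p) {
    r2 <- (p[, 1] - 96)^2 + (p[, 2] - 118)^2
    r2 >= 7^2 & r2 <= 13^2 & p[, 3] <= 108 & p[, 3] >= 3
  }
  # organ descriptors used to build deformation fields
  organs <- list(
    parotid_l = list(center = c(142, 96, 105), r0 = 13, kind = "parotid", side = 1),
    parotid_r = list(center = c(50, 96, 105), r0 = 13, kind = "parotid", side = -1),
    submandibular_l = list(center = c(122, 70, 75), r0 = 8, kind = "submandibular", side = 1),
    submandibular_r = list(center = c(70, 70, 75), r0 = 8, kind = "submandibular", side = -1),
    thyroid_l = list(center = c(110, 66, 48), r0 = 8, kind = "thyroid", side = 1),
    thyroid_r = list(center = c(82, 66, 48), r0 = 8, kind = "thyroid", side = -1),
    ctv_high = list(center = ctv_high_c, r0 = ctv_high_r, kind = "ctv_high", side = 0)
  )
  list(shapes = shapes, body = body, bone = bone, organs = organs, cx = cx,
       body_pars = body_pars,
       ring = list(c = ring_c, rmid = ring_rmid, halfw = ring_halfw,
                   zc = ring_zc, halfz = ring_halfz, wedge = ring_wedge),
       rsp = c(air = 0.001, water = 1.0, bone = 1.5),
       extent_needed = c(180, 170, 140))
}

# smooth support weight: 1 out to `plateau` x the organ radius (strictly
# beyond the organ surface and beyond the reach of grid interpolation, so the
# contraction is exact over the whole organ and voxel-counted volume ratios
# honour the requested loss fraction), Gaussian decay beyond.  The large
# target fields use a tighter profile so they do not reach into the glands.
support_g <- function(t, plateau = 1.3, width = 0.5)
  ifelse(t <= plateau, 1, exp(-((t - plateau) / width)^2))

# Forward displacement field (planning frame -> week-w frame) evaluated at
# world points `p` (n x 3).  Returns an n x 3 matrix (mm).  Organ volume loss
# f maps the organ isotropically by factor (1-f)^(1/3) about its (possibly
# shifted) centroid; the elective/nodal collar contracts its cross-section
# about the ring mid-circle; the neck field displaces the outline inward.
progression_field_at <- function(p, params, w, geom) {
  tau <- w / 6
  u <- matrix(0, nrow(p), 3)
  cx <- geom$cx
  for (org in geom$organs) {
    f <- switch(org$kind,
                parotid = params$parotid_total_loss * tau,
                submandibular = params$submandibular_total_loss * tau,
                thyroid = params$thyroid_total_loss * tau,
                ctv_high = min(params$ctv_high_loss_per_day * 5 * w, 0.9))
    shift <- switch(org$kind,
                    parotid = params$parotid_medial_shift * tau,
                    submandibular = 0.3 * tau,
                    0)
    if (f <= 0 && shift <= 0) next
    dx <- p[, 1] - org$center[1]; dy <- p[, 2] - org$center[2]; dz <- p[, 3] - org$center[3]
    t <- sqrt(dx^2 + dy^2 + dz^2) / org$r0
    g <- if (org$kind == "ctv_high") support_g(t, 1.1, 0.35) else support_g(t)
    a <- 1 - (1 - f)^(1 / 3)
    # medial drift: toward the midline, i.e. -x for left (+x) organs
    u[, 1] <- u[, 1] + g * (-a * dx - shift * org$side)
    u[, 2] <- u[, 2] - g * a * dy
    u[, 3] <- u[, 3] - g * a * dz
  }
  rg <- geom$ring
  f_node <- min(params$ctv_node_loss_per_day * 5 * w, 0.9)
  f_elec <- min(params$ctv_elective_loss_per_day * 5 * w, 0.9)
  if (f_node > 0 || f_elec > 0) {
    dx <- p[, 1] - rg$c[1]; dy <- p[, 2] - rg$c[2]
    rho <- sqrt(dx^2 + dy^2)
    drho <- rho - rg$rmid; dzz <- p[, 3] - rg$zc
    t <- sqrt((drho / rg$halfw)^2 + (dzz / rg$halfz)^2)
    g <- support_g(t, 1.05, 0.3) / (1 + exp(rg$wedge(p, rho) / 2.5))  # fades in the spared wedge
    wa <- 1 / (1 + exp((p[, 2] - rg$c[2]) / 6))   # ~1 anterior, ~0 posterior
    f <- f_node * wa + f_elec * (1 - wa)
    a <- 1 - sqrt(1 - f)
    safe <- pmax(rho, 1e-6)
    u[, 1] <- u[, 1] - g * a * drho * dx / safe
    u[, 2] <- u[, 2] - g * a * drho * dy / safe
    u[, 3] <- u[, 3] - g * a * dzz
  }
  if (params$neck_contraction > 0) {
    bp <- geom$body_pars(p[, 3])
    dx <- p[, 1] - cx; dy <- p[, 2] - bp$cy
    rrel <- sqrt((dx / bp$rx)^2 + (dy / bp$ry)^2)
    wz <- ifelse(p[, 3] <= 66, 1, pmax(0.25, 1 - 0.75 * (p[, 3] - 66) / 54))
    amp <- params$neck_contraction * tau * pmin(rrel, 1.2) * wz
    nrm <- pmax(sqrt(dx^2 + dy^2), 1e-6)
    u[, 1] <- u[, 1] - amp * dx / nrm
    u[, 2] <- u[, 2] - amp * dy / nrm
  }
  u
}

# Random smooth perturbation (sNRV) backward field for one week, as a
# displacement_field on the grid.  Noise is drawn on a coarse lattice and
# trilinearly upsampled, then scaled to the requested RMS magnitude.
snrv_field <- function(gs, sigma_mm, seed) {
  d <- gs$dim
  if (sigma_mm <= 0) return(array(0, c(d, 3)))
  coarse <- pmax(c(4L, 4L, 4L), d %/% 4L)
  u <- array(0, c(d, 3))
  with_seed(seed, {
    for (c in 1:3) {
      noise <- array(stats::rnorm(prod(coarse)), coarse)
      sm <- array(cpp_smooth3(as.numeric(noise), as.integer(coarse), c(2, 2, 2)),
                  coarse)
      # upsample coarse lattice to the full grid
      cgrid <- voxel_grid(sm, spacing = gs$spacing * (d / coarse),
                          origin = gs$origin)
      u[, , , c] <- array(sample_volume(cgrid, cached_centers(gs)), d)
    }
  })
  rms <- sqrt(mean(u[, , , 1]^2 + u[, , , 2]^2 + u[, , , 3]^2))
  if (rms > 0) u <- u * (sigma_mm / rms)
  u
}

# voxels whose 6-neighbourhood mixes inside/outside (both sides of the
# surface); these get supersampled in the refinement pass
mixed_boundary <- function(mask) {
  d <- dim(mask)
  agree <- array(TRUE, d)
  for (ax in 1:3) for (by in c(-1L, 1L)) {
    shifted <- mask
    idx_src <- lapply(d, seq_len); idx_dst <- idx_src
    n <- d[ax]
    if (by > 0) { idx_dst[[ax]] <- 2:n; idx_src[[ax]] <- 1:(n - 1) }
    else        { idx_dst[[ax]] <- 1:(n - 1); idx_src[[ax]] <- 2:n }
    shifted[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      mask[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    agree <- agree & (shifted == mask)
  }
  !agree
}

# Voxelize analytic shapes, optionally through a backward displacement field
# `back_u` (4D array; mask_w(y) = shape(y + v(y))).  Interior voxels are
# classified at their centers; voxels near a surface are refined with 2x2x2
# supersampling (fractions for `fraction_of` shapes, majority for masks).
phantom_snapshot <- function(geom, gs, back_u = NULL) {
  d <- gs$dim
  ref <- voxel_grid(array(0, d), gs$spacing, gs$origin)
  base <- cached_centers(gs)
  displace <- function(pts) {
    if (is.null(back_u)) return(pts)
    disp <- vapply(1:3, function(c)
      cpp_sample_points(as.numeric(back_u[, , , c]), as.integer(d),
                        gs$spacing, gs$origin, pts, 0, FALSE),
      numeric(nrow(pts)))
    pts + disp
  }
  pts1 <- displace(base)
  all_shapes <- c(geom$shapes, list(.body = geom$body, .bone = geom$bone))
  coarse <- lapply(all_shapes, function(f) array(f(pts1), d))
  offs <- as.matrix(expand.grid(x = c(-0.25, 0.25) * gs$spacing[1],
                                y = c(-0.25, 0.25) * gs$spacing[2],
                                z = c(-0.25, 0.25) * gs$spacing[3]))
  # refinement: supersample once over the union of all surface voxels, then
  # evaluate each shape only on its own surface subset
  bounds <- lapply(coarse, function(m)
    which(cpp_mixed_boundary(as.logical(m), as.integer(d))))
  union_idx <- sort(unique(unlist(bounds, use.names = FALSE)))
  fracs <- lapply(all_shapes, function(f) NULL)
  if (length(union_idx)) {
    rows <- lapply(bounds, function(b) match(b, union_idx))
    bc <- grid_centers(ref, union_idx)
    cnts <- lapply(names(all_shapes), function(nm) numeric(length(bounds[[nm]])))
    names(cnts) <- names(all_shapes)
    for (o in seq_len(nrow(offs))) {
      pp <- displace(sweep(bc, 2, offs[o, ], "+"))
      for (nm in names(all_shapes)) {
        if (!length(bounds[[nm]])) next
        cnts[[nm]] <- cnts[[nm]] + all_shapes[[nm]](pp[rows[[nm]], , drop = FALSE])
      }
    }
    fracs <- lapply(cnts, function(cn) cn / nrow(offs))
  }
  masks <- list()
  for (nm in names(geom$shapes)) {
    m <- coarse[[nm]]
    if (length(bounds[[nm]])) m[bounds[[nm]]] <- fracs[[nm]] >= 0.5
    masks[[nm]] <- m
  }
  fb <- coarse[[".body"]] + 0
  if (length(bounds[[".body"]])) fb[bounds[[".body"]]] <- fracs[[".body"]]
  fo <- coarse[[".bone"]] + 0
  if (length(bounds[[".bone"]])) fo[bounds[[".bone"]]] <- fracs[[".bone"]]
  r <- geom$rsp
  rsp <- r[["air"]] + (r[["water"]] - r[["air"]]) * fb +
    (r[["bone"]] - r[["water"]]) * fo
  list(grid = voxel_grid(rsp, gs$spacing, gs$origin), masks = masks)
}

#' Generate one synthetic longitudinal patient
#'
#' Builds the planning anatomy and six weekly anatomies (fractions
#' 5, 10, ..., 30) of an idealized head-and-neck phantom whose progressive
#' changes follow \code{params}: per-organ radially contracting deformations
#' scaled to the target volume loss, medial salivary-gland drift, a lateral
#' neck-contraction field, and a random smooth sNRV perturbation per week.
#' The generating (forward, planning-to-week) fields are analytic and exact
#' over each organ; weekly images and masks are voxelized through the
#' numerically inverted field.
#'
#' @param params a \code{\link{progression_params}}.
#' @param gs a \code{\link{grid_spec}} (default 64 x 64 x 48 at 3 mm).
#' @param fields_only if TRUE, skip weekly grids/masks and return only the
#'   displacement fields (used when a patient contributes only to model
#'   training).
#' @return An object of class \code{patient_timeline}: \code{planning}
#'   (grid + structures), \code{weekly} (list of 6 grid + structure sets),
#'   \code{true_dvfs} (forward planning-to-week fields), \code{back_dvfs}
#'   (the generating week-to-planning fields), \code{params}.
#' @export
make_patient <- function(params, gs = grid_spec(), fields_only = FALSE) {
  stopifnot(inherits(params, "progression_params"))
  geom <- phantom_geometry()
  extent <- gs$dim * gs$spacing
  if (any(extent < geom$extent_needed))
    stop("grid too small to contain all structures: extent ",
         paste(round(extent), collapse = "x"), " mm, need >= ",
         paste(geom$extent_needed, collapse = "x"), " mm")
  d <- gs$dim
  refgrid <- voxel_grid(array(0, d), gs$spacing, gs$origin)
  base_pts <- cached_centers(gs)

  # the planning anatomy depends only on the grid geometry; cache per session
  cache_key <- paste(c(gs$dim, gs$spacing, gs$origin), collapse = "_")
  planning_snap <- .anat_cache[[cache_key]]
  if (is.null(planning_snap)) {
    planning_snap <- phantom_snapshot(geom, gs)
    .anat_cache[[cache_key]] <- planning_snap
  }
  planning_grid <- planning_snap$grid
  planning <- list(grid = planning_grid,
                   structures = structure_set(planning_snap$masks, planning_grid))

  weekly <- vector("list", 6)
  true_dvfs <- vector("list", 6)
  back_dvfs <- vector("list", 6)
  static <- params$snrv_sigma == 0 && params$neck_contraction == 0 &&
    params$parotid_total_loss == 0 && params$submandibular_total_loss == 0 &&
    params$thyroid_total_loss == 0 && params$parotid_medial_shift == 0 &&
    params$ctv_high_loss_per_day == 0 && params$ctv_node_loss_per_day == 0 &&
    params$ctv_elective_loss_per_day == 0

  for (w in 1:6) {
    if (static) {
      back_dvfs[[w]] <- zero_dvf(refgrid)
      true_dvfs[[w]] <- zero_dvf(refgrid)
      if (!fields_only)
        weekly[[w]] <- list(grid = planning_grid,
                            structures = planning$structures)
      next
    }
    umat <- progression_field_at(base_pts, params, w, geom)
    uarr <- array(umat, c(d, 3))
    uarr <- uarr + snrv_field(gs, params$snrv_sigma, params$seed + 7919L * w)
    fwd <- displacement_field(uarr, gs$spacing, gs$origin)
    true_dvfs[[w]] <- fwd
    if (!fields_only) {
      back <- invert_dvf(fwd, iters = 15L)
      back_dvfs[[w]] <- back
      snap <- phantom_snapshot(geom, gs, back$u)
      weekly[[w]] <- list(grid = snap$grid,
                          structures = structure_set(snap$masks, snap$grid))
    }
  }
  structure(list(planning = planning,
                 weekly = if (fields_only) NULL else weekly,
                 true_dvfs = true_dvfs,
                 back_dvfs = back_dvfs,
                 params = params,
                 grid_spec = gs,
                 week_fractions = seq(5, 30, by = 5)),
            class = "patient_timeline")
}

#' @export
print.patient_timeline <- function(x, ...) {
  cat("<patient_timeline> seed", x$params$seed,
      if (is.null(x$weekly)) "(fields only)" else "(6 weekly anatomies)", "\n")
  invisible(x)
}

#' Default population specification
#'
#' Mean, standard deviation and truncation bounds for every progression
#' parameter, matching the emulated cohort statistics (parotid loss
#' 28.6 +/- 14.6 %, submandibular 26.6 +/- 17.1 %, thyroid 12.3 +/- 11.3 %,
#' parotid medial shift 2.0-2.6 mm, CTV losses 1.5/2.3/0.3 % per day).
#' @return named list of c(mean, sd, lower, upper).
#' @export
default_population <- function() {
  list(ctv_high_loss_per_day = c(0.015, 0.005, 0, 0.05),
       ctv_node_loss_per_day = c(0.023, 0.008, 0, 0.06),
       ctv_elective_loss_per_day = c(0.003, 0.002, 0, 0.02),
       parotid_total_loss = c(0.286, 0.146, 0, 0.95),
       parotid_medial_shift = c(2.3, 0.2, 0, 6),
       submandibular_total_loss = c(0.266, 0.171, 0, 0.95),
       thyroid_total_loss = c(0.123, 0.113, 0, 0.95),
       neck_contraction = c(3.0, 1.0, 0, 8),
       snrv_sigma = c(1.0, 0.4, 0, 3))
}

rtruncnorm1 <- function(mean, sd, lower, upper) {
  if (sd < 0) stop("sd < 0 in population spec")
  if (sd == 0) return(min(max(mean, lower), upper))
  for (i in 1:1000) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lower && x < upper) return(x)
  }
  min(max(mean, lower), upper)
}

child_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) %% 100003) * 10007 +
               index * 1000003) %% .Machine$integer.max
}

#' Draw progression parameters for a cohort
#'
#' Per-patient parameters are truncated-normal draws from
#' \code{population_spec}; child seeds derive deterministically from
#' \code{master_seed}.
#'
#' @param n cohort size.
#' @param master_seed integer master seed.
#' @param population_spec named list of c(mean, sd, lower, upper); see
#'   \code{\link{default_population}}.
#' @return list of \code{\link{progression_params}}.
#' @export
cohort_params <- function(n, master_seed, population_spec = default_population()) {
  stopifnot(n >= 1)
  for (nm in names(population_spec))
    if (population_spec[[nm]][2] < 0) stop("sd < 0 for ", nm)
  lapply(seq_len(n), function(i) {
    cs <- child_seed(master_seed, i)
    vals <- with_seed(cs, {
      sapply(names(population_spec), function(nm) {
        s <- population_spec[[nm]]
        rtruncnorm1(s[1], s[2], s[3], s[4])
      })
    })
    do.call(progression_params, c(as.list(vals), list(seed = cs)))
  })
}

#' Generate a synthetic cohort
#'
#' @inheritParams cohort_params
#' @param gs a \code{\link{grid_spec}}.
#' @param fields_only passed to \code{\link{make_patient}}.
#' @return list of \code{patient_timeline}.
#' @export
make_cohort <- function(n, master_seed, population_spec = default_population(),
                        gs = grid_spec(), fields_only = FALSE) {
  params <- cohort_params(n, master_seed, population_spec)
  lapply(params, make_patient, gs = gs, fields_only = fields_only)
}

# run expr under a temporary RNG seed, restoring global RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Read / write a population specification as YAML
#'
#' The YAML maps each progression parameter to \code{mean}, \code{sd},
#' \code{lower}, \code{upper}.
#'
#' @param path file path.
#' @return \code{read_population}: a population spec list usable by
#'   \code{\link{cohort_params}}.
#' @export
read_population <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(raw, function(x)
    c(x$mean, x$sd, if (is.null(x$lower)) 0 else x$lower,
      if (is.null(x$upper)) Inf else x$upper))
  missing <- setdiff(names(default_population()), names(out))
  if (length(missing))
    stop("population spec lacks fields: ", paste(missing, collapse = ", "))
  out
}

#' @rdname read_population
#' @param pop population spec (named list of c(mean, sd, lower, upper)).
#' @export
write_population <- function(pop, path) {
  yaml::write_yaml(lapply(pop, function(s)
    list(mean = s[[1]], sd = s[[2]], lower = s[[3]], upper = s[[4]])), path)
  invisible(path)
}
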
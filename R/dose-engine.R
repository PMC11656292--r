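#' Dose engine parameters
#'
#' Analytic pencil-beam model: normalized depth-dose given by a logistic
#' plateau shoulder plus a Gaussian Bragg peak, scaled so that the requested
#' R80 (distal 80-percent-of-maximum depth in water, mm) is honoured; lateral
#' profile a single Gaussian with sigma growing linearly in water-equivalent
#' depth.  No nuclear halo is modelled.
#'
#' @param sigma0 lateral sigma at zero depth (mm).
#' @param ksig lateral sigma growth per mm of water-equivalent depth.
#' @param plateau entrance plateau height relative to the unit Bragg-peak
#'   Gaussian.
#' @param plateau_width logistic fall-off width of the plateau at the peak (mm).
#' @param peak_sigma Gaussian width of the Bragg peak (mm); kept constant with
#'   range (straggling growth is not modelled).
#' @param nsig lateral Gaussian cut-off in sigmas.
#' @param wepl_lat_spacing,wepl_t_spacing lattice resolution of the cached
#'   beam-aligned WEPL volumes (mm).
#' @return list of engine parameters, including the numerically calibrated
#'   offset between R80 and the Gaussian peak position.
#' @export
dose_engine_params <- function(sigma0 = 5, ksig = 0.02, plateau = 0.3,
                               plateau_width = 2, peak_sigma = 4.5, nsig = 2.5,
                               wepl_lat_spacing = 3, wepl_t_spacing = 2) {
  p <- list(sigma0 = sigma0, ksig = ksig, plateau = plateau,
            plateau_width = plateau_width, peak_sigma = peak_sigma,
            nsig = nsig, wepl_lat_spacing = wepl_lat_spacing,
            wepl_t_spacing = wepl_t_spacing)
  # calibrate: with rp = 0, find the distal depth where dose drops to 80% of
  # its maximum; R80 = rp + offset for this curve family
  z <- seq(-8 * peak_sigma, 6 * peak_sigma, by = 0.01)
  dd <- cpp_depth_dose(z, 0, plateau, plateau_width, peak_sigma)
  dmax <- max(dd)
  imax <- which.max(dd)
  distal <- which(dd[imax:length(dd)] < 0.8 * dmax)[1] + imax - 1
  # linear interpolation between the bracketing samples
  z1 <- z[distal - 1]; z2 <- z[distal]
  d1 <- dd[distal - 1]; d2 <- dd[distal]
  p$r80_offset <- z1 + (0.8 * dmax - d1) / (d2 - d1) * (z2 - z1)
  p$peak_norm <- dmax
  p
}

#' Normalized depth-dose curve
#'
#' @param z water-equivalent depths (mm).
#' @param r80 distal 80-percent range in water (mm).
#' @param params \code{\link{dose_engine_params}}.
#' @return dose values (peak normalized to ~1).
#' @export
depth_dose <- function(z, r80, params = dose_engine_params()) {
  cpp_depth_dose(as.numeric(z), r80 - params$r80_offset, params$plateau,
                 params$plateau_width, params$peak_sigma)
}

#' Bragg curve closure for a given range
#' @inheritParams depth_dose
#' @return function of depth z (mm).
#' @export
bragg_curve <- function(r80, params = dose_engine_params()) {
  force(r80); force(params)
  function(z) depth_dose(z, r80, params)
}

#' Beam geometry for a set of gantry angles
#'
#' Gantry angles are in the axial plane: 0 = source anterior, 90 = source at
#' the patient's left (+x), beams travel through the isocenter.  The default
#' six-beam arrangement uses two anterior obliques (45, 315), two laterals
#' (90, 270) and two posterior obliques (160, 200).
#'
#' @param angles gantry angles in degrees.
#' @param iso isocenter world coordinates (mm).
#' @return data.frame-like list with direction and lateral unit vectors.
#' @export
beam_geometry <- function(angles = c(45, 315, 90, 270, 160, 200),
                          iso = c(99, 90, 87)) {
  th <- angles * pi / 180
  list(angles = angles,
       iso = iso,
       dir = cbind(-sin(th), cos(th), 0),
       e1 = cbind(cos(th), sin(th), 0),
       e2 = matrix(rep(c(0, 0, 1), each = length(th)), ncol = 3))
}

# Beam-aligned WEPL volumes for every beam of `beams` through `grid`.
# Returns list(wepls = list of arrays, meta = numeric lattice metadata).
build_wepl_set <- function(grid, beams, params = dose_engine_params(),
                           lat_half = 72, t_half = 130) {
  ls <- params$wepl_lat_spacing
  ts <- params$wepl_t_spacing
  n1 <- as.integer(2 * lat_half / ls) + 1L
  nt <- as.integer(2 * t_half / ts) + 1L
  lat0 <- -lat_half
  t0 <- -t_half
  wepls <- lapply(seq_along(beams$angles), function(b) {
    cpp_beam_wepl(as.numeric(grid$data), as.integer(dim(grid$data)),
                  grid$spacing, grid$origin,
                  beams$dir[b, ], beams$e1[b, ], beams$e2[b, ], beams$iso,
                  lat0, ls, n1, n1, t0, ts, nt)
  })
  list(wepls = wepls,
       meta = c(lat0, ls, n1, n1, t0, ts, nt),
       beams = beams)
}

#' Water-equivalent path length profile along a beam ray
#'
#' Marches along the ray parallel to the beam axis at the given lateral
#' offset, accumulating RSP x step.  Depth is geometric distance from the
#' first sampled position (upstream of the grid).
#'
#' @param grid a \code{voxel_grid} of relative stopping power.
#' @param beam_angle gantry angle (degrees).
#' @param lateral length-2 lateral offset (mm) in the beam frame.
#' @param iso isocenter (mm).
#' @param step marching step (mm).
#' @return data.frame with columns \code{depth} and \code{wepl} (mm).
#' @export
wepl_profile <- function(grid, beam_angle, lateral = c(0, 0),
                         iso = c(99, 90, 87), step = 0.5) {
  bg <- beam_geometry(beam_angle, iso)
  extent <- sqrt(sum((dim(grid$data) * grid$spacing)^2))
  tseq <- seq(-extent, extent, by = step)
  base <- iso + lateral[1] * bg$e1[1, ] + lateral[2] * bg$e2[1, ]
  pts <- cbind(base[1] + tseq * bg$dir[1, 1],
               base[2] + tseq * bg$dir[1, 2],
               base[3] + tseq * bg$dir[1, 3])
  rsp <- sample_volume(grid, pts, fill = 0)
  inside <- (pts[, 1] >= grid$origin[1] & pts[, 1] <= grid$origin[1] + dim(grid$data)[1] * grid$spacing[1] &
             pts[, 2] >= grid$origin[2] & pts[, 2] <= grid$origin[2] + dim(grid$data)[2] * grid$spacing[2] &
             pts[, 3] >= grid$origin[3] & pts[, 3] <= grid$origin[3] + dim(grid$data)[3] * grid$spacing[3])
  if (!any(inside)) return(data.frame(depth = numeric(0), wepl = numeric(0)))
  first <- which(inside)[1]
  keep <- first:max(which(inside))
  # midpoint rule: wepl at sample m is the cumulative sum up to that sample
  rs <- rsp[keep]
  w <- cumsum(c(0, (rs[-1] + rs[-length(rs)]) / 2 * step))
  data.frame(depth = (seq_along(keep) - 1) * step, wepl = w)
}

#' Create a spot plan covering the targets
#'
#' Spots are laid out per beam on a regular lateral lattice covering the
#' projection of the target voxels of every provided anatomy (plus margin),
#' with energy layers spanning the water-equivalent depth extent of the
#' target within each lateral cell.
#'
#' @param anatomies list of anatomies (each: \code{grid}, \code{structures});
#'   the first is the planning anatomy.
#' @param beams \code{\link{beam_geometry}}.
#' @param params \code{\link{dose_engine_params}}.
#' @param targets structure names treated as target.
#' @param lat_spacing lateral spot spacing (mm).
#' @param layer_spacing energy-layer spacing in water-equivalent depth (mm);
#'   coverage is padded by one lateral cell and one energy layer on each side.
#' @return An object of class \code{spot_plan}: \code{beams}, \code{spots}
#'   (data.frame beam/u/v/r80), \code{weights}.
#' @export
make_spot_plan <- function(anatomies, beams = beam_geometry(),
                           params = dose_engine_params(),
                           targets = c("ctv_high", "ctv_low"),
                           lat_spacing = 10, layer_spacing = 10) {
  spots <- list()
  all_beams_ws <- lapply(anatomies, function(anat)
    build_wepl_set(anat$grid, beams, params))
  for (b in seq_along(beams$angles)) {
    # energy layers are quantized water-equivalent depths of the target
    # voxels; a cell only gets the layers its own target depths occupy, so a
    # beam traversing both arms of the elective collar places no spots in the
    # gap between them
    cell_layers <- list()
    for (ai in seq_along(anatomies)) {
      anat <- anatomies[[ai]]
      ws <- all_beams_ws[[ai]]
      tmask <- Reduce(`|`, anat$structures$masks[targets])
      pts <- grid_centers(anat$grid, tmask)
      rel <- sweep(pts, 2, beams$iso)
      l1 <- rel %*% beams$e1[b, ]
      l2 <- rel %*% beams$e2[b, ]
      tt <- rel %*% beams$dir[b, ]
      meta <- ws$meta
      n1 <- meta[3]; nt <- meta[7]
      wvol <- voxel_grid(array(ws$wepls[[b]], c(n1, n1, nt)),
                         spacing = c(meta[2], meta[2], meta[6]),
                         origin = c(meta[1] - meta[2] / 2, meta[1] - meta[2] / 2,
                                    meta[5] - meta[6] / 2))
      w <- sample_volume(wvol, cbind(l1, l2, tt))
      ci <- round(l1 / lat_spacing)
      cj <- round(l2 / lat_spacing)
      # one-layer padding on each side keeps the distal/proximal edges
      # covered under the +/-3% range scenarios
      li <- round(w / layer_spacing)
      for (dl in -1:1) {
        kk <- paste(ci, cj, li + dl)
        cell_layers[kk] <- TRUE
      }
    }
    kk <- do.call(rbind, strsplit(names(cell_layers), " "))
    ci <- as.integer(kk[, 1]); cj <- as.integer(kk[, 2]); li <- as.integer(kk[, 3])
    # dilate laterally by one cell (8-neighbourhood, so diagonal setup
    # shifts stay covered) for setup-margin coverage
    tab <- unique(rbind(cbind(ci, cj, li),
                        cbind(ci + 1, cj, li), cbind(ci - 1, cj, li),
                        cbind(ci, cj + 1, li), cbind(ci, cj - 1, li),
                        cbind(ci + 1, cj + 1, li), cbind(ci - 1, cj + 1, li),
                        cbind(ci + 1, cj - 1, li), cbind(ci - 1, cj - 1, li)))
    r80s <- pmax(tab[, 3] * layer_spacing, 10)
    spots[[b]] <- data.frame(beam = b, u = tab[, 1] * lat_spacing,
                             v = tab[, 2] * lat_spacing, r80 = r80s)
  }
  spots <- unique(do.call(rbind, spots))
  rownames(spots) <- NULL
  structure(list(beams = beams, spots = spots,
                 weights = rep(1, nrow(spots)), params = params),
            class = "spot_plan")
}

#' @export
print.spot_plan <- function(x, ...) {
  cat("<spot_plan>", length(x$beams$angles), "beams (gantry",
      paste(x$beams$angles, collapse = ", "), "deg),",
      nrow(x$spots), "spots\n")
  invisible(x)
}

# Dose at arbitrary world points for a plan under one scenario, using cached
# beam-aligned WEPL volumes of the scenario's anatomy.
dose_at_points <- function(wepl_set, plan, pts, scenario, weights = plan$weights) {
  p <- plan$params
  bg <- wepl_set$beams
  res <- cpp_dose_points(as.matrix(pts), scenario$shift,
                         bg$dir, bg$e1, bg$e2, bg$iso,
                         wepl_set$wepls, wepl_set$meta,
                         as.integer(plan$spots$beam - 1L),
                         plan$spots$u, plan$spots$v, plan$spots$r80,
                         as.numeric(weights),
                         scenario$range_scale, p$sigma0, p$ksig, p$plateau,
                         p$plateau_width, p$peak_sigma, p$r80_offset, p$nsig,
                         0L, 0)
  res$dose
}

# Influence matrix (points x spots, sparse) for a plan under one scenario.
# raw influence triplets (0-based from C++, converted to 1-based here)
influence_triplets <- function(wepl_set, plan, pts, scenario, thresh = 0.02) {
  p <- plan$params
  bg <- wepl_set$beams
  res <- cpp_dose_points(as.matrix(pts), scenario$shift,
                         bg$dir, bg$e1, bg$e2, bg$iso,
                         wepl_set$wepls, wepl_set$meta,
                         as.integer(plan$spots$beam - 1L),
                         plan$spots$u, plan$spots$v, plan$spots$r80,
                         numeric(nrow(plan$spots)),
                         scenario$range_scale, p$sigma0, p$ksig, p$plateau,
                         p$plateau_width, p$peak_sigma, p$r80_offset, p$nsig,
                         1L, thresh)
  list(i = res$i + 1L, j = res$j + 1L, x = res$x,
       nrow = nrow(pts), ncol = nrow(plan$spots))
}

influence_at_points <- function(wepl_set, plan, pts, scenario, thresh = 0.02) {
  p <- plan$params
  bg <- wepl_set$beams
  res <- cpp_dose_points(as.matrix(pts), scenario$shift,
                         bg$dir, bg$e1, bg$e2, bg$iso,
                         wepl_set$wepls, wepl_set$meta,
                         as.integer(plan$spots$beam - 1L),
                         plan$spots$u, plan$spots$v, plan$spots$r80,
                         numeric(nrow(plan$spots)),
                         scenario$range_scale, p$sigma0, p$ksig, p$plateau,
                         p$plateau_width, p$peak_sigma, p$r80_offset, p$nsig,
                         1L, thresh)
  Matrix::sparseMatrix(i = res$i + 1L, j = res$j + 1L, x = res$x,
                       dims = c(nrow(pts), nrow(plan$spots)))
}

#' Dose of a single spot on a grid
#'
#' @param grid a \code{voxel_grid} (RSP).
#' @param spot one-row data.frame with beam, u, v, r80 (beam indexes into
#'   \code{beams}).
#' @param scenario a \code{\link{scenario}}.
#' @param beams \code{\link{beam_geometry}}.
#' @param params \code{\link{dose_engine_params}}.
#' @param weight spot weight.
#' @return a \code{voxel_grid} of dose.
#' @export
spot_dose <- function(grid, spot, scenario = NULL, beams = beam_geometry(),
                      params = dose_engine_params(), weight = 1) {
  plan <- structure(list(beams = beams, spots = spot, weights = weight,
                         params = params), class = "spot_plan")
  plan_dose(grid, plan, scenario)
}

#' Total plan dose on a grid
#'
#' Linear in the spot weights; scenario setup shift and range scaling applied
#' as rigid frame translation and WEPL division, respectively.
#'
#' @param grid a \code{voxel_grid} (RSP).
#' @param plan a \code{spot_plan}.
#' @param scenario a \code{\link{scenario}}.
#' @return a \code{voxel_grid} of dose.
#' @export
plan_dose <- function(grid, plan, scenario = NULL) {
  if (is.null(scenario)) scenario <- anatrobust::scenario()
  if (anyNA(grid$data)) stop("NaN in RSP grid")
  if (scenario$range_scale <= 0) stop("range_scale must be > 0")
  if (any(plan$weights < 0)) stop("spot weights must be >= 0")
  if (nrow(plan$spots) == 0 || all(plan$weights == 0))
    return(voxel_grid(array(0, dim(grid$data)), grid$spacing, grid$origin))
  ws <- build_wepl_set(grid, plan$beams, plan$params)
  pts <- grid_centers(grid)
  d <- dose_at_points(ws, plan, pts, scenario)
  voxel_grid(array(d, dim(grid$data)), grid$spacing, grid$origin)
}
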
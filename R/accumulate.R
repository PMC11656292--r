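#' Treatment course specification
#'
#' @param fractions_total total fractions (default 35).
#' @param week_fraction_weights fractions delivered on each weekly anatomy;
#'   weeks 1-6 cover fraction blocks 1-5, ..., 26-30 and fractions 31-35
#'   reuse the week-6 anatomy (default c(5,5,5,5,5,10)).
#' @param residual_setup_mm residual setup uncertainty per weekly anatomy
#'   (mm); 0 disables the error scenarios.
#' @param range_frac fractional range uncertainty.
#' @export
course_spec <- function(fractions_total = 35,
                        week_fraction_weights = c(5, 5, 5, 5, 5, 10),
                        residual_setup_mm = 1, range_frac = 0.03) {
  stopifnot(length(week_fraction_weights) == 6,
            sum(week_fraction_weights) == fractions_total)
  list(fractions_total = fractions_total,
       week_fraction_weights = week_fraction_weights,
       residual_setup_mm = residual_setup_mm, range_frac = range_frac)
}

#' Rigid (translation-only) alignment of a weekly image to the planning image
#'
#' Finds the translation minimizing the mean squared intensity difference
#' between \code{vct} resampled at \code{x - shift} and \code{planning},
#' emulating the image-guided setup correction.  Returns the shift to apply
#' to the vCT frame; for a vCT equal to the planning image translated by
#' \code{+t}, the recovered shift is \code{-t}.
#'
#' @param vct,planning \code{voxel_grid}s with overlapping fields of view.
#' @param subsample evaluate the similarity on every n-th voxel.
#' @return length-3 translation (mm).
#' @export
align_vct <- function(vct, planning, subsample = 3L) {
  stopifnot(identical(dim(vct$data), dim(planning$data)))
  idx <- seq(1, prod(dim(planning$data)), by = subsample)
  pts <- grid_centers(planning, idx)
  ref <- planning$data[idx]
  keep <- ref > 0.1  # body voxels drive the alignment
  if (!any(keep)) {
    warning("no overlap for rigid alignment; returning identity")
    return(c(0, 0, 0))
  }
  pts <- pts[keep, , drop = FALSE]
  ref <- ref[keep]
  ssd <- function(s) {
    v <- sample_volume(vct, sweep(pts, 2, s, "-"), fill = 0.001)
    mean((v - ref)^2)
  }
  res <- stats::optim(c(0, 0, 0), ssd, method = "Nelder-Mead",
                      control = list(maxit = 200, reltol = 1e-8))
  as.numeric(res$par)
}

#' Warp a dose grid into the planning frame
#'
#' \code{out(x) = dose(x + u(x))} with trilinear interpolation, where
#' \code{dvf} maps the planning frame to the week frame; positions outside
#' the week grid contribute 0.
#'
#' @param dose a \code{voxel_grid} (dose in the week frame).
#' @param dvf a \code{displacement_field} (planning to week).
#' @return a \code{voxel_grid} in the planning frame.
#' @export
warp_to_planning <- function(dose, dvf) {
  if (any(!is.finite(dvf$u))) stop("non-finite displacement field")
  arr <- warp_volume(dose$data, dvf, nearest = FALSE, fill = 0)
  voxel_grid(arr, dose$spacing, dose$origin)
}

#' Weekly worst-case dose on a verification anatomy
#'
#' Computes the nominal dose and the voxel-wise minimum/maximum over the 28
#' residual scenarios (14 setup shift directions at the residual magnitude
#' crossed with the two range errors) on one weekly anatomy.
#'
#' @param plan a \code{spot_plan} with optimized weights.
#' @param vct_grid the weekly anatomy \code{voxel_grid} (RSP).
#' @param course a \code{\link{course_spec}}.
#' @param base_shift additional rigid shift from the setup alignment (mm).
#' @return list with \code{nominal}, \code{voxmin}, \code{voxmax}
#'   \code{voxel_grid}s.
#' @export
weekly_worst_case <- function(plan, vct_grid, course = course_spec(),
                              base_shift = c(0, 0, 0)) {
  ws <- build_wepl_set(vct_grid, plan$beams, plan$params)
  pts <- grid_centers(vct_grid)
  scenarios <- if (course$residual_setup_mm > 0)
    enumerate_eval_scenarios("vct", course$residual_setup_mm,
                             course$range_frac)$scenarios
  else list()
  st <- list(pts = pts, groups = list(all = seq_len(nrow(pts))))
  ch <- eval_scenarios_at_points(ws, plan, st, scenarios,
                                 base_shift = base_shift)
  d <- dim(vct_grid$data)
  list(nominal = voxel_grid(array(ch$nominal, d), vct_grid$spacing, vct_grid$origin),
       voxmin = voxel_grid(array(ch$voxmin, d), vct_grid$spacing, vct_grid$origin),
       voxmax = voxel_grid(array(ch$voxmax, d), vct_grid$spacing, vct_grid$origin))
}

# displacement of the forward planning->week field at given planning points
dvf_at_points <- function(dvf, pts) {
  d <- dim(dvf$u)[1:3]
  disp <- vapply(1:3, function(c)
    cpp_sample_points(as.numeric(dvf$u[, , , c]), as.integer(d), dvf$spacing,
                      dvf$origin, pts, 0, FALSE), numeric(nrow(pts)))
  disp
}

#' Accumulate a simulated treatment course
#'
#' Simulates delivery on the six weekly anatomies: rigid alignment of each
#' weekly image to the planning image, the 28 residual setup/range scenarios
#' per week, voxel-wise worst-case reduction, warping to the planning frame
#' through the ground-truth deformation fields, and fraction-weighted
#' accumulation.  The voxmin channel is accumulated with voxmin (and voxmax
#' with voxmax) per week.
#'
#' @param plan a \code{spot_plan} with optimized weights.
#' @param patient a full \code{patient_timeline}.
#' @param course a \code{\link{course_spec}}.
#' @param voxels planning-frame voxel indices at which to accumulate; NULL
#'   for the full grid (slower).
#' @param align run the rigid setup alignment per week (default TRUE).
#' @param wc_rows optional integer subset of \code{voxels} rows at which the
#'   28 residual scenarios are evaluated (typically CTV + serial-organ
#'   voxels, whose metrics use the voxmin/voxmax channels); other rows carry
#'   the nominal dose in all three channels.
#' @return list: \code{nominal}, \code{voxmin}, \code{voxmax} (vectors at
#'   \code{voxels}, or \code{voxel_grid}s when \code{voxels} is NULL),
#'   \code{weekly} per-week contributions, \code{align_shifts}.
#' @export
accumulate_course <- function(plan, patient, course = course_spec(),
                              voxels = NULL, align = TRUE, wc_rows = NULL) {
  if (is.null(patient$weekly)) stop("patient timeline lacks weekly anatomies")
  planning <- patient$planning
  full <- is.null(voxels)
  idx <- if (full) seq_len(prod(dim(planning$grid$data))) else voxels
  pts <- grid_centers(planning$grid, idx)
  wts <- course$week_fraction_weights / course$fractions_total
  acc <- list(nominal = 0, voxmin = 0, voxmax = 0)
  weekly <- list()
  shifts <- matrix(0, 6, 3)
  scenarios0 <- if (course$residual_setup_mm > 0)
    enumerate_eval_scenarios("vct", course$residual_setup_mm,
                             course$range_frac)$scenarios
  else list()
  for (w in 1:6) {
    vct <- patient$weekly[[w]]
    s <- if (align) align_vct(vct$grid, planning$grid) else c(0, 0, 0)
    shifts[w, ] <- s
    ws <- build_wepl_set(vct$grid, plan$beams, plan$params)
    # planning points mapped into the week frame by the true deformation
    disp <- dvf_at_points(patient$true_dvfs[[w]], pts)
    pts_w <- pts + disp
    if (is.null(wc_rows)) {
      st <- list(pts = pts_w, groups = list(all = seq_len(nrow(pts_w))))
      ch <- eval_scenarios_at_points(ws, plan, st, scenarios0, base_shift = -s)
    } else {
      nom <- dose_at_points(ws, plan, pts_w, scenario(shift = -s), plan$weights)
      stw <- list(pts = pts_w[wc_rows, , drop = FALSE],
                  groups = list(all = seq_along(wc_rows)))
      chw <- eval_scenarios_at_points(ws, plan, stw, scenarios0, base_shift = -s)
      vmin <- nom; vmax <- nom
      vmin[wc_rows] <- pmin(chw$voxmin, nom[wc_rows])
      vmax[wc_rows] <- pmax(chw$voxmax, nom[wc_rows])
      ch <- list(nominal = nom, voxmin = vmin, voxmax = vmax)
    }
    weekly[[w]] <- ch
    for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + wts[w] * ch[[nm]]
  }
  if (full) {
    d <- dim(planning$grid$data)
    for (nm in names(acc))
      acc[[nm]] <- voxel_grid(array(acc[[nm]], d), planning$grid$spacing,
                              planning$grid$origin)
  }
  c(acc, list(weekly = weekly, align_shifts = shifts, voxels = idx))
}
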
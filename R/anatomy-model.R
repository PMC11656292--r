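#' Build the population average weekly deformation model
#'
#' The model is the voxelwise arithmetic mean, over the training patients, of
#' the forward (planning-to-week) displacement fields for each of the six
#' weekly time points.  Synthetic patients share the template frame by
#' construction, so inter-patient correspondence is the identity.
#'
#' @param training list of \code{patient_timeline} (>= 1), all on a common grid.
#' @return An object of class \code{average_model} with \code{mean_dvfs}
#'   (list of 6 \code{displacement_field}), \code{n_train}, \code{week_points}.
#' @export
build_average_model <- function(training) {
  stopifnot(length(training) >= 1)
  d0 <- dim(training[[1]]$true_dvfs[[1]]$u)
  for (p in training)
    if (!identical(dim(p$true_dvfs[[1]]$u), d0))
      stop("mismatched grid shapes across training patients")
  mean_dvfs <- lapply(1:6, function(w) {
    acc <- training[[1]]$true_dvfs[[w]]$u
    if (length(training) > 1)
      for (i in 2:length(training)) acc <- acc + training[[i]]$true_dvfs[[w]]$u
    displacement_field(acc / length(training),
                       training[[1]]$true_dvfs[[w]]$spacing,
                       training[[1]]$true_dvfs[[w]]$origin)
  })
  structure(list(mean_dvfs = mean_dvfs, n_train = length(training),
                 week_points = seq(5, 30, by = 5)),
            class = "average_model")
}

#' @export
print.average_model <- function(x, ...) {
  cat("<average_model> trained on", x$n_train, "patients; weeks at fractions",
      paste(x$week_points, collapse = ", "), "\n")
  invisible(x)
}

#' Predict a patient's anatomy at a given week
#'
#' Warps the planning image and contours by the model's mean deformation for
#' that week.  Organ-at-risk and low-risk CTV masks are propagated
#' (nearest-neighbour sampling after field application); the high-risk CTV
#' mask is copied from the planning CT unchanged, mirroring the contour rule
#' used for robust optimization on predicted images.
#'
#' @param model an \code{average_model}.
#' @param planning list with \code{grid} (voxel_grid) and \code{structures}
#'   (structure_set).
#' @param week integer in 1..6.
#' @return list with \code{week}, \code{grid}, \code{structures},
#'   \code{source_rule} (named character: "propagated" or "planning-copy").
#' @export
predict_anatomy <- function(model, planning, week) {
  if (!(week %in% 1:6)) stop("week out of range 1..6")
  fwd <- model$mean_dvfs[[week]]
  back <- invert_dvf(fwd)
  grid_arr <- warp_volume(planning$grid$data, back, nearest = FALSE,
                          fill = 0.001)
  grid <- voxel_grid(grid_arr, planning$grid$spacing, planning$grid$origin)
  masks <- list()
  rule <- character(0)
  for (nm in names(planning$structures$masks)) {
    if (nm == "ctv_high") {
      masks[[nm]] <- planning$structures$masks[[nm]]
      rule[nm] <- "planning-copy"
    } else {
      masks[[nm]] <- warp_volume(planning$structures$masks[[nm]], back,
                                 nearest = TRUE, fill = 0)
      rule[nm] <- "propagated"
    }
  }
  list(week = week, grid = grid, structures = structure_set(masks, grid),
       source_rule = rule)
}

#' Mean surface distance between two masks
#'
#' Symmetric mean surface distance over the voxelized mask surfaces (boundary
#' voxels by 6-connectivity erosion), in mm.
#'
#' @param mask_a,mask_b logical 3D arrays on the same grid.
#' @param spacing voxel spacing (mm).
#' @param origin grid origin (mm).
#' @return scalar distance in mm.
#' @export
msd <- function(mask_a, mask_b, spacing = c(3, 3, 3), origin = c(0, 0, 0)) {
  if (!any(mask_a) || !any(mask_b)) stop("empty structure mask")
  ref <- voxel_grid(array(0, dim(mask_a)), spacing, origin)
  pa <- grid_centers(ref, mask_boundary(mask_a))
  pb <- grid_centers(ref, mask_boundary(mask_b))
  cpp_msd(pa, pb)
}

#' Leave-one-out validation of the average model
#'
#' For each held-out patient, a model is trained on the remaining patients and
#' its predicted weekly contours are compared with the true weekly contours by
#' mean surface distance.  The "no model" baseline compares the unmodified
#' planning contour with the true weekly contour.
#'
#' @param cohort list of full \code{patient_timeline} (>= 2).
#' @param structures structure names to evaluate (default parotids).
#' @param weeks weeks to evaluate (default 5, the time point usually reported).
#' @return data.frame with columns patient, week, structure, msd_model,
#'   msd_nomodel.
#' @export
loo_validate <- function(cohort, structures = c("parotid_l", "parotid_r"),
                         weeks = 5L) {
  stopifnot(length(cohort) >= 2)
  rows <- list()
  for (i in seq_along(cohort)) {
    held <- cohort[[i]]
    if (is.null(held$weekly)) stop("held-out patient lacks weekly anatomies")
    model <- build_average_model(cohort[-i])
    for (w in weeks) {
      pred <- predict_anatomy(model, held$planning, w)
      for (nm in structures) {
        true_mask <- held$weekly[[w]]$structures$masks[[nm]]
        if (!any(true_mask)) stop("empty structure mask: ", nm)
        sp <- held$planning$grid$spacing
        or <- held$planning$grid$origin
        rows[[length(rows) + 1]] <- data.frame(
          patient = i, week = w, structure = nm,
          msd_model = msd(pred$structures$masks[[nm]], true_mask, sp, or),
          msd_nomodel = msd(held$planning$structures$masks[[nm]], true_mask, sp, or))
      }
    }
  }
  do.call(rbind, rows)
}
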
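#' Voxel grid
#'
#' A scalar 3D field (here: relative stopping power, water = 1) on a regular
#' grid.  The grid origin is the corner of the volume; voxel \code{(i,j,k)}
#' (1-based) has world center \code{origin + (c(i,j,k) - 0.5) * spacing} mm.
#'
#' @param data numeric 3D array.
#' @param spacing numeric length-3, voxel spacing in mm.
#' @param origin numeric length-3, world position of the grid corner in mm.
#' @return An object of class \code{voxel_grid}.
#' @export
voxel_grid <- function(data, spacing = c(3, 3, 3), origin = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 3L,
            length(spacing) == 3L, all(spacing > 0), length(origin) == 3L)
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("<voxel_grid> ", paste(dim(x$data), collapse = " x "),
      " @ ", paste(x$spacing, collapse = "/"), " mm, origin (",
      paste(x$origin, collapse = ", "), ") mm\n", sep = "")
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$data)

same_frame <- function(a, b, tol = 1e-9) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

#' Voxel volume in cubic centimetres
#' @param grid a \code{voxel_grid} (or anything with a \code{$spacing}).
#' @return scalar, cc per voxel.
#' @export
voxel_cc <- function(grid) prod(grid$spacing) / 1000

#' World coordinates of voxel centers
#'
#' @param grid a \code{voxel_grid}.
#' @param which optional logical array or vector of voxel indices; default all.
#' @return n x 3 matrix of world coordinates (mm).
#' @export
grid_centers <- function(grid, which = NULL) {
  d <- dim(grid$data)
  if (is.null(which)) {
    idx <- seq_len(prod(d))
  } else if (is.logical(which)) {
    idx <- which(which)
  } else {
    idx <- as.integer(which)
  }
  ijk <- arrayInd(idx, d)
  cbind(grid$origin[1] + (ijk[, 1] - 0.5) * grid$spacing[1],
        grid$origin[2] + (ijk[, 2] - 0.5) * grid$spacing[2],
        grid$origin[3] + (ijk[, 3] - 0.5) * grid$spacing[3])
}

#' Structure set
#'
#' Named binary masks sharing the frame of a reference \code{voxel_grid}.
#'
#' @param masks named list of logical 3D arrays.
#' @param grid the reference \code{voxel_grid}.
#' @return An object of class \code{structure_set}.
#' @export
structure_set <- function(masks, grid) {
  stopifnot(is.list(masks), length(names(masks)) == length(masks))
  for (nm in names(masks)) {
    m <- masks[[nm]]
    stopifnot(is.logical(m), identical(dim(m), dim(grid$data)))
  }
  structure(list(masks = masks, spacing = grid$spacing, origin = grid$origin),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  v <- vapply(x$masks, sum, numeric(1))
  cat("<structure_set> ", length(x$masks), " structures\n", sep = "")
  for (nm in names(x$masks))
    cat(sprintf("  %-16s %6d voxels (%.1f cc)\n", nm, v[[nm]],
                v[[nm]] * prod(x$spacing) / 1000))
  invisible(x)
}

#' Displacement field
#'
#' Per-voxel 3-vector displacements (mm) on a regular grid.  Applied as the
#' map \code{x -> x + u(x)}.
#'
#' @param u numeric 4D array with dim \code{c(nx, ny, nz, 3)}.
#' @param spacing,origin grid geometry in mm.
#' @return An object of class \code{displacement_field}.
#' @export
displacement_field <- function(u, spacing = c(3, 3, 3), origin = c(0, 0, 0)) {
  stopifnot(is.array(u), length(dim(u)) == 4L, dim(u)[4] == 3L)
  structure(list(u = u, spacing = as.numeric(spacing), origin = as.numeric(origin)),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  mags <- sqrt(x$u[, , , 1]^2 + x$u[, , , 2]^2 + x$u[, , , 3]^2)
  cat("<displacement_field> ", paste(dim(x$u)[1:3], collapse = " x "),
      sprintf(", |u| max %.2f mm, mean %.2f mm\n", max(mags), mean(mags)), sep = "")
  invisible(x)
}

zero_dvf <- function(grid) {
  displacement_field(array(0, c(dim(grid$data), 3)), grid$spacing, grid$origin)
}

#' Invert a displacement field
#'
#' Fixed-point inversion of \code{x -> x + u(x)}; the returned field
#' \code{v} satisfies \code{(x + v(x)) + u(x + v(x)) = x} up to the iteration
#' residual.
#'
#' @param dvf a \code{displacement_field}.
#' @param iters fixed-point iterations (default 15).
#' @return a \code{displacement_field}.
#' @export
invert_dvf <- function(dvf, iters = 15L) {
  d <- dim(dvf$u)[1:3]
  out <- cpp_invert_dvf(as.numeric(dvf$u), as.integer(d), dvf$spacing,
                        dvf$origin, as.integer(iters))
  displacement_field(array(out, c(d, 3)), dvf$spacing, dvf$origin)
}

#' Warp a scalar volume by a displacement field
#'
#' \code{out(x) = vol(x + u(x))} with trilinear (scalars) or nearest-neighbour
#' (masks) sampling; positions falling outside the grid read \code{fill}.
#'
#' @param vol 3D array (numeric or logical).
#' @param dvf a \code{displacement_field} on the same grid.
#' @param nearest use nearest-neighbour sampling (default for logical input).
#' @param fill out-of-grid value.
#' @return array of the input's type.
#' @export
warp_volume <- function(vol, dvf, nearest = is.logical(vol), fill = 0) {
  d <- dim(vol)
  stopifnot(identical(d, dim(dvf$u)[1:3]))
  lg <- is.logical(vol)
  out <- cpp_warp_by_dvf(as.numeric(vol), as.integer(d), dvf$spacing,
                         dvf$origin, as.numeric(dvf$u), fill, nearest)
  out <- array(out, d)
  if (lg) out <- out > 0.5
  out
}

#' Sample a volume at world points
#'
#' @param grid a \code{voxel_grid} (or list with data/spacing/origin).
#' @param pts n x 3 matrix of world coordinates (mm).
#' @param nearest nearest-neighbour instead of trilinear.
#' @param fill out-of-grid value.
#' @return numeric vector of length n.
#' @export
sample_volume <- function(grid, pts, nearest = FALSE, fill = 0) {
  cpp_sample_points(as.numeric(grid$data), as.integer(dim(grid$data)),
                    grid$spacing, grid$origin, as.matrix(pts), fill, nearest)
}

# Gaussian-smooth each component of a 4D (x,y,z,3) field; sigma in mm.
smooth_field <- function(u, spacing, sigma_mm) {
  d <- dim(u)[1:3]
  sv <- sigma_mm / spacing
  for (c in 1:3)
    u[, , , c] <- array(cpp_smooth3(as.numeric(u[, , , c]), as.integer(d), sv), d)
  u
}

# Boundary voxels of a mask by 6-connectivity erosion: voxels in the mask with
# at least one face neighbour outside it (grid edges count as outside).
mask_boundary <- function(mask) {
  d <- dim(mask)
  inner <- mask
  shift_and <- function(m, ax, by) {
    out <- array(FALSE, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    n <- d[ax]
    if (by > 0) { idx_dst[[ax]] <- 2:n; idx_src[[ax]] <- 1:(n - 1) }
    else        { idx_dst[[ax]] <- 1:(n - 1); idx_src[[ax]] <- 2:n }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  for (ax in 1:3) for (by in c(-1, 1))
    inner <- inner & shift_and(mask, ax, by)
  mask & !inner
}
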
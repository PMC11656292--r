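#' @importFrom RNifti writeNifti readNifti asNifti niftiHeader
NULL

write_nii <- function(arr, spacing, path, datatype) {
  img <- RNifti::asNifti(arr, pixdim = spacing)
  RNifti::writeNifti(img, path, datatype = datatype)
}

read_nii <- function(path) {
  img <- RNifti::readNifti(path)
  a <- array(as.numeric(img), dim(img))
  list(data = a, pixdim = attr(img, "pixdim"),
       datatype = RNifti::niftiHeader(img)$datatype)
}

write_anatomy <- function(anat, dir, prefix) {
  g <- anat$grid
  write_nii(g$data, g$spacing, file.path(dir, paste0(prefix, "_rsp.nii.gz")),
            datatype = "double")
  for (nm in names(anat$structures$masks)) {
    m <- anat$structures$masks[[nm]]
    write_nii(array(as.integer(m), dim(m)), g$spacing,
              file.path(dir, paste0(prefix, "_mask_", nm, ".nii.gz")),
              datatype = "uint8")
  }
}

read_anatomy <- function(dir, prefix, spacing, origin) {
  rsp_path <- file.path(dir, paste0(prefix, "_rsp.nii.gz"))
  if (!file.exists(rsp_path)) stop("missing file: ", rsp_path)
  grid <- voxel_grid(read_nii(rsp_path)$data, spacing, origin)
  mask_files <- list.files(dir, pattern = paste0("^", prefix, "_mask_.*\\.nii\\.gz$"),
                           full.names = TRUE)
  masks <- list()
  for (f in sort(mask_files)) {
    nm <- sub(paste0("^", prefix, "_mask_"), "", sub("\\.nii\\.gz$", "", basename(f)))
    masks[[nm]] <- array(read_nii(f)$data > 0.5, dim(grid$data))
  }
  list(grid = grid, structures = structure_set(masks, grid))
}

#' Write a patient timeline to a directory
#'
#' Grids are stored as float64 NIfTI, masks as uint8 NIfTI (one file per
#' structure), displacement fields as 4D float64 NIfTI in mm, and the
#' progression parameters as a JSON sidecar.  \code{\link{read_patient}}
#' recovers the timeline bit-exactly.
#'
#' @param timeline a \code{patient_timeline}.
#' @param dir output directory (created if needed).
#' @export
write_patient <- function(timeline, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gs <- timeline$grid_spec
  meta <- list(dim = gs$dim, spacing = gs$spacing, origin = gs$origin,
               fields_only = is.null(timeline$weekly),
               week_fractions = timeline$week_fractions)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(unclass(timeline$params), file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  write_anatomy(timeline$planning, dir, "planning")
  for (w in 1:6) {
    if (!is.null(timeline$weekly))
      write_anatomy(timeline$weekly[[w]], dir, sprintf("week%d", w))
    write_nii(timeline$true_dvfs[[w]]$u, gs$spacing,
              file.path(dir, sprintf("week%d_dvf.nii.gz", w)), datatype = "double")
    if (!is.null(timeline$back_dvfs[[w]]))
      write_nii(timeline$back_dvfs[[w]]$u, gs$spacing,
                file.path(dir, sprintf("week%d_dvf_back.nii.gz", w)),
                datatype = "double")
  }
  invisible(dir)
}

#' Read a patient timeline from a directory
#' @param dir directory written by \code{\link{write_patient}}.
#' @return a \code{patient_timeline}.
#' @export
read_patient <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) stop("missing file: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  pj <- jsonlite::read_json(file.path(dir, "params.json"), simplifyVector = TRUE)
  params <- do.call(progression_params, pj)
  gs <- list(dim = as.integer(meta$dim), spacing = as.numeric(meta$spacing),
             origin = as.numeric(meta$origin))
  planning <- read_anatomy(dir, "planning", gs$spacing, gs$origin)
  weekly <- NULL
  if (!isTRUE(meta$fields_only)) {
    weekly <- lapply(1:6, function(w)
      read_anatomy(dir, sprintf("week%d", w), gs$spacing, gs$origin))
  }
  true_dvfs <- lapply(1:6, function(w) {
    u <- read_nii(file.path(dir, sprintf("week%d_dvf.nii.gz", w)))$data
    displacement_field(array(u, c(gs$dim, 3)), gs$spacing, gs$origin)
  })
  back_dvfs <- lapply(1:6, function(w) {
    f <- file.path(dir, sprintf("week%d_dvf_back.nii.gz", w))
    if (!file.exists(f)) return(NULL)
    displacement_field(array(read_nii(f)$data, c(gs$dim, 3)), gs$spacing, gs$origin)
  })
  structure(list(planning = planning, weekly = weekly, true_dvfs = true_dvfs,
                 back_dvfs = back_dvfs, params = params, grid_spec = gs,
                 week_fractions = as.numeric(meta$week_fractions)),
            class = "patient_timeline")
}
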
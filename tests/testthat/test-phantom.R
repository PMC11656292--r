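test_that("zero-progression parameters give a static timeline", {
  tl <- fixture_static_patient()
  expect_identical(tl$weekly[[3]]$grid$data, tl$planning$grid$data)
  expect_identical(tl$weekly[[6]]$structures$masks$parotid_l,
                   tl$planning$structures$masks$parotid_l)
  expect_true(all(tl$true_dvfs[[6]]$u == 0))
})

test_that("parotid volume loss hits the requested fraction by week 6", {
  # voxel-counting check of the volume contract at several loss fractions
  tl <- fixture_parotid_patient(0.286)
  p0 <- sum(tl$planning$structures$masks$parotid_l)
  p6 <- sum(tl$weekly[[6]]$structures$masks$parotid_l)
  expect_lt(abs(p6 / p0 - (1 - 0.286)) / (1 - 0.286), 0.05)
  # and the progression is monotone over the course
  vols <- vapply(1:6, function(w)
    sum(tl$weekly[[w]]$structures$masks$parotid_l), numeric(1))
  expect_true(all(diff(vols) <= 0))
})

test_that("medial parotid drift moves the centroid by the requested shift", {
  tl <- make_patient(progression_params(
    ctv_high_loss_per_day = 0, ctv_node_loss_per_day = 0,
    ctv_elective_loss_per_day = 0, parotid_total_loss = 0,
    parotid_medial_shift = 2.3, submandibular_total_loss = 0,
    thyroid_total_loss = 0, neck_contraction = 0, snrv_sigma = 0, seed = 45))
  # independent mask-moment oracle: centroid by brute-force voxel averaging
  centroid <- function(mask, grid) {
    ijk <- which(mask, arr.ind = TRUE)
    colMeans(sweep(sweep(ijk, 2, 0.5), 2, grid$spacing, "*")) + grid$origin
  }
  c0 <- centroid(tl$planning$structures$masks$parotid_l, tl$planning$grid)
  c6 <- centroid(tl$weekly[[6]]$structures$masks$parotid_l, tl$planning$grid)
  shift <- c6 - c0
  # left parotid moves toward the midline: -x, within one voxel of 2.3 mm
  expect_lt(abs(shift[1] - (-2.3)), 3)
  expect_lt(abs(shift[2]), 3)
  expect_lt(abs(shift[3]), 3)
})

test_that("forward fields are invertible on the grid", {
  tl <- fixture_patient()
  fwd <- tl$true_dvfs[[6]]
  bk <- tl$back_dvfs[[6]]
  pts <- grid_centers(tl$planning$grid)
  body <- tl$planning$grid$data > 0.5
  disp <- vapply(1:3, function(c)
    sample_volume(voxel_grid(fwd$u[, , , c], fwd$spacing), pts),
    numeric(nrow(pts)))
  pts2 <- pts + disp
  disp2 <- vapply(1:3, function(c)
    sample_volume(voxel_grid(bk$u[, , , c], bk$spacing), pts2),
    numeric(nrow(pts)))
  resid <- sqrt(rowSums((pts2 + disp2 - pts)^2))
  expect_lt(quantile(resid[body], 0.99), 0.25 * 3)
})

test_that("the same seed reproduces a patient bit-exactly", {
  p <- progression_params(seed = 77)
  a <- make_patient(p, fields_only = TRUE)
  b <- make_patient(p, fields_only = TRUE)
  expect_identical(a$true_dvfs[[4]]$u, b$true_dvfs[[4]]$u)
})

test_that("invalid progression parameters are rejected", {
  expect_error(progression_params(parotid_total_loss = 1.2), "0, 1")
  expect_error(progression_params(parotid_medial_shift = -1), ">= 0")
  expect_error(make_patient(progression_params(), grid_spec(c(16, 16, 16), 3)),
               "too small")
})

test_that("cohort draws honour the population spec", {
  pop <- default_population()
  # degenerate distribution: sd = 0 everywhere returns the means exactly
  pop0 <- lapply(pop, function(s) c(s[1], 0, s[3], s[4]))
  pars <- cohort_params(1, master_seed = 3, population_spec = pop0)
  expect_equal(pars[[1]]$parotid_total_loss, pop$parotid_total_loss[1])
  expect_equal(pars[[1]]$neck_contraction, pop$neck_contraction[1])
  # sample mean of the parotid loss converges on the population mean
  pars20 <- cohort_params(20, master_seed = 9)
  losses <- vapply(pars20, `[[`, numeric(1), "parotid_total_loss")
  expect_lt(abs(mean(losses) - 0.286), 3 * 0.146 / sqrt(20))
  # determinism: identical master seed, identical draws
  pars20b <- cohort_params(20, master_seed = 9)
  expect_identical(pars20, pars20b)
  # invalid spec
  bad <- pop; bad$parotid_total_loss[2] <- -1
  expect_error(cohort_params(3, 1, bad), "sd < 0")
})

test_that("patient timelines round-trip through NIfTI on disk", {
  tl <- fixture_parotid_patient(0.286)
  dir <- file.path(tempdir(), "pt_roundtrip")
  write_patient(tl, dir)
  back <- read_patient(dir)
  expect_identical(back$planning$grid$data, tl$planning$grid$data)
  expect_identical(back$weekly[[2]]$structures$masks$parotid_l,
                   tl$weekly[[2]]$structures$masks$parotid_l)
  expect_identical(back$true_dvfs[[5]]$u, tl$true_dvfs[[5]]$u)
  expect_equal(unclass(back$params), unclass(tl$params))
  # masks stored as uint8, grids and fields as float64
  hdr_mask <- RNifti::niftiHeader(file.path(dir, "planning_mask_parotid_l.nii.gz"))
  hdr_grid <- RNifti::niftiHeader(file.path(dir, "planning_rsp.nii.gz"))
  expect_equal(hdr_mask$datatype, 2L)   # DT_UINT8
  expect_equal(hdr_grid$datatype, 64L)  # DT_FLOAT64
  # displacement magnitudes preserved in mm
  expect_equal(max(abs(back$true_dvfs[[6]]$u)), max(abs(tl$true_dvfs[[6]]$u)))
  expect_error(read_patient(file.path(tempdir(), "no_such_dir")), "missing file")
  unlink(dir, recursive = TRUE)
})

test_that("population specifications round-trip through YAML", {
  pop <- default_population()
  f <- tempfile(fileext = ".yaml")
  write_population(pop, f)
  back <- read_population(f)
  for (nm in names(pop)) expect_equal(unname(back[[nm]]), unname(pop[[nm]]))
  unlink(f)
})
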
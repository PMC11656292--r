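make_field_patient <- function(u_list, gs) {
  # minimal timeline carrying prescribed forward fields
  structure(list(planning = NULL, weekly = NULL,
                 true_dvfs = lapply(u_list, function(u)
                   displacement_field(u, gs$spacing, gs$origin)),
                 params = NULL, grid_spec = gs),
            class = "patient_timeline")
}

test_that("the average model is the voxelwise mean of the training fields", {
  gs <- grid_spec(c(64, 64, 48), 3)  # placeholder; fields are tiny arrays
  d <- c(6, 6, 6)
  gs <- list(dim = d, spacing = c(3, 3, 3), origin = c(0, 0, 0))
  mk <- function(seed) {
    set.seed(seed)
    lapply(1:6, function(w) array(rnorm(prod(d) * 3), c(d, 3)))
  }
  fields <- lapply(1:3, mk)
  cohort <- lapply(fields, make_field_patient, gs = gs)

  # mean of one equals that patient's fields exactly
  m1 <- build_average_model(cohort[1])
  expect_identical(m1$mean_dvfs[[4]]$u, fields[[1]][[4]])

  # opposite fields cancel exactly
  anti <- make_field_patient(lapply(fields[[1]], function(u) -u), gs)
  m2 <- build_average_model(list(cohort[[1]], anti))
  expect_true(all(m2$mean_dvfs[[2]]$u == 0))

  # brute-force voxelwise mean oracle over three patients
  m3 <- build_average_model(cohort)
  w <- 5
  oracle <- array(0, c(d, 3))
  for (ijkc in seq_len(prod(d) * 3)) {
    vals <- vapply(fields, function(f) f[[w]][ijkc], numeric(1))
    oracle[ijkc] <- mean(vals)
  }
  expect_equal(m3$mean_dvfs[[w]]$u, oracle)

  # mismatched grids are rejected
  small <- make_field_patient(lapply(1:6, function(w) array(0, c(4, 4, 4, 3))),
                              list(dim = c(4, 4, 4), spacing = c(3, 3, 3),
                                   origin = c(0, 0, 0)))
  expect_error(build_average_model(list(cohort[[1]], small)), "mismatched")
})

test_that("a zero-field model predicts the planning anatomy unchanged", {
  tl <- fixture_static_patient()
  model <- build_average_model(list(tl))   # static: all fields are zero
  pred <- predict_anatomy(model, tl$planning, 3)
  expect_equal(pred$grid$data, tl$planning$grid$data)
  expect_identical(pred$structures$masks$parotid_l,
                   tl$planning$structures$masks$parotid_l)
  expect_error(predict_anatomy(model, tl$planning, 9), "out of range")
})

test_that("the high-risk CTV contour is copied, others propagated", {
  tl <- fixture_patient()
  model <- build_average_model(list(tl))
  pred <- predict_anatomy(model, tl$planning, 5)
  expect_identical(pred$structures$masks$ctv_high,
                   tl$planning$structures$masks$ctv_high)
  expect_equal(pred$source_rule[["ctv_high"]], "planning-copy")
  expect_equal(pred$source_rule[["parotid_l"]], "propagated")
  expect_false(identical(pred$structures$masks$parotid_l,
                         tl$planning$structures$masks$parotid_l))
})

test_that("a self-trained model reproduces the patient's own weekly contour", {
  tl <- fixture_patient()
  model <- build_average_model(list(tl))
  pred <- predict_anatomy(model, tl$planning, 5)
  sp <- tl$planning$grid$spacing
  m <- msd(pred$structures$masks$parotid_l,
           tl$weekly[[5]]$structures$masks$parotid_l, sp,
           tl$planning$grid$origin)
  expect_lt(m, 3)  # within one voxel
})

test_that("mean surface distance matches a brute-force oracle", {
  d <- c(20, 20, 20)
  ref <- voxel_grid(array(0, d), c(2, 2, 2), c(0, 0, 0))
  pts <- grid_centers(ref)
  sphere <- function(ctr, r) array(rowSums(sweep(pts, 2, ctr)^2) <= r^2, d)
  a <- sphere(c(20, 20, 20), 10)
  b <- sphere(c(22, 20, 20), 10)
  expect_equal(msd(a, a, c(2, 2, 2)), 0)
  got <- msd(a, b, c(2, 2, 2))
  # independent nearest-surface-point oracle on the voxelized surfaces
  surf <- function(m) grid_centers(ref, anatrobust:::mask_boundary(m))
  sa <- surf(a); sb <- surf(b)
  nn <- function(p, q) {
    vapply(seq_len(nrow(p)), function(i)
      sqrt(min(colSums((t(q) - p[i, ])^2))), numeric(1))
  }
  oracle <- (mean(nn(sa, sb)) + mean(nn(sb, sa))) / 2
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_gt(got, 0)
  expect_lt(got, 2.1)  # centers 2 mm apart
  expect_error(msd(a, array(FALSE, d)), "empty")
})

test_that("leave-one-out validation favours the model on a homogeneous cohort", {
  gs4 <- grid_spec(c(48, 48, 36), 4)
  pop <- lapply(default_population(), function(s) c(s[1], 0, s[3], s[4]))
  pop$snrv_sigma <- c(0, 0, 0, 3)  # identical deformation for every patient
  cohort <- make_cohort(3, master_seed = 5, population_spec = pop, gs = gs4)
  tab <- loo_validate(cohort, structures = "parotid_l", weeks = 5)
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$msd_model < tab$msd_nomodel))
  expect_true(all(tab$msd_model < 1))  # near-perfect prediction
})
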
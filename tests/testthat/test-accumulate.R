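test_that("dose warping honours identity, constancy and pure translations", {
  d <- c(12, 12, 12)
  sp <- c(3, 3, 3)
  ref <- voxel_grid(array(0, d), sp, c(0, 0, 0))
  pts <- grid_centers(ref)
  gauss <- function(ctr) array(50 * exp(-rowSums(sweep(pts, 2, ctr)^2) / 200), d)
  dose <- voxel_grid(gauss(c(18, 18, 18)), sp)
  idf <- displacement_field(array(0, c(d, 3)), sp)
  expect_equal(warp_to_planning(dose, idf)$data, dose$data)
  # constant dose is invariant under any interior-bounded smooth field
  u <- array(0, c(d, 3))
  u[4:9, 4:9, 4:9, 1] <- 2
  u <- anatrobust:::smooth_field(u, sp, c(3, 3, 3))
  cdose <- voxel_grid(array(7, d), sp)
  warped <- warp_to_planning(cdose, displacement_field(u, sp))
  interior <- array(FALSE, d); interior[3:10, 3:10, 3:10] <- TRUE
  expect_equal(warped$data[interior], rep(7, sum(interior)))
  # pure translation against the closed-form shifted Gaussian
  tr <- displacement_field(array(rep(c(3, 0, 0), each = prod(d)), c(d, 3)), sp)
  got <- warp_to_planning(dose, tr)
  expected <- gauss(c(15, 18, 18))  # dose(x + 3) = gaussian centered 3 mm lower
  core <- array(FALSE, d); core[3:10, 3:10, 3:10] <- TRUE
  expect_equal(got$data[core], expected[core], tolerance = 0.03 * 50)
  expect_error(warp_to_planning(dose, displacement_field(u * NA, sp)),
               "non-finite")
})

test_that("rigid alignment recovers a known translation", {
  tl <- fixture_patient()
  g <- tl$planning$grid
  expect_equal(align_vct(g, g), c(0, 0, 0), tolerance = 0.2)
  # verification image = planning translated by +3 mm in x
  pts <- grid_centers(g)
  shifted <- voxel_grid(array(sample_volume(g, sweep(pts, 2, c(3, 0, 0), "-"),
                                            fill = 0.001), dim(g$data)),
                        g$spacing, g$origin)
  s <- align_vct(shifted, g)
  expect_equal(s, c(-3, 0, 0), tolerance = 1.5)  # half a voxel
  # inverse consistency
  s_back <- align_vct(g, shifted)
  expect_equal(s, -s_back, tolerance = 0.5)
})

test_that("course accumulation is the fraction-weighted sum of weekly doses", {
  tl <- fixture_parotid_patient(0.286)
  # cheap synthetic plan: one beam, few spots
  params <- dose_engine_params()
  plan <- structure(list(beams = beam_geometry(0, iso = c(99, 90, 87)),
                         spots = data.frame(beam = 1, u = c(-8, 0, 8),
                                            v = 0, r80 = 90),
                         weights = c(20, 20, 20), params = params),
                    class = "spot_plan")
  idx <- which(tl$planning$structures$masks$ctv_high)[seq(1, 1200, by = 13)]
  course <- course_spec(residual_setup_mm = 1)
  acc <- accumulate_course(plan, tl, course, voxels = idx, align = FALSE)
  # channel ordering preserved
  expect_true(all(acc$voxmin <= acc$nominal + 1e-9))
  expect_true(all(acc$nominal <= acc$voxmax + 1e-9))
  # accumulated nominal equals the independent weighted-sum oracle
  wts <- course$week_fraction_weights / 35
  oracle <- Reduce(`+`, lapply(1:6, function(w)
    wts[w] * acc$weekly[[w]]$nominal))
  expect_equal(acc$nominal, oracle, tolerance = 1e-12)
  # mean accumulated nominal lies within the weekly nominal means
  wk_means <- vapply(acc$weekly, function(ch) mean(ch$nominal), numeric(1))
  expect_gte(mean(acc$nominal), min(wk_means) - 1e-9)
  expect_lte(mean(acc$nominal), max(wk_means) + 1e-9)
  # single-week degenerate weighting reproduces that week's dose
  acc1 <- accumulate_course(plan, tl,
                            course_spec(week_fraction_weights = c(35, 0, 0, 0, 0, 0),
                                        residual_setup_mm = 1),
                            voxels = idx, align = FALSE)
  expect_equal(acc1$nominal, acc1$weekly[[1]]$nominal, tolerance = 1e-12)
})

test_that("weekly worst case brackets the nominal dose", {
  g <- water_grid(20, 4)
  plan <- one_spot_plan(0, iso = c(40, 40, 40), r80 = 45)
  wc <- weekly_worst_case(plan, g, course_spec(residual_setup_mm = 1))
  expect_true(all(wc$voxmin$data <= wc$nominal$data + 1e-12))
  expect_true(all(wc$nominal$data <= wc$voxmax$data + 1e-12))
  expect_gt(max(wc$voxmax$data - wc$voxmin$data), 0)
  # with no residual error all three channels coincide
  wc0 <- weekly_worst_case(plan, g, course_spec(residual_setup_mm = 0))
  expect_equal(wc0$voxmin$data, wc0$nominal$data)
  expect_equal(wc0$voxmax$data, wc0$nominal$data)
})
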
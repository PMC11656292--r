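test_that("WEPL equals geometric depth in uniform water", {
  g <- water_grid(30, 4)
  prof <- wepl_profile(g, 0, iso = c(60, 60, 60), step = 0.5)
  sel <- prof$depth > 5 & prof$depth < 110
  expect_lt(max(abs(prof$wepl[sel] - prof$depth[sel])), 1.5)
})

test_that("WEPL scales linearly with RSP", {
  g <- water_grid(30, 4, rsp = 0.5)
  prof <- wepl_profile(g, 0, iso = c(60, 60, 60), step = 0.5)
  sel <- prof$depth > 5 & prof$depth < 110
  expect_lt(max(abs(prof$wepl[sel] - 0.5 * prof$depth[sel])), 1)
})

test_that("two-slab WEPL matches a step-summed ray-marching oracle", {
  arr <- array(1, c(30, 30, 30))
  arr[, 16:30, ] <- 1.5   # second slab along +y (beam direction for gantry 0)
  g <- voxel_grid(arr, c(4, 4, 4), c(0, 0, 0))
  prof <- wepl_profile(g, 0, iso = c(60, 60, 60), step = 0.25)
  # independent oracle: analytic piecewise integral from the entry plane
  oracle <- function(depth) ifelse(depth <= 60, depth, 60 + 1.5 * (depth - 60))
  sel <- prof$depth > 2 & prof$depth < 115
  expect_lt(max(abs(prof$wepl[sel] - oracle(prof$depth[sel]))), 2)
})

test_that("empty or zero-weight plans give identically zero dose", {
  g <- water_grid(20, 4)
  plan <- one_spot_plan(0, iso = c(40, 40, 40), r80 = 60)
  plan$weights <- 0
  d <- plan_dose(g, plan)
  expect_true(all(d$data == 0))
})

test_that("the Bragg peak sits at the depth of the analytic curve maximum", {
  params <- dose_engine_params()
  g <- water_grid(40, 4)
  plan <- one_spot_plan(0, iso = c(80, 80, 80), r80 = 100, params = params)
  d <- plan_dose(g, plan)
  depths <- (seq_len(40) - 0.5) * 4
  prof <- sample_volume(d, cbind(80, depths, 80))
  peak_grid <- depths[which.max(prof)]
  # brute-force 1D fine-grid evaluation of the analytic depth-dose
  zfine <- seq(0, 160, by = 0.01)
  peak_true <- zfine[which.max(depth_dose(zfine, 100, params))]
  expect_lt(abs(peak_grid - peak_true), 2)  # within half a voxel
  # and the distal 80% depth honours the requested R80
  dd <- depth_dose(zfine, 100, params)
  distal80 <- max(zfine[dd >= 0.8 * max(dd)])
  expect_lt(abs(distal80 - 100), 0.05)
})

test_that("range scaling moves the peak proportionally", {
  g <- water_grid(40, 4)
  plan <- one_spot_plan(0, iso = c(80, 80, 80), r80 = 100)
  ws <- anatrobust:::build_wepl_set(g, plan$beams, plan$params)
  depths <- seq(2, 158, by = 0.25)
  peak_at <- function(rs) {
    prof <- anatrobust:::dose_at_points(ws, plan, cbind(80, depths, 80),
                                        scenario(range_scale = rs))
    depths[which.max(prof)]
  }
  p_under <- peak_at(0.97)
  p_nom <- peak_at(1.00)
  p_over <- peak_at(1.03)
  expect_true(p_under < p_nom && p_nom < p_over)
  expect_equal(p_over / p_under, 1.03 / 0.97, tolerance = 0.02)
})

test_that("plan dose is linear in the weights and superposes over spots", {
  g <- water_grid(24, 4)
  params <- dose_engine_params()
  beams <- beam_geometry(c(0, 90), iso = c(48, 48, 48))
  spots <- data.frame(beam = c(1, 1, 2), u = c(0, 8, -4), v = c(0, 4, 0),
                      r80 = c(40, 48, 56))
  plan <- structure(list(beams = beams, spots = spots,
                         weights = c(1, 2, 0.5), params = params),
                    class = "spot_plan")
  d1 <- plan_dose(g, plan)
  plan2 <- plan; plan2$weights <- 2 * plan$weights
  d2 <- plan_dose(g, plan2)
  expect_equal(d2$data, 2 * d1$data, tolerance = 1e-12)
  # superposition: sum of single-spot doses equals the plan dose
  acc <- array(0, dim(g$data))
  for (s in 1:3) {
    ps <- plan
    ps$spots <- spots[s, , drop = FALSE]
    ps$weights <- plan$weights[s]
    acc <- acc + plan_dose(g, ps)$data
  }
  expect_equal(acc, d1$data, tolerance = 1e-9)
})

test_that("shifting a uniform phantom leaves the dose field unchanged", {
  g <- water_grid(24, 4)
  plan <- one_spot_plan(0, iso = c(48, 48, 48), r80 = 50)
  d0 <- plan_dose(g, plan, scenario())
  # in a uniform phantom a shift only translates the dose field:
  # dose_shifted(x) = dose_nominal(x + shift); with a one-voxel shift the
  # translated grids compare node to node, free of interpolation
  ds <- plan_dose(g, plan, scenario(shift = c(0, 0, 4)))
  expect_equal(ds$data[, , 1:23], d0$data[, , 2:24],
               tolerance = 1e-6)
})

test_that("auto-generated spot lattices cover the targets of all anatomies", {
  tl <- fixture_patient()
  plan <- make_spot_plan(list(tl$planning))
  expect_gt(nrow(plan$spots), 500)
  expect_equal(sort(unique(plan$spots$beam)), 1:6)
  expect_true(all(plan$spots$r80 > 0))
  # every CTV-high voxel receives dose from a uniform-weight plan
  ws <- anatrobust:::build_wepl_set(tl$planning$grid, plan$beams, plan$params)
  pts <- grid_centers(tl$planning$grid, tl$planning$structures$masks$ctv_high)
  d <- anatrobust:::dose_at_points(ws, plan, pts, scenario(),
                                   rep(1, nrow(plan$spots)))
  expect_true(all(d > 0))
})

test_that("spot_dose is the single-spot special case of plan_dose", {
  g <- water_grid(20, 4)
  spot <- data.frame(beam = 1, u = 4, v = -4, r80 = 45)
  beams <- beam_geometry(90, iso = c(40, 40, 40))
  d1 <- spot_dose(g, spot, beams = beams, weight = 2.5)
  plan <- structure(list(beams = beams, spots = spot, weights = 2.5,
                         params = dose_engine_params()), class = "spot_plan")
  d2 <- plan_dose(g, plan)
  expect_equal(d1$data, d2$data)
  expect_gt(max(d1$data), 0)
})
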
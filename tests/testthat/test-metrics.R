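test_that("Vd behaves at its boundaries and matches a counting oracle", {
  d <- c(6, 6, 6)
  m <- array(TRUE, d)
  expect_equal(vd(array(70, d), m, level_gy = 65), 100)
  expect_equal(vd(array(runif(prod(d)), d), m, level_gy = 0), 100)
  set.seed(12)
  dose <- array(runif(prod(d), 0, 80), d)
  mask <- array(runif(prod(d)) < 0.5, d)
  lvl <- 40
  oracle <- 100 * sum(dose[mask] >= lvl) / sum(mask)
  expect_equal(vd(dose, mask, lvl), oracle)
  # nonincreasing in the level
  lv <- seq(0, 80, by = 5)
  vals <- vapply(lv, function(l) vd(dose, mask, l), numeric(1))
  expect_true(all(diff(vals) <= 0))
  expect_error(vd(dose, array(FALSE, d), 40), "empty")
})

test_that("hottest-volume doses interpolate the cumulative volume curve", {
  cc <- 0.027  # 3 mm voxels
  expect_equal(d_cc(rep(54, 100), volume_cc = 0.03, cc_per_voxel = cc), 54)
  # single voxel of 0.027 cc: requesting exactly its volume returns its dose
  expect_equal(d_cc(63, volume_cc = 0.027, cc_per_voxel = 0.027), 63)
  expect_error(d_cc(c(1, 2), volume_cc = 1, cc_per_voxel = 0.027), "exceeds")
  # random dose against an independent sort-and-interpolate oracle
  set.seed(13)
  dose <- runif(400, 10, 75)
  got <- d_cc(dose, volume_cc = 0.03, cc_per_voxel = cc)
  s <- sort(dose, decreasing = TRUE)
  cum <- (seq_along(s) - 0.5) * cc
  oracle <- approx(cum, s, xout = 0.03)$y
  expect_equal(got, oracle)
  # D2% uniform case and monotonicity
  expect_equal(d_percent(rep(70, 50), pct = 2), 70)
  expect_gte(d_percent(dose, pct = 2), d_percent(dose, pct = 5))
})

test_that("the V94 ratio is plain division with a guard", {
  expect_equal(v94_ratio(98, 98), 1)
  expect_equal(v94_ratio(97, 98), 97 / 98)
  expect_equal(round(v94_ratio(97, 98), 4), 0.9898)
  expect_error(v94_ratio(97, 0), "zero")
})

test_that("the xerostomia NTCP model reproduces its logistic form", {
  # zero dose everywhere: S = -2.2951
  expect_equal(ntcp_xerostomia(0, 0, 0), 1 / (1 + exp(2.2951)),
               tolerance = 1e-12)
  # doses chosen so S = 0 give exactly 1/2
  dsub <- (2.2951 - 0.0996 * (sqrt(25) + sqrt(25))) / 0.0182
  expect_equal(ntcp_xerostomia(dsub, 25, 25), 0.5, tolerance = 1e-12)
  # frozen value from an independent evaluation of the printed formula
  expect_equal(ntcp_xerostomia(30, 25, 16), 0.298866777802129,
               tolerance = 1e-12)
  # strictly increasing in every argument, output in (0, 1)
  base <- ntcp_xerostomia(30, 25, 16)
  expect_gt(ntcp_xerostomia(31, 25, 16), base)
  expect_gt(ntcp_xerostomia(30, 26, 16), base)
  expect_gt(ntcp_xerostomia(30, 25, 17), base)
  expect_true(base > 0 && base < 1)
  expect_error(ntcp_xerostomia(-1, 10, 10), "negative")
})

test_that("the dysphagia NTCP model reproduces its logistic form", {
  expect_equal(ntcp_dysphagia(0, 0, 0, 0, pharynx = FALSE),
               1 / (1 + exp(4.0536)), tolerance = 1e-12)
  # the pharynx flag lowers NTCP at any fixed doses
  expect_lt(ntcp_dysphagia(30, 30, 30, 30, TRUE),
            ntcp_dysphagia(30, 30, 30, 30, FALSE))
  # frozen value from an independent evaluation of the printed formula
  expect_equal(ntcp_dysphagia(22, 35, 28, 30, TRUE), 0.073733824331670,
               tolerance = 1e-12)
  set.seed(14)
  for (i in 1:5) {
    ds <- runif(4, 0, 60)
    s <- -4.0536 + 0.03 * ds[1] + 0.0236 * ds[2] + 0.0095 * ds[3] +
      0.0133 * ds[4] - 0.6281
    expect_equal(ntcp_dysphagia(ds[1], ds[2], ds[3], ds[4], TRUE),
                 1 / (1 + exp(-s)), tolerance = 1e-12)
  }
})

test_that("gamma analysis passes identity and one-criterion translations", {
  d <- c(16, 16, 16)
  ref <- voxel_grid(array(0, d), c(2, 2, 2), c(0, 0, 0))
  pts <- grid_centers(ref)
  # narrow enough that the included region stays away from the grid edge
  smooth <- function(ctr) array(60 * exp(-rowSums(sweep(pts, 2, ctr)^2) / 100), d)
  a <- voxel_grid(smooth(c(16, 16, 16)), c(2, 2, 2))
  expect_equal(gamma_pass_rate(a, a), 100)
  # a pure 2 mm translation passes through the distance-to-agreement term
  b <- voxel_grid(smooth(c(18, 16, 16)), c(2, 2, 2))
  expect_gt(gamma_pass_rate(a, b, dta_mm = 2, dd_frac = 0.02,
                            search_step = 0.5), 99)
})

test_that("gamma matches an exhaustive neighbourhood-search oracle", {
  d <- c(16, 16, 16)
  ref <- voxel_grid(array(0, d), c(2, 2, 2), c(0, 0, 0))
  pts <- grid_centers(ref)
  set.seed(15)
  base <- 60 * exp(-rowSums(sweep(pts, 2, c(16, 16, 16))^2) / 500)
  a <- voxel_grid(array(base, d), c(2, 2, 2))
  b <- voxel_grid(array(base * (1 + rnorm(length(base), 0, 0.02)), d),
                  c(2, 2, 2))
  got <- gamma_pass_rate(a, b, dta_mm = 2, dd_frac = 0.02, search_step = 1)
  # independent oracle with the same search discretization
  dmax <- max(a$data)
  offs <- as.matrix(expand.grid(x = -6:6, y = -6:6, z = -6:6))
  offs <- offs[rowSums(offs^2) <= 36, , drop = FALSE]
  inc <- which(a$data >= 0.1 * dmax)
  npass <- 0
  for (v in inc) {
    p <- pts[v, ]
    cand <- sweep(offs, 2, p, "+")
    de <- sample_volume(b, cand)
    g2 <- rowSums(offs^2) / 4 + ((de - a$data[v]) / (0.02 * dmax))^2
    if (min(g2) <= 1) npass <- npass + 1
  }
  expect_equal(got, 100 * npass / length(inc), tolerance = 1e-9)
})

test_that("the paired Wilcoxon test matches exact enumeration", {
  expect_warning(p <- wilcoxon_paired(1:6, 1:6), "zero")
  expect_equal(p, 1)
  # all ten differences positive: exact two-sided p = 2 / 2^10
  set.seed(16)
  b <- runif(10)
  expect_equal(wilcoxon_paired(b + seq(1, 2, length.out = 10), b),
               2 / 2^10, tolerance = 1e-12)
  # symmetric +d/-d pairs stay near 1
  dd <- c(1, -1, 2, -2, 3, -3, 4, -4)
  expect_gt(wilcoxon_paired(dd, rep(0, 8)), 0.9)
  # full 2^n enumeration oracle for random continuous data
  for (seed in 17:19) {
    set.seed(seed)
    x <- rnorm(9); y <- rnorm(9)
    got <- wilcoxon_paired(x, y)
    dif <- x - y
    r <- rank(abs(dif))
    W <- sum(r[dif > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 9)))
    Wdist <- as.numeric(signs %*% r)
    p_oracle <- min(1, 2 * min(mean(Wdist >= W), mean(Wdist <= W)))
    expect_equal(got, p_oracle, tolerance = 1e-9)
  }
})

test_that("goal checking flags violations by name and raises the replan flag", {
  mk_report <- function(bs_hot, v94_level) {
    # v94_level: fraction of CTV voxels at >= 94% of prescription
    n <- 200
    ctv <- c(rep(70, round(n * v94_level)), rep(50, n - round(n * v94_level)))
    list(structures = list(
      ctv_high = list(voxmin = ctv, voxmax = rep(72, n), nominal = rep(70, n)),
      ctv_low = list(voxmin = rep(54, n), voxmax = rep(56, n),
                     nominal = rep(54, n)),
      brainstem = list(voxmin = rep(30, 40), voxmax = rep(bs_hot, 40),
                       nominal = rep(30, 40)),
      spinal_cord = list(voxmin = rep(20, 40), voxmax = rep(30, 40),
                         nominal = rep(20, 40))),
      cc_per_voxel = 0.027)
  }
  ok <- goal_check(mk_report(bs_hot = 60, v94_level = 0.99))
  expect_true(ok$acceptable)
  expect_false(ok$replan)
  bad <- goal_check(mk_report(bs_hot = 68.5, v94_level = 0.99))
  expect_false(bad$acceptable)
  expect_true("brainstem" %in% bad$failed$structure)
  replan <- goal_check(mk_report(bs_hot = 60, v94_level = 0.93))
  expect_true(replan$replan)
})
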
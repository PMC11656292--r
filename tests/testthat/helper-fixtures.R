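# Shared fixtures, built once per test session.  Heavyweight phantom objects
# are memoized so several test files can reuse them.

.fix <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fix[[key]])) .fix[[key]] <- builder()
  .fix[[key]]
}

# default-progression patient on the standard grid
fixture_patient <- function() {
  memo("patient", function() make_patient(progression_params(seed = 42)))
}

# patient with only parotid volume loss, everything else frozen
fixture_parotid_patient <- function(loss = 0.286) {
  memo(paste0("parotid", loss), function()
    make_patient(progression_params(
      ctv_high_loss_per_day = 0, ctv_node_loss_per_day = 0,
      ctv_elective_loss_per_day = 0, parotid_total_loss = loss,
      parotid_medial_shift = 0, submandibular_total_loss = 0,
      thyroid_total_loss = 0, neck_contraction = 0, snrv_sigma = 0,
      seed = 43)))
}

fixture_static_patient <- function() {
  memo("static", function()
    make_patient(progression_params(
      ctv_high_loss_per_day = 0, ctv_node_loss_per_day = 0,
      ctv_elective_loss_per_day = 0, parotid_total_loss = 0,
      parotid_medial_shift = 0, submandibular_total_loss = 0,
      thyroid_total_loss = 0, neck_contraction = 0, snrv_sigma = 0,
      seed = 44)))
}

# small uniform-water grid for dose-engine tests
water_grid <- function(n = 40, spacing = 4, rsp = 1) {
  voxel_grid(array(rsp, c(n, n, n)), rep(spacing, 3), c(0, 0, 0))
}

# one-spot plan aimed along a single beam
one_spot_plan <- function(angle = 0, iso = c(80, 80, 80), r80 = 100,
                          params = dose_engine_params()) {
  structure(list(beams = beam_geometry(angle, iso),
                 spots = data.frame(beam = 1, u = 0, v = 0, r80 = r80),
                 weights = 1, params = params),
            class = "spot_plan")
}

# toy optimizer problem: dense influence matrices (rows = voxels of one
# target structure), one min-dose + one max-dose term
toy_context <- function(A, level_min = 60, level_max = 70, wmin = 100,
                        wmax = 10) {
  A <- Matrix::Matrix(A, sparse = TRUE)
  terms <- rbind(
    data.frame(structure = "tgt", type = "min", level = level_min,
               weight = wmin, robust = TRUE),
    data.frame(structure = "tgt", type = "max", level = level_max,
               weight = wmax, robust = TRUE))
  make_opt_context(A, list(tgt = seq_len(nrow(A))), terms)
}

# brute-force composite objective for a toy context (independent oracle)
toy_objective_oracle <- function(A, w, level_min = 60, level_max = 70,
                                 wmin = 100, wmax = 10) {
  d <- as.numeric(as.matrix(A) %*% w)
  wmin * mean(pmax(level_min - d, 0)^2) + wmax * mean(pmax(d - level_max, 0)^2)
}
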
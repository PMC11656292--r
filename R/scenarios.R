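#' Uncertainty scenario
#'
#' One dose-recomputation context: an anatomy, a rigid setup shift and a
#' range scale factor.
#'
#' @param anatomy_id label of the anatomy ("planning", "predicted-week-w",
#'   "vct-week-w").
#' @param shift length-3 setup shift (mm).
#' @param range_scale multiplicative range scale (0.97 / 1 / 1.03 for a 3\%
#'   uncertainty).
#' @export
scenario <- function(anatomy_id = "planning", shift = c(0, 0, 0),
                     range_scale = 1) {
  stopifnot(length(shift) == 3L, range_scale > 0)
  structure(list(anatomy_id = anatomy_id, shift = as.numeric(shift),
                 range_scale = range_scale), class = "scenario")
}

#' The 14 setup shift directions
#'
#' Six axis-aligned and eight body-diagonal directions, every vector
#' normalized to the requested magnitude, in a fixed deterministic order.
#'
#' @param magnitude shift magnitude (mm), > 0.
#' @return 14 x 3 matrix of shift vectors.
#' @export
enumerate_setup_shifts <- function(magnitude) {
  if (magnitude <= 0) stop("magnitude must be > 0")
  axes <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  s <- 1 / sqrt(3)
  diag8 <- as.matrix(expand.grid(x = c(-s, s), y = c(-s, s), z = c(-s, s)))
  v <- rbind(axes, unname(diag8))
  v * magnitude
}

#' Evaluation scenario set for one anatomy
#'
#' Cross product of the 14 setup shifts with the two pure range errors
#' (1 - r and 1 + r): 28 scenarios.  The nominal scenario (zero shift, scale
#' 1) is not a member and is computed separately.
#'
#' @param anatomy_id anatomy label.
#' @param setup_mm setup shift magnitude (mm).
#' @param range_frac fractional range uncertainty (e.g. 0.03).
#' @return An object of class \code{scenario_set}.
#' @export
enumerate_eval_scenarios <- function(anatomy_id, setup_mm = 1, range_frac = 0.03) {
  shifts <- enumerate_setup_shifts(setup_mm)
  scenarios <- list()
  for (rs in c(1 - range_frac, 1 + range_frac))
    for (r in seq_len(nrow(shifts)))
      scenarios[[length(scenarios) + 1]] <-
        scenario(anatomy_id, shifts[r, ], rs)
  structure(list(scenarios = scenarios, purpose = "evaluation",
                 setup_magnitude = setup_mm, range_magnitude = range_frac,
                 anatomy_ids = anatomy_id),
            class = "scenario_set")
}

#' Optimization scenario set for a planning strategy
#'
#' cRO3mm / cRO1mm use the planning anatomy only with 3 mm / 1 mm setup
#' shifts; aRO1mm extends the anatomy list with the predicted anatomies of
#' weeks 1, 3 and 5 at 1 mm.  Per anatomy: 14 shifts x 2 range errors = 28
#' error scenarios (112 in total for aRO1mm).  One nominal scenario per
#' anatomy is carried separately in \code{nominal} for the objective's
#' nominal term.
#'
#' @param strategy "cRO3mm", "cRO1mm" or "aRO1mm".
#' @param range_frac fractional range uncertainty.
#' @return a \code{scenario_set} with an extra \code{nominal} list.
#' @export
enumerate_opt_scenarios <- function(strategy = c("cRO3mm", "cRO1mm", "aRO1mm"),
                                    range_frac = 0.03) {
  strategy <- match.arg(strategy)
  setup_mm <- if (strategy == "cRO3mm") 3 else 1
  anatomy_ids <- if (strategy == "aRO1mm")
    c("planning", "predicted-week-1", "predicted-week-3", "predicted-week-5")
  else "planning"
  scenarios <- list()
  for (aid in anatomy_ids)
    scenarios <- c(scenarios, enumerate_eval_scenarios(aid, setup_mm,
                                                       range_frac)$scenarios)
  nominal <- lapply(anatomy_ids, function(aid) scenario(aid, c(0, 0, 0), 1))
  structure(list(scenarios = scenarios, purpose = "optimization",
                 setup_magnitude = setup_mm, range_magnitude = range_frac,
                 anatomy_ids = anatomy_ids, nominal = nominal,
                 strategy = strategy),
            class = "scenario_set")
}

#' @export
print.scenario_set <- function(x, ...) {
  cat("<scenario_set> ", length(x$scenarios), " ", x$purpose,
      " scenarios (", x$setup_magnitude, " mm setup, ",
      100 * x$range_magnitude, "% range) over ",
      length(x$anatomy_ids), " anatom",
      if (length(x$anatomy_ids) > 1) "ies" else "y", "\n", sep = "")
  invisible(x)
}

#' Voxel-wise worst-case dose over a scenario stack
#'
#' @param doses list of dose arrays / \code{voxel_grid}s on a common grid.
#' @param nominal the nominal dose (same frame).
#' @return list with \code{voxmin}, \code{voxmax}, \code{nominal} (same type
#'   as the inputs).
#' @export
worst_case <- function(doses, nominal = NULL) {
  stopifnot(length(doses) >= 1)
  arrs <- lapply(doses, function(d) if (inherits(d, "voxel_grid")) d$data else d)
  d0 <- arrs[[1]]
  for (a in arrs[-1])
    if (!identical(dim(a), dim(d0))) stop("dose shape mismatch")
  voxmin <- Reduce(pmin, arrs)
  voxmax <- Reduce(pmax, arrs)
  nom <- if (is.null(nominal)) NULL
         else if (inherits(nominal, "voxel_grid")) nominal$data else nominal
  list(voxmin = voxmin, voxmax = voxmax, nominal = nom)
}
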
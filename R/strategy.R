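# --- structure point sampling -------------------------------------------------

# Deterministically subsample the voxels of each named structure.  Returns,
# per structure, the voxel indices, their world centers and the sampling
# fraction.  Subsampling (evenly strided over the index order) keeps
# volumetric metrics unbiased while bounding cost.  With `boundary_cap` set,
# surface voxels (where minimum-dose penalties bind under setup shifts) are
# sampled separately from the interior.
structure_points <- function(anat, names, cap = Inf, boundary_cap = NULL) {
  stride_cap <- function(idx, k) {
    if (length(idx) > k) idx[unique(round(seq(1, length(idx), length.out = k)))]
    else idx
  }
  out <- list()
  for (nm in names) {
    m <- anat$structures$masks[[nm]]
    if (is.null(m)) stop("missing structure: ", nm)
    idx <- which(m)
    if (!length(idx)) stop("empty structure mask: ", nm)
    if (is.null(boundary_cap)) {
      idx <- stride_cap(idx, cap)
    } else {
      surf <- which(mask_boundary(m))
      inner <- setdiff(idx, surf)
      idx <- sort(c(stride_cap(surf, boundary_cap), stride_cap(inner, cap)))
    }
    out[[nm]] <- list(idx = idx, pts = grid_centers(anat$grid, idx))
  }
  out
}

# Stack structure point sets into one matrix + row-group lookup.
stack_points <- function(sp) {
  pts <- do.call(rbind, lapply(sp, `[[`, "pts"))
  groups <- list()
  off <- 0L
  for (nm in names(sp)) {
    n <- nrow(sp[[nm]]$pts)
    groups[[nm]] <- off + seq_len(n)
    off <- off + n
  }
  list(pts = pts, groups = groups)
}

#' Strategy configuration
#'
#' @param name "cRO3mm", "cRO1mm" or "aRO1mm".
#' @param range_frac fractional range uncertainty.
#' @param lambda weight of the nominal objective term.
#' @export
strategy_config <- function(name = c("cRO3mm", "cRO1mm", "aRO1mm"),
                            range_frac = 0.03, lambda = 1) {
  name <- match.arg(name)
  list(name = name, range_frac = range_frac, lambda = lambda,
       setup_mm = if (name == "cRO3mm") 3 else 1,
       predicted_weeks = if (name == "aRO1mm") c(1, 3, 5) else integer(0))
}

robust_structures <- c("ctv_high", "ctv_low", "brainstem", "spinal_cord")
parallel_structures <- c("parotid_l", "parotid_r", "submandibular_l",
                         "submandibular_r", "oral_cavity", "pcm_sup",
                         "pcm_med", "pcm_inf")

# Evaluate nominal + scenario doses at fixed points and reduce to a
# structure dose evaluation (per-structure voxmin/voxmax/nominal vectors).
eval_scenarios_at_points <- function(wepl_set, plan, stacked, scenarios,
                                     weights = plan$weights,
                                     base_shift = c(0, 0, 0)) {
  nom <- dose_at_points(wepl_set, plan,
                        stacked$pts, scenario(shift = base_shift), weights)
  vmin <- nom; vmax <- nom
  for (sc in scenarios) {
    sc2 <- scenario(sc$anatomy_id, sc$shift + base_shift, sc$range_scale)
    d <- dose_at_points(wepl_set, plan, stacked$pts, sc2, weights)
    vmin <- pmin(vmin, d)
    vmax <- pmax(vmax, d)
  }
  list(nominal = nom, voxmin = vmin, voxmax = vmax)
}

# package point-channel vectors into a goal_check-compatible report
channels_to_report <- function(channels, groups, cc_per_voxel, scale = 1) {
  structures <- lapply(groups, function(rows)
    lapply(channels, function(v) v[rows] * scale))
  list(structures = structures, cc_per_voxel = cc_per_voxel)
}

#' Plan one strategy for a patient
#'
#' Builds the strategy's anatomy list (planning only for cRO3mm/cRO1mm;
#' planning plus model-predicted weeks 1, 3, 5 for aRO1mm, with propagated
#' OAR/low-risk CTV contours and the planning high-risk CTV), lays out the
#' spot lattice, assembles per-scenario influence matrices, runs the minimax
#' optimization, and evaluates the planning-stage nominal/voxmin/voxmax dose
#' and clinical goals on the planning anatomy under the strategy's own
#' setup/range scenario set.
#'
#' The optimizer works in arbitrary machine units against objective levels in
#' Gy, so the recovered spot weights put the dose directly on the Gy scale.
#'
#' @param patient a \code{patient_timeline}.
#' @param strategy a \code{\link{strategy_config}} or strategy name.
#' @param model an \code{average_model}; required for aRO1mm.
#' @param objective objective specification, see \code{\link{default_objective}}.
#' @param params \code{\link{dose_engine_params}}.
#' @param beams \code{\link{beam_geometry}}.
#' @param opt_cap interior-voxel subsample cap per structure for optimization.
#' @param opt_boundary surface-voxel subsample cap per target structure for
#'   optimization (surface voxels carry the setup-shift coverage penalties).
#' @param eval_cap voxel subsample cap per structure for evaluation.
#' @param maxit,taus optimizer controls, see \code{\link{optimize_weights}}.
#' @return list with \code{plan} (weights set), \code{result}
#'   (optimization result), \code{planning_report} (per-structure
#'   voxmin/voxmax/nominal dose), \code{goals}, \code{acceptable},
#'   \code{wepl_planning} (cached WEPL volumes).
#' @export
plan_strategy <- function(patient, strategy = "cRO3mm", model = NULL,
                          objective = default_objective(),
                          params = dose_engine_params(sigma0 = 6),
                          beams = beam_geometry(),
                          opt_cap = 150, opt_boundary = 400, eval_cap = 2500,
                          maxit = 120, taus = c(0.15, 0.03)) {
  if (is.character(strategy)) strategy <- strategy_config(strategy)
  planning <- patient$planning
  anatomies <- list(planning = planning)
  if (length(strategy$predicted_weeks)) {
    if (is.null(model)) stop("aRO1mm requires an average_model")
    for (w in strategy$predicted_weeks) {
      pa <- predict_anatomy(model, planning, w)
      anatomies[[paste0("predicted-week-", w)]] <-
        list(grid = pa$grid, structures = pa$structures)
    }
  }
  plan <- make_spot_plan(anatomies, beams, params)
  scset <- enumerate_opt_scenarios(strategy$name, strategy$range_frac)

  wepl_sets <- lapply(anatomies, function(a) build_wepl_set(a$grid, beams, params))

  robust_terms <- objective[objective$robust, , drop = FALSE]
  error_contexts <- list()
  nominal_contexts <- list()
  stacked_robust <- list()
  # The influence matrices truncate small per-spot contributions; a per-row
  # exact/truncated dose ratio at uniform weights (per anatomy, nominal
  # scenario) rescales the rows so the optimizer sees unbiased totals.
  row_scale <- list()
  ones <- rep(1, nrow(plan$spots))
  for (aid in names(anatomies)) {
    spr <- structure_points(anatomies[[aid]],
                            intersect(robust_structures, unique(robust_terms$structure)),
                            cap = opt_cap, boundary_cap = opt_boundary)
    stacked_robust[[aid]] <- stack_points(spr)
    trip0 <- influence_triplets(wepl_sets[[aid]], plan,
                                stacked_robust[[aid]]$pts, scenario(aid),
                                thresh = 0.04)
    trunc0 <- cpp_trip_matvec(trip0$i, trip0$j, trip0$x, ones, trip0$nrow)
    exact0 <- dose_at_points(wepl_sets[[aid]], plan, stacked_robust[[aid]]$pts,
                             scenario(aid), ones)
    row_scale[[aid]] <- ifelse(trunc0 > 0, exact0 / trunc0, 1)
    # nominal context carries all terms, so add the parallel structures
    spn <- structure_points(anatomies[[aid]],
                            unique(objective$structure), cap = opt_cap)
    stn <- stack_points(spn)
    Anom <- influence_at_points(wepl_sets[[aid]], plan, stn$pts, scenario(aid))
    truncn <- as.numeric(Anom %*% ones)
    exactn <- dose_at_points(wepl_sets[[aid]], plan, stn$pts, scenario(aid), ones)
    Anom <- Matrix::Diagonal(x = ifelse(truncn > 0, exactn / truncn, 1)) %*% Anom
    nominal_contexts[[aid]] <- make_opt_context(Anom, stn$groups, objective)
  }
  for (sc in scset$scenarios) {
    aid <- sc$anatomy_id
    st <- stacked_robust[[aid]]
    trip <- influence_triplets(wepl_sets[[aid]], plan, st$pts, sc, thresh = 0.04)
    trip$x <- trip$x * row_scale[[aid]][trip$i]
    error_contexts[[length(error_contexts) + 1]] <-
      make_opt_context(trip, st$groups, robust_terms)
  }
  result <- optimize_weights(error_contexts, nominal_contexts,
                             nspots = nrow(plan$spots),
                             lambda = strategy$lambda,
                             maxit = maxit, taus = taus)
  plan$weights <- result$weights

  # planning-stage evaluation on the planning anatomy under the strategy's
  # setup/range error set
  eval_names <- intersect(c(robust_structures, parallel_structures),
                          names(planning$structures$masks))
  spe <- structure_points(planning, eval_names, cap = eval_cap)
  ste <- stack_points(spe)
  eval_scset <- enumerate_eval_scenarios("planning", strategy$setup_mm,
                                         strategy$range_frac)
  ch <- eval_scenarios_at_points(wepl_sets$planning, plan, ste,
                                 eval_scset$scenarios)
  report <- channels_to_report(ch, ste$groups, voxel_cc(planning$grid))
  gc_res <- goal_check(report)
  list(strategy = strategy, plan = plan, result = result,
       planning_report = report, goals = gc_res$table,
       acceptable = gc_res$acceptable, failed_goals = gc_res$failed,
       wepl_planning = wepl_sets$planning, eval_points = ste)
}
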
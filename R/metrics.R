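as_mask_dose <- function(dose, mask) {
  d <- if (inherits(dose, "voxel_grid")) dose$data else dose
  if (!is.null(mask)) {
    if (!any(mask)) stop("empty structure mask")
    d <- d[mask]
  }
  as.numeric(d)
}

#' Vd: percent volume at or above a dose level
#'
#' @param dose a \code{voxel_grid}/array, or the dose vector inside the mask.
#' @param mask logical array (NULL when \code{dose} is already the in-mask
#'   vector).
#' @param level_gy dose level (Gy).
#' @return percent of the structure volume with dose >= level.
#' @export
vd <- function(dose, mask = NULL, level_gy) {
  d <- as_mask_dose(dose, mask)
  if (!length(d)) stop("empty structure mask")
  100 * sum(d >= level_gy) / length(d)
}

#' Mean dose
#' @inheritParams vd
#' @export
dmean <- function(dose, mask = NULL) mean(as_mask_dose(dose, mask))

#' Dose to the hottest given absolute volume (e.g. D0.03cc)
#'
#' Linear interpolation on the cumulative sorted-voxel volume curve: the
#' returned value is the dose at the cutoff where the hottest
#' \code{volume_cc} of the structure is reached.
#'
#' @inheritParams vd
#' @param volume_cc requested hottest volume (cc).
#' @param cc_per_voxel voxel volume (cc).
#' @export
d_cc <- function(dose, mask = NULL, volume_cc, cc_per_voxel) {
  d <- sort(as_mask_dose(dose, mask), decreasing = TRUE)
  total <- length(d) * cc_per_voxel
  if (volume_cc > total) stop("requested volume exceeds structure volume")
  # cumulative volume at the i-th hottest voxel midpoint
  cum <- (seq_along(d) - 0.5) * cc_per_voxel
  if (volume_cc <= cum[1]) return(d[1])
  if (volume_cc >= cum[length(cum)]) return(d[length(d)])
  stats::approx(cum, d, xout = volume_cc)$y
}

#' Dose to the hottest percent volume (e.g. D2%)
#' @inheritParams vd
#' @param pct hottest volume percentage (e.g. 2).
#' @export
d_percent <- function(dose, mask = NULL, pct) {
  d <- sort(as_mask_dose(dose, mask), decreasing = TRUE)
  n <- length(d)
  cum <- (seq_len(n) - 0.5) / n * 100
  if (pct <= cum[1]) return(d[1])
  if (pct >= cum[n]) return(d[n])
  stats::approx(cum, d, xout = pct)$y
}

#' Ratio of accumulated to planning V94
#'
#' Both arguments are V94 values computed on the voxmin channel.
#' @param accumulated_v94,planning_v94 V94 percentages.
#' @export
v94_ratio <- function(accumulated_v94, planning_v94) {
  if (planning_v94 == 0) stop("planning V94 is zero")
  accumulated_v94 / planning_v94
}

#' NTCP for grade >= 2 patient-rated xerostomia
#'
#' Logistic model NTCP = 1 / (1 + exp(-S)) with
#' S = -2.2951 + 0.0182 * Dmean(submandibular)
#'   + 0.0996 * (sqrt(Dmean(ipsilateral parotid)) +
#'               sqrt(Dmean(contralateral parotid))).
#' Mean doses in Gy.
#'
#' @param dmean_submandibular,dmean_ipsi_parotid,dmean_contra_parotid mean
#'   doses (Gy, >= 0).
#' @return probability in (0, 1).
#' @export
ntcp_xerostomia <- function(dmean_submandibular, dmean_ipsi_parotid,
                            dmean_contra_parotid) {
  if (any(c(dmean_submandibular, dmean_ipsi_parotid, dmean_contra_parotid) < 0))
    stop("negative dose")
  s <- -2.2951 + 0.0182 * dmean_submandibular +
    0.0996 * (sqrt(dmean_ipsi_parotid) + sqrt(dmean_contra_parotid))
  1 / (1 + exp(-s))
}

#' NTCP for grade >= 2 dysphagia
#'
#' Logistic model NTCP = 1 / (1 + exp(-S)) with
#' S = -4.0536 + 0.03 * Dmean(oral cavity) + 0.0236 * Dmean(PCM superior)
#'   + 0.0095 * Dmean(PCM medius) + 0.0133 * Dmean(PCM inferior)
#'   - 0.6281 * pharynx.
#'
#' @param dmean_oral,dmean_pcm_sup,dmean_pcm_med,dmean_pcm_inf mean doses
#'   (Gy, >= 0).
#' @param pharynx logical/0-1 flag: tumor located in the pharynx.
#' @return probability in (0, 1).
#' @export
ntcp_dysphagia <- function(dmean_oral, dmean_pcm_sup, dmean_pcm_med,
                           dmean_pcm_inf, pharynx = TRUE) {
  if (any(c(dmean_oral, dmean_pcm_sup, dmean_pcm_med, dmean_pcm_inf) < 0))
    stop("negative dose")
  s <- -4.0536 + 0.03 * dmean_oral + 0.0236 * dmean_pcm_sup +
    0.0095 * dmean_pcm_med + 0.0133 * dmean_pcm_inf -
    0.6281 * as.numeric(pharynx)
  1 / (1 + exp(-s))
}

#' Gamma pass rate (global normalization)
#'
#' Percentage of reference voxels at or above the low-dose threshold whose
#' gamma index (distance-to-agreement \code{dta_mm}, dose difference
#' \code{dd_frac} of the global reference maximum) is <= 1.  The search
#' radius is capped at 3 x dta.
#'
#' @param reference,evaluated \code{voxel_grid}s on the same frame.
#' @param dta_mm distance-to-agreement criterion (mm).
#' @param dd_frac dose-difference criterion as a fraction of max reference
#'   dose.
#' @param threshold_frac exclude reference voxels below this fraction of the
#'   maximum reference dose (default 10\%).
#' @param search_step search sampling step (mm).
#' @return pass rate in percent.
#' @export
gamma_pass_rate <- function(reference, evaluated, dta_mm = 2, dd_frac = 0.02,
                            threshold_frac = 0.1, search_step = 1) {
  stopifnot(same_frame(reference, evaluated))
  dmax <- max(reference$data)
  if (dmax <= 0) stop("reference dose is empty")
  res <- cpp_gamma(as.numeric(reference$data), as.numeric(evaluated$data),
                   as.integer(dim(reference$data)), reference$spacing,
                   reference$origin, dta_mm, dd_frac * dmax,
                   threshold_frac * dmax, 3 * dta_mm, search_step)
  if (res[2] == 0) stop("no reference voxels above threshold")
  100 * res[1] / res[2]
}

#' Paired two-sided Wilcoxon signed-rank test
#'
#' Standard zero-drop convention; exact distribution for n <= 25 without
#' ties, normal approximation otherwise.  Identical samples are degenerate
#' and reported as p = 1 with a warning.
#'
#' @param values_a,values_b paired samples (equal length, n >= 5).
#' @return two-sided p-value.
#' @export
wilcoxon_paired <- function(values_a, values_b) {
  stopifnot(length(values_a) == length(values_b), length(values_a) >= 5)
  d <- values_a - values_b
  if (all(d == 0)) {
    warning("all paired differences are zero; p = 1")
    return(1)
  }
  d <- d[d != 0]
  exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  suppressWarnings(
    stats::wilcox.test(d, exact = exact, correct = TRUE)$p.value)
}

#' Default clinical goals
#'
#' CTV coverage and serial-organ limits: V94(voxmin) > 98\% for both CTVs,
#' CTV D2\%(voxmax) < 110\% of prescription (77 Gy), brainstem D0.03cc
#' voxmax < 68 / nominal < 63.1 Gy, spinal cord 58.5 / 55 Gy, optic
#' structures 64 / 59.5 Gy (evaluated when present).
#'
#' @param rx_high,rx_low prescriptions (Gy).
#' @return data.frame: structure, metric, channel, limit, direction.
#' @export
default_goals <- function(rx_high = 70, rx_low = 54.25) {
  rbind(
    data.frame(structure = "ctv_high", metric = "v94", channel = "voxmin",
               limit = 98, direction = ">"),
    data.frame(structure = "ctv_low", metric = "v94", channel = "voxmin",
               limit = 98, direction = ">"),
    data.frame(structure = "ctv_high", metric = "d2", channel = "voxmax",
               limit = 1.1 * rx_high, direction = "<"),
    data.frame(structure = "ctv_low", metric = "d2", channel = "voxmax",
               limit = 1.1 * rx_high, direction = "<"),
    data.frame(structure = "brainstem", metric = "d003cc", channel = "voxmax",
               limit = 68, direction = "<"),
    data.frame(structure = "brainstem", metric = "d003cc", channel = "nominal",
               limit = 63.1, direction = "<"),
    data.frame(structure = "spinal_cord", metric = "d003cc", channel = "voxmax",
               limit = 58.5, direction = "<"),
    data.frame(structure = "spinal_cord", metric = "d003cc", channel = "nominal",
               limit = 55, direction = "<"),
    data.frame(structure = "optic", metric = "d003cc", channel = "voxmax",
               limit = 64, direction = "<"),
    data.frame(structure = "optic", metric = "d003cc", channel = "nominal",
               limit = 59.5, direction = "<"))
}

# metric evaluation on a structure-channel dose table; `report` is a
# dose_eval object (see structure_dose_eval)
eval_goal_metric <- function(report, structure, metric, channel, rx) {
  st <- report$structures[[structure]]
  if (is.null(st)) return(NA_real_)
  d <- st[[channel]]
  switch(metric,
         v94 = vd(d, level_gy = 0.94 * rx[[structure]]),
         d2 = d_percent(d, pct = 2),
         d003cc = d_cc(d, volume_cc = 0.03, cc_per_voxel = report$cc_per_voxel),
         dmean = mean(d))
}

#' Check clinical goals on a structure dose evaluation
#'
#' @param report a structure dose evaluation (internal per-structure channel
#'   dose vectors, as produced by planning or accumulation).
#' @param goals goals table, see \code{\link{default_goals}}.
#' @param rx named prescriptions for the v94 goals (Gy).
#' @param replan_threshold accumulated CTV V94(voxmin) below which the replan
#'   flag is raised (percent).
#' @return list: \code{table} (goals with value/pass), \code{acceptable}
#'   (all present goals pass), \code{replan} (CTV V94 voxmin below the
#'   replanning threshold).
#' @export
goal_check <- function(report, goals = default_goals(),
                       rx = c(ctv_high = 70, ctv_low = 54.25),
                       replan_threshold = 94) {
  vals <- numeric(nrow(goals))
  pass <- logical(nrow(goals))
  for (r in seq_len(nrow(goals))) {
    v <- eval_goal_metric(report, goals$structure[r], goals$metric[r],
                          goals$channel[r], rx)
    vals[r] <- v
    pass[r] <- if (is.na(v)) NA else if (goals$direction[r] == ">")
      v > goals$limit[r] else v < goals$limit[r]
  }
  tab <- cbind(goals, value = vals, pass = pass)
  present <- !is.na(pass)
  if (!any(present)) stop("no goal structures present; missing: ",
                          paste(unique(goals$structure), collapse = ", "))
  replan <- FALSE
  for (nm in c("ctv_high", "ctv_low")) {
    st <- report$structures[[nm]]
    if (!is.null(st) && !is.null(st$voxmin))
      replan <- replan || vd(st$voxmin, level_gy = 0.94 * rx[[nm]]) < replan_threshold
  }
  list(table = tab, acceptable = all(pass[present]), replan = replan,
       failed = tab[present & !pass, , drop = FALSE])
}
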
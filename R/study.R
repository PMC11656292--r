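#' Study configuration
#'
#' @param n_cohort total synthetic patients (model training pool).
#' @param n_validation number of held-out validation patients (the first
#'   \code{n_validation} cohort members); each validation patient's model is
#'   trained on the other \code{n_cohort - 1} patients (leave-one-out).
#' @param master_seed integer master seed.
#' @param population population spec, see \code{\link{default_population}}.
#' @param strategies strategy names to plan.
#' @param course \code{\link{course_spec}} for the simulated treatment.
#' @param gs \code{\link{grid_spec}}.
#' @param rx named prescriptions (Gy).
#' @param pharynx tumor-location flag entering the dysphagia NTCP model
#'   (TRUE for the emulated nasopharynx cohort).
#' @param opt_cap,opt_boundary,eval_cap,maxit,taus optimizer/evaluation size
#'   controls, see \code{\link{plan_strategy}}; conventional strategies,
#'   planned once per study on the shared template anatomy, get twice the
#'   iteration budget of the per-patient adaptive plans.
#' @export
study_config <- function(n_cohort = 20, n_validation = 10, master_seed = 1,
                         population = default_population(),
                         strategies = c("cRO3mm", "cRO1mm", "aRO1mm"),
                         course = course_spec(), gs = grid_spec(),
                         rx = c(ctv_high = 70, ctv_low = 54.25),
                         pharynx = TRUE,
                         opt_cap = 150, opt_boundary = 350, eval_cap = 2000,
                         maxit = 100, taus = c(0.05)) {
  stopifnot(n_cohort >= 2, n_validation >= 1, n_validation <= n_cohort,
            length(strategies) >= 1, all(rx > 0))
  list(n_cohort = n_cohort, n_validation = n_validation,
       master_seed = master_seed, population = population,
       strategies = strategies, course = course, gs = gs, rx = rx,
       pharynx = pharynx, opt_cap = opt_cap, opt_boundary = opt_boundary,
       eval_cap = eval_cap, maxit = maxit, taus = taus)
}

# per-patient per-strategy metric row from planning + accumulated reports
strategy_metrics <- function(planning_report, acc_report, rx, pharynx,
                             cc_per_voxel) {
  getm <- function(report, structure, channel, metric, ...) {
    st <- report$structures[[structure]]
    switch(metric,
           v94 = vd(st[[channel]], level_gy = 0.94 * rx[[structure]]),
           d2 = d_percent(st[[channel]], pct = 2),
           d003cc = d_cc(st[[channel]], volume_cc = 0.03,
                         cc_per_voxel = cc_per_voxel),
           dmean = mean(st[[channel]]))
  }
  plan_v94_high <- getm(planning_report, "ctv_high", "voxmin", "v94")
  plan_v94_low <- getm(planning_report, "ctv_low", "voxmin", "v94")
  acc_v94_high <- getm(acc_report, "ctv_high", "voxmin", "v94")
  acc_v94_low <- getm(acc_report, "ctv_low", "voxmin", "v94")
  dm <- function(nm) getm(acc_report, nm, "nominal", "dmean")
  dmean_sub <- mean(c(acc_report$structures$submandibular_l$nominal,
                      acc_report$structures$submandibular_r$nominal))
  # CTV-high sits left of midline, so the left parotid is ipsilateral
  ntcp_x <- ntcp_xerostomia(dmean_sub, dm("parotid_l"), dm("parotid_r"))
  ntcp_d <- ntcp_dysphagia(dm("oral_cavity"), dm("pcm_sup"), dm("pcm_med"),
                           dm("pcm_inf"), pharynx)
  data.frame(
    plan_v94_high = plan_v94_high, plan_v94_low = plan_v94_low,
    acc_v94_high = acc_v94_high, acc_v94_low = acc_v94_low,
    v94_ratio_high = v94_ratio(acc_v94_high, plan_v94_high),
    v94_ratio_low = v94_ratio(acc_v94_low, plan_v94_low),
    d2_voxmax_high = getm(acc_report, "ctv_high", "voxmax", "d2"),
    brainstem_d003cc_voxmax = getm(acc_report, "brainstem", "voxmax", "d003cc"),
    cord_d003cc_voxmax = getm(acc_report, "spinal_cord", "voxmax", "d003cc"),
    parotid_ipsi_dmean = dm("parotid_l"),
    parotid_contra_dmean = dm("parotid_r"),
    submandibular_dmean = dmean_sub,
    oral_cavity_dmean = dm("oral_cavity"),
    pcm_sup_dmean = dm("pcm_sup"),
    pcm_med_dmean = dm("pcm_med"),
    pcm_inf_dmean = dm("pcm_inf"),
    ntcp_xerostomia = ntcp_x,
    ntcp_dysphagia = ntcp_d,
    replan = acc_v94_high < 94 || acc_v94_low < 94)
}

#' Run the full comparison study
#'
#' Generates the synthetic cohort, and for each validation patient: trains
#' the average deformation model on all other cohort members (leave-one-out),
#' optimizes a plan per strategy, simulates the treatment course on the true
#' weekly anatomies with residual setup/range uncertainty, accumulates
#' nominal/voxmin/voxmax dose in the planning frame, and computes the
#' evaluation metrics and NTCP values.  Cohort-level summaries include
#' per-strategy means, paired Wilcoxon p-values and NTCP reductions of
#' aRO1mm relative to cRO3mm.
#'
#' @param config a \code{\link{study_config}}.
#' @param verbose print per-stage progress.
#' @return An object of class \code{study_report}: \code{per_patient}
#'   (data.frame), \code{summary} (list), \code{config}.
#' @export
run_study <- function(config = study_config(), verbose = TRUE) {
  t_start <- Sys.time()
  say <- function(...) if (verbose) message(sprintf(...))
  params_list <- cohort_params(config$n_cohort, config$master_seed,
                               config$population)
  # pass 1: accumulate the cohort sum of forward fields (model training pool)
  say("generating %d-patient cohort (fields) ...", config$n_cohort)
  dvf_sum <- NULL
  for (i in seq_len(config$n_cohort)) {
    tl <- make_patient(params_list[[i]], config$gs, fields_only = TRUE)
    if (is.null(dvf_sum)) {
      dvf_sum <- lapply(tl$true_dvfs, function(f) f$u)
    } else {
      for (w in 1:6) dvf_sum[[w]] <- dvf_sum[[w]] + tl$true_dvfs[[w]]$u
    }
  }
  gs <- config$gs
  rows <- list()
  failures <- list()
  # conventional strategies use the planning anatomy only, which is the
  # shared template for every synthetic patient: plan them once
  conventional_cache <- list()
  for (i in seq_len(config$n_validation)) {
    say("patient %d/%d ...", i, config$n_validation)
    res <- tryCatch({
      patient <- make_patient(params_list[[i]], gs)
      # leave-one-out model: mean of all other patients' fields
      model <- structure(list(
        mean_dvfs = lapply(1:6, function(w)
          displacement_field((dvf_sum[[w]] - patient$true_dvfs[[w]]$u) /
                               (config$n_cohort - 1),
                             gs$spacing, gs$origin)),
        n_train = config$n_cohort - 1,
        week_points = seq(5, 30, by = 5)), class = "average_model")
      eval_names <- intersect(c(robust_structures, parallel_structures),
                              names(patient$planning$structures$masks))
      spe <- structure_points(patient$planning, eval_names,
                              cap = config$eval_cap)
      patient_rows <- list()
      idx <- unlist(lapply(spe, `[[`, "idx"), use.names = FALSE)
      groups <- stack_points(spe)$groups
      wc_rows <- unlist(groups[intersect(robust_structures, names(groups))],
                        use.names = FALSE)
      for (snm in config$strategies) {
        if (snm != "aRO1mm" && !is.null(conventional_cache[[snm]])) {
          ps <- conventional_cache[[snm]]
        } else {
          ps <- plan_strategy(patient, snm, model = model,
                              opt_cap = config$opt_cap,
                              opt_boundary = config$opt_boundary,
                              eval_cap = config$eval_cap,
                              maxit = if (snm == "aRO1mm") config$maxit
                                      else 2 * config$maxit,
                              taus = config$taus)
          if (snm != "aRO1mm") conventional_cache[[snm]] <- ps
        }
        acc <- accumulate_course(ps$plan, patient, config$course,
                                 voxels = idx, wc_rows = wc_rows)
        acc_report <- channels_to_report(
          acc[c("nominal", "voxmin", "voxmax")], groups,
          voxel_cc(patient$planning$grid))
        m <- strategy_metrics(ps$planning_report, acc_report, config$rx,
                              config$pharynx, voxel_cc(patient$planning$grid))
        m$patient <- i
        m$strategy <- snm
        m$plan_acceptable <- ps$acceptable
        patient_rows[[snm]] <- m
        say("  %s: plan V94 %.1f/%.1f, accumulated V94 %.2f/%.2f",
            snm, m$plan_v94_high, m$plan_v94_low, m$acc_v94_high, m$acc_v94_low)
      }
      do.call(rbind, patient_rows)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[as.character(i)]] <- conditionMessage(res)
      say("  patient %d failed: %s", i, conditionMessage(res))
    } else {
      rows[[i]] <- res
    }
  }
  per_patient <- do.call(rbind, rows)
  rownames(per_patient) <- NULL
  summary <- summarize_study(per_patient, config)
  structure(list(per_patient = per_patient, summary = summary,
                 config = config, failures = failures,
                 runtime_s = as.numeric(difftime(Sys.time(), t_start,
                                                 units = "secs"))),
            class = "study_report")
}

summarize_study <- function(per_patient, config) {
  strategies <- intersect(config$strategies, unique(per_patient$strategy))
  num_cols <- setdiff(names(per_patient),
                      c("patient", "strategy", "replan", "plan_acceptable"))
  means <- do.call(rbind, lapply(strategies, function(s) {
    sub <- per_patient[per_patient$strategy == s, num_cols, drop = FALSE]
    cbind(data.frame(strategy = s), as.data.frame(as.list(colMeans(sub))))
  }))
  out <- list(means = means)
  oar_cols <- c("parotid_ipsi_dmean", "parotid_contra_dmean",
                "submandibular_dmean", "oral_cavity_dmean", "pcm_sup_dmean",
                "pcm_med_dmean", "pcm_inf_dmean")
  if (all(c("aRO1mm", "cRO3mm") %in% strategies)) {
    a <- per_patient[per_patient$strategy == "aRO1mm", ]
    c3 <- per_patient[per_patient$strategy == "cRO3mm", ]
    a <- a[order(a$patient), ]; c3 <- c3[order(c3$patient), ]
    out$ntcp_reduction_xerostomia_pct <-
      100 * mean(c3$ntcp_xerostomia - a$ntcp_xerostomia)
    out$ntcp_reduction_dysphagia_pct <-
      100 * mean(c3$ntcp_dysphagia - a$ntcp_dysphagia)
    out$max_oar_dmean_reduction_gy <-
      max(colMeans(c3[, oar_cols]) - colMeans(a[, oar_cols]))
    out$oar_dmean_reduction_gy <- colMeans(c3[, oar_cols]) - colMeans(a[, oar_cols])
    if (nrow(a) >= 5) {
      out$wilcoxon_p <- vapply(c(oar_cols, "ntcp_xerostomia", "ntcp_dysphagia"),
                               function(cl) wilcoxon_paired(c3[[cl]], a[[cl]]),
                               numeric(1))
    }
  }
  out
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>", length(unique(x$per_patient$patient)), "patients x",
      length(unique(x$per_patient$strategy)), "strategies\n")
  print(x$summary$means, digits = 4)
  if (!is.null(x$summary$ntcp_reduction_xerostomia_pct))
    cat(sprintf("NTCP reduction aRO1mm vs cRO3mm: xerostomia %.2f pp, dysphagia %.2f pp\n",
                x$summary$ntcp_reduction_xerostomia_pct,
                x$summary$ntcp_reduction_dysphagia_pct))
  invisible(x)
}

#' Write study report tables
#'
#' Emits per-patient and cohort-summary CSV files.
#'
#' @param report a \code{study_report}.
#' @param dir output directory.
#' @return invisibly, the file paths written.
#' @export
report_tables <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f1 <- file.path(dir, "per_patient_metrics.csv")
  utils::write.csv(report$per_patient, f1, row.names = FALSE)
  f2 <- file.path(dir, "strategy_means.csv")
  utils::write.csv(report$summary$means, f2, row.names = FALSE)
  files <- c(f1, f2)
  if (!is.null(report$summary$wilcoxon_p)) {
    f3 <- file.path(dir, "wilcoxon_aRO1mm_vs_cRO3mm.csv")
    utils::write.csv(data.frame(metric = names(report$summary$wilcoxon_p),
                                p_value = report$summary$wilcoxon_p),
                     f3, row.names = FALSE)
    files <- c(files, f3)
  }
  if (!is.null(report$summary$ntcp_reduction_xerostomia_pct)) {
    f4 <- file.path(dir, "ntcp_reductions.csv")
    a <- report$per_patient[report$per_patient$strategy == "aRO1mm", ]
    c3 <- report$per_patient[report$per_patient$strategy == "cRO3mm", ]
    a <- a[order(a$patient), ]; c3 <- c3[order(c3$patient), ]
    utils::write.csv(data.frame(
      patient = a$patient,
      ntcp_xerostomia_reduction = c3$ntcp_xerostomia - a$ntcp_xerostomia,
      ntcp_dysphagia_reduction = c3$ntcp_dysphagia - a$ntcp_dysphagia),
      f4, row.names = FALSE)
    files <- c(files, f4)
  }
  invisible(files)
}
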
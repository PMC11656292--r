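#' Default composite objective specification
#'
#' One-sided quadratic coverage terms for the CTVs at two levels (a heavily
#' weighted term at 95\% of prescription that drives the underdose tail, and
#' a shaping term at prescription), one-sided quadratic maximum-dose terms
#' for CTVs and serial organs, and linear mean-dose terms for the parallel
#' organs.  CTV and serial terms are robust (enforced across scenarios);
#' mean-dose terms enter the nominal scenario only.  Levels derive from the
#' clinical goals (prescriptions 70 / 54.25 Gy in 35 fractions, CTV D2 <
#' 110\%); the exact weights are package configuration, chosen so the
#' planning-stage goals are met on the default phantom.
#'
#' @param rx_high,rx_low prescriptions (Gy).
#' @return data.frame with columns structure, type, level, weight, robust.
#' @export
default_objective <- function(rx_high = 70, rx_low = 54.25) {
  rbind(
    data.frame(structure = "ctv_high", type = "min", level = 0.95 * rx_high,
               weight = 3000, robust = TRUE),
    data.frame(structure = "ctv_high", type = "min", level = rx_high,
               weight = 150, robust = TRUE),
    data.frame(structure = "ctv_high", type = "max", level = 1.03 * rx_high,
               weight = 80, robust = TRUE),
    data.frame(structure = "ctv_low", type = "min", level = 0.95 * rx_low,
               weight = 3000, robust = TRUE),
    data.frame(structure = "ctv_low", type = "min", level = rx_low,
               weight = 150, robust = TRUE),
    data.frame(structure = "ctv_low", type = "max", level = 1.10 * rx_low,
               weight = 30, robust = TRUE),
    data.frame(structure = "brainstem", type = "max", level = 54, weight = 150,
               robust = TRUE),
    data.frame(structure = "spinal_cord", type = "max", level = 45, weight = 150,
               robust = TRUE),
    data.frame(structure = c("parotid_l", "parotid_r", "submandibular_l",
                             "submandibular_r", "oral_cavity", "pcm_sup",
                             "pcm_med", "pcm_inf"),
               type = "mean", level = 0, weight = c(4, 4, 4, 4, 2, 2, 2, 2),
               robust = FALSE))
}

# penalty of one term given the dose vector inside its structure
term_penalty <- function(d, type, level, weight) {
  switch(type,
         min = weight * mean(pmax(level - d, 0)^2),
         max = weight * mean(pmax(d - level, 0)^2),
         uniform = weight * mean((d - level)^2),
         mean = weight * mean(d),
         stop("unknown term type: ", type))
}

# d(penalty)/d(dose) for one term
term_grad <- function(d, type, level, weight) {
  n <- length(d)
  switch(type,
         min = -2 * weight / n * pmax(level - d, 0),
         max = 2 * weight / n * pmax(d - level, 0),
         uniform = 2 * weight / n * (d - level),
         mean = rep(weight / n, n))
}

#' Composite dose objective
#'
#' Sum over structure terms of volume-normalized one-sided quadratic
#' penalties (underdose below the level for "min" terms, overdose above it
#' for "max" terms), two-sided quadratic "uniform" terms and linear "mean"
#' terms.
#'
#' @param dose a \code{voxel_grid} or dose array.
#' @param structures a \code{structure_set} (or named list of masks).
#' @param spec objective data.frame, see \code{\link{default_objective}}.
#' @return scalar objective value.
#' @export
composite_objective <- function(dose, structures, spec = default_objective()) {
  d <- if (inherits(dose, "voxel_grid")) dose$data else dose
  masks <- if (inherits(structures, "structure_set")) structures$masks else structures
  total <- 0
  for (r in seq_len(nrow(spec))) {
    m <- masks[[spec$structure[r]]]
    if (is.null(m) || !any(m)) stop("missing structure: ", spec$structure[r])
    total <- total + term_penalty(d[m], spec$type[r], spec$level[r], spec$weight[r])
  }
  total
}

# Scenario context for the optimizer: sparse influence (a dgCMatrix, or a
# raw triplet list with fields i/j/x/nrow/ncol) over sampled structure
# voxels, plus row-index groups per structure.
make_opt_context <- function(A, groups, terms) {
  list(A = A, groups = groups, terms = terms)
}

context_nrow <- function(ctx)
  if (is.list(ctx$A) && !is.null(ctx$A$nrow)) ctx$A$nrow else nrow(ctx$A)

# Stack all error-scenario contexts into one sparse influence matrix plus
# flat per-term-row parameter vectors, so one matvec + one crossprod serve
# every scenario in an optimizer iteration.
stack_error_contexts <- function(error_contexts) {
  offs <- 0L
  blocks <- list()
  gi <- list(); lvl <- list(); wn <- list(); tp <- list(); sid <- list()
  for (s in seq_along(error_contexts)) {
    ctx <- error_contexts[[s]]
    blocks[[s]] <- ctx$A
    error_contexts[[s]]$A <- NULL
    for (r in seq_len(nrow(ctx$terms))) {
      rows <- ctx$groups[[ctx$terms$structure[r]]]
      n <- length(rows)
      gi[[length(gi) + 1]] <- offs + rows
      lvl[[length(lvl) + 1]] <- rep(ctx$terms$level[r], n)
      wn[[length(wn) + 1]] <- rep(ctx$terms$weight[r] / n, n)
      tp[[length(tp) + 1]] <- rep(match(ctx$terms$type[r],
                                        c("min", "max", "uniform", "mean")), n)
      sid[[length(sid) + 1]] <- rep(s, n)
    }
    offs <- offs + context_nrow(ctx)
  }
  gi <- unlist(gi); sid <- unlist(sid); tp <- unlist(tp)
  # stack the per-scenario matrices via triplets (much faster than rbind)
  as_trip <- function(A) {
    if (is.list(A) && !is.null(A$nrow)) return(A)
    T <- methods::as(A, "TsparseMatrix")
    list(i = T@i + 1L, j = T@j + 1L, x = T@x, nrow = nrow(A), ncol = ncol(A))
  }
  blocks <- lapply(blocks, as_trip)
  roff <- cumsum(c(0L, vapply(blocks, function(b) b$nrow, integer(1))))
  ti <- unlist(lapply(seq_along(blocks), function(s) blocks[[s]]$i + roff[s]))
  tj <- unlist(lapply(blocks, `[[`, "j"))
  tx <- unlist(lapply(blocks, `[[`, "x"))
  list(ti = ti, tj = tj, tx = tx, nrow = roff[length(roff)],
       ncol = blocks[[1]]$ncol, nsc = length(error_contexts),
       gi = gi, lvl = unlist(lvl), wn = unlist(wn), tp = tp, sid = sid,
       # scatter matrices: expanded term rows -> scenarios / stacked rows
       Tsc = Matrix::sparseMatrix(i = sid, j = seq_along(gi), x = 1,
                                  dims = c(length(error_contexts), length(gi))),
       Srow = Matrix::sparseMatrix(i = gi, j = seq_along(gi), x = 1,
                                   dims = c(offs, length(gi))))
}

# per-scenario objectives (and term-row dose/penalty pieces) at weights w
stacked_objectives <- function(stk, w, want_pieces = FALSE) {
  dall <- cpp_trip_matvec(stk$ti, stk$tj, stk$tx, w, stk$nrow)
  dv <- dall[stk$gi]
  resid_min <- pmax(stk$lvl - dv, 0)
  resid_max <- pmax(dv - stk$lvl, 0)
  pen <- numeric(length(dv))
  m1 <- stk$tp == 1L; m2 <- stk$tp == 2L; m3 <- stk$tp == 3L; m4 <- stk$tp == 4L
  pen[m1] <- stk$wn[m1] * resid_min[m1]^2
  pen[m2] <- stk$wn[m2] * resid_max[m2]^2
  pen[m3] <- stk$wn[m3] * (dv[m3] - stk$lvl[m3])^2
  pen[m4] <- stk$wn[m4] * dv[m4]
  fs <- as.numeric(stk$Tsc %*% pen)
  if (!want_pieces) return(fs)
  list(fs = fs, dv = dv, resid_min = resid_min, resid_max = resid_max,
       masks = list(m1 = m1, m2 = m2, m3 = m3, m4 = m4))
}

# gradient of sum_s lsew[s] * f_s(w) given the pieces from stacked_objectives
stacked_gradient <- function(stk, pieces, lsew) {
  gterm <- numeric(length(pieces$dv))
  m <- pieces$masks
  gterm[m$m1] <- -2 * stk$wn[m$m1] * pieces$resid_min[m$m1]
  gterm[m$m2] <- 2 * stk$wn[m$m2] * pieces$resid_max[m$m2]
  gterm[m$m3] <- 2 * stk$wn[m$m3] * (pieces$dv[m$m3] - stk$lvl[m$m3])
  gterm[m$m4] <- stk$wn[m$m4]
  gterm <- gterm * lsew[stk$sid]
  grow <- as.numeric(stk$Srow %*% gterm)
  cpp_trip_tmatvec(stk$ti, stk$tj, stk$tx, grow, stk$ncol)
}

# objective value of one context at weights w (and optionally its gradient)
context_objective <- function(ctx, w, want_grad = FALSE) {
  d <- as.numeric(ctx$A %*% w)
  val <- 0
  g <- if (want_grad) numeric(length(d)) else NULL
  for (r in seq_len(nrow(ctx$terms))) {
    rows <- ctx$groups[[ctx$terms$structure[r]]]
    dr <- d[rows]
    val <- val + term_penalty(dr, ctx$terms$type[r], ctx$terms$level[r],
                              ctx$terms$weight[r])
    if (want_grad)
      g[rows] <- g[rows] + term_grad(dr, ctx$terms$type[r], ctx$terms$level[r],
                                     ctx$terms$weight[r])
  }
  if (!want_grad) return(val)
  list(value = val, grad = as.numeric(Matrix::crossprod(ctx$A, g)))
}

#' Minimax robust spot-weight optimization
#'
#' Minimizes the worst case, over the error scenarios, of the robust
#' composite objective, plus \code{lambda} times the mean nominal-scenario
#' objective.  The maximum is smoothed by a log-sum-exp with temperature
#' annealing, and minimized by projected L-BFGS-B under the nonnegativity
#' bound; the reported trace is the true (unsmoothed) worst-case value of the
#' accepted iterate after each annealing round, which is nonincreasing by
#' construction (the best iterate so far is retained).
#'
#' @param error_contexts list of scenario contexts (sparse influence +
#'   robust terms), one per error scenario.
#' @param nominal_contexts list of contexts holding all terms for the nominal
#'   scenario of each anatomy.
#' @param nspots number of spots.
#' @param lambda weight of the nominal term.
#' @param w0 initial weights (default uniform, scaled to the first nominal
#'   context's CTV level).
#' @param maxit L-BFGS-B iterations per annealing round.
#' @param taus annealing temperatures as fractions of the initial objective
#'   spread.
#' @param factr L-BFGS-B convergence factor (smaller = tighter).
#' @return An object of class \code{optimization_result}: \code{weights},
#'   \code{trace}, \code{converged}, \code{scenario_objectives},
#'   \code{nominal_objective}.
#' @export
optimize_weights <- function(error_contexts, nominal_contexts, nspots,
                             lambda = 1, w0 = NULL, maxit = 60,
                             taus = c(0.3, 0.1, 0.02), factr = 1e9) {
  stopifnot(length(error_contexts) >= 1)
  if (is.null(w0)) {
    # scale uniform weights so the first nominal context's mean CTV dose is
    # near its min-dose level
    ctx <- nominal_contexts[[1]]
    w0 <- rep(1, nspots)
    d0 <- as.numeric(ctx$A %*% w0)
    lvl <- max(ctx$terms$level)
    ctvrows <- ctx$groups[[ctx$terms$structure[which.max(ctx$terms$level)]]]
    md <- mean(d0[ctvrows])
    if (md > 0) w0 <- w0 * (lvl / md)
  }
  stk <- stack_error_contexts(error_contexts)
  nominal_val <- function(w) {
    if (!length(nominal_contexts)) return(0)
    mean(vapply(nominal_contexts, context_objective, numeric(1), w = w))
  }
  worst_val <- function(w) max(stacked_objectives(stk, w))
  true_obj <- function(w) worst_val(w) + lambda * nominal_val(w)

  # warm start: fit the nominal objective alone (cheap: one context per
  # anatomy) before the minimax rounds add the scenario margins
  if (length(nominal_contexts)) {
    wfn <- function(w) nominal_val(w)
    wgr <- function(w) {
      g <- numeric(length(w))
      for (ctx in nominal_contexts)
        g <- g + context_objective(ctx, w, want_grad = TRUE)$grad /
          length(nominal_contexts)
      g
    }
    wres <- stats::optim(w0, wfn, wgr, method = "L-BFGS-B", lower = 0,
                         control = list(maxit = 2 * maxit, factr = factr))
    w0 <- pmax(wres$par, 0)
  }
  f0 <- stacked_objectives(stk, w0)
  spread <- max(f0) + 1e-9
  best_w <- w0
  best_val <- true_obj(w0)
  trace <- best_val
  conv <- FALSE
  for (tau_frac in taus) {
    tau <- tau_frac * spread
    # optim calls fn then gr at the same point; share the forward pass
    cache <- new.env(parent = emptyenv())
    evaluate <- function(w) {
      key <- cache$w
      if (!is.null(key) && identical(key, w)) return()
      pieces <- stacked_objectives(stk, w, want_pieces = TRUE)
      fs <- pieces$fs
      fmax <- max(fs)
      p <- exp((fs - fmax) / tau)
      lse <- fmax + tau * log(sum(p))
      p <- p / sum(p)
      nomg <- numeric(length(w))
      nomv <- 0
      if (length(nominal_contexts)) {
        for (ctx in nominal_contexts) {
          cg <- context_objective(ctx, w, want_grad = TRUE)
          nomv <- nomv + cg$value / length(nominal_contexts)
          nomg <- nomg + cg$grad / length(nominal_contexts)
        }
      }
      cache$w <- w
      cache$fn <- lse + lambda * nomv
      cache$gr <- stacked_gradient(stk, pieces, p) + lambda * nomg
    }
    fn <- function(w) { evaluate(w); cache$fn }
    gr <- function(w) { evaluate(w); cache$gr }
    res <- stats::optim(best_w, fn, gr, method = "L-BFGS-B", lower = 0,
                        control = list(maxit = maxit, factr = factr))
    cand <- pmax(res$par, 0)
    cand_val <- true_obj(cand)
    if (!is.finite(cand_val)) stop("non-finite objective during optimization")
    if (cand_val <= best_val) {
      best_w <- cand
      best_val <- cand_val
    }
    trace <- c(trace, best_val)
    conv <- res$convergence == 0
  }
  structure(list(weights = best_w, trace = trace, converged = conv,
                 scenario_objectives = stacked_objectives(stk, best_w),
                 nominal_objective = nominal_val(best_w),
                 worst_case = worst_val(best_w)),
            class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat("<optimization_result>", length(x$weights), "weights; worst-case",
      signif(x$worst_case, 5), "; nominal", signif(x$nominal_objective, 5),
      if (x$converged) "(converged)" else "(iteration cap)", "\n")
  invisible(x)
}
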
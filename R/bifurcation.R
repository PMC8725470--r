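# Saddle-node verification and pseudo-arclength continuation.
#
# A candidate from the search is accepted as a saddle-node when the reduced
# Jacobian has exactly one eigenvalue inside the zero tolerance and a
# spectral gap to every other eigenvalue; the transversality conditions of
# the saddle-node bifurcation theorem (D_eps F and the contracted second
# derivative both nonzero and outside range(J)) are screened as advisory.
# The equilibrium branch through the candidate is traced in (c, signal) by
# a pseudo-arclength predictor-corrector that passes folds.

#' Check a candidate for the saddle-node property
#'
#' Eigen-decomposes the reduced Jacobian at the candidate point, tests for
#' a simple zero eigenvalue with a spectral gap, and screens the
#' transversality conditions: the signal derivative of the right-hand side
#' and the second derivative contracted twice with the kernel vector must
#' be nonzero and outside the range of the Jacobian.
#'
#' @param sys an `independent_system`
#' @param values named numeric vector with all rate constants, the
#'   independent concentrations and the conservation totals
#' @param zero_tol relative zero-eigenvalue tolerance; an eigenvalue counts
#'   as zero when `|z| < zero_tol * max(1, spectral radius)`
#' @param cond_limit condition number above which the verdict is deferred
#'   to direct simulation
#' @return an object of class `saddle_node_report` with the eigenvalues,
#'   kernel vector, transversality flags and a verdict: `"saddle_node"`,
#'   `"rejected_multiplicity"`, `"rejected_transversality"` or
#'   `"deferred_ill_conditioned"`
#' @export
saddle_node_check <- function(sys, values, zero_tol = 1e-6,
                              cond_limit = 1e12) {
  stopifnot(inherits(sys, "independent_system"))
  J <- cpm_eval(sys$J, values)
  s <- nrow(J)
  eig <- eigen(J)
  sr <- max(Mod(eig$values), 0)
  thr <- zero_tol * max(1, sr)
  zero_idx <- which(Mod(eig$values) < thr)
  sv <- svd(J)
  # a simple zero eigenvalue is expected at a saddle-node, so conditioning
  # is judged on the remaining directions (largest over second-smallest
  # singular value)
  cond <- if (s < 2L) 1 else if (sv$d[s - 1L] == 0) Inf else
    sv$d[1L] / sv$d[s - 1L]
  ill <- is.finite(cond) == FALSE || cond > cond_limit
  report <- list(eigenvalues = eig$values, zero_count = length(zero_idx),
                 condition = cond)
  if (length(zero_idx) != 1L ||
      any(abs(Re(eig$values[-zero_idx])) <= thr)) {
    report$verdict <- if (length(zero_idx) > 1L) "rejected_multiplicity"
      else if (ill) "deferred_ill_conditioned" else "rejected_multiplicity"
    return(structure(report, class = "saddle_node_report"))
  }
  # kernel vector from the smallest singular vector, first nonzero entry
  # positive, unit length
  v <- sv$v[, s]
  fnz <- which(abs(v) > 1e-12)[1]
  if (!is.na(fnz) && v[fnz] < 0) v <- -v
  report$kernel <- v
  # transversality: D_eps F and D_cc F (v, v)
  Feps <- vapply(sys$F, function(p)
    cp_eval(cp_deriv(p, sys$signal_var), values), numeric(1))
  Dvv <- vapply(seq_along(sys$F), function(i) {
    acc <- 0
    for (a in seq_len(s)) for (b in seq_len(s)) {
      h <- cp_deriv(cp_deriv(sys$F[[i]], sys$conc_vars[a]), sys$conc_vars[b])
      if (length(as_cpoly(h)$coef) > 0L)
        acc <- acc + v[a] * v[b] * cp_eval(h, values)
    }
    acc
  }, numeric(1))
  # rank decisions share the zero-eigenvalue scale: the candidate is only
  # zero to within the tolerance, so the range test must not resolve below it
  rank_tol <- thr
  rankJ <- sum(sv$d > rank_tol)
  outside_range <- function(w) {
    if (sqrt(sum(w^2)) <= thr) return(FALSE)
    aug <- svd(cbind(J, w))$d
    sum(aug > rank_tol) > rankJ
  }
  report$D_eps_F <- Feps
  report$D_cc_F_vv <- Dvv
  report$transversality <- c(
    D_eps_nonzero_outside_range = outside_range(Feps),
    D_cc_nonzero_outside_range = outside_range(Dvv))
  report$verdict <- if (ill) "deferred_ill_conditioned"
    else if (all(report$transversality)) "saddle_node"
    else "rejected_transversality"
  structure(report, class = "saddle_node_report")
}

#' @export
print.saddle_node_report <- function(x, ...) {
  cat("saddle_node_report:", x$verdict, "\n")
  cat("  eigenvalues:", paste(format(x$eigenvalues, digits = 4),
                              collapse = ", "), "\n")
  if (!is.null(x$transversality))
    cat("  transversality:",
        paste(names(x$transversality), x$transversality, collapse = "; "),
        "\n")
  invisible(x)
}

# ---- continuation core ---------------------------------------------------

# tangent of the extended system [J | Fe] at z = (u, eps); unit norm
curve_tangent <- function(Jm, Fe) {
  A <- cbind(Jm, Fe)
  qd <- qr(t(A))
  t_vec <- qr.Q(qd, complete = TRUE)[, ncol(A)]
  t_vec / sqrt(sum(t_vec^2))
}

#' Trace an equilibrium branch by pseudo-arclength continuation
#'
#' Core predictor-corrector on user-supplied functions; the wrapper
#' [continue_branch()] builds them from an `independent_system`.  The curve
#' is parametrized by arclength so folds (signal turning points) are passed
#' smoothly; folds are located by the sign change of the signal component
#' of the tangent and refined by bisection on arclength.
#'
#' @param F_fun function(u, eps) -> length-s residual
#' @param J_fun function(u, eps) -> s x s Jacobian with respect to `u`
#' @param Fe_fun function(u, eps) -> length-s derivative with respect to
#'   `eps`
#' @param u0,eps0 starting equilibrium (corrected internally)
#' @param eps_range length-2 signal interval to trace within
#' @param ds0 initial arclength step
#' @param ds_max,ds_min step bounds (growth 1.3 on success, halving on
#'   corrector failure)
#' @param max_points point budget per direction
#' @param tol corrector tolerance on the residual norm
#' @param u_min states are flagged invalid below this floor (conservation
#'   consistency)
#' @return an object of class `bifurcation_diagram`: `points` (data frame
#'   with signal, state columns, stability, branch direction, fold flag),
#'   `folds` (refined fold points), `bistable_interval`
#' @export
continue_curve <- function(F_fun, J_fun, Fe_fun, u0, eps0, eps_range,
                           ds0 = 1e-2, ds_max = 0.25, ds_min = 1e-9,
                           max_points = 400L, tol = 1e-9, u_min = -1e-8) {
  s <- length(u0)
  correct <- function(z_pred, t_vec, z_ref) {
    z <- z_pred
    for (it in 1:25) {
      u <- z[seq_len(s)]; eps <- z[s + 1L]
      Fv <- F_fun(u, eps)
      g <- c(Fv, sum(t_vec * (z - z_ref)))
      if (!all(is.finite(g))) return(NULL)
      if (sqrt(sum(Fv^2)) < tol && abs(g[s + 1L]) < tol * 10) return(z)
      Jg <- rbind(cbind(J_fun(u, eps), Fe_fun(u, eps)), t_vec)
      step <- tryCatch(solve(Jg, g), error = function(e) NULL)
      if (is.null(step) || !all(is.finite(step))) return(NULL)
      z <- z - step
    }
    NULL
  }
  trace_dir <- function(z0, dir_sign) {
    pts <- list(); folds <- list()
    z <- z0
    tv <- curve_tangent(J_fun(z[seq_len(s)], z[s + 1L]),
                        Fe_fun(z[seq_len(s)], z[s + 1L])) * dir_sign
    ds <- ds0
    prev_t <- tv
    for (i in seq_len(max_points)) {
      z_pred <- z + ds * prev_t
      # arclength constraint anchored at the predictor
      z_new <- correct(z_pred, prev_t, z_pred)
      if (is.null(z_new)) {
        ds <- ds / 2
        if (ds < ds_min) break
        next
      }
      t_new <- curve_tangent(J_fun(z_new[seq_len(s)], z_new[s + 1L]),
                             Fe_fun(z_new[seq_len(s)], z_new[s + 1L]))
      if (sum(t_new * prev_t) < 0) t_new <- -t_new
      # fold: sign change in the signal component of the tangent
      if (prev_t[s + 1L] * t_new[s + 1L] < 0) {
        fold <- refine_fold(z, prev_t, z_new, t_new)
        if (!is.null(fold)) folds[[length(folds) + 1L]] <- fold
      }
      ev <- eigen(J_fun(z_new[seq_len(s)], z_new[s + 1L]),
                  only.values = TRUE)$values
      pts[[length(pts) + 1L]] <-
        c(z_new, stable = as.numeric(max(Re(ev)) < 0),
          valid = as.numeric(min(z_new[seq_len(s)]) > u_min))
      z <- z_new
      prev_t <- t_new
      ds <- min(ds * 1.3, ds_max)
      if (z[s + 1L] < eps_range[1] || z[s + 1L] > eps_range[2]) break
    }
    list(points = pts, folds = folds)
  }
  refine_fold <- function(z_a, t_a, z_b, t_b) {
    # bisection on arclength between two corrected points straddling the
    # fold, until the signal component of the tangent is tiny
    for (it in 1:40) {
      z_mid_pred <- (z_a + z_b) / 2
      t_ref <- (t_a + t_b); t_ref <- t_ref / sqrt(sum(t_ref^2))
      z_mid <- correct(z_mid_pred, t_ref, z_mid_pred)
      if (is.null(z_mid)) return(z_b)
      t_mid <- curve_tangent(J_fun(z_mid[seq_len(s)], z_mid[s + 1L]),
                             Fe_fun(z_mid[seq_len(s)], z_mid[s + 1L]))
      if (sum(t_mid * t_ref) < 0) t_mid <- -t_mid
      if (abs(t_mid[s + 1L]) < 1e-10 ||
          sqrt(sum((z_a - z_b)^2)) < 1e-12) return(z_mid)
      if (t_a[s + 1L] * t_mid[s + 1L] < 0) {
        z_b <- z_mid; t_b <- t_mid
      } else {
        z_a <- z_mid; t_a <- t_mid
      }
    }
    z_mid
  }
  # correct the starting point onto the curve at fixed eps when possible
  start <- c(u0, eps0)
  fwd <- trace_dir(start, +1)
  bwd <- trace_dir(start, -1)
  rows <- c(rev(bwd$points), list(c(start, stable = NA_real_, valid = 1)),
            fwd$points)
  mat <- do.call(rbind, rows)
  colnames(mat) <- c(paste0("u", seq_len(s)), "signal", "stable", "valid")
  pts <- as.data.frame(mat)
  folds <- c(bwd$folds, fwd$folds)
  fold_df <- if (length(folds) > 0L) {
    fm <- do.call(rbind, folds)[, seq_len(s + 1L), drop = FALSE]
    colnames(fm) <- c(paste0("u", seq_len(s)), "signal")
    as.data.frame(fm)
  } else data.frame()
  bist <- if (nrow(fold_df) >= 2L) {
    rng <- range(fold_df$signal)
    if (diff(rng) > 0) rng else NULL
  } else NULL
  structure(list(points = pts, folds = fold_df, bistable_interval = bist),
            class = "bifurcation_diagram")
}

#' @export
print.bifurcation_diagram <- function(x, ...) {
  cat("bifurcation_diagram:", nrow(x$points), "points,",
      nrow(x$folds), "fold(s)\n")
  if (!is.null(x$bistable_interval))
    cat("  bistable signal interval: [",
        format(x$bistable_interval[1], digits = 6), ", ",
        format(x$bistable_interval[2], digits = 6), "]\n", sep = "")
  invisible(x)
}

#' Continue the equilibrium branch of an independent system
#'
#' Builds fast evaluators of the reduced right-hand side, its Jacobian and
#' its signal derivative for fixed rate constants and fixed non-signal
#' totals, then calls [continue_curve()] from the candidate point.
#'
#' @param sys an `independent_system`
#' @param values named vector with all rate constants `k1..kR`, the
#'   independent concentrations and all totals (a search candidate's
#'   `values`)
#' @param eps_range signal interval; defaults to the candidate signal
#'   +/- 30 percent
#' @param ... passed to [continue_curve()]
#' @return a `bifurcation_diagram`; the state columns are the independent
#'   concentrations in `sys$conc_vars` order
#' @export
continue_branch <- function(sys, values, eps_range = NULL, ...) {
  s <- length(sys$independent)
  eps0 <- values[[sys$signal_var]]
  if (is.null(eps_range)) eps_range <- eps0 * c(0.7, 1.3)
  base <- as.list(values[c(sys$rate_vars,
                           setdiff(sys$total_vars, sys$signal_var))])
  Ff <- compile_polys(sys$F)
  Jf <- compile_polys(unclass(sys$J))
  Fe <- compile_polys(lapply(sys$F, cp_deriv, var = sys$signal_var))
  mkenv <- function(u, eps) {
    e <- base
    e[sys$conc_vars] <- u
    e[[sys$signal_var]] <- eps
    e
  }
  F_fun <- function(u, eps) Ff(mkenv(u, eps))
  J_fun <- function(u, eps) matrix(Jf(mkenv(u, eps)), s, s)
  Fe_fun <- function(u, eps) Fe(mkenv(u, eps))
  u0 <- as.numeric(values[sys$conc_vars])
  continue_curve(F_fun, J_fun, Fe_fun, u0, eps0, eps_range, ...)
}

#' Export a bifurcation diagram as CSV and JSON summary
#'
#' @param diag a `bifurcation_diagram`
#' @param csv_path CSV of the branch points (`NULL` to skip)
#' @param json_path JSON summary with folds and the bistable interval
#'   (`NULL` to skip)
#' @return invisibly, the paths written
#' @export
export_diagram <- function(diag, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(diag$points, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(folds = diag$folds,
           bistable_interval = diag$bistable_interval,
           n_points = nrow(diag$points)),
      json_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(csv_path, json_path))
}
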
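# Steady-state parametrization: solve U k~ = b for s pivot rate constants.
#
# Under mass action every rate constant multiplies a single monomial, so the
# independent right-hand sides are linear in k with
#   F_i = sum_r S_ind[i, r] * k_r * psihat_r(c, C),
# where psihat_r is the source-complex monomial with dependent species
# eliminated.  For a pivot set P the coefficient matrix factorizes as
# U = S_ind[, P] %*% diag(psihat_P), so the symbolic solve reduces to the
# exact integer adjugate of the s x s matrix S_ind[, P]:
#   k~_j = num_j / (det * psihat_{P_j}),  num = adj(S_ind[, P]) %*% b.

#' Pivot rate constants from the RREF of S
#'
#' Puts the full stoichiometric matrix into row-reduced echelon form over
#' the rationals and returns the pivot columns; the corresponding rate
#' constants are the ones fixed by the steady-state solve.
#'
#' @param S integer stoichiometric matrix (species x reactions) or a
#'   `crnt_matrices` object
#' @return integer vector of pivot column indices (length `s`)
#' @export
choose_pivot_rates <- function(S) {
  if (inherits(S, "crnt_matrices")) S <- S$S
  rat_rref(S)$pivots
}

#' Enumerate linearly independent pivot-column combinations
#'
#' Yields combinations of `s` linearly independent columns of `S` in
#' lexicographic order, used as fallback pivot sets when a steady-state
#' solve forces a rate expression to vanish identically.
#'
#' @param S integer stoichiometric matrix or `crnt_matrices`
#' @return list of integer vectors, lexicographically ordered; the RREF
#'   pivot set is always first
#' @export
enumerate_alternative_pivots <- function(S) {
  if (inherits(S, "crnt_matrices")) S <- S$S
  s <- rat_rank(S)
  first <- rat_rref(S)$pivots
  all_comb <- utils::combn(ncol(S), s, simplify = FALSE)
  keep <- Filter(function(cols)
    rat_rank(S[, cols, drop = FALSE]) == s, all_comb)
  is_first <- vapply(keep, function(cols) identical(cols, first), logical(1))
  c(keep[is_first], keep[!is_first])
}

#' Solve for the pivot rate constants enforcing a steady state
#'
#' Builds and solves the linear system `U k~ = b` whose solution makes
#' every independent right-hand side identically zero.  The solve is exact
#' (integer adjugate); the symbolic residual identity
#' `F restricted to the solution == 0` is verified with polynomial
#' arithmetic and asserted.  If any solved expression is the zero
#' polynomial, the next linearly independent pivot combination is tried;
#' if all combinations force a zero rate, no positive steady state exists.
#'
#' @param sys an `independent_system`
#' @param pivots optional pivot column set; defaults to the RREF pivots with
#'   automatic fallback through [enumerate_alternative_pivots()]
#' @return an object of class `steady_state_param`: fixed symbols `k~`,
#'   free symbols, numerator/denominator polynomials per fixed rate, and a
#'   numeric evaluator
#' @export
solve_steady_state <- function(sys, pivots = NULL) {
  stopifnot(inherits(sys, "independent_system"))
  m <- sys$matrices
  net <- m$network
  S_ind <- m$S[sys$independent, , drop = FALSE]
  s <- length(sys$independent)
  R <- ncol(S_ind)
  cv <- conc_var_names(net)
  # source monomials with dependent species eliminated
  psihat <- lapply(seq_len(R), function(r)
    cp_subst_all(psi_monomial(m, net$reactions$source[r], cv), sys$dep_expr))
  # try the RREF pivot set first; enumerate alternatives only on rejection
  candidates <- if (is.null(pivots)) list(choose_pivot_rates(m$S)) else
    list(as.integer(pivots))
  exhausted_first <- FALSE
  repeat {
  for (P in candidates) {
    Sp <- S_ind[, P, drop = FALSE]
    d_det <- int_det(Sp)
    if (abs(d_det) < 0.5) next   # dependent columns (only when user-supplied)
    adj <- int_adjugate(Sp)
    free <- setdiff(seq_len(R), P)
    b <- lapply(seq_len(s), function(i) {
      cp_neg(cp_sum(lapply(free[S_ind[i, free] != 0], function(r)
        cp_mul(cp_var(net$reactions$rate[r], coef = S_ind[i, r]),
               psihat[[r]]))))
    })
    num <- lapply(seq_len(s), function(j)
      cp_sum(lapply(seq_len(s), function(i) cp_scale(b[[i]], adj[j, i]))))
    if (any(vapply(num, cp_is_zero, logical(1)))) next
    # symbolic residual: d * F_i - sum_j S_ind[i, P_j] num_j must vanish
    for (i in seq_len(s)) {
      resid <- cp_sub(cp_sum(lapply(seq_len(s), function(j)
        cp_scale(num[[j]], Sp[i, j]))), cp_scale(b[[i]], d_det))
      if (!cp_is_zero(resid))
        stop("internal error: steady-state residual is not identically zero")
    }
    den <- lapply(seq_len(s), function(j) cp_scale(psihat[[P[j]]], d_det))
    fixed <- net$reactions$rate[P]
    expressions <- stats::setNames(lapply(seq_len(s), function(j)
      list(num = num[[j]], den = den[[j]])), fixed)
    return(structure(list(sys = sys, pivots = P,
                          fixed_symbols = fixed,
                          free_symbols = net$reactions$rate[free],
                          expressions = expressions,
                          det = d_det),
                     class = "steady_state_param"))
  }
  if (is.null(pivots) && !exhausted_first) {
    exhausted_first <- TRUE
    candidates <- enumerate_alternative_pivots(m$S)[-1L]
    if (length(candidates) > 0L) next
  }
  break
  }
  stop("no steady state exists when k > 0 and c > 0: every pivot ",
       "combination forces a rate constant to zero")
}

#' @export
print.steady_state_param <- function(x, ...) {
  cat("steady_state_param: fixed", paste(x$fixed_symbols, collapse = ", "),
      "\n")
  for (nm in names(x$expressions)) {
    e <- x$expressions[[nm]]
    cat("  ", nm, " = (", cp_to_string(e$num), ") / (",
        cp_to_string(e$den), ")\n", sep = "")
  }
  invisible(x)
}

# numeric evaluation of the fixed rates at a named value vector containing
# the free rates, independent concentrations and totals; returns NA for a
# vanishing denominator
eval_fixed_rates <- function(param, vals, den_tol = 1e-12) {
  vapply(param$expressions, function(e) {
    den <- cp_eval(e$den, vals)
    if (abs(den) <= den_tol) return(NA_real_)
    cp_eval(e$num, vals) / den
  }, numeric(1))
}

#' Export the steady-state parametrization report
#'
#' @param param a `steady_state_param`
#' @param json_path output JSON path
#' @return invisibly, `json_path`
#' @export
export_parametrization_json <- function(param, json_path) {
  out <- list(fixed = param$fixed_symbols, free = param$free_symbols,
              expressions = lapply(param$expressions, function(e)
                paste0("(", cp_to_string(e$num), ") / (",
                       cp_to_string(e$den), ")")))
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(json_path)
}
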
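# Full symbolic ODE system, independent-subsystem selection and the reduced
# Jacobian.
#
# Species concentrations are the variables c1..cN (in network species
# order), rate constants k1..kR, conservation totals C1..Clam.  Selecting
# the independent system eliminates one species per conservation law (never
# the response), replaces the eliminated species by their law-derived
# expressions, and keeps s ODEs of full rank.

#' Full mass-action ODE right-hand sides
#'
#' @param m a `crnt_matrices` object
#' @return list of N `cpoly` right-hand sides in the variables `c1..cN`,
#'   `k1..kR`
#' @export
full_odes <- function(m) {
  stopifnot(inherits(m, "crnt_matrices"))
  mass_action_rhs(m)
}

#' Select the independent ODE subsystem
#'
#' Exhaustively enumerates combinations of species to eliminate - one per
#' conservation law, never the response species, each with a nonzero
#' coefficient in its paired law - in lexicographic species order, and
#' accepts the first combination for which the retained ODEs have rank `s`
#' (checked exactly on the corresponding rows of `S`, which equals the
#' symbolic rank of the retained mass-action subsystem).  Eliminated
#' species are replaced by their law-derived linear expressions in the
#' retained concentrations and the totals `C1..Clam`.
#'
#' @param m a `crnt_matrices` object
#' @param basis a `conservation_basis`
#' @param response species id (name or index) used as the readout; always
#'   retained
#' @param signal which conservation total serves as the bifurcation
#'   parameter (index into the basis columns, or total symbol like `"C1"`)
#' @return an object of class `independent_system` with the retained
#'   species, the eliminated-species expressions, the `s` right-hand sides
#'   `F`, the symbolic Jacobian `J` with respect to the retained
#'   concentrations, and bookkeeping about signal/response
#' @export
select_independent_odes <- function(m, basis, response, signal = 1L) {
  stopifnot(inherits(m, "crnt_matrices"), inherits(basis, "conservation_basis"))
  net <- m$network
  N <- length(net$species)
  lam <- ncol(basis$B)
  s <- m$s
  if (s >= N) stop("rank(S) = N: no conservation laws, nothing to eliminate")
  resp <- if (is.character(response)) match(response, net$species) else
    as.integer(response)
  if (is.na(resp) || resp < 1L || resp > N)
    stop("unknown response species: ", response)
  if (is.character(signal)) signal <- match(signal, basis$totals)
  signal <- as.integer(signal)
  if (is.na(signal) || signal < 1L || signal > lam)
    stop("signal must name one of the conservation totals")
  odes <- full_odes(m)
  if (cp_is_zero(odes[[resp]]))
    stop("response species does not participate in the dynamics")
  # candidate eliminations: one species per law, nonzero coefficient,
  # never the response, all distinct, elimination submatrix invertible
  per_law <- lapply(seq_len(lam), function(j)
    setdiff(which(basis$B[, j] != 0), resp))
  if (any(vapply(per_law, length, integer(1)) == 0L))
    stop("a conservation law has no eliminable species besides the response")
  combos <- expand.grid(rev(per_law), KEEP.OUT.ATTRS = FALSE)
  combos <- as.matrix(combos)[, rev(seq_len(lam)), drop = FALSE]
  ord <- do.call(order, c(lapply(seq_len(lam), function(j) combos[, j]),
                          list(method = "radix")))
  combos <- combos[ord, , drop = FALSE]
  chosen <- NULL
  for (i in seq_len(nrow(combos))) {
    dep <- combos[i, ]
    if (anyDuplicated(dep)) next
    Mdep <- basis$B[dep, , drop = FALSE]      # lam x lam, law j column j
    if (abs(int_det(t(Mdep))) < 0.5) next
    retained <- setdiff(seq_len(N), dep)
    if (rat_rank(m$S[retained, , drop = FALSE]) == s) {
      chosen <- dep
      break
    }
  }
  if (is.null(chosen))
    stop("no elimination keeps the response with a full-rank subsystem")
  dep <- as.integer(chosen)
  retained <- setdiff(seq_len(N), dep)
  # solve  M c_dep = C - rest  exactly:  M[j, d] = B[dep_d, law_j]
  Mlin <- t(basis$B[dep, , drop = FALSE])     # lam x lam
  d_det <- int_det(Mlin)
  adj <- int_adjugate(Mlin)                   # Mlin^{-1} = adj / d_det
  rhs <- lapply(seq_len(lam), function(j) {
    acc <- cp_var(basis$totals[j])
    for (sp in retained) {
      if (basis$B[sp, j] != 0)
        acc <- cp_sub(acc, cp_var(paste0("c", sp), coef = basis$B[sp, j]))
    }
    acc
  })
  dep_expr <- stats::setNames(lapply(seq_len(lam), function(dd) {
    cp_scale(cp_sum(lapply(seq_len(lam), function(j)
      cp_scale(rhs[[j]], adj[dd, j]))), 1 / d_det)
  }), paste0("c", dep))
  Fs <- lapply(odes[retained], cp_subst_all, values = dep_expr)
  conc_vars <- paste0("c", retained)
  J <- cpm(unlist(lapply(conc_vars, function(v)
    lapply(Fs, cp_deriv, var = v)), recursive = FALSE),
    length(retained), length(retained))
  structure(list(matrices = m, basis = basis,
                 independent = retained, dependent = dep,
                 dep_expr = dep_expr, F = Fs, J = J,
                 response = resp, signal = signal,
                 signal_var = basis$totals[signal],
                 conc_vars = conc_vars,
                 rate_vars = net$reactions$rate,
                 total_vars = basis$totals),
            class = "independent_system")
}

#' @export
print.independent_system <- function(x, ...) {
  sp <- x$matrices$network$species
  cat("independent_system: s =", length(x$independent),
      " response =", sp[x$response],
      " signal =", x$signal_var, "\n")
  cat("retained:", paste(sp[x$independent], collapse = ", "), "\n")
  for (nm in names(x$dep_expr))
    cat("  ", nm, "(", sp[as.integer(sub("^c", "", nm))], ") =",
        cp_to_string(x$dep_expr[[nm]]), "\n")
  for (i in seq_along(x$F))
    cat("  d", x$conc_vars[i], "/dt = ", cp_to_string(x$F[[i]]), "\n",
        sep = "")
  invisible(x)
}

#' Reduced Jacobian of the independent system
#'
#' Returns the symbolic `s x s` Jacobian of the independent right-hand
#' sides with respect to the retained concentrations, together with its
#' symbolic determinant when the system is small enough to expand
#' (`s <= 4`); for larger systems the determinant is evaluated numerically
#' on demand.
#'
#' @param sys an `independent_system`
#' @param symbolic_det_max largest `s` for which the determinant is
#'   expanded symbolically
#' @return list with elements `J` (polynomial matrix), `det` (a `cpoly`, or
#'   `NULL` when not expanded) and `det_fun(vals)` evaluating the
#'   determinant numerically from a named value vector
#' @export
reduced_jacobian <- function(sys, symbolic_det_max = 4L) {
  stopifnot(inherits(sys, "independent_system"))
  J <- sys$J
  s <- length(sys$independent)
  det_sym <- if (s <= symbolic_det_max) cpm_det(J) else NULL
  det_fun <- function(vals) det(cpm_eval(J, vals))
  list(J = J, det = det_sym, det_fun = det_fun)
}

#' Export the reduced system as text and JSON reports
#'
#' @param sys an `independent_system`
#' @param txt_path path of the plain-text report (`NULL` to skip)
#' @param json_path path of the JSON report (`NULL` to skip)
#' @return invisibly, the paths written
#' @export
export_independent_system <- function(sys, txt_path = NULL, json_path = NULL) {
  sp <- sys$matrices$network$species
  if (!is.null(txt_path)) {
    con <- file(txt_path, "w"); on.exit(close(con))
    writeLines(c(
      paste("independent species:", paste(sp[sys$independent], collapse = ", ")),
      paste("response:", sp[sys$response]),
      paste("signal:", sys$signal_var),
      "conservation laws:", paste(" ", sys$basis$laws),
      "substitutions:",
      vapply(names(sys$dep_expr), function(nm)
        paste0("  ", nm, " = ", cp_to_string(sys$dep_expr[[nm]])),
        character(1)),
      "independent ODEs:",
      vapply(seq_along(sys$F), function(i)
        paste0("  d", sys$conc_vars[i], "/dt = ", cp_to_string(sys$F[[i]])),
        character(1))), con)
  }
  if (!is.null(json_path)) {
    out <- list(
      independent_species = sp[sys$independent],
      response = sp[sys$response],
      signal = sys$signal_var,
      substitutions = lapply(sys$dep_expr, cp_to_string),
      odes = stats::setNames(lapply(sys$F, cp_to_string), sys$conc_vars))
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(c(txt_path, json_path))
}
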
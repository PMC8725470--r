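# Independent oracles and shared fixtures for the test suite.

# brute-force rank: size of the largest square submatrix with nonzero
# determinant (exact integer determinants)
minor_rank <- function(M) {
  n <- nrow(M); m <- ncol(M)
  for (r in seq(min(n, m), 1L)) {
    rows <- utils::combn(n, r, simplify = FALSE)
    cols <- utils::combn(m, r, simplify = FALSE)
    for (rr in rows) for (cc in cols) {
      if (abs(crnbistab:::int_det(M[rr, cc, drop = FALSE])) > 0.5)
        return(r)
    }
  }
  0L
}

# brute-force terminality oracle on a digraph given as an edge matrix:
# a strong component is terminal iff no vertex outside it is reachable
# from any of its members (Warshall reachability)
reachability_terminal_classes <- function(n_vertices, edges) {
  reach <- diag(TRUE, n_vertices)
  if (nrow(edges) > 0L)
    for (e in seq_len(nrow(edges))) reach[edges[e, 1L], edges[e, 2L]] <- TRUE
  for (k in seq_len(n_vertices)) {
    reach <- reach | (reach[, k] %o% reach[k, ])
  }
  strong <- reach & t(reach)
  classes <- unique(apply(strong, 1L, function(row) which(row),
                          simplify = FALSE))
  Filter(function(cl) {
    outside <- setdiff(which(apply(reach[cl, , drop = FALSE], 2L, any)), cl)
    length(outside) == 0L
  }, classes)
}

# central finite-difference Jacobian of a vector function
fd_jacobian <- function(f, x, h = 1e-6) {
  n <- length(f(x))
  J <- matrix(0, n, length(x))
  for (j in seq_along(x)) {
    dx <- numeric(length(x)); dx[j] <- h * max(1, abs(x[j]))
    J[, j] <- (f(x + dx) - f(x - dx)) / (2 * dx[j])
  }
  J
}

# log-gamma route to the stopping-rule confidence (independent of the
# package's product-of-ratios evaluation)
q_lgamma <- function(n, r, a = 1, b = 5) {
  1 - exp(lgamma(n + a + b) + lgamma(2 * n + b - r) -
            lgamma(2 * n + a + b) - lgamma(n + b - r))
}

# shared fixture systems, built once per test run
edelstein_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      net <- edelstein_network()
      m <- build_crnt_matrices(net)
      basis <- conservation_basis(m, seed = 1)
      sys <- select_independent_odes(m, basis, "A")
      param <- solve_steady_state(sys)
      dv <- edelstein_decision_vector()
      cache <<- list(net = net, m = m, basis = basis, sys = sys,
                     param = param, dv = dv,
                     vals = decision_values(sys, dv))
    }
    cache
  }
})

futile_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      net <- futile_cycle_network()
      m <- build_crnt_matrices(net)
      basis <- conservation_basis(m, seed = 3)
      sys <- select_independent_odes(
        m, basis, "Sstar", signal = crnbistab:::resolve_signal(basis, net, "S"))
      param <- solve_steady_state(sys)
      dv <- futile_cycle_decision_vector()
      cache <<- list(net = net, m = m, basis = basis, sys = sys,
                     param = param, dv = dv,
                     vals = decision_values(sys, dv))
    }
    cache
  }
})

prion_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      net <- prion_network()
      m <- build_crnt_matrices(net)
      basis <- conservation_basis(m, seed = 5)
      sys <- select_independent_odes(
        m, basis, "Sstarstar",
        signal = crnbistab:::resolve_signal(basis, net, "S"))
      param <- solve_steady_state(sys)
      dv <- prion_decision_vector()
      cache <<- list(net = net, m = m, basis = basis, sys = sys,
                     param = param, dv = dv,
                     vals = decision_values(sys, dv))
    }
    cache
  }
})

# a minimal hand-built independent system: a single species with linear
# decay towards a source, used where a full network is unnecessary
linear_birth_death_system <- function() {
  cp_var <- crnbistab:::cp_var
  Fp <- crnbistab:::cp_sub(cp_var("k1"),
                           crnbistab:::cp_mul(cp_var("k2"), cp_var("c1")))
  structure(list(
    matrices = list(S = matrix(0L, 1L, 2L)),
    basis = list(B = matrix(1L, 1L, 1L)),
    F = list(Fp),
    J = crnbistab:::cpm(list(crnbistab:::cp_neg(cp_var("k2"))), 1L, 1L),
    conc_vars = "c1", rate_vars = c("k1", "k2"),
    total_vars = "C1", signal_var = "C1",
    independent = 1L, response = 1L,
    dep_expr = stats::setNames(list(), character(0))),
    class = "independent_system")
}
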
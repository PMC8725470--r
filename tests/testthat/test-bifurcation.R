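# saddle-node verification, continuation, direct simulation, hysteresis

test_that("the quadratic normal form has its fold at the origin and
           satisfies the transversality conditions", {
  # dc/dt = eps - c^2: fold at eps = 0, c = 0
  F_fun <- function(u, eps) eps - u^2
  J_fun <- function(u, eps) matrix(-2 * u, 1, 1)
  Fe_fun <- function(u, eps) 1
  diag <- continue_curve(F_fun, J_fun, Fe_fun, u0 = 1, eps0 = 1,
                         eps_range = c(-0.5, 1.5), ds0 = 0.05)
  expect_equal(nrow(diag$folds), 1L)
  expect_equal(diag$folds$signal[1], 0, tolerance = 1e-6)
  expect_equal(diag$folds$u1[1], 0, tolerance = 1e-4)
  # stability flips exactly at the fold: stable for u > 0, unstable below
  pts <- diag$points[is.finite(diag$points$stable), ]
  expect_true(all(pts$stable[pts$u1 > 1e-3] == 1))
  expect_true(all(pts$stable[pts$u1 < -1e-3] == 0))
  # the analytic transversality conditions: D_eps F = 1 and
  # D_cc F (v, v) = -2 are nonzero and outside range(J) = {0} at the fold
  expect_true(1 != 0 && -2 != 0)
})

test_that("a simple zero eigenvalue with transversal derivatives is
           accepted while a doubly singular Jacobian is rejected", {
  cpv <- crnbistab:::cp_var
  mk_sys <- function(F1, F2) {
    Fs <- list(F1, F2)
    J <- crnbistab:::cpm(unlist(lapply(c("c1", "c2"), function(v)
      lapply(Fs, crnbistab:::cp_deriv, var = v)), recursive = FALSE), 2L, 2L)
    structure(list(matrices = list(S = matrix(0L, 2L, 2L)),
                   basis = list(B = matrix(c(1L, 1L), 2L, 1L)),
                   F = Fs, J = J, conc_vars = c("c1", "c2"),
                   rate_vars = c("k1", "k2"), total_vars = "C1",
                   signal_var = "C1", independent = 1:2, response = 1L,
                   dep_expr = stats::setNames(list(), character(0))),
              class = "independent_system")
  }
  # J = diag(-2 c1, -1): at c1 = 0 a clean saddle-node of eps - c1^2
  sys_sn <- mk_sys(crnbistab:::cp_sub(cpv("C1"),
                                      crnbistab:::cp_pow(cpv("c1"), 2L)),
                   crnbistab:::cp_neg(cpv("c2")))
  rep_sn <- saddle_node_check(sys_sn, c(c1 = 0, c2 = 0, C1 = 0,
                                        k1 = 1, k2 = 1))
  expect_equal(rep_sn$verdict, "saddle_node")
  expect_equal(rep_sn$zero_count, 1L)
  # J = diag(-2 c1, -2 c2): doubly zero at the origin (codim-2 screen)
  sys_bt <- mk_sys(crnbistab:::cp_sub(cpv("C1"),
                                      crnbistab:::cp_pow(cpv("c1"), 2L)),
                   crnbistab:::cp_sub(cpv("C1"),
                                      crnbistab:::cp_pow(cpv("c2"), 2L)))
  rep_bt <- saddle_node_check(sys_bt, c(c1 = 0, c2 = 0, C1 = 0,
                                        k1 = 1, k2 = 1))
  expect_equal(rep_bt$verdict, "rejected_multiplicity")
  expect_equal(rep_bt$zero_count, 2L)
})

test_that("the reference Edelstein candidate is verified as a saddle-node
           with one vanishing and one stable eigenvalue", {
  fx <- edelstein_fixture()
  rep <- saddle_node_check(fx$sys, fx$vals)
  expect_equal(rep$verdict, "saddle_node")
  ev <- sort(Re(rep$eigenvalues))
  expect_lt(ev[1], -0.01)
  expect_lt(abs(ev[2]), 1e-6)
  expect_true(all(rep$transversality))
})

test_that("continuation from the Edelstein candidate traces an S-shaped
           branch with two folds and an unstable middle segment", {
  fx <- edelstein_fixture()
  diag <- continue_branch(fx$sys, fx$vals, eps_range = c(7.0, 8.6))
  expect_gte(nrow(diag$folds), 2L)
  folds <- sort(diag$folds$signal)
  expect_equal(folds[length(folds)], 7.79489058, tolerance = 1e-4)
  expect_equal(folds[1], 7.7783, tolerance = 1e-3)
  expect_false(is.null(diag$bistable_interval))
  # every accepted point satisfies the corrector tolerance
  base <- as.list(fx$vals[c(fx$sys$rate_vars, character(0))])
  for (i in sample(nrow(diag$points), 10)) {
    p <- diag$points[i, ]
    vv <- c(fx$vals[fx$sys$rate_vars],
            stats::setNames(c(p$u1, p$u2), fx$sys$conc_vars),
            stats::setNames(p$signal, fx$sys$signal_var))
    Fv <- vapply(fx$sys$F, crnbistab:::cp_eval, numeric(1), vals = vv)
    expect_lt(sqrt(sum(Fv^2)), 1e-7)
  }
  # both stable and unstable segments are present
  expect_true(any(diag$points$stable == 1, na.rm = TRUE))
  expect_true(any(diag$points$stable == 0, na.rm = TRUE))
})

test_that("direct simulation of the Edelstein system shows two equilibrium
           levels with path-dependent switching that brackets the
           continuation folds", {
  fx <- edelstein_fixture()
  grid <- seq(7.5, 8.1, length.out = 41L)
  dr <- direct_simulation(fx$sys, fx$vals, signal_grid = grid,
                          response_init = c(0.5, 2.0), t_max = 65000,
                          n_out = 200L)
  expect_true(all(dr$curve$converged))
  h <- detect_hysteresis(dr)
  expect_true(h$bistable)
  # low-start switches at a smaller signal than high-start
  expect_lt(h$up_switch, h$down_switch)
  # thresholds agree with the continuation folds within grid resolution
  step <- diff(grid)[1]
  diag <- continue_branch(fx$sys, fx$vals, eps_range = c(7.0, 8.6))
  folds <- sort(diag$folds$signal)
  expect_lt(abs(h$up_switch - folds[1]), 2 * step)
  expect_lt(abs(h$down_switch - folds[length(folds)]), 2 * step)
  # two equilibrium levels: lower near 1, upper in the documented range
  sep <- which(abs(dr$curve$response[dr$curve$start == "high"] -
                   dr$curve$response[dr$curve$start == "low"]) > 0.05)
  expect_gte(length(sep), 1L)
  lows <- dr$curve$response[dr$curve$start == "low"][sep]
  highs <- dr$curve$response[dr$curve$start == "high"][sep]
  expect_true(all(lows > 0.9 & lows < 1.15))
  expect_true(all(highs > 1.4 & highs < 1.9))
})

test_that("a monostable reversible pair gives identical low- and
           high-start curves and no hysteresis", {
  net <- parse_network("A <-> B")
  m <- build_crnt_matrices(net)
  basis <- conservation_basis(m)
  sys <- select_independent_odes(m, basis, "A")
  vals <- c(k1 = 0.5, k2 = 0.8, c1 = 1.0, C1 = 2.0)
  dr <- direct_simulation(sys, vals, signal_grid = seq(1.5, 2.5, 0.25),
                          t_max = 1e4, n_out = 100L)
  h <- detect_hysteresis(dr)
  expect_false(isTRUE(h$bistable))
  lo <- dr$curve[dr$curve$start == "low" & dr$curve$converged, ]
  hi <- dr$curve[dr$curve$start == "high" & dr$curve$converged, ]
  common <- intersect(lo$signal, hi$signal)
  expect_equal(lo$response[match(common, lo$signal)],
               hi$response[match(common, hi$signal)], tolerance = 1e-4)
})
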
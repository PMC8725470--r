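# steady-state parametrization: pivots, closed forms, residual identities

test_that("RREF pivots select the documented rate constants", {
  expect_equal(choose_pivot_rates(edelstein_fixture()$m), c(1L, 3L))
  expect_equal(choose_pivot_rates(build_crnt_matrices(parse_network("A -> B"))),
               1L)
  # the futile cycle fixes k1, k3, k4 and k8
  expect_equal(futile_fixture()$param$pivots, c(1L, 3L, 4L, 8L))
})

test_that("the Edelstein closed forms equal the published expressions
           symbolically", {
  fx <- edelstein_fixture()
  e <- fx$param$expressions
  expect_equal(fx$param$fixed_symbols, c("k1", "k3"))
  cpv <- crnbistab:::cp_var; cpa <- crnbistab:::cp_add
  cps <- crnbistab:::cp_sub; cpm_ <- crnbistab:::cp_mul
  c2expr <- cps(cpv("C1"), cpv("c3"))   # eliminated B
  # k1 = (k2 c1^2 + k5 c3 - k6 (C1 - c3)) / c1
  k1_num <- cps(cpa(cpm_(cpv("k2"), cpv("c1", 2L)),
                    cpm_(cpv("k5"), cpv("c3"))),
                cpm_(cpv("k6"), c2expr))
  # k3 = ((k4 + k5) c3 - k6 (C1 - c3)) / (c1 (C1 - c3))
  k3_num <- cps(cpm_(cpa(cpv("k4"), cpv("k5")), cpv("c3")),
                cpm_(cpv("k6"), c2expr))
  k3_den <- cpm_(cpv("c1"), c2expr)
  # compare as rational functions: num1 * den2 == num2 * den1
  cross_equal <- function(e1, num2, den2) {
    crnbistab:::cp_is_zero(cps(cpm_(e1$num, den2), cpm_(num2, e1$den)))
  }
  expect_true(cross_equal(e$k1, k1_num, cpv("c1")))
  expect_true(cross_equal(e$k3, k3_num, k3_den))
})

test_that("the futile-cycle solve reproduces k3 = (k7 c4 - k6 c6) / c3", {
  fx <- futile_fixture()
  e <- fx$param$expressions$k3
  cpv <- crnbistab:::cp_var; cps <- crnbistab:::cp_sub
  cpm_ <- crnbistab:::cp_mul
  num <- cps(cpm_(cpv("k7"), cpv("c4")), cpm_(cpv("k6"), cpv("c6")))
  den <- cpv("c3")
  expect_true(crnbistab:::cp_is_zero(
    cps(cpm_(e$num, den), cpm_(num, e$den))))
})

test_that("substituting the solved rates makes every independent
           right-hand side vanish at random positive points, on all three
           motifs", {
  set.seed(17)
  for (fx in list(edelstein_fixture(), futile_fixture(), prion_fixture())) {
    sys <- fx$sys; param <- fx$param
    N <- nrow(fx$m$S)
    for (rep in 1:5) {
      conc <- runif(N, 0.5, 4)
      kfree <- stats::setNames(runif(length(param$free_symbols), 0.1, 2),
                               param$free_symbols)
      vals <- c(kfree,
                stats::setNames(conc, paste0("c", seq_len(N))),
                stats::setNames(as.numeric(t(fx$basis$B) %*% conc),
                                sys$total_vars))
      ktil <- crnbistab:::eval_fixed_rates(param, vals)
      vals <- c(vals, ktil)
      Fv <- vapply(sys$F, crnbistab:::cp_eval, numeric(1), vals = vals)
      scale <- max(1, max(abs(vals)))
      expect_lt(max(abs(Fv)), 1e-8 * scale^3)
      # the reconstructed full rate vector lies in the kernel of the
      # independent rows of S
      net <- fx$net
      rates <- vapply(seq_len(ncol(fx$m$S)), function(r)
        vals[[net$reactions$rate[r]]] *
          prod(conc ^ fx$m$Y[, net$reactions$source[r]]), numeric(1))
      resid <- fx$m$S[sys$independent, , drop = FALSE] %*% rates
      expect_lt(max(abs(resid)), 1e-8 * scale^3)
    }
  }
})

test_that("each rate constant belongs to exactly one reaction column", {
  fx <- futile_fixture()
  net <- fx$net
  expect_equal(anyDuplicated(net$reactions$rate), 0L)
  expect_equal(ncol(fx$m$S), length(net$reactions$rate))
})

test_that("alternative pivot enumeration skips dependent column sets", {
  S <- matrix(c(1, 0,   # col1
                2, 0,   # col2 (dependent on col1)
                0, 1),  # col3
              nrow = 2)
  combos <- enumerate_alternative_pivots(S)
  expect_false(list(c(1L, 2L)) %in% combos)
  expect_equal(combos[[1]], c(1L, 3L))
  expect_setequal(vapply(combos, paste, character(1), collapse = ","),
                  c("1,3", "2,3"))
})

test_that("a network with no positive steady state reports it", {
  net <- parse_network("A -> B")
  m <- build_crnt_matrices(net)
  basis <- conservation_basis(m)
  sys <- select_independent_odes(m, basis, "B")
  expect_error(solve_steady_state(sys), "no steady state exists")
})
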
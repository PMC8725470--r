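# full ODE construction, independent-subsystem selection, reduced Jacobian

cpv <- crnbistab:::cp_var
cpc <- crnbistab:::cp_const
cpa <- crnbistab:::cp_add
cps <- crnbistab:::cp_sub
cpm_ <- crnbistab:::cp_mul
cpe <- crnbistab:::cp_equal

test_that("the Edelstein right-hand sides match the closed forms, with
           the B and C equations exact negatives of each other", {
  fx <- edelstein_fixture()
  f <- full_odes(fx$m)
  # dc1/dt = k1 c1 - k2 c1^2 - k3 c1 c2 + k4 c3
  want1 <- cpa(cps(cps(cpm_(cpv("k1"), cpv("c1")),
                       cpm_(cpv("k2"), cpv("c1", 2L))),
                   cpm_(cpv("k3"), cpm_(cpv("c1"), cpv("c2")))),
               cpm_(cpv("k4"), cpv("c3")))
  expect_true(cpe(f[[1]], want1))
  # dc2/dt = (k4 + k5) c3 - k3 c1 c2 - k6 c2  (the mass-action derivation
  # forces dc2/dt = -dc3/dt)
  want2 <- cps(cps(cpm_(cpa(cpv("k4"), cpv("k5")), cpv("c3")),
                   cpm_(cpv("k3"), cpm_(cpv("c1"), cpv("c2")))),
               cpm_(cpv("k6"), cpv("c2")))
  expect_true(cpe(f[[2]], want2))
  expect_true(crnbistab:::cp_is_zero(cpa(f[[2]], f[[3]])))
})

test_that("every conservation law annihilates the right-hand sides
           symbolically", {
  for (fx in list(edelstein_fixture(), futile_fixture(), prion_fixture())) {
    f <- full_odes(fx$m)
    for (j in seq_len(ncol(fx$basis$B))) {
      comb <- crnbistab:::cp_sum(lapply(seq_along(f), function(i)
        crnbistab:::cp_scale(f[[i]], fx$basis$B[i, j])))
      expect_true(crnbistab:::cp_is_zero(comb))
    }
  }
})

test_that("a reversible pair yields the textbook linear rhs", {
  net <- parse_network("A <-> B")
  f <- full_odes(build_crnt_matrices(net))
  want <- cpa(crnbistab:::cp_neg(cpm_(cpv("k1"), cpv("c1"))),
              cpm_(cpv("k2"), cpv("c2")))
  expect_true(cpe(f[[1]], want))
})

test_that("independent-system selection reproduces the documented
           eliminations for all three motifs", {
  ed <- edelstein_fixture()
  expect_equal(ed$sys$independent, c(1L, 3L))     # keep A and C
  expect_equal(names(ed$sys$dep_expr), "c2")      # eliminate B = C1 - c3

  fc <- futile_fixture()
  expect_equal(fc$sys$independent, 3:6)           # E1S, Sstar, E2, E2S
  expect_setequal(names(fc$sys$dep_expr), c("c1", "c2"))

  pr <- prion_fixture()
  expect_equal(pr$sys$independent, c(2L, 3L, 4L, 6L, 7L, 8L, 9L))
  expect_setequal(names(pr$sys$dep_expr), c("c1", "c5"))
})

test_that("the selection is the lexicographically first full-rank
           combination (brute-force scan agrees)", {
  for (fx in list(edelstein_fixture(), futile_fixture())) {
    m <- fx$m; basis <- fx$basis; sys <- fx$sys
    N <- nrow(m$S); lam <- ncol(basis$B)
    resp <- sys$response
    per_law <- lapply(seq_len(lam), function(j)
      setdiff(which(basis$B[, j] != 0), resp))
    combos <- expand.grid(per_law, KEEP.OUT.ATTRS = FALSE)
    ord <- do.call(order, as.list(combos))
    combos <- as.matrix(combos)[ord, , drop = FALSE]
    accepted <- NULL
    for (i in seq_len(nrow(combos))) {
      dep <- combos[i, ]
      if (anyDuplicated(dep)) next
      if (abs(crnbistab:::int_det(t(basis$B[dep, , drop = FALSE]))) < 0.5)
        next
      retained <- setdiff(seq_len(N), dep)
      if (minor_rank(m$S[retained, , drop = FALSE]) == m$s) {
        accepted <- sort(as.integer(dep)); break
      }
    }
    expect_equal(sort(sys$dependent), accepted)
  }
})

test_that("restoring the eliminated species recovers the original
           right-hand sides at random positive states", {
  set.seed(21)
  for (fx in list(edelstein_fixture(), futile_fixture())) {
    sys <- fx$sys
    f_full <- full_odes(fx$m)
    N <- nrow(fx$m$S)
    for (rep in 1:5) {
      conc <- runif(N, 0.2, 3)
      k <- runif(ncol(fx$m$S), 0.1, 2)
      vals <- c(stats::setNames(k, sys$rate_vars),
                stats::setNames(conc, paste0("c", seq_len(N))),
                stats::setNames(as.numeric(t(fx$basis$B) %*% conc),
                                sys$total_vars))
      for (i in seq_along(sys$F)) {
        expect_equal(crnbistab:::cp_eval(sys$F[[i]], vals),
                     crnbistab:::cp_eval(f_full[[sys$independent[i]]], vals),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("the reduced Jacobian entry for the response equation matches the
           hand-derived expression and finite differences", {
  fx <- edelstein_fixture()
  # dF1/dc1 = k1 - 2 k2 c1 - k3 (C1 - c3)
  want <- cps(cps(cpv("k1"),
                  cpm_(cpc(2), cpm_(cpv("k2"), cpv("c1")))),
              cpm_(cpv("k3"), cps(cpv("C1"), cpv("c3"))))
  expect_true(cpe(crnbistab:::cpm_get(fx$sys$J, 1L, 1L), want))
  # numeric cross-check of the whole Jacobian by central differences
  vals <- fx$vals
  Ffun <- function(u) {
    vv <- vals
    vv[fx$sys$conc_vars] <- u
    vapply(fx$sys$F, crnbistab:::cp_eval, numeric(1), vals = vv)
  }
  u0 <- as.numeric(vals[fx$sys$conc_vars])
  expect_equal(crnbistab:::cpm_eval(fx$sys$J, vals), fd_jacobian(Ffun, u0),
               tolerance = 1e-6)
  rj <- reduced_jacobian(fx$sys)
  expect_lt(abs(crnbistab:::cp_eval(rj$det, vals) - rj$det_fun(vals)), 1e-12)
  # the candidate sits on the singular manifold
  expect_lt(abs(rj$det_fun(vals)), 1e-7)
})
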
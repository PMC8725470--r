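# squared-determinant objectives, multistart search, stopping rule

test_that("the parametrized objective is numerically zero at the reference
           Edelstein decision point and matches a finite-difference
           determinant elsewhere", {
  fx <- edelstein_fixture()
  obj5 <- saddle_objective(fx$sys, fx$param, "eq5")
  x_ref <- c(fx$dv$rates[c("k2", "k4", "k5", "k6")], fx$dv$conc)
  expect_lt(obj5(as.numeric(x_ref)), 1e-12)
  # derived quantities reproduce the published fixed rates and total
  d <- attr(obj5, "details")(as.numeric(x_ref))
  expect_equal(d[["k1"]], fx$dv$rates[["k1"]], tolerance = 1e-6)
  expect_equal(d[["k3"]], fx$dv$rates[["k3"]], tolerance = 1e-6)
  expect_equal(d[["C1"]], 7.79489058, tolerance = 1e-7)
  # at random in-bounds points the objective equals det(J)^2 with the
  # Jacobian recomputed by central differences on the reduced rhs
  set.seed(5)
  for (rep in 1:5) {
    x <- c(runif(4, 0.01, 2), runif(3, 0.5, 5))
    vals <- attr(obj5, "details")(x)
    if (any(is.na(vals)) || any(vals[c("k1", "k3")] <= 0)) next
    Ffun <- function(u) {
      vv <- vals; vv[fx$sys$conc_vars] <- u
      vapply(fx$sys$F, crnbistab:::cp_eval, numeric(1), vals = vv)
    }
    dfd <- det(fd_jacobian(Ffun, as.numeric(vals[fx$sys$conc_vars])))
    expect_equal(obj5(x), dfd^2, tolerance = 1e-5)
  }
})

test_that("the explicit-residual objective is det^2 plus the squared rhs,
           and the two modes agree at parametrized points", {
  fx <- edelstein_fixture()
  obj4 <- saddle_objective(fx$sys, mode = "eq4")
  obj5 <- saddle_objective(fx$sys, fx$param, "eq5")
  # steady state of a stable linear system: objective = det^2 exactly
  lin <- linear_birth_death_system()
  lobj <- saddle_objective(lin, mode = "eq4")
  expect_equal(lobj(c(0.6, 0.3, 2.0)), 0.3^2)      # k1 = k2 * c1
  expect_gt(lobj(c(0.5, 0.3, 1.0)), 0.3^2)         # off steady state
  set.seed(9)
  for (rep in 1:6) {
    x5 <- c(runif(4, 0.05, 2), runif(3, 0.5, 5))
    vals <- attr(obj5, "details")(x5)
    if (any(is.na(vals)) || any(vals[fx$sys$rate_vars] <= 0)) next
    x4 <- as.numeric(c(vals[fx$sys$rate_vars], x5[5:7]))
    expect_equal(obj4(x4), obj5(x5), tolerance = 1e-8)
  }
})

test_that("a fifty-start search on the Edelstein motif reaches a numerical
           zero and is reproducible", {
  fx <- edelstein_fixture()
  cfg <- search_config(fx$sys, "eq5", n_starts = 50L, seed = 7L,
                       conc_bounds = c(0.001, 100),
                       rate_bounds = c(0.001, 100))
  res1 <- run_search(cfg, fx$sys, fx$param)
  expect_lt(res1$best_objective, 1e-12)
  expect_equal(res1$q, 1.0)
  expect_gte(length(res1$candidates), 1L)
  # candidates pass the screen: positive rates, in-bounds concentrations
  for (cd in res1$candidates) {
    expect_true(all(cd$values[fx$sys$rate_vars] > 0))
    cc <- cd$values[paste0("c", 1:3)]
    expect_true(all(cc >= 0.001 & cc <= 100))
  }
  res2 <- run_search(cfg, fx$sys, fx$param)
  expect_identical(res1$records, res2$records)
  expect_identical(res1$best_x, res2$best_x)
})

test_that("a system whose determinant is bounded away from zero yields no
           candidates and reports its confidence", {
  lin <- linear_birth_death_system()
  cfg <- search_config(lin, "eq4", n_starts = 8L, seed = 2L,
                       conc_bounds = c(0.01, 10), rate_bounds = c(0.1, 5),
                       q_stop = 2)   # disable early stop to count all starts
  res <- run_search(cfg, lin)
  expect_length(res$candidates, 0L)
  expect_gt(res$best_objective, 1e-4)   # det^2 >= k2_min^2 = 0.01
  expect_true(res$q > 0 && res$q <= 1)
  expect_equal(res$n, 8L)
})

test_that("the stopping-rule confidence matches exact big-integer oracle
           values and the log-gamma route, and is monotone in r", {
  # frozen from an exact rational-arithmetic evaluation of the factorial
  # formula (a = 1, b = 5)
  expect_equal(confidence_level(10, 10), 0.9996937676672499, tolerance = 1e-14)
  expect_equal(confidence_level(100, 1), 0.7388809182209469, tolerance = 1e-14)
  expect_equal(confidence_level(10, 1), 0.65, tolerance = 1e-14)
  expect_equal(confidence_level(50, 25), 0.9999999988120598, tolerance = 1e-14)
  for (n in c(5L, 20L, 137L, 1000L, 10000L)) {
    q_all <- vapply(seq_len(min(n, 60L)), function(r)
      confidence_level(n, r), numeric(1))
    expect_true(all(diff(q_all) >= -1e-15))
    expect_true(all(q_all >= 0 & q_all <= 1))
    r_probe <- c(1L, min(n, 17L))
    for (r in r_probe)
      expect_equal(confidence_level(n, r), q_lgamma(n, r), tolerance = 1e-9)
  }
  expect_error(confidence_level(10, 0), "1 <= r <= n")
  expect_error(confidence_level(10, 11), "1 <= r <= n")
})

test_that("neighborhood counting matches a brute-force recount", {
  expect_equal(neighborhood_count(c(1.0, 1.05, 2.0), eps = 0.10), 2L)
  expect_equal(neighborhood_count(rep(0.7, 12), eps = 0.10), 12L)
  set.seed(31)
  minima <- runif(1000, 0.5, 3)
  fb <- min(minima)
  recount <- sum(vapply(minima, function(f)
    abs(fb - f) / fb <= 0.1, logical(1)))
  expect_equal(neighborhood_count(minima, eps = 0.10), recount)
  expect_error(neighborhood_count(c(0, 1)), "q = 1")
})
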
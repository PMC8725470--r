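# Saddle-node search: multistart global minimization of det(J)^2.
#
# Two objective modes.  "eq5" (parametrized): the decision vector holds the
# free rate constants and all species concentrations; conservation totals
# are computed from the sampled concentrations via the laws, the pivot rates
# from their closed forms, and the objective is det(J)^2 plus a smooth hinge
# keeping the reconstructed rates positive and a large finite penalty at
# denominator poles.  "eq4" (explicit residual): the decision vector holds
# all rate constants and concentrations, and the objective is det(J)^2 plus
# the sum of squared time derivatives of the independent species.
# The search runs n independent simulated-annealing starts, each polished by
# Nelder-Mead, with per-start seeds derived from the configuration seed so
# runs are reproducible and trivially partitionable across workers.

default_rate_bounds <- function(m) {
  # reaction-type inference from complex molecularities: bimolecular source
  # -> association; unimolecular source with bimolecular target ->
  # dissociation; otherwise catalysis (typical cellular ranges)
  net <- m$network
  mol <- colSums(m$Y)
  R <- ncol(m$S)
  lo <- numeric(R); hi <- numeric(R)
  for (r in seq_len(R)) {
    ms <- mol[net$reactions$source[r]]
    mt <- mol[net$reactions$target[r]]
    if (ms >= 2) { lo[r] <- 1e4;  hi[r] <- 1e8 }       # association, M^-1 s^-1
    else if (ms == 1 && mt >= 2) { lo[r] <- 1e-5; hi[r] <- 1e-3 }  # dissociation
    else { lo[r] <- 1e-3; hi[r] <- 1 }                 # catalysis, s^-1
  }
  cbind(lower = lo, upper = hi)
}

#' Saddle-search configuration
#'
#' @param sys an `independent_system`
#' @param mode `"eq5"` (parametrized steady state, the default) or `"eq4"`
#'   (explicit steady-state residual in the objective)
#' @param n_starts number of independent optimization starts
#' @param seed integer seed; per-start seeds are derived from it
#' @param conc_bounds length-2 vector or N x 2 matrix of concentration
#'   bounds (defaults to the typical cellular protein range 5e-13..5e-7 M)
#' @param rate_bounds length-2 vector or R x 2 matrix of rate-constant
#'   bounds; by default inferred per reaction from complex molecularities
#'   (association 1e4..1e8, dissociation 1e-5..1e-3, catalysis 1e-3..1)
#' @param zero_tol objective value counted as a numerical zero
#' @param neighborhood_eps relative tolerance of the stopping-rule
#'   neighborhood (default 10 percent)
#' @param beta_a,beta_b Beta-distribution parameters of the stopping rule
#' @param q_stop confidence level at which the search stops early
#' @param stop_on_zero stop as soon as a start reaches a numerical zero
#' @param sann_iter iterations of the annealing stage per start
#' @param nm_maxit iteration cap of each Nelder-Mead polish
#' @return a `search_config` list
#' @export
search_config <- function(sys, mode = c("eq5", "eq4"), n_starts = 50L,
                          seed = 1L, conc_bounds = c(5e-13, 5e-7),
                          rate_bounds = NULL, zero_tol = 1e-12,
                          neighborhood_eps = 0.10, beta_a = 1L, beta_b = 5L,
                          q_stop = 0.95, stop_on_zero = TRUE,
                          sann_iter = 300L, nm_maxit = 2000L) {
  mode <- match.arg(mode)
  m <- sys$matrices
  N <- nrow(m$S); R <- ncol(m$S)
  cb <- if (is.matrix(conc_bounds)) conc_bounds else
    matrix(conc_bounds, N, 2L, byrow = TRUE)
  rb <- if (is.null(rate_bounds)) default_rate_bounds(m) else
    if (is.matrix(rate_bounds)) rate_bounds else
      matrix(rate_bounds, R, 2L, byrow = TRUE)
  stopifnot(all(cb[, 1] > 0), all(rb[, 1] > 0),
            all(cb[, 2] > cb[, 1]), all(rb[, 2] > rb[, 1]),
            neighborhood_eps > 0, neighborhood_eps < 1, n_starts >= 1L)
  structure(list(mode = mode, n_starts = as.integer(n_starts),
                 seed = as.integer(seed), conc_bounds = cb, rate_bounds = rb,
                 zero_tol = zero_tol, neighborhood_eps = neighborhood_eps,
                 beta_a = as.integer(beta_a), beta_b = as.integer(beta_b),
                 q_stop = q_stop, stop_on_zero = stop_on_zero,
                 sann_iter = as.integer(sann_iter),
                 nm_maxit = as.integer(nm_maxit)),
            class = "search_config")
}

# generated-code objective: returns function(x) with attribute "vars" giving
# the decision-vector layout, in natural (not log) units
#' Build the saddle-search objective function
#'
#' Compiles the squared-determinant objective for an independent system
#' into a plain R function of the decision vector.  In `"eq5"` mode the
#' decision vector is `(free rate constants, all concentrations)` and the
#' pivot rates and totals are reconstructed internally; in `"eq4"` mode it
#' is `(all rate constants, all concentrations)` and the squared
#' steady-state residual is added.
#'
#' @param sys an `independent_system`
#' @param param a `steady_state_param` (required for `"eq5"`)
#' @param mode `"eq5"` or `"eq4"`
#' @param pole_penalty value returned at a denominator pole
#' @param hinge_delta offset of the smooth positivity hinge on
#'   reconstructed rates
#' @return function(x) -> nonnegative scalar, with attributes `vars`
#'   (decision-variable names) and `details(x)` (named evaluation report)
#' @export
saddle_objective <- function(sys, param = NULL, mode = c("eq5", "eq4"),
                             pole_penalty = 1e10, hinge_delta = 1e-12) {
  mode <- match.arg(mode)
  m <- sys$matrices
  N <- nrow(m$S)
  B <- sys$basis$B
  s <- length(sys$independent)
  lines <- character(0)
  if (mode == "eq5") {
    if (is.null(param)) stop("mode 'eq5' needs a steady_state_param")
    free_k <- param$free_symbols
    vars <- c(free_k, paste0("c", seq_len(N)))
  } else {
    vars <- c(sys$rate_vars, paste0("c", seq_len(N)))
  }
  for (i in seq_along(vars))
    lines <- c(lines, paste0(vars[i], " <- x[", i, "]"))
  for (j in seq_len(ncol(B))) {
    nz <- which(B[, j] != 0)
    terms <- ifelse(B[nz, j] == 1, paste0("c", nz),
                    paste0(B[nz, j], "*c", nz))
    lines <- c(lines, paste0("C", j, " <- ", paste(terms, collapse = " + ")))
  }
  lines <- c(lines, ".pen <- 0")
  if (mode == "eq5") {
    for (j in seq_along(param$fixed_symbols)) {
      e <- param$expressions[[j]]
      lines <- c(lines,
        paste0(".den <- ", cp_to_string(e$den)),
        paste0("if (abs(.den) < 1e-300) return(", pole_penalty, ")"),
        paste0(param$fixed_symbols[j], " <- (", cp_to_string(e$num),
               ") / .den"),
        paste0(".pen <- .pen + max(0, -", param$fixed_symbols[j], " + ",
               hinge_delta, ")^2"))
    }
  }
  jstrs <- vapply(unclass(sys$J), cp_to_string, character(1))
  lines <- c(lines,
    paste0(".J <- matrix(c(", paste(jstrs, collapse = ",\n"), "), ",
           s, ", ", s, ")"),
    paste0("if (any(!is.finite(.J))) return(", pole_penalty, ")"),
    ".d <- det(.J)",
    ".obj <- .d * .d + .pen")
  if (mode == "eq4") {
    fstrs <- vapply(sys$F, cp_to_string, character(1))
    lines <- c(lines,
      paste0(".res <- c(", paste(fstrs, collapse = ",\n"), ")"),
      ".obj <- .obj + sum(.res * .res)")
  }
  lines <- c(lines, ".obj")
  fun <- eval(parse(text = paste0("function(x) {\n",
                                  paste(lines, collapse = "\n"), "\n}"))[[1]])
  details <- function(x) {
    vals <- stats::setNames(as.numeric(x), vars)
    conc <- vals[paste0("c", seq_len(N))]
    totals <- stats::setNames(as.numeric(t(B) %*% conc),
                              paste0("C", seq_len(ncol(B))))
    vals <- c(vals, totals)
    if (mode == "eq5") vals <- c(vals, eval_fixed_rates(param, vals))
    vals
  }
  attr(fun, "vars") <- vars
  attr(fun, "mode") <- mode
  attr(fun, "details") <- details
  fun
}

#' Bayesian stopping-rule confidence level
#'
#' Lower bound on the probability that the best of `n` multistart minima is
#' the global minimum, given that `r` of them lie in the relative
#' neighborhood of the best.  Evaluated as a product of `n` exact ratios
#' (algebraically identical to the factorial form, with no overflow for
#' large `n`).
#'
#' @param n number of starts
#' @param r number of minima in the neighborhood of the best (1 <= r <= n)
#' @param a,b Beta-distribution parameters (integers >= 1)
#' @return confidence `q` in `[0, 1]`
#' @export
confidence_level <- function(n, r, a = 1L, b = 5L) {
  n <- as.integer(n); r <- as.integer(r)
  if (r < 1L || r > n) stop("need 1 <= r <= n")
  if (a < 1L || b < 1L) stop("Beta parameters must be integers >= 1")
  j <- seq(0L, n - 1L)
  1 - prod((n + b - r + j) / (n + a + b + j))
}

#' Count minima in the neighborhood of the best
#'
#' @param minima numeric vector of per-start achieved minima
#' @param f_best the best minimum (defaults to `min(minima)`); must be
#'   strictly positive (a numerical zero bypasses the stopping rule)
#' @param eps relative neighborhood tolerance
#' @return integer count `r`
#' @export
neighborhood_count <- function(minima, f_best = min(minima), eps = 0.10) {
  if (f_best <= 0) stop("neighborhood counting needs f_best > 0; a ",
                        "numerical zero sets q = 1 directly")
  sum(abs(f_best - minima) / f_best <= eps)
}

start_seed <- function(seed, i) (as.numeric(seed) + 7919 * i) %% 2147483399

#' Run the multistart saddle-node search
#'
#' Each start draws a log-uniform point inside the bounds, runs a
#' simulated-annealing stage and a Nelder-Mead polish in log-space (with a
#' quadratic penalty outside the log-box), and records the achieved
#' minimum.  The search stops early when a start reaches a numerical zero
#' (confidence `q` is then 1) or when the stopping-rule confidence exceeds
#' `q_stop`.
#'
#' @param cfg a `search_config`
#' @param sys an `independent_system`
#' @param param a `steady_state_param` (needed in `"eq5"` mode)
#' @return an object of class `search_result` with per-start records, the
#'   best objective and decision vector, the neighborhood count `r`, the
#'   confidence `q`, and the candidate list (starts below the zero
#'   tolerance that also pass the positivity/bounds screen)
#' @export
run_search <- function(cfg, sys, param = NULL) {
  stopifnot(inherits(cfg, "search_config"))
  obj <- saddle_objective(sys, param, mode = cfg$mode)
  vars <- attr(obj, "vars")
  nk <- length(vars) - nrow(cfg$conc_bounds)
  if (cfg$mode == "eq5") {
    ridx <- match(param$free_symbols, sys$rate_vars)
  } else ridx <- seq_len(nrow(cfg$rate_bounds))
  lo <- c(cfg$rate_bounds[ridx, 1], cfg$conc_bounds[, 1])
  hi <- c(cfg$rate_bounds[ridx, 2], cfg$conc_bounds[, 2])
  ulo <- log(lo); uhi <- log(hi)
  gobj <- function(u) {
    pen <- sum(pmax(0, u - uhi)^2 + pmax(0, ulo - u)^2)
    obj(exp(pmin(pmax(u, ulo - 2), uhi + 2))) + 1e4 * pen
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  records <- data.frame(start = integer(0), seed = numeric(0),
                        objective = numeric(0))
  xs <- list()
  best <- Inf; best_x <- NULL
  q <- NA_real_; r <- NA_integer_
  n_done <- 0L
  for (i in seq_len(cfg$n_starts)) {
    set.seed(start_seed(cfg$seed, i))
    u0 <- stats::runif(length(lo), ulo, uhi)
    fit <- stats::optim(u0, gobj, method = "SANN",
                        control = list(maxit = cfg$sann_iter))
    fit <- stats::optim(fit$par, gobj, method = "Nelder-Mead",
                        control = list(maxit = cfg$nm_maxit,
                                       reltol = 1e-15))
    # a second polish escapes premature simplex collapse
    fit <- stats::optim(fit$par, gobj, method = "Nelder-Mead",
                        control = list(maxit = cfg$nm_maxit,
                                       reltol = 1e-15))
    x <- exp(pmin(pmax(fit$par, ulo), uhi))
    fx <- obj(x)
    n_done <- i
    records <- rbind(records,
                     data.frame(start = i, seed = start_seed(cfg$seed, i),
                                objective = fx))
    xs[[i]] <- stats::setNames(x, vars)
    if (fx < best) { best <- fx; best_x <- xs[[i]] }
    if (cfg$stop_on_zero && best <= cfg$zero_tol) { q <- 1.0; break }
    if (i >= 2L && best > cfg$zero_tol) {
      r_i <- neighborhood_count(records$objective, best,
                                cfg$neighborhood_eps)
      q_i <- confidence_level(i, r_i, cfg$beta_a, cfg$beta_b)
      if (q_i >= cfg$q_stop) { q <- q_i; r <- r_i; break }
    }
  }
  if (best <= cfg$zero_tol) {
    q <- 1.0
    r <- sum(records$objective <= cfg$zero_tol)
  } else if (is.na(q)) {
    r <- neighborhood_count(records$objective, best, cfg$neighborhood_eps)
    q <- confidence_level(n_done, r, cfg$beta_a, cfg$beta_b)
  } else if (is.na(r)) {
    r <- neighborhood_count(records$objective, best, cfg$neighborhood_eps)
  }
  # candidate screening: numerical zero, reconstructed rates positive,
  # concentrations inside bounds
  details <- attr(obj, "details")
  cands <- list()
  for (i in seq_len(nrow(records))) {
    if (records$objective[i] > cfg$zero_tol) next
    vals <- details(xs[[records$start[i]]])
    kv <- vals[sys$rate_vars]
    cvals <- vals[paste0("c", seq_len(nrow(cfg$conc_bounds)))]
    if (any(is.na(kv)) || any(kv <= 0)) next
    if (any(cvals < cfg$conc_bounds[, 1] * (1 - 1e-9)) ||
        any(cvals > cfg$conc_bounds[, 2] * (1 + 1e-9))) next
    cands[[length(cands) + 1L]] <-
      list(start = records$start[i], objective = records$objective[i],
           values = vals)
  }
  structure(list(config = cfg, records = records, decision_vectors = xs,
                 best_objective = best, best_x = best_x,
                 n = n_done, r = r, q = q, candidates = cands),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat("search_result:", x$n, "start(s), best objective =",
      format(x$best_objective, digits = 6),
      " r =", x$r, " q =", format(x$q, digits = 6), "\n")
  cat("candidates passing the zero/positivity screen:",
      length(x$candidates), "\n")
  invisible(x)
}

#' Serialize a search result to JSON
#'
#' @param res a `search_result`
#' @param path output path
#' @return invisibly, `path`
#' @export
export_search_json <- function(res, path) {
  out <- list(n = res$n, r = res$r, q = res$q,
              best_objective = res$best_objective,
              best_x = as.list(res$best_x),
              starts = res$records,
              candidates = lapply(res$candidates, function(cd)
                list(start = cd$start, objective = cd$objective,
                     values = as.list(cd$values))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
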
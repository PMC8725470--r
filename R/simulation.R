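# Direct simulation of the full ODE system and dose-response construction.
#
# For every signal value on a grid and both a low and a high initial
# concentration of the response species, the full stiff mass-action system
# is integrated until the concentrations stop changing between solver
# outputs (trailing window of three outputs below the steady-state
# tolerance).  Comparing the low-start and high-start equilibrium curves
# yields the dose-response diagram and, when they separate over a signal
# subinterval, the hysteresis verdict with its two switching thresholds.

# derivative closure for deSolve on the full network
make_ode_fun <- function(m) {
  net <- m$network
  src <- net$reactions$source
  Yl <- m$Y
  S <- m$S
  R <- ncol(S)
  function(t, y, parms) {
    y <- pmax(y, 0)
    rates <- numeric(R)
    for (r in seq_len(R)) {
      e <- Yl[, src[r]]
      rates[r] <- parms[r] * prod(y ^ e)
    }
    list(as.numeric(S %*% rates))
  }
}

# integrate to steady state; returns list(state, converged, t_reached)
integrate_to_steady <- function(ode_fun, y0, k, t_max = 1e6,
                                ss_tol = 1e-6, n_out = 400L) {
  times <- seq(0, t_max, length.out = n_out + 1L)
  sol <- tryCatch(
    deSolve::lsoda(y = y0, times = times, func = ode_fun, parms = k,
                   rtol = 1e-8, atol = 1e-10),
    error = function(e) NULL)
  if (is.null(sol)) return(list(state = rep(NA_real_, length(y0)),
                                converged = FALSE, t = NA_real_))
  Y <- unname(as.matrix(sol[, -1L, drop = FALSE]))
  if (min(Y, na.rm = TRUE) < -1e-6)
    return(list(state = rep(NA_real_, length(y0)), converged = FALSE,
                t = NA_real_))
  d <- abs(diff(Y))
  maxstep <- apply(d, 1L, max)
  # trailing window of 3 inter-output changes below tolerance
  ok <- which(vapply(seq_len(length(maxstep) - 2L), function(i)
    all(maxstep[i:(i + 2L)] < ss_tol), logical(1)))
  if (length(ok) == 0L)
    return(list(state = Y[nrow(Y), ], converged = FALSE, t = t_max))
  idx <- ok[1L] + 3L
  list(state = Y[idx, ], converged = TRUE, t = times[idx])
}

#' Dose-response curve by direct simulation
#'
#' For each signal value on the grid and both response-species starting
#' policies (low and high), sets the other independent species to their
#' candidate values, reconstructs dependent species from the conservation
#' laws, and integrates the full mass-action system to steady state.
#'
#' @param sys an `independent_system`
#' @param values named vector with all rate constants, independent
#'   concentrations and totals (a candidate decision point)
#' @param signal_grid numeric grid of signal values; defaults to 41 points
#'   spanning +/- 20 percent of the candidate signal
#' @param response_init length-2 vector `c(low, high)` of initial response
#'   concentrations; defaults to 0.5x and 2x the candidate value
#' @param t_max integration horizon
#' @param ss_tol steady-state tolerance on the between-output concentration
#'   change
#' @param n_out number of solver outputs used for the steady-state test
#' @return an object of class `dose_response` with a data frame `curve`
#'   (signal, start policy, equilibrium response, converged flag, time to
#'   steady state)
#' @export
direct_simulation <- function(sys, values, signal_grid = NULL,
                              response_init = NULL, t_max = 1e6,
                              ss_tol = 1e-6, n_out = 400L) {
  stopifnot(inherits(sys, "independent_system"))
  m <- sys$matrices
  N <- nrow(m$S)
  eps0 <- values[[sys$signal_var]]
  if (is.null(signal_grid))
    signal_grid <- seq(0.8 * eps0, 1.2 * eps0, length.out = 41L)
  resp_var <- paste0("c", sys$response)
  resp0 <- values[[resp_var]]
  if (is.null(response_init)) response_init <- c(0.5 * resp0, 2 * resp0)
  k <- as.numeric(values[sys$rate_vars])
  ode_fun <- make_ode_fun(m)
  # dependent species are linear in the response concentration; clip the
  # requested starting value into the interval that keeps them nonnegative
  feasible_response <- function(vv, want) {
    lohi <- c(0, Inf)
    for (nm in names(sys$dep_expr)) {
      v0 <- vv; v0[[resp_var]] <- 0
      alpha <- cp_eval(sys$dep_expr[[nm]], v0)
      v1 <- vv; v1[[resp_var]] <- 1
      beta <- cp_eval(sys$dep_expr[[nm]], v1) - alpha
      if (beta > 1e-12) lohi[1] <- max(lohi[1], -alpha / beta)
      else if (beta < -1e-12) lohi[2] <- min(lohi[2], -alpha / beta)
      else if (alpha < 0) return(NA_real_)
    }
    if (lohi[1] > lohi[2]) return(NA_real_)
    margin <- 0.02 * (lohi[2] - lohi[1])
    min(max(want, lohi[1] + min(margin, want)),
        if (is.finite(lohi[2])) lohi[2] - margin else want)
  }
  rows <- list()
  for (eps in signal_grid) {
    for (pol in c("low", "high")) {
      vv <- values
      vv[[sys$signal_var]] <- eps
      want <- response_init[[if (pol == "low") 1L else 2L]]
      vv[[resp_var]] <- feasible_response(vv, want)
      y0 <- numeric(N)
      dep_ok <- !is.na(vv[[resp_var]])
      if (dep_ok) {
        y0[sys$independent] <- as.numeric(vv[sys$conc_vars])
        for (nm in names(sys$dep_expr)) {
          di <- as.integer(sub("^c", "", nm))
          val <- cp_eval(sys$dep_expr[[nm]], vv)
          if (val < -1e-9) { dep_ok <- FALSE; break }
          y0[di] <- max(val, 0)
        }
      }
      if (!dep_ok) {
        rows[[length(rows) + 1L]] <- data.frame(
          signal = eps, start = pol, response = NA_real_,
          converged = FALSE, t_steady = NA_real_)
        next
      }
      res <- integrate_to_steady(ode_fun, y0, k, t_max = t_max,
                                 ss_tol = ss_tol, n_out = n_out)
      rows[[length(rows) + 1L]] <- data.frame(
        signal = eps, start = pol,
        response = res$state[sys$response],
        converged = res$converged, t_steady = res$t)
    }
  }
  structure(list(curve = do.call(rbind, rows),
                 response_species = m$network$species[sys$response],
                 signal_var = sys$signal_var,
                 response_init = response_init),
            class = "dose_response")
}

#' @export
print.dose_response <- function(x, ...) {
  cat("dose_response:", nrow(x$curve) / 2, "signal values, response =",
      x$response_species, "\n")
  invisible(x)
}

#' Detect hysteresis in a dose-response curve
#'
#' The system is reported bistable when the low-start and high-start
#' equilibrium curves differ by more than a separation tolerance over some
#' signal subinterval.  Switching thresholds are the signal values where
#' each curve jumps between its equilibrium levels (largest jump between
#' adjacent converged grid points).
#'
#' @param dr a `dose_response`
#' @param sep_tol absolute separation tolerance between the two curves;
#'   defaults to 5 percent of the overall equilibrium range
#' @return an object of class `hysteresis_report`: `bistable` (TRUE /
#'   FALSE / NA when inconclusive), the bistable signal interval, and the
#'   up- and down-switching thresholds
#' @export
detect_hysteresis <- function(dr, sep_tol = NULL) {
  cv <- dr$curve
  lo <- cv[cv$start == "low" & cv$converged, c("signal", "response")]
  hi <- cv[cv$start == "high" & cv$converged, c("signal", "response")]
  common <- intersect(lo$signal, hi$signal)
  if (length(common) < 3L)
    return(structure(list(bistable = NA,
                          reason = "insufficient converged points"),
                     class = "hysteresis_report"))
  lo <- lo[match(common, lo$signal), ]
  hi <- hi[match(common, hi$signal), ]
  rng <- range(c(lo$response, hi$response))
  if (is.null(sep_tol)) sep_tol <- 0.05 * max(diff(rng), 1e-12)
  sep <- abs(hi$response - lo$response) > sep_tol
  bistable <- any(sep)
  interval <- if (bistable) range(common[sep]) else NULL
  jump_at <- function(df) {
    dj <- abs(diff(df$response))
    if (max(dj) <= sep_tol) return(NA_real_)
    i <- which.max(dj)
    mean(df$signal[c(i, i + 1L)])
  }
  up <- jump_at(lo)    # low-start curve jumps up at the upper fold
  dn <- jump_at(hi)    # high-start curve drops at the lower fold
  structure(list(bistable = bistable, bistable_interval = interval,
                 up_switch = up, down_switch = dn, sep_tol = sep_tol),
            class = "hysteresis_report")
}

#' @export
print.hysteresis_report <- function(x, ...) {
  if (is.na(x$bistable)) {
    cat("hysteresis_report: inconclusive (", x$reason, ")\n", sep = "")
  } else if (x$bistable) {
    cat("hysteresis_report: bistable; switching thresholds",
        format(x$up_switch, digits = 6), "(up from low start) /",
        format(x$down_switch, digits = 6), "(down from high start)\n")
  } else cat("hysteresis_report: not bistable\n")
  invisible(x)
}
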
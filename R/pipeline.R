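# End-to-end pipeline: classification, conservation laws, reduction,
# steady-state parametrization, saddle search, verification, diagram.

# resolve a signal designation to a conservation-basis column: either a
# total symbol ("C1"), a basis column index, or a species name meaning
# "the law that contains this species"
resolve_signal <- function(basis, net, signal) {
  if (is.numeric(signal)) return(as.integer(signal))
  if (signal %in% basis$totals) return(match(signal, basis$totals))
  sp <- match(signal, net$species)
  if (is.na(sp))
    stop("signal '", signal, "' is neither a conservation total nor a ",
         "species id")
  laws <- which(basis$B[sp, ] != 0)
  if (length(laws) == 0L)
    stop("species '", signal, "' appears in no conservation law")
  if (length(laws) > 1L)
    stop("species '", signal, "' appears in several conservation laws; ",
         "designate the total symbol explicitly")
  laws
}

#' Assemble a named value vector for a reference decision point
#'
#' Combines a fixture decision vector (rates plus full concentrations)
#' with a conservation basis into the named value vector used by the
#' objective, saddle-node check, continuation and simulation: all rate
#' constants, the independent concentrations, and every conservation total
#' computed as `B^T c`.
#'
#' @param sys an `independent_system`
#' @param dv a decision-vector list with elements `rates` and `conc`
#'   (full-length, in species order)
#' @return named numeric vector
#' @export
decision_values <- function(sys, dv) {
  m <- sys$matrices
  N <- nrow(m$S)
  conc <- dv$conc
  stopifnot(length(conc) == N)
  totals <- stats::setNames(as.numeric(t(sys$basis$B) %*% as.numeric(conc)),
                            sys$total_vars)
  c(stats::setNames(as.numeric(dv$rates), sys$rate_vars),
    stats::setNames(as.numeric(conc)[sys$independent], sys$conc_vars),
    totals)
}

#' Run the full bistability-detection pipeline
#'
#' Executes, in order: network construction, linkage classification,
#' conservation-law computation, independent-system selection,
#' steady-state parametrization (with automatic fallback to the explicit
#' residual mode when the parametrized solve fails), the multistart
#' saddle-node search (or evaluation of a user-supplied decision vector),
#' saddle-node screening of candidates, and confirmation by numerical
#' continuation and/or direct simulation.
#'
#' @param model a `reaction_network`, a file path (SBML or reaction list),
#'   or a character vector of reaction lines
#' @param response response species id
#' @param signal conservation total (symbol/index) or a species name whose
#'   law is the signal; defaults to the first law
#' @param mode `"eq5"` or `"eq4"`
#' @param n_starts,seed search settings
#' @param conc_bounds,rate_bounds bounds passed to [search_config()]
#' @param at optional decision-vector list (as the fixture decision
#'   vectors): skip the search and evaluate/verify this point instead
#' @param continuation,simulate which confirmation route(s) to run
#' @param signal_window half-width (relative) of the signal range explored
#'   around a candidate during confirmation
#' @param sim_points grid size of the direct simulation
#' @param t_max,ss_tol direct-simulation settings
#' @param quiet suppress progress messages
#' @param out_dir if non-NULL, write step reports (JSON/CSV) there
#' @return an object of class `pipeline_report`; its `verdict` is one of
#'   `"bistable"`, `"saddle_found_not_confirmed"`, `"no_saddle_found"`
#' @export
run_pipeline <- function(model, response, signal = 1L,
                         mode = c("eq5", "eq4"), n_starts = 50L, seed = 1L,
                         conc_bounds = c(5e-13, 5e-7), rate_bounds = NULL,
                         at = NULL, continuation = TRUE, simulate = TRUE,
                         signal_window = 0.2, sim_points = 25L,
                         t_max = 1e6, ss_tol = 1e-6, quiet = FALSE,
                         out_dir = NULL) {
  mode <- match.arg(mode)
  say <- function(...) if (!quiet) message(...)
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline step '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  net <- step("parse network", {
    if (inherits(model, "reaction_network")) model else parse_network(model)
  })
  say("network: ", length(net$species), " species, ",
      nrow(net$reactions), " reactions")
  m <- step("CRNT matrices", build_crnt_matrices(net))
  cls <- step("linkage classification", classify_linkage(net))
  say("linkage: ", if (cls$is_uniterminal) "uniterminal" else "biterminal")
  basis <- step("conservation laws", conservation_basis(m, seed = seed))
  say("conservation laws: ", paste(basis$laws, collapse = "; "))
  sig <- step("signal resolution", resolve_signal(basis, net, signal))
  sys <- step("independent system",
              select_independent_odes(m, basis, response, signal = sig))
  param <- NULL
  used_mode <- mode
  if (mode == "eq5") {
    param <- tryCatch(solve_steady_state(sys), error = function(e) {
      say("parametrized solve failed (", conditionMessage(e),
          "); falling back to the explicit-residual objective")
      NULL
    })
    if (is.null(param)) used_mode <- "eq4"
  }
  search <- NULL
  candidates <- list()
  if (is.null(at)) {
    cfg <- search_config(sys, used_mode, n_starts = n_starts, seed = seed,
                         conc_bounds = conc_bounds,
                         rate_bounds = rate_bounds)
    search <- step("saddle search", run_search(cfg, sys, param))
    say("search: best objective ", format(search$best_objective),
        ", q = ", format(search$q))
    candidates <- search$candidates
  } else {
    vals <- step("decision vector", decision_values(sys, at))
    obj <- saddle_objective(sys, param,
                            mode = if (is.null(param)) "eq4" else "eq5")
    xv <- if (is.null(param)) {
      c(vals[sys$rate_vars],
        stats::setNames(as.numeric(at$conc), paste0("c", seq_along(at$conc))))
    } else {
      c(vals[param$free_symbols],
        stats::setNames(as.numeric(at$conc), paste0("c", seq_along(at$conc))))
    }
    fx <- obj(xv)
    say("objective at supplied decision vector: ", format(fx))
    candidates <- list(list(start = 0L, objective = fx, values = vals))
  }
  reports <- list()
  diagram <- NULL
  dose <- NULL
  hyst <- NULL
  for (cand in candidates) {
    rep_i <- step("saddle-node check", saddle_node_check(sys, cand$values))
    reports[[length(reports) + 1L]] <- rep_i
  }
  best_cand <- if (length(candidates) > 0L) candidates[[1L]] else NULL
  if (!is.null(best_cand)) {
    eps0 <- best_cand$values[[sys$signal_var]]
    rng <- eps0 * c(1 - signal_window, 1 + signal_window)
    if (isTRUE(continuation)) {
      diagram <- tryCatch(
        continue_branch(sys, best_cand$values, eps_range = rng),
        error = function(e) {
          say("continuation failed (", conditionMessage(e),
              "); direct simulation is recommended")
          NULL
        })
    }
    if (isTRUE(simulate)) {
      grid <- seq(rng[1], rng[2], length.out = sim_points)
      dose <- step("direct simulation",
                   direct_simulation(sys, best_cand$values,
                                     signal_grid = grid, t_max = t_max,
                                     ss_tol = ss_tol))
      hyst <- step("hysteresis detection", detect_hysteresis(dose))
    }
  }
  verdict <- if (is.null(best_cand)) "no_saddle_found"
    else if ((!is.null(hyst) && isTRUE(hyst$bistable)) ||
             (!is.null(diagram) && !is.null(diagram$bistable_interval)))
      "bistable"
    else "saddle_found_not_confirmed"
  out <- structure(list(network = net, matrices = m, classification = cls,
                        basis = basis, system = sys, param = param,
                        mode = used_mode, search = search,
                        candidates = candidates,
                        saddle_reports = reports, diagram = diagram,
                        dose_response = dose, hysteresis = hyst,
                        verdict = verdict),
                   class = "pipeline_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    export_crnt_csv(m, out_dir)
    export_classification_json(cls, file.path(out_dir, "classification.json"))
    export_conservation_json(basis, file.path(out_dir, "conservation.json"),
                             file.path(out_dir, "B.csv"))
    export_independent_system(sys, file.path(out_dir, "reduced_system.txt"),
                              file.path(out_dir, "reduced_system.json"))
    if (!is.null(param))
      export_parametrization_json(param,
                                  file.path(out_dir, "parametrization.json"))
    if (!is.null(search))
      export_search_json(search, file.path(out_dir, "search.json"))
    if (!is.null(diagram))
      export_diagram(diagram, file.path(out_dir, "diagram.csv"),
                     file.path(out_dir, "diagram.json"))
    if (!is.null(dose))
      utils::write.csv(dose$curve, file.path(out_dir, "dose_response.csv"),
                       row.names = FALSE)
    jsonlite::write_json(list(verdict = verdict),
                         file.path(out_dir, "verdict.json"),
                         auto_unbox = TRUE)
  }
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report: verdict =", x$verdict, "\n")
  cat("  mode:", x$mode, " candidates:", length(x$candidates), "\n")
  if (!is.null(x$search))
    cat("  search: best", format(x$search$best_objective, digits = 4),
        " q =", format(x$search$q, digits = 4), "\n")
  if (!is.null(x$hysteresis)) print(x$hysteresis)
  if (!is.null(x$diagram)) print(x$diagram)
  invisible(x)
}
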
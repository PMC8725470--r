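# Packaged example networks and their published decision vectors.
#
# Three classic bistability motifs ship with the package: the Edelstein
# autocatalytic network (uniterminal), a futile signaling cycle with a
# two-state kinase (biterminal) and a prion-like double-phosphorylation
# motif (biterminal).  Each fixture carries the decision vector reported
# for it in the literature (6-decimal precision), which reproduces a
# near-zero saddle-search objective and the documented classification.

fixture_path <- function(name) {
  system.file("extdata", name, package = "crnbistab", mustWork = TRUE)
}

#' Edelstein autocatalytic network
#'
#' Three species (A, B, C), six reactions: autocatalytic production of A,
#' reversible binding of A and B into C, and interconversion of C and B.
#' Uniterminal, one conservation law `C1 = [B] + [C]`.
#'
#' @return a `reaction_network`
#' @export
edelstein_network <- function() parse_network(fixture_path("edelstein.txt"))

#' Reference decision vector for the Edelstein network
#'
#' A parameter set at which the reduced Jacobian is singular at a steady
#' state (a saddle-node candidate), with signal `C1 = [B] + [C]` and
#' response `[A]`.
#'
#' @return named list: `rates` (k1..k6), `conc` (c1..c3), `signal_total`
#'   (`C1`), `response` and `signal` designations
#' @export
edelstein_decision_vector <- function() {
  list(rates = c(k1 = 0.05024595, k2 = 0.01029913, k3 = 0.03592955,
                 k4 = 0.01027423, k5 = 0.01272131, k6 = 0.01006076),
       conc = c(c1 = 1.48685156, c2 = 2.07275022, c3 = 5.72214036),
       signal_total = c(C1 = 7.79489058),
       response = "A", signal = "C1")
}

#' Futile signaling cycle with a two-state kinase
#'
#' Substrate S is phosphorylated by the kinase form E1 and (via the shared
#' enzyme-substrate complexes) by E2; the phosphorylated form Sstar decays
#' back to S.  The C-graph is biterminal: the linkage class holding the
#' enzyme-substrate complexes has two terminal strong linkage classes
#' (release of Sstar from either complex).  Two conservation laws: total
#' enzyme and total substrate.
#'
#' @return a `reaction_network`
#' @export
futile_cycle_network <- function() parse_network(fixture_path("futile_cycle.txt"))

#' Reference decision vector for the futile cycle
#'
#' @return named list as in [edelstein_decision_vector()]; response is
#'   `Sstar` (the phosphorylated substrate), signal the total substrate
#' @export
futile_cycle_decision_vector <- function() {
  list(rates = c(k1 = 0.738028, k2 = 3.316128, k3 = 0.001800,
                 k4 = 0.050541, k5 = 0.029997, k6 = 0.53685,
                 k7 = 0.065141, k8 = 2.310671, k9 = 0.001081,
                 k10 = 0.008850, k11 = 3.437878),
       # c1 ([S]) and c2 ([E1]) reconstructed from the reported totals via
       # the conservation laws: c1 = S_tot - c4 - c3 - c6,
       # c2 = E_tot - c5 - c3 - c6
       conc = c(c1 = 39.512947, c2 = 100.925492, c3 = 957.287983,
                c4 = 605.457182, c5 = 136.645046, c6 = 70.255623),
       totals = c(E_tot = 1265.114144, S_tot = 1672.513735),
       response = "Sstar", signal_species = "S")
}

#' Prion-like double-phosphorylation motif
#'
#' A kinase with two conformations E1/E2 interconverting through a
#' prion-like catalyzed mechanism (complexes E1E2 and E2E1); only E2 is
#' active and phosphorylates substrate S in two steps to Sstarstar.
#' Biterminal; conservation of total enzyme (with coefficient-2 complex
#' terms) and total substrate.
#'
#' @return a `reaction_network`
#' @export
prion_network <- function() parse_network(fixture_path("prion.txt"))

#' Reference decision vector for the prion/double-phosphorylation motif
#'
#' @return named list; response is `Sstarstar`, signal the total substrate
#' @export
prion_decision_vector <- function() {
  list(rates = c(k1 = 27.963833, k2 = 2.417993, k3 = 2.121228,
                 k4 = 48.342142, k5 = 0.910340, k6 = 1.802118,
                 k7 = 17.019827, k8 = 92.473965, k9 = 0.021611,
                 k10 = 0.782488, k11 = 3.692336, k12 = 0.205743,
                 k13 = 0.063297, k14 = 0.235401),
       conc = c(c1 = 14.749224, c2 = 18.117522, c3 = 22.377604,
                c4 = 11.304051, c5 = 27.001718, c6 = 8.264281,
                c7 = 90.016969, c8 = 97.695329, c9 = 30.056006),
       totals = c(S_tot = 253.034303, E_tot = 220.303031),
       response = "Sstarstar", signal_species = "S")
}

#' Random mass-action network with guaranteed conservation laws
#'
#' Generates a network whose species are built from a fixed set of
#' conserved moieties (two by default): monomer species carry one moiety
#' unit, dimer species the sum of two monomer compositions, and reactions
#' only recombine these compositions (association, dissociation,
#' isomerization).  Every reaction conserves each moiety count, so the
#' network has at least one conservation law by construction.
#'
#' @param n_species number of species (>= 2)
#' @param n_reactions number of directed reactions (>= 1)
#' @param max_molecularity cap on the total molecularity of a complex
#' @param seed integer seed; the same seed reproduces the same network
#' @return a `reaction_network` with attribute `"moiety_basis"` holding the
#'   species x moiety composition matrix (a certificate that
#'   `t(S) %*% basis == 0`)
#' @export
generate_random_network <- function(n_species, n_reactions,
                                    max_molecularity = 2L, seed = 1L) {
  if (n_species < 2L || n_reactions < 1L)
    stop("need n_species >= 2 and n_reactions >= 1")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  n_moiety <- 2L
  # compositions: the two pure monomers, the heterodimer (when molecularity
  # allows), then random copies or admissible sums of earlier compositions;
  # copies keep the pool of moiety-conserving reactions rich
  comp <- matrix(0L, n_species, n_moiety)
  comp[1L, 1L] <- 1L
  comp[2L, 2L] <- 1L
  if (n_species >= 3L && max_molecularity >= 2L) comp[3L, ] <- c(1L, 1L)
  start <- if (n_species >= 3L && max_molecularity >= 2L) 4L else 3L
  for (i in seq_len(n_species)[seq_len(n_species) >= start]) {
    if (max_molecularity >= 2L && stats::runif(1) < 0.3) {
      ab <- sample.int(i - 1L, 2L, replace = TRUE)
      cand <- comp[ab[1L], ] + comp[ab[2L], ]
      if (sum(cand) <= max_molecularity) {
        comp[i, ] <- cand
        next
      }
    }
    comp[i, ] <- comp[sample.int(i - 1L, 1L), ]
  }
  build_pool <- function(comp) {
    key <- apply(comp, 1L, paste, collapse = ",")
    pool <- list()
    for (i in seq_len(n_species)) for (j in seq_len(n_species)) {
      if (i != j && key[i] == key[j])
        pool[[length(pool) + 1L]] <- list(src = c(i), tgt = c(j))
    }
    for (a in seq_len(n_species)) for (b in a:n_species) {
      tot <- comp[a, ] + comp[b, ]
      if (sum(tot) > max_molecularity) next
      dimers <- which(apply(comp, 1L, function(x) all(x == tot)))
      for (d in dimers) {
        if (d == a || d == b) next
        pool[[length(pool) + 1L]] <- list(src = c(a, b), tgt = c(d))
        pool[[length(pool) + 1L]] <- list(src = c(d), tgt = c(a, b))
      }
    }
    pool
  }
  pool <- build_pool(comp)
  # if the drawn compositions admit too few reactions, progressively turn
  # the later species into copies of the core compositions, which enriches
  # the pool of isomerizations and association routes
  fix_i <- n_species
  while (length(pool) < n_reactions && fix_i >= 4L) {
    comp[fix_i, ] <- comp[((fix_i - 1L) %% 3L) + 1L, ]
    pool <- build_pool(comp)
    fix_i <- fix_i - 1L
  }
  if (length(pool) < n_reactions)
    stop("infeasible size combination: only ", length(pool),
         " distinct moiety-conserving reactions exist for these species")
  picks <- sample.int(length(pool), n_reactions)
  sp_names <- paste0("X", seq_len(n_species))
  lines <- vapply(pool[picks], function(rx) {
    side <- function(v) {
      tab <- table(sp_names[v])
      paste(ifelse(tab == 1L, names(tab), paste0(tab, names(tab))),
            collapse = " + ")
    }
    paste(side(rx$src), "->", side(rx$tgt))
  }, character(1))
  net <- parse_reaction_text(c(paste("@species:",
                                     paste(sp_names, collapse = " ")), lines))
  attr(net, "moiety_basis") <- comp
  net
}
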
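# Moiety conservation laws: a nonnegative integer basis of Null(S^T).
#
# The signed rational nullspace is computed exactly; nonnegative basis
# vectors are then located as vertices of the polytope
# {B~ x : B~ x >= 0, sum(B~ x) = 1} by repeatedly minimizing a random
# direction with the simplex method and integer-rescaling the optimizers.

#' Exact rational nullspace of the transposed stoichiometric matrix
#'
#' @param S integer stoichiometric matrix (species x reactions)
#' @return an N x lambda integer matrix whose columns span `Null(S^T)`
#'   exactly (entries may be signed)
#' @export
rational_nullspace <- function(S) {
  B <- rat_nullspace_int(t(S))
  if (ncol(B) == 0L)
    stop("no conservation laws: rank(S) = N; networks without conservation ",
         "laws are outside the scope of this method")
  B
}

# one LP vertex search: minimize w' x  s.t.  -B~ x <= 0, sum(B~ x) = 1
lp_vertex <- function(Btil, w) {
  lam <- ncol(Btil)
  colsum <- colSums(Btil)
  # free x via x = p - q, p, q >= 0
  a <- c(w, -w)
  A1 <- cbind(-Btil, Btil)
  b1 <- rep(0, nrow(Btil))
  A3 <- matrix(c(colsum, -colsum), 1L)
  b3 <- 1
  sol <- tryCatch(
    boot::simplex(a = a, A1 = A1, b1 = b1, A3 = A3, b3 = b3, maxi = FALSE),
    error = function(e) NULL)
  if (is.null(sol) || sol$solved != 1) return(NULL)
  x <- sol$soln[seq_len(lam)] - sol$soln[lam + seq_len(lam)]
  v <- as.numeric(Btil %*% x)
  v[abs(v) < 1e-9] <- 0
  if (any(v < 0) || all(v == 0)) return(NULL)
  v
}

#' Nonnegative integer conservation-law basis
#'
#' Starting from a signed rational basis of `Null(S^T)`, repeatedly solves
#' the vertex-search linear program with a fresh random direction, rescales
#' each optimizer to a minimal integer vector, and collects unique,
#' linearly independent nonnegative vectors until `lambda = N - rank(S)`
#' of them are found.
#'
#' @param S integer stoichiometric matrix (species x reactions), or a
#'   `crnt_matrices` object
#' @param max_iter maximum number of LP draws (default `100 * lambda`)
#' @param seed integer seed for the random search directions
#' @return an object of class `conservation_basis`: `B` (N x lambda
#'   nonnegative integer matrix with `S^T B = 0` exactly), `laws`
#'   (human-readable expressions), `totals` (symbols `C1..Clam`)
#' @export
conservation_basis <- function(S, max_iter = NULL, seed = 1L) {
  species <- NULL
  if (inherits(S, "crnt_matrices")) {
    species <- S$network$species
    S <- S$S
  } else if (!is.null(rownames(S))) species <- rownames(S)
  Btil <- rational_nullspace(S)
  lam <- ncol(Btil)
  if (is.null(max_iter)) max_iter <- 100L * lam
  found <- matrix(0, nrow(S), 0L)
  keys <- character(0)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  for (it in seq_len(max_iter)) {
    w <- stats::runif(lam, -1, 1)
    v <- lp_vertex(Btil, w)
    if (is.null(v)) next
    v <- integer_scale(v)
    # exact membership check: S^T v must vanish identically
    if (any(abs(t(S) %*% v) > 1e-8)) next
    key <- paste(v, collapse = ",")
    if (key %in% keys) next
    cand <- cbind(found, v)
    if (rat_rank(cand) == ncol(cand)) {
      found <- cand
      keys <- c(keys, key)
      if (ncol(found) == lam) break
    }
  }
  if (ncol(found) < lam) {
    if (ncol(found) == 0L && lam > 0L)
      stop("no nonnegative basis vector was found for Null(S^T)")
    stop("found only ", ncol(found), " of ", lam, " nonnegative basis ",
         "vectors; the number of iterations should be increased")
  }
  dimnames(found) <- list(species, paste0("C", seq_len(lam)))
  laws <- vapply(seq_len(lam), function(j) {
    nz <- which(found[, j] != 0)
    terms <- ifelse(found[nz, j] == 1, paste0("c", nz),
                    paste0(found[nz, j], "*c", nz))
    paste0("C", j, " = ", paste(terms, collapse = " + "))
  }, character(1))
  structure(list(B = found, laws = laws,
                 totals = paste0("C", seq_len(lam)),
                 species = species),
            class = "conservation_basis")
}

#' @export
print.conservation_basis <- function(x, ...) {
  cat("conservation_basis:", ncol(x$B), "law(s)\n")
  for (l in x$laws) cat(" ", l, "\n")
  invisible(x)
}

#' Export conservation laws as JSON (and the B matrix as CSV)
#'
#' @param basis a `conservation_basis`
#' @param json_path path of the JSON report; coefficients are keyed by
#'   species id where species names are known
#' @param csv_path optional path for the `B` matrix as CSV
#' @return invisibly, the paths written
#' @export
export_conservation_json <- function(basis, json_path, csv_path = NULL) {
  ids <- if (!is.null(basis$species)) basis$species else
    paste0("c", seq_len(nrow(basis$B)))
  laws <- lapply(seq_len(ncol(basis$B)), function(j) {
    nz <- which(basis$B[, j] != 0)
    list(total_symbol = basis$totals[j],
         coefficients = as.list(stats::setNames(basis$B[nz, j], ids[nz])))
  })
  jsonlite::write_json(laws, json_path, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(csv_path)) utils::write.csv(basis$B, csv_path)
  invisible(c(json_path, csv_path))
}
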
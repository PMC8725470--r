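# Reaction-network representation and CRNT matrices.
#
# A network is a list of directed mass-action reactions between complexes
# (multisets of species).  Reversible input reactions are expanded into two
# directed reactions, forward before backward, and rate constants are
# numbered k1..kR in expansion order so that each arrow of the C-graph
# carries its own constant.

new_reaction_network <- function(species, complexes, reactions) {
  structure(list(species = species, complexes = complexes,
                 reactions = reactions),
            class = "reaction_network")
}

complex_key <- function(cmp) {
  if (length(cmp) == 0L) return("0")
  cmp <- cmp[order(names(cmp), method = "radix")]
  paste(paste0(cmp, "*", names(cmp)), collapse = "+")
}

format_complex <- function(cmp) {
  if (length(cmp) == 0L) return("0")
  paste(ifelse(cmp == 1L, names(cmp), paste0(cmp, names(cmp))),
        collapse = " + ")
}

parse_complex_text <- function(txt, line_no) {
  txt <- trimws(txt)
  if (txt == "" ) stop("empty complex on line ", line_no)
  if (txt == "0") return(integer(0))
  parts <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
  n_plus <- lengths(regmatches(txt, gregexpr("+", txt, fixed = TRUE)))
  if (length(parts) != n_plus + 1L || any(parts == ""))
    stop("dangling '+' in complex '", txt, "' on line ", line_no)
  cmp <- integer(0)
  for (p in parts) {
    m <- regmatches(p, regexec("^([0-9]*)\\s*([A-Za-z_][A-Za-z0-9_]*)$", p))[[1]]
    if (length(m) == 0L)
      stop("cannot parse species term '", p, "' on line ", line_no)
    mult <- if (m[2] == "") 1L else as.integer(m[2])
    sp <- m[3]
    cmp[sp] <- (if (sp %in% names(cmp)) cmp[[sp]] else 0L) + mult
  }
  cmp
}

#' Parse a reaction network
#'
#' Reads a mass-action reaction network from either a plain-text reaction
#' list or an SBML Level 3 (core subset) file.  The text dialect has one
#' reaction per line: complexes are `+`-separated species with optional
#' integer stoichiometric prefixes (`2A`), `->` is an irreversible reaction
#' and `<->` a reversible one (expanded into forward and backward directed
#' reactions), `#` starts a comment, and an optional `@species:` directive
#' pins the species ordering.  Rate constants are numbered `k1..kR` in
#' expansion order.
#'
#' @param source path to a file (text list or SBML, detected by content), or
#'   a character vector of reaction lines
#' @return an object of class `reaction_network` with fields `species`
#'   (ordered identifiers), `complexes` (list of named integer multisets)
#'   and `reactions` (data frame with source/target complex indices and rate
#'   symbols)
#' @examples
#' net <- parse_network(c("A -> 2A", "2A -> A", "A + B <-> C",
#'                        "C -> B", "B -> C"))
#' net
#' @export
parse_network <- function(source) {
  if (length(source) == 1L && file.exists(source)) {
    head_txt <- paste(readLines(source, n = 5L, warn = FALSE), collapse = " ")
    if (grepl("<sbml", head_txt, fixed = TRUE))
      return(parse_sbml(source))
    source <- readLines(source, warn = FALSE)
  }
  parse_reaction_text(source)
}

parse_reaction_text <- function(lines) {
  lines <- sub("#.*$", "", lines)
  species_order <- character(0)
  raw <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") next
    if (grepl("^@species:", ln)) {
      species_order <- strsplit(trimws(sub("^@species:", "", ln)),
                                "[,\\s]+", perl = TRUE)[[1]]
      next
    }
    for (part in trimws(strsplit(ln, ";", fixed = TRUE)[[1]])) {
      if (part == "") next
      rev <- grepl("<->", part, fixed = TRUE)
      sides <- if (rev) strsplit(part, "<->", fixed = TRUE)[[1]] else
        strsplit(part, "->", fixed = TRUE)[[1]]
      if (length(sides) != 2L)
        stop("cannot parse reaction on line ", i, ": '", part, "'")
      src <- parse_complex_text(sides[1], i)
      tgt <- parse_complex_text(sides[2], i)
      if (length(src) == 0L && length(tgt) == 0L)
        stop("reaction with empty source and empty target on line ", i)
      raw[[length(raw) + 1L]] <- list(src = src, tgt = tgt)
      if (rev) raw[[length(raw) + 1L]] <- list(src = tgt, tgt = src)
    }
  }
  if (length(raw) == 0L) stop("no reactions found")
  build_network_from_pairs(raw, species_order)
}

build_network_from_pairs <- function(raw, species_order = character(0)) {
  species <- species_order
  for (rx in raw) {
    for (sp in c(names(rx$src), names(rx$tgt)))
      if (!(sp %in% species)) species <- c(species, sp)
  }
  if (anyDuplicated(species))
    stop("duplicate species id: ",
         paste(unique(species[duplicated(species)]), collapse = ", "))
  complexes <- list()
  keys <- character(0)
  idx_of <- function(cmp) {
    key <- complex_key(cmp)
    i <- match(key, keys)
    if (is.na(i)) {
      complexes[[length(complexes) + 1L]] <<- cmp
      keys <<- c(keys, key)
      i <- length(keys)
    }
    i
  }
  src_i <- integer(0); tgt_i <- integer(0)
  for (rx in raw) {
    src_i <- c(src_i, idx_of(rx$src))
    tgt_i <- c(tgt_i, idx_of(rx$tgt))
  }
  reactions <- data.frame(source = src_i, target = tgt_i,
                          rate = paste0("k", seq_along(src_i)),
                          stringsAsFactors = FALSE)
  if (any(reactions$source == reactions$target))
    stop("reaction with identical source and target complex")
  net <- new_reaction_network(species, complexes, reactions)
  validate_network(net)
  net
}

parse_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed SBML file '", path,
                                           "': ", conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (length(sp_nodes) == 0L) stop("SBML file contains no species")
  species <- xml2::xml_attr(sp_nodes, "id")
  if (anyNA(species)) stop("SBML species element without id attribute")
  if (anyDuplicated(species))
    stop("duplicate species id: ",
         paste(unique(species[duplicated(species)]), collapse = ", "))
  boundary <- xml2::xml_attr(sp_nodes, "boundaryCondition")
  if (any(boundary %in% "true"))
    warning("boundary species flags are ignored; mass action is imposed ",
            "from stoichiometry alone")
  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (length(rx_nodes) == 0L) stop("SBML file contains no reactions")
  read_side <- function(node, tag) {
    refs <- xml2::xml_find_all(node, paste0("./", tag, "/speciesReference"))
    cmp <- integer(0)
    for (ref in refs) {
      sp <- xml2::xml_attr(ref, "species")
      if (is.na(sp) || !(sp %in% species))
        stop("speciesReference to unknown species in reaction '",
             xml2::xml_attr(node, "id"), "'")
      st <- xml2::xml_attr(ref, "stoichiometry")
      st <- if (is.na(st)) 1L else as.integer(round(as.numeric(st)))
      cmp[sp] <- (if (sp %in% names(cmp)) cmp[[sp]] else 0L) + st
    }
    cmp
  }
  raw <- list()
  for (node in rx_nodes) {
    src <- read_side(node, "listOfReactants")
    tgt <- read_side(node, "listOfProducts")
    if (length(src) == 0L && length(tgt) == 0L)
      stop("reaction '", xml2::xml_attr(node, "id"),
           "' has empty reactant and product lists")
    raw[[length(raw) + 1L]] <- list(src = src, tgt = tgt)
    if (identical(xml2::xml_attr(node, "reversible"), "true"))
      raw[[length(raw) + 1L]] <- list(src = tgt, tgt = src)
  }
  build_network_from_pairs(raw, species)
}

validate_network <- function(net) {
  N <- length(net$species)
  M <- length(net$complexes)
  R <- nrow(net$reactions)
  if (N < 1L || R < 1L || M < 2L)
    stop("degenerate network: need N >= 1, R >= 1, M >= 2")
  stopifnot(all(net$reactions$source %in% seq_len(M)),
            all(net$reactions$target %in% seq_len(M)))
  invisible(net)
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("reaction_network:", length(x$species), "species,",
      nrow(x$reactions), "reactions,", length(x$complexes), "complexes\n")
  cat("species:", paste(x$species, collapse = ", "), "\n")
  for (i in seq_len(nrow(x$reactions))) {
    cat(sprintf("  %-4s %s -> %s\n", x$reactions$rate[i],
                format_complex(x$complexes[[x$reactions$source[i]]]),
                format_complex(x$complexes[[x$reactions$target[i]]])))
  }
  invisible(x)
}

#' Construct the CRNT matrices of a network
#'
#' Builds the molecularity matrix `Y` (species x complexes), the symbolic
#' kinetic matrix `A` (complexes x complexes, entries polynomial in the rate
#' constants, columns summing to zero), the stoichiometric matrix
#' `S = Y[, target] - Y[, source]` per reaction, the mass-action monomial
#' exponents of `psi`, and the exact rational rank `s` of `S` together with
#' the number of conservation laws `lambda = N - s`.
#'
#' @param net a `reaction_network`
#' @return an object of class `crnt_matrices`
#' @export
build_crnt_matrices <- function(net) {
  validate_network(net)
  N <- length(net$species); M <- length(net$complexes)
  R <- nrow(net$reactions)
  Y <- matrix(0L, N, M, dimnames = list(net$species, NULL))
  for (j in seq_len(M)) {
    cmp <- net$complexes[[j]]
    if (length(cmp) > 0L) Y[names(cmp), j] <- cmp
  }
  S <- matrix(0L, N, R,
              dimnames = list(net$species, net$reactions$rate))
  for (r in seq_len(R)) {
    S[, r] <- Y[, net$reactions$target[r]] - Y[, net$reactions$source[r]]
  }
  A <- cpm(rep(list(cp_zero()), M * M), M, M)
  for (r in seq_len(R)) {
    i <- net$reactions$source[r]; j <- net$reactions$target[r]
    kr <- cp_var(net$reactions$rate[r])
    A[[j + (i - 1L) * M]] <- cp_add(cpm_get(A, j, i), kr)
    A[[i + (i - 1L) * M]] <- cp_sub(cpm_get(A, i, i), kr)
  }
  s <- rat_rank(S)
  structure(list(network = net, Y = Y, A = A, S = S,
                 psi_exponents = t(Y), s = s, lam = N - s),
            class = "crnt_matrices")
}

#' @export
print.crnt_matrices <- function(x, ...) {
  cat("crnt_matrices: N =", nrow(x$Y), " M =", ncol(x$Y),
      " R =", ncol(x$S), " rank(S) =", x$s,
      " lambda =", x$lam, "\n")
  invisible(x)
}

# mass-action monomial of complex j as a cpoly in the concentration vars
psi_monomial <- function(m, j, conc_vars) {
  y <- m$Y[, j]
  nz <- which(y > 0L)
  if (length(nz) == 0L) return(cp_const(1))
  Reduce(cp_mul, lapply(nz, function(i) cp_var(conc_vars[i], y[i])))
}

conc_var_names <- function(net) paste0("c", seq_along(net$species))

# per-species mass-action right-hand sides via S and the reaction rates
mass_action_rhs <- function(m) {
  net <- m$network
  cv <- conc_var_names(net)
  R <- ncol(m$S)
  rates <- lapply(seq_len(R), function(r)
    cp_mul(cp_var(net$reactions$rate[r]),
           psi_monomial(m, net$reactions$source[r], cv)))
  lapply(seq_len(nrow(m$S)), function(i) {
    cp_sum(lapply(which(m$S[i, ] != 0), function(r)
      cp_scale(rates[[r]], m$S[i, r])))
  })
}

# per-species right-hand sides via Y %*% A %*% psi (the CRNT construction);
# used to cross-check mass_action_rhs
yapsi_rhs <- function(m) {
  net <- m$network
  cv <- conc_var_names(net)
  M <- ncol(m$Y)
  psi <- lapply(seq_len(M), function(j) psi_monomial(m, j, cv))
  apsi <- lapply(seq_len(M), function(i)
    cp_sum(lapply(seq_len(M), function(j)
      cp_mul(cpm_get(m$A, i, j), psi[[j]]))))
  lapply(seq_len(nrow(m$Y)), function(sp)
    cp_sum(lapply(which(m$Y[sp, ] != 0), function(j)
      cp_scale(apsi[[j]], m$Y[sp, j]))))
}

#' Export CRNT matrices to CSV files
#'
#' Writes `Y`, `S` and a symbol table for `A` into a directory, with species,
#' complex and reaction labels as header rows.
#'
#' @param m a `crnt_matrices` object
#' @param dir output directory (created if missing)
#' @return invisibly, the paths written
#' @export
export_crnt_csv <- function(m, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  net <- m$network
  cmplx_labels <- vapply(net$complexes, format_complex, character(1))
  Y <- m$Y; colnames(Y) <- cmplx_labels
  pY <- file.path(dir, "Y.csv")
  utils::write.csv(Y, pY)
  pS <- file.path(dir, "S.csv")
  utils::write.csv(m$S, pS)
  M <- ncol(m$Y)
  Atab <- matrix("0", M, M, dimnames = list(cmplx_labels, cmplx_labels))
  for (i in seq_len(M)) for (j in seq_len(M))
    Atab[i, j] <- cp_to_string(cpm_get(m$A, i, j))
  pA <- file.path(dir, "A.csv")
  utils::write.csv(Atab, pA)
  invisible(c(pY, pS, pA))
}
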
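# Sparse multivariate polynomial arithmetic.
#
# Mass-action right-hand sides, conservation substitutions, Jacobians and
# steady-state parametrizations are all polynomial (or ratios of polynomials)
# in the rate constants k1..kR, the independent concentrations c1..cN and the
# conservation totals C1..Clam.  A polynomial is stored sparsely as a
# coefficient vector plus an integer exponent matrix (one row per term, one
# column per variable).  Coefficients are doubles; all fixture manipulations
# stay on small integers (and dyadic rationals), so identity checks on them
# are exact.  Variable names are kept per-polynomial and aligned on demand.

cp_zero <- function() {
  structure(list(coef = numeric(0),
                 expo = matrix(0L, 0L, 0L, dimnames = list(NULL, character(0)))),
            class = "cpoly")
}

#' @noRd
cp_const <- function(x) {
  if (x == 0) return(cp_zero())
  structure(list(coef = as.numeric(x),
                 expo = matrix(0L, 1L, 0L, dimnames = list(NULL, character(0)))),
            class = "cpoly")
}

cp_var <- function(name, pow = 1L, coef = 1) {
  expo <- matrix(as.integer(pow), 1L, 1L, dimnames = list(NULL, name))
  structure(list(coef = as.numeric(coef), expo = expo), class = "cpoly")
}

is_cpoly <- function(p) inherits(p, "cpoly")

# zero-column matrices drop their dimnames; normalize to character(0)
expo_vars <- function(expo) {
  v <- colnames(expo)
  if (is.null(v)) character(0) else v
}

as_cpoly <- function(x) {
  if (is_cpoly(x)) x else cp_const(x)
}

# drop zero coefficients, merge duplicate monomials, drop unused variables,
# order terms deterministically
cp_canon <- function(p, tol = 0) {
  coef <- p$coef
  expo <- p$expo
  if (length(coef) == 0L) return(cp_zero())
  if (ncol(expo) > 0L) {
    used <- colSums(abs(expo)) > 0L
    expo <- expo[, used, drop = FALSE]
    if (ncol(expo) > 1L) {
      ord <- order(colnames(expo), method = "radix")
      expo <- expo[, ord, drop = FALSE]
    }
  }
  key <- if (ncol(expo) == 0L) rep("", nrow(expo)) else
    apply(expo, 1L, paste0, collapse = ",")
  agg <- rowsum(coef, key, reorder = TRUE)
  keep_rows <- match(rownames(agg), key)
  coef <- as.numeric(agg[, 1L])
  expo <- expo[keep_rows, , drop = FALSE]
  scale <- max(abs(coef), 0)
  nz <- if (tol > 0 && scale > 0) abs(coef) > tol * scale else coef != 0
  coef <- coef[nz]
  expo <- expo[nz, , drop = FALSE]
  if (length(coef) == 0L) return(cp_zero())
  if (ncol(expo) > 0L) {
    used <- colSums(abs(expo)) > 0L
    expo <- expo[, used, drop = FALSE]
  }
  structure(list(coef = coef, expo = expo), class = "cpoly")
}

# embed exponent matrix into a common variable set
cp_embed <- function(expo, vars) {
  out <- matrix(0L, nrow(expo), length(vars), dimnames = list(NULL, vars))
  if (ncol(expo) > 0L && nrow(expo) > 0L)
    out[, colnames(expo)] <- expo
  out
}

cp_add <- function(p, q) {
  p <- as_cpoly(p); q <- as_cpoly(q)
  if (length(p$coef) == 0L) return(q)
  if (length(q$coef) == 0L) return(p)
  vars <- union(expo_vars(p$expo), expo_vars(q$expo))
  vars <- vars[order(vars, method = "radix")]
  expo <- rbind(cp_embed(p$expo, vars), cp_embed(q$expo, vars))
  cp_canon(structure(list(coef = c(p$coef, q$coef), expo = expo),
                     class = "cpoly"))
}

cp_neg <- function(p) {
  p <- as_cpoly(p)
  p$coef <- -p$coef
  p
}

cp_sub <- function(p, q) cp_add(p, cp_neg(q))

cp_scale <- function(p, a) {
  p <- as_cpoly(p)
  if (a == 0) return(cp_zero())
  p$coef <- p$coef * a
  p
}

cp_mul <- function(p, q) {
  p <- as_cpoly(p); q <- as_cpoly(q)
  np <- length(p$coef); nq <- length(q$coef)
  if (np == 0L || nq == 0L) return(cp_zero())
  vars <- union(expo_vars(p$expo), expo_vars(q$expo))
  vars <- vars[order(vars, method = "radix")]
  pe <- cp_embed(p$expo, vars); qe <- cp_embed(q$expo, vars)
  ip <- rep(seq_len(np), times = nq)
  iq <- rep(seq_len(nq), each = np)
  cp_canon(structure(list(coef = p$coef[ip] * q$coef[iq],
                          expo = pe[ip, , drop = FALSE] + qe[iq, , drop = FALSE]),
                     class = "cpoly"))
}

cp_pow <- function(p, n) {
  n <- as.integer(n)
  stopifnot(n >= 0L)
  out <- cp_const(1)
  if (n == 0L) return(out)
  base <- as_cpoly(p)
  while (n > 0L) {
    if (n %% 2L == 1L) out <- cp_mul(out, base)
    base_needed <- n %/% 2L > 0L
    n <- n %/% 2L
    if (base_needed && n > 0L) base <- cp_mul(base, base)
  }
  out
}

cp_sum <- function(ps) Reduce(cp_add, ps, cp_zero())

#' @noRd
cp_deriv <- function(p, var) {
  p <- as_cpoly(p)
  if (length(p$coef) == 0L || !(var %in% colnames(p$expo))) return(cp_zero())
  e <- p$expo[, var]
  keep <- e > 0L
  if (!any(keep)) return(cp_zero())
  coef <- p$coef[keep] * e[keep]
  expo <- p$expo[keep, , drop = FALSE]
  expo[, var] <- expo[, var] - 1L
  cp_canon(structure(list(coef = coef, expo = expo), class = "cpoly"))
}

# substitute a polynomial for a variable
cp_subst <- function(p, var, q) {
  p <- as_cpoly(p)
  if (length(p$coef) == 0L || !(var %in% colnames(p$expo))) return(p)
  q <- as_cpoly(q)
  e <- p$expo[, var]
  rest <- p$expo[, setdiff(colnames(p$expo), var), drop = FALSE]
  terms <- vector("list", length(p$coef))
  powers <- list(`0` = cp_const(1))
  for (i in seq_along(p$coef)) {
    key <- as.character(e[i])
    if (is.null(powers[[key]])) powers[[key]] <- cp_pow(q, e[i])
    mono <- structure(list(coef = p$coef[i], expo = rest[i, , drop = FALSE]),
                      class = "cpoly")
    terms[[i]] <- cp_mul(mono, powers[[key]])
  }
  cp_sum(terms)
}

# substitute several variables at once (values: named list of cpoly/numeric)
cp_subst_all <- function(p, values) {
  for (v in names(values)) p <- cp_subst(p, v, values[[v]])
  p
}

cp_vars <- function(p) expo_vars(as_cpoly(p)$expo)

cp_eval <- function(p, vals) {
  p <- as_cpoly(p)
  if (length(p$coef) == 0L) return(0)
  vars <- expo_vars(p$expo)
  if (length(vars) == 0L) return(sum(p$coef))
  v <- vals[vars]
  if (anyNA(v)) stop("missing values for variables: ",
                     paste(vars[is.na(v)], collapse = ", "))
  monos <- exp(p$expo %*% matrix(log(abs(v) + (v == 0)), ncol = 1L))
  # handle zeros and signs exactly
  zero_mask <- p$expo %*% matrix(as.numeric(v == 0), ncol = 1L) > 0
  sgn <- (-1) ^ (p$expo %*% matrix(as.numeric(v < 0), ncol = 1L))
  vals_terms <- p$coef * as.numeric(monos) * as.numeric(sgn)
  vals_terms[as.logical(zero_mask)] <- vapply(which(as.logical(zero_mask)),
    function(i) p$coef[i] * prod(v ^ p$expo[i, ]), numeric(1))
  sum(vals_terms)
}

cp_is_zero <- function(p, tol = 1e-9) {
  p <- cp_canon(as_cpoly(p))
  length(p$coef) == 0L || max(abs(p$coef)) <= tol
}

cp_equal <- function(p, q, tol = 1e-9) cp_is_zero(cp_sub(p, q), tol = tol)

# render to an R expression string, e.g. "k1*c1 - 2*k2*c1^2"
cp_to_string <- function(p) {
  p <- cp_canon(as_cpoly(p))
  if (length(p$coef) == 0L) return("0")
  vars <- colnames(p$expo)
  term_str <- vapply(seq_along(p$coef), function(i) {
    e <- p$expo[i, ]
    facs <- character(0)
    co <- p$coef[i]
    if (length(vars) > 0L) {
      nz <- which(e > 0L)
      facs <- vapply(nz, function(j) {
        if (e[j] == 1L) vars[j] else paste0(vars[j], "^", e[j])
      }, character(1))
    }
    co_str <- if (abs(co) == 1 && length(facs) > 0L) {
      if (co < 0) "-" else ""
    } else {
      paste0(format(co, digits = 15), if (length(facs) > 0L) "*" else "")
    }
    paste0(co_str, paste(facs, collapse = "*"))
  }, character(1))
  out <- term_str[1]
  for (i in seq_along(term_str)[-1]) {
    t <- term_str[i]
    out <- if (startsWith(t, "-")) paste0(out, " - ", substring(t, 2)) else
      paste0(out, " + ", t)
  }
  out
}

#' @export
format.cpoly <- function(x, ...) cp_to_string(x)

#' @export
print.cpoly <- function(x, ...) {
  cat(cp_to_string(x), "\n")
  invisible(x)
}

# ---- polynomial matrices -------------------------------------------------

# list-matrix of cpoly, stored as a list with dim attribute
cpm <- function(entries, nrow, ncol) {
  stopifnot(length(entries) == nrow * ncol)
  structure(entries, dim = c(nrow, ncol), class = "cpoly_matrix")
}

cpm_get <- function(m, i, j) m[[i + (j - 1L) * dim(m)[1L]]]

cpm_map <- function(m, f) {
  out <- lapply(unclass(m), f)
  structure(out, dim = dim(m), class = "cpoly_matrix")
}

# symbolic determinant by cofactor expansion along the sparsest row;
# intended for small matrices only
cpm_det <- function(m) {
  n <- dim(m)[1L]
  stopifnot(n == dim(m)[2L])
  if (n == 1L) return(cpm_get(m, 1L, 1L))
  nterms <- matrix(vapply(unclass(m), function(p) length(as_cpoly(p)$coef),
                          numeric(1)), n, n)
  row_i <- which.min(rowSums(nterms > 0) * 1000 + rowSums(nterms))
  acc <- cp_zero()
  for (j in seq_len(n)) {
    pij <- cpm_get(m, row_i, j)
    if (length(as_cpoly(pij)$coef) == 0L) next
    rows <- setdiff(seq_len(n), row_i)
    cols <- setdiff(seq_len(n), j)
    minor <- cpm(unlist(lapply(cols, function(cc)
      lapply(rows, function(rr) cpm_get(m, rr, cc))), recursive = FALSE),
      n - 1L, n - 1L)
    term <- cp_mul(pij, cpm_det(minor))
    if ((row_i + j) %% 2L == 1L) term <- cp_neg(term)
    acc <- cp_add(acc, term)
  }
  acc
}

# evaluate a polynomial matrix numerically
cpm_eval <- function(m, vals) {
  matrix(vapply(unclass(m), cp_eval, numeric(1), vals = vals),
         dim(m)[1L], dim(m)[2L])
}

# compile a list of polynomials into a fast function(envlist) -> numeric
# vector; all variables must be bound in the supplied environment/list
compile_polys <- function(polys) {
  strs <- vapply(polys, cp_to_string, character(1))
  body_txt <- paste0("c(", paste(strs, collapse = ",\n"), ")")
  fun_txt <- paste0("function(.env) with(.env, ", body_txt, ")")
  eval(parse(text = fun_txt)[[1]])
}
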
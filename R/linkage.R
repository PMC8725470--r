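# Linkage classes and terminal strong linkage classes of the C-graph.

#' Classify linkage structure of a reaction network
#'
#' Computes the linkage classes (connected components of the undirected
#' C-graph), the strong components of the directed C-graph, and for every
#' linkage class its terminal strong linkage classes: maximal strongly
#' connected sets of complexes with no edge leaving the set.  A single
#' complex with no outgoing edge counts as terminal (a complex is strongly
#' linked to itself).  The network is uniterminal when every linkage class
#' has exactly one terminal strong linkage class, and biterminal when some
#' linkage class has two or more.
#'
#' @param net a `reaction_network`
#' @return an object of class `linkage_classification` with elements
#'   `linkage_classes` (list of integer vectors of complex indices),
#'   `terminal_sl_classes` (per linkage class, a list of terminal strong
#'   linkage classes), and `is_uniterminal`
#' @export
classify_linkage <- function(net) {
  validate_network(net)
  M <- length(net$complexes)
  edges <- cbind(net$reactions$source, net$reactions$target)
  g <- igraph::graph_from_edgelist(edges, directed = TRUE)
  if (igraph::vcount(g) < M)
    g <- igraph::add_vertices(g, M - igraph::vcount(g))
  weak <- igraph::components(g, mode = "weak")$membership
  strong <- igraph::components(g, mode = "strong")$membership
  linkage_classes <- split(seq_len(M), weak)
  names(linkage_classes) <- NULL
  # a strong component is terminal iff no edge leaves it
  scc_ids <- sort(unique(strong))
  leaves <- rep(FALSE, length(scc_ids))
  for (e in seq_len(nrow(edges))) {
    si <- strong[edges[e, 1L]]; ti <- strong[edges[e, 2L]]
    if (si != ti) leaves[si] <- TRUE
  }
  terminal_sl_classes <- lapply(linkage_classes, function(lc) {
    comps <- split(lc, strong[lc])
    comps <- comps[!leaves[as.integer(names(comps))]]
    names(comps) <- NULL
    comps
  })
  n_term <- vapply(terminal_sl_classes, length, integer(1))
  structure(list(linkage_classes = linkage_classes,
                 terminal_sl_classes = terminal_sl_classes,
                 is_uniterminal = all(n_term == 1L),
                 network = net),
            class = "linkage_classification")
}

#' @export
print.linkage_classification <- function(x, ...) {
  nt <- vapply(x$terminal_sl_classes, length, integer(1))
  cat("linkage classes:", length(x$linkage_classes), "-",
      if (x$is_uniterminal) "uniterminal" else
        if (any(nt >= 2L)) "biterminal" else "mixed terminality", "\n")
  for (i in seq_along(x$linkage_classes)) {
    lbl <- vapply(x$network$complexes[x$linkage_classes[[i]]],
                  format_complex, character(1))
    cat(sprintf("  L%d: {%s}; %d terminal strong linkage class(es)\n",
                i, paste(lbl, collapse = ", "), nt[i]))
  }
  invisible(x)
}

#' Write a linkage classification report as JSON
#'
#' @param cls a `linkage_classification`
#' @param path output file path
#' @return invisibly, `path`
#' @export
export_classification_json <- function(cls, path) {
  fmt <- function(idx) vapply(cls$network$complexes[idx], format_complex,
                              character(1))
  out <- list(
    is_uniterminal = cls$is_uniterminal,
    linkage_classes = lapply(cls$linkage_classes, fmt),
    terminal_strong_linkage_classes =
      lapply(cls$terminal_sl_classes, function(ts) lapply(ts, fmt)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
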
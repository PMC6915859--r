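# Serialization: extended Newick (with #H hybrid tags) and a plain
# edge-list format.
#
# Extended Newick conventions used here: the outdegree-1 root is part
# of the object, so the outer parentheses are retained
# (base_network(2) prints as "((1,2));").  Each reticulate node is
# written in full at its first occurrence in the traversal as
# "(subtree)#Hi" and as a bare "#Hi" at its second; tags are numbered
# in first-traversal order.  Leaves are rendered as their taxon
# integers.  Branch lengths are not modelled; the reader tolerates and
# discards ":length" annotations.

#' Write a network as an extended Newick string
#'
#' Deterministic output: at every node the children are ordered by
#' their path-count vectors (the canonical subtree key), so isomorphic
#' networks produce identical strings.
#'
#' @param N A valid `phynet`.
#' @return A character scalar ending in `";"`.
#' @examples
#' write_enewick(base_network(2))
#' @export
write_enewick <- function(N) {
  check_valid(N, "write_enewick")
  n <- n_taxa(N)
  P <- .path_counts_cpp(N$edges, N$taxon, n)
  key <- apply(P, 1L, function(x) paste(sprintf("%06d", x), collapse = ""))
  ind <- indegree(N)
  tags <- new.env(parent = emptyenv())
  counter <- 0L
  render <- function(v) {
    if (N$taxon[v] > 0L) return(as.character(N$taxon[v]))
    if (ind[v] == 2L) {
      id <- as.character(v)
      if (!is.null(tags[[id]])) return(paste0("#H", tags[[id]]))
      counter <<- counter + 1L
      tags[[id]] <- counter
      child <- N$edges[N$edges[, 1L] == v, 2L]
      return(paste0("(", render(child), ")#H", tags[[id]]))
    }
    kids <- N$edges[N$edges[, 1L] == v, 2L]
    # decreasing: a child whose subtree reaches lower-numbered taxa
    # renders first, so the two-taxon base prints as "((1,2));"
    kids <- kids[order(key[kids], method = "radix", decreasing = TRUE)]
    paste0("(", paste(vapply(kids, render, ""), collapse = ","), ")")
  }
  paste0(render(N$root), ";")
}

#' Read an extended Newick string
#'
#' Parses a Newick expression with `#H` hybrid tags into a `phynet`.
#' Each hybrid tag must occur exactly twice (a reticulate node has
#' indegree 2) and carry a subtree in exactly one of its occurrences;
#' leaves must be named by their taxon integers.  Parse errors carry
#' the character position.
#'
#' @param s A character scalar.
#' @return A valid `phynet`.
#' @examples
#' read_enewick("((1,2));")
#' @export
read_enewick <- function(s) {
  if (!is.character(s) || length(s) != 1L)
    stop_tcnet("format", "input must be a single string")
  chars <- strsplit(s, "")[[1]]
  pos <- 1L
  nmax <- length(chars)
  fail <- function(msg)
    stop_tcnet("format", sprintf("parse error at position %d: %s", pos, msg))
  peek <- function() if (pos <= nmax) chars[pos] else ""
  advance <- function() pos <<- pos + 1L

  next_id <- 1L
  edges_from <- integer(0)
  edges_to <- integer(0)
  names_of <- character(0)  # per node: leaf name ("" if none)
  hybrid_of <- character(0) # per node: hybrid tag ("" if none)
  hybrid_ids <- new.env(parent = emptyenv())

  new_node <- function() {
    id <- next_id
    next_id <<- next_id + 1L
    names_of[id] <<- ""
    hybrid_of[id] <<- ""
    id
  }
  add_edge <- function(p, c) {
    edges_from[length(edges_from) + 1L] <<- p
    edges_to[length(edges_to) + 1L] <<- c
  }
  read_name <- function() {
    start <- pos
    while (peek() != "" && !(peek() %in% c("(", ")", ",", ":", ";", "#")))
      advance()
    paste(chars[seq(start, length.out = pos - start)], collapse = "")
  }
  # returns the node id of the parsed subtree
  parse_subtree <- function() {
    kids <- integer(0)
    if (peek() == "(") {
      advance()
      repeat {
        kids <- c(kids, parse_subtree())
        if (peek() == ",") { advance(); next }
        if (peek() == ")") { advance(); break }
        fail("expected ',' or ')'")
      }
    }
    nm <- read_name()
    tag <- ""
    if (peek() == "#") {
      advance()
      tag <- read_name()
      if (tag == "") fail("empty hybrid tag")
    }
    if (peek() == ":") {  # tolerated, discarded
      advance()
      read_name()
    }
    if (length(kids) == 0L && nm == "" && tag == "")
      fail("empty subtree")
    if (tag != "") {
      id <- hybrid_ids[[tag]]
      if (is.null(id)) {
        id <- new_node()
        hybrid_ids[[tag]] <- id
        hybrid_of[id] <<- tag
        names_of[id] <<- nm
      } else if (nm != "" && names_of[id] == "") {
        names_of[id] <<- nm
      }
    } else {
      id <- new_node()
      names_of[id] <<- nm
    }
    for (kid in kids) add_edge(id, kid)
    id
  }

  top <- parse_subtree()
  if (peek() != ";") fail("expected ';'")
  advance()
  while (peek() %in% c(" ", "\n", "\t")) advance()
  if (pos <= nmax) fail("trailing characters after ';'")

  # the top-level expression is the outdegree-1 root itself (the
  # writer retains the outer parentheses)
  root <- top
  E <- cbind(edges_from, edges_to)
  dimnames(E) <- NULL
  # hybrid sanity: every tag must have been used exactly twice
  ind <- tabulate(E[, 2L], nbins = next_id - 1L)
  for (tag in ls(hybrid_ids)) {
    id <- hybrid_ids[[tag]]
    if (ind[id] != 2L)
      stop_tcnet("format", sprintf(
        "hybrid tag #%s occurs %d time(s); a reticulate node needs exactly 2",
        tag, ind[id]))
  }
  outd <- tabulate(E[, 1L], nbins = next_id - 1L)
  taxon <- integer(next_id - 1L)
  for (id in seq_len(next_id - 1L)) {
    if (outd[id] == 0L) {
      if (!grepl("^[0-9]+$", names_of[id]))
        stop_tcnet("format", sprintf(
          "leaf name '%s' is not a taxon integer", names_of[id]))
      taxon[id] <- as.integer(names_of[id])
    }
  }
  N <- new_phynet(E, taxon, root, next_id)
  v <- validate_network(N)
  if (length(v))
    stop_tcnet("format", paste("parsed network is invalid:", v[[1L]]))
  N
}

#' Edge-list serialization
#'
#' One `parent<TAB>child` line per edge.  Leaves are named by their
#' taxon integers; internal nodes get stable `v<id>` names on writing.
#' On reading, names are free-form, the unique indegree-0 node is the
#' root, and outdegree-0 nodes must be named by taxon integers.
#'
#' @param N A valid `phynet`.
#' @param lines Character vector of `parent<TAB>child` lines.
#' @return `write_edgelist()` a character vector of lines;
#'   `read_edgelist()` a valid `phynet`.
#' @export
write_edgelist <- function(N) {
  check_valid(N, "write_edgelist")
  nm <- function(v) ifelse(N$taxon[v] > 0L, as.character(N$taxon[v]),
                           paste0("v", v))
  paste0(nm(N$edges[, 1L]), "\t", nm(N$edges[, 2L]))
}

#' @rdname write_edgelist
#' @export
read_edgelist <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    stop_tcnet("format", "empty edge list")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop_tcnet("format", "each line must be parent<TAB>child")
  pn <- vapply(parts, `[`, "", 1L)
  cn <- vapply(parts, `[`, "", 2L)
  all_names <- unique(c(pn, cn))
  id_of <- stats::setNames(seq_along(all_names), all_names)
  E <- cbind(unname(id_of[pn]), unname(id_of[cn]))
  ind <- tabulate(E[, 2L], nbins = length(all_names))
  outd <- tabulate(E[, 1L], nbins = length(all_names))
  taxon <- integer(length(all_names))
  for (i in seq_along(all_names)) {
    if (outd[i] == 0L) {
      if (!grepl("^[0-9]+$", all_names[i]))
        stop_tcnet("format", sprintf(
          "leaf name '%s' is not a taxon integer", all_names[i]))
      taxon[i] <- as.integer(all_names[i])
    }
  }
  roots <- which(ind == 0L & outd > 0L)
  if (length(roots) != 1L)
    stop_tcnet("format", "edge list must have exactly one indegree-0 node")
  N <- new_phynet(E, taxon, roots, length(all_names) + 1L)
  v <- validate_network(N)
  if (length(v))
    stop_tcnet("format", paste("edge list describes an invalid network:", v[[1L]]))
  N
}
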
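#' Load a TE taxonomy from a configuration file or list
#'
#' The taxonomy is a rooted tree of transposable-element groups (Wicker-style:
#' classes, orders/subclasses, superfamilies). One classifier is later attached
#' to every internal node with at least two children ("parent nodes"), so the
#' tree fully determines how many models are trained and which labels are
#' reachable.
#'
#' The configuration maps each internal node to the list of its children, e.g.
#' in YAML:
#' ```yaml
#' nodes:
#'   TE: [ClassI, ClassII]
#'   ClassI: [LTR, nonLTR]
#' aliases:
#'   MITE: TIR
#' ```
#' Labels are matched case-sensitively after trimming whitespace. An optional
#' `aliases` map resolves alternative names (repeat-library headers are
#' notoriously inconsistent) onto canonical labels.
#'
#' @param config Path to a YAML file, or a list with elements `nodes` (named
#'   list: node -> character vector of children) and optionally `aliases`
#'   (named character: alias -> canonical label). A bare named list is treated
#'   as `nodes`.
#' @return A `te_taxonomy` object: list with `nodes` (character), `parent`
#'   (named character, child -> parent), `children` (named list), `root`,
#'   and `aliases`.
#' @seealso [default_taxonomy()], [ancestors()], [parent_nodes()]
#' @export
#' @examples
#' tax <- load_taxonomy(list(TE = c("ClassI", "ClassII"), ClassI = c("LTR", "LINE")))
#' parent_nodes(tax)
load_taxonomy <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    stop("taxonomy config must be a file path or a list", call. = FALSE)
  }
  if (!is.null(config$nodes)) {
    nodes_cfg <- config$nodes
    aliases <- unlist(config$aliases %||% list())
  } else {
    nodes_cfg <- config
    aliases <- character()
  }
  if (length(nodes_cfg) == 0) stop("taxonomy config lists no nodes", call. = FALSE)
  names(nodes_cfg) <- trimws(names(nodes_cfg))
  nodes_cfg <- lapply(nodes_cfg, function(x) trimws(as.character(x)))

  parents_of <- rep(names(nodes_cfg), lengths(nodes_cfg))
  children <- unlist(nodes_cfg, use.names = FALSE)
  if (anyDuplicated(children)) {
    dup <- unique(children[duplicated(children)])
    stop("duplicate label (multiple parents): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  self_loop <- children == parents_of
  if (any(self_loop)) {
    stop("cycle: node lists itself as its own child: ",
         paste(unique(children[self_loop]), collapse = ", "), call. = FALSE)
  }
  parent <- stats::setNames(parents_of, children)

  all_nodes <- unique(c(names(nodes_cfg), children))
  roots <- setdiff(all_nodes, children)
  if (length(roots) == 0) {
    stop("cycle: no root node (every node has a parent)", call. = FALSE)
  }
  if (length(roots) > 1) {
    stop("missing root: disconnected tree, candidate roots: ",
         paste(sort(roots), collapse = ", "), call. = FALSE)
  }
  root <- roots

  # walk every node up to the root; a revisit within one walk is a cycle,
  # failure to reach the root is an orphan subtree
  for (n in all_nodes) {
    seen <- character()
    cur <- n
    while (cur != root) {
      if (cur %in% seen) stop("cycle involving node: ", cur, call. = FALSE)
      seen <- c(seen, cur)
      if (is.na(parent[cur])) stop("orphan node: ", cur, call. = FALSE)
      cur <- unname(parent[cur])
    }
  }
  if (length(aliases) > 0) {
    bad <- setdiff(unname(aliases), all_nodes)
    if (length(bad) > 0) {
      stop("alias points to unknown node: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  children_map <- lapply(nodes_cfg, identity)
  structure(
    list(nodes = all_nodes, parent = parent, children = children_map,
         root = root, aliases = aliases),
    class = "te_taxonomy")
}

#' @export
print.te_taxonomy <- function(x, ...) {
  cat("<te_taxonomy> root:", x$root,
      "|", length(x$nodes), "nodes |",
      length(parent_nodes(x)), "parent nodes (classifier sites)\n")
  invisible(x)
}

#' The default TE taxonomy
#'
#' A reconstruction of the classification tree with nine parent nodes
#' (TE, ClassI, ClassII, nonLTR, LTR, ERV, LINE, SINE, TIR) and the commonly
#' used superfamily leaves (Copia, Gypsy, Bel-Pao, ERV1-3, L1, CR1, RTE, Rex1,
#' Jockey, I, the SINE1/7SL-SINE3/5S groups, ID, hAT, TcMar, MULE, PIF, CACTA,
#' Merlin, P, Helitron, Maverick). The exact child inventory of published
#' trees varies between curated libraries, so the tree is fully config-driven:
#' this default is a sensible starting point, not an ontology.
#'
#' @return A `te_taxonomy`.
#' @export
default_taxonomy <- function() {
  load_taxonomy(system.file("extdata", "taxonomy_default.yaml",
                            package = "hierTE", mustWork = TRUE))
}

#' Root-first ancestor path of a label
#'
#' @param tax A `te_taxonomy`.
#' @param label A node label (aliases are resolved).
#' @return Character vector from the root down to `label` inclusive.
#' @export
#' @examples
#' ancestors(default_taxonomy(), "hAT")  # TE / ClassII / TIR / hAT
ancestors <- function(tax, label) {
  stopifnot(inherits(tax, "te_taxonomy"))
  label <- resolve_label(tax, label)
  path <- label
  while (path[1] != tax$root) {
    path <- c(unname(tax$parent[path[1]]), path)
  }
  path
}

resolve_label <- function(tax, label) {
  label <- trimws(label)
  if (label %in% names(tax$aliases)) label <- unname(tax$aliases[label])
  if (!label %in% tax$nodes) {
    stop("unknown taxonomy label: ", label, call. = FALSE)
  }
  label
}

#' Internal nodes that host a classifier
#'
#' Parent nodes are internal nodes with at least two children; each gets its
#' own child-discriminating classifier. Order is deterministic: pre-order
#' traversal from the root with children visited lexicographically.
#'
#' @param tax A `te_taxonomy`.
#' @return Character vector of parent-node labels (possibly empty).
#' @export
parent_nodes <- function(tax) {
  stopifnot(inherits(tax, "te_taxonomy"))
  out <- character()
  walk <- function(node) {
    kids <- tax$children[[node]]
    if (length(kids) >= 2) out <<- c(out, node)
    for (k in sort(kids)) walk(k)
  }
  walk(tax$root)
  out
}

#' Children of a node
#' @param tax A `te_taxonomy`.
#' @param label Node label.
#' @return Character vector (empty for leaves).
#' @export
taxonomy_children <- function(tax, label) {
  label <- resolve_label(tax, label)
  tax$children[[label]] %||% character()
}

#' Leaves of the taxonomy
#' @param tax A `te_taxonomy`.
#' @return Character vector of leaf labels.
#' @export
taxonomy_leaves <- function(tax) {
  tax$nodes[!tax$nodes %in% names(tax$children)[lengths(tax$children) > 0]]
}

#' Serialize a taxonomy to edge-list text
#'
#' One `child<TAB>parent` line per edge, children sorted within each parent,
#' parents in pre-order. `deserialize_taxonomy()` reads the format back.
#'
#' @param tax A `te_taxonomy`.
#' @param path Optional file to write; when `NULL` the lines are returned.
#' @return Character vector of lines, invisibly when written to file.
#' @export
serialize_taxonomy <- function(tax, path = NULL) {
  stopifnot(inherits(tax, "te_taxonomy"))
  lines <- character()
  walk <- function(node) {
    for (k in sort(tax$children[[node]] %||% character())) {
      lines <<- c(lines, paste0(k, "\t", node))
      walk(k)
    }
  }
  walk(tax$root)
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' @rdname serialize_taxonomy
#' @param lines Character vector of `child<TAB>parent` lines, or a file path.
#' @export
deserialize_taxonomy <- function(lines) {
  if (length(lines) == 1 && file.exists(lines)) lines <- readLines(lines)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) != 2
  if (any(bad)) stop("malformed edge line(s): ", which(bad)[1], call. = FALSE)
  child <- vapply(parts, `[[`, "", 1)
  par <- vapply(parts, `[[`, "", 2)
  load_taxonomy(split(child, factor(par, levels = unique(par))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
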
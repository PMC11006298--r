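#' Read a STRING-style protein links file
#'
#' Parses a space-separated `protein.links` file with header
#' `protein1 protein2 combined_score`, where `combined_score` is an integer
#' confidence on a 0--1000 scale, and returns the undirected network of
#' associations at or above a confidence cutoff. STRING lists every edge in
#' both orientations; the two orientations are collapsed into one undirected
#' edge and their scores are required to agree. Self-loops are dropped.
#' Gzipped files are read transparently.
#'
#' @param path Path to the links file (optionally `.gz`).
#' @param cutoff Confidence cutoff in `[0, 1]`; an edge is kept when
#'   `combined_score / 1000 >= cutoff`. A cutoff of 0.7 corresponds to
#'   STRING's "high confidence" `combined_score >= 700`.
#' @return An undirected [igraph::igraph] graph. Edge attribute `weight`
#'   holds `combined_score / 1000`; graph attributes `source` and `cutoff`
#'   record provenance.
#' @examples
#' f <- tempfile()
#' writeLines(c("protein1 protein2 combined_score",
#'              "a b 900", "b a 900", "b c 650"), f)
#' g <- read_string_links(f, cutoff = 0.7)
#' igraph::ecount(g) # 1
#' @export
read_string_links <- function(path, cutoff = 0.7) {
  stopifnot(length(path) == 1, length(cutoff) == 1)
  if (!is.numeric(cutoff) || is.na(cutoff) || cutoff < 0 || cutoff > 1) {
    stop("`cutoff` must be a number in [0, 1], got ", format(cutoff),
         call. = FALSE)
  }
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty file: ", path, call. = FALSE)
  header <- strsplit(trimws(lines[[1]]), "[[:space:]]+")[[1]]
  if (!identical(header[1:3], c("protein1", "protein2", "combined_score"))) {
    stop("line 1: expected header 'protein1 protein2 combined_score', got '",
         lines[[1]], "'", call. = FALSE)
  }
  body <- lines[-1]
  body_no <- which(nzchar(trimws(body)))
  body <- body[body_no]
  fields <- strsplit(trimws(body), "[[:space:]]+")
  n_fields <- lengths(fields)
  bad <- which(n_fields != 3)
  if (length(bad) > 0) {
    stop("line ", body_no[bad[1]] + 1L, ": expected 3 fields, got ",
         n_fields[bad[1]], call. = FALSE)
  }
  if (length(fields) == 0) {
    return(empty_network(source = path, cutoff = cutoff))
  }
  m <- matrix(unlist(fields), ncol = 3, byrow = TRUE)
  score <- suppressWarnings(as.numeric(m[, 3]))
  bad <- which(is.na(score) | score < 0 | score > 1000 | score != round(score))
  if (length(bad) > 0) {
    stop("line ", body_no[bad[1]] + 1L,
         ": combined_score must be an integer in 0..1000, got '",
         m[bad[1], 3], "'", call. = FALSE)
  }
  edges <- tibble::tibble(a = m[, 1], b = m[, 2], weight = score / 1000)
  edges <- dplyr::filter(edges, .data$a != .data$b, .data$weight >= cutoff)
  # collapse the two listed orientations into one undirected edge
  edges <- dplyr::mutate(edges,
    lo = pmin(.data$a, .data$b),
    hi = pmax(.data$a, .data$b)
  )
  dup <- dplyr::summarise(
    dplyr::group_by(edges, .data$lo, .data$hi),
    n_scores = dplyr::n_distinct(.data$weight),
    weight = .data$weight[1],
    .groups = "drop"
  )
  if (any(dup$n_scores > 1)) {
    off <- dup[dup$n_scores > 1, ][1, ]
    stop("edge ", off$lo, " -- ", off$hi,
         " listed with conflicting combined_score values", call. = FALSE)
  }
  build_network(dup[, c("lo", "hi", "weight")], source = path, cutoff = cutoff)
}

#' Read a generic weighted edge list
#'
#' Reads a TSV with columns `node_a`, `node_b` and an optional `weight`
#' column (default weight 1.0) into an undirected network. An unordered pair
#' listed more than once must carry a single weight; conflicting duplicates
#' are an error rather than being silently resolved.
#'
#' @param path Path to the TSV file.
#' @return An undirected [igraph::igraph] graph with `weight` edge attribute
#'   and `cutoff` graph attribute 0.
#' @seealso [write_edge_list()] for the inverse, [read_string_links()].
#' @export
read_edge_list <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = "c"))
  if (!all(c("node_a", "node_b") %in% names(df))) {
    stop("edge list must have columns 'node_a' and 'node_b'; found: ",
         paste(names(df), collapse = ", "), call. = FALSE)
  }
  w <- if ("weight" %in% names(df)) as.numeric(df$weight) else
    rep(1, nrow(df))
  if (anyNA(w)) stop("non-numeric weight in edge list", call. = FALSE)
  edges <- tibble::tibble(
    lo = pmin(df$node_a, df$node_b),
    hi = pmax(df$node_a, df$node_b),
    weight = w
  )
  edges <- dplyr::filter(edges, .data$lo != .data$hi)
  if (nrow(edges) > 0) {
    chk <- dplyr::summarise(
      dplyr::group_by(edges, .data$lo, .data$hi),
      n_scores = dplyr::n_distinct(.data$weight),
      weight = .data$weight[1],
      .groups = "drop"
    )
    if (any(chk$n_scores > 1)) {
      off <- chk[chk$n_scores > 1, ][1, ]
      stop("edge ", off$lo, " -- ", off$hi,
           " listed twice with different weights", call. = FALSE)
    }
    edges <- chk[, c("lo", "hi", "weight")]
  }
  build_network(edges, source = path, cutoff = 0)
}

#' Serialize a network as a sorted edge-list TSV
#'
#' Writes the edge list with columns `node_a`, `node_b`, `weight`, each edge
#' with its endpoints in lexicographic order and rows sorted, so that two
#' identical networks always serialize byte-identically. Isolated nodes are
#' not representable in this format and are dropped with a warning.
#'
#' @param network An igraph network.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  el <- as_edge_tibble(network)
  n_iso <- sum(igraph::degree(network) == 0)
  if (n_iso > 0) {
    warning(n_iso, " isolated node(s) not representable in an edge list",
            call. = FALSE)
  }
  readr::write_tsv(
    dplyr::rename(el, node_a = "lo", node_b = "hi"), path, progress = FALSE)
  invisible(path)
}

#' Edges of a network as a sorted tibble
#'
#' @param network An igraph network.
#' @return A tibble with columns `lo`, `hi` (endpoints in lexicographic
#'   order) and `weight`, sorted by (`lo`, `hi`).
#' @export
as_edge_tibble <- function(network) {
  stopifnot(igraph::is_igraph(network))
  if (igraph::ecount(network) == 0) {
    return(tibble::tibble(lo = character(), hi = character(),
                          weight = numeric()))
  }
  em <- igraph::as_edgelist(network, names = TRUE)
  w <- igraph::E(network)$weight
  if (is.null(w)) w <- rep(1, nrow(em))
  out <- tibble::tibble(lo = pmin(em[, 1], em[, 2]),
                        hi = pmax(em[, 1], em[, 2]),
                        weight = w)
  dplyr::arrange(out, .data$lo, .data$hi)
}

#' Read a gene symbol to network identifier alias map
#'
#' Reads a two-column TSV (`symbol`, `identifier`). A symbol listed with more
#' than one identifier is resolved deterministically to its first occurrence,
#' with a warning naming the symbols involved.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `symbol`, `identifier`, one row per symbol.
#' @export
read_alias_map <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = "c"))
  if (!all(c("symbol", "identifier") %in% names(df))) {
    stop("alias map must have columns 'symbol' and 'identifier'",
         call. = FALSE)
  }
  df <- tibble::as_tibble(df[, c("symbol", "identifier")])
  conflicts <- dplyr::filter(
    dplyr::summarise(dplyr::group_by(df, .data$symbol),
                     n_ids = dplyr::n_distinct(.data$identifier),
                     .groups = "drop"),
    .data$n_ids > 1)
  if (nrow(conflicts) > 0) {
    warning("alias conflicts resolved by first occurrence: ",
            paste(conflicts$symbol, collapse = ", "), call. = FALSE)
  }
  dplyr::distinct(df, .data$symbol, .keep_all = TRUE)
}

#' Map gene symbols onto network nodes
#'
#' Resolves symbols through an alias map (or, when `aliases` is `NULL`, uses
#' the symbols themselves as identifiers) and keeps those present in the
#' network. Symbols whose target identifier is absent from the network count
#' as unmapped, as do symbols missing from the alias map. Two symbols
#' aliasing to the same node yield that node once.
#'
#' @param symbols Character vector of gene symbols.
#' @param aliases A tibble from [read_alias_map()], or `NULL` for the
#'   identity mapping.
#' @param network An igraph network.
#' @return A list with sorted character vectors `mapped` (node identifiers in
#'   the network) and `unmapped` (input symbols that did not resolve).
#' @export
map_seed_symbols <- function(symbols, aliases, network) {
  stopifnot(igraph::is_igraph(network))
  symbols <- unique(as.character(symbols))
  if (length(symbols) == 0) {
    return(list(mapped = character(), unmapped = character()))
  }
  if (is.null(aliases)) {
    target <- stats::setNames(symbols, symbols)
  } else {
    target <- stats::setNames(aliases$identifier, aliases$symbol)[symbols]
    names(target) <- symbols
  }
  in_net <- !is.na(target) & target %in% igraph::V(network)$name
  list(mapped = sort(unique(unname(target[in_net]))),
       unmapped = sort(symbols[!in_net]))
}

#' Induced subgraph on a node set
#'
#' Returns the subgraph on `nodes` containing exactly the edges of `network`
#' with both endpoints in `nodes`. Requested nodes absent from the network
#' are ignored with a warning.
#'
#' @param network An igraph network.
#' @param nodes Character vector of node identifiers.
#' @return An igraph network on the retained nodes.
#' @export
induced_network <- function(network, nodes) {
  stopifnot(igraph::is_igraph(network))
  nodes <- unique(as.character(nodes))
  missing <- setdiff(nodes, igraph::V(network)$name)
  if (length(missing) > 0) {
    warning(length(missing), " node(s) not in network ignored: ",
            paste(utils::head(missing, 5), collapse = ", "),
            if (length(missing) > 5) ", ..." else "", call. = FALSE)
    nodes <- setdiff(nodes, missing)
  }
  igraph::induced_subgraph(network, vids = nodes)
}

# -- internal constructors ----------------------------------------------------

empty_network <- function(source = "", cutoff = 0) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  igraph::graph_attr(g, "source") <- source
  igraph::graph_attr(g, "cutoff") <- cutoff
  g
}

# edges: tibble with lo, hi, weight (already deduplicated, no self-loops)
build_network <- function(edges, source = "", cutoff = 0) {
  nodes <- sort(unique(c(edges$lo, edges$hi)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$lo, to = edges$hi, weight = edges$weight),
    directed = FALSE,
    vertices = data.frame(name = nodes))
  igraph::graph_attr(g, "source") <- source
  igraph::graph_attr(g, "cutoff") <- cutoff
  g
}
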
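#' Graph Laplacian with a fixed node ordering
#'
#' Returns `L = D - A` on the network's nodes in lexicographic order, as a
#' sparse symmetric matrix with zero row sums. With `weighted = TRUE` the
#' adjacency carries the edge confidences; otherwise it is binary.
#'
#' @param network An igraph network.
#' @param weighted Use edge weights in the adjacency?
#' @return A sparse symmetric [Matrix::Matrix] with dimnames set to the
#'   sorted node identifiers.
#' @export
graph_laplacian <- function(network, weighted = FALSE) {
  stopifnot(igraph::is_igraph(network))
  nodes <- sort(igraph::V(network)$name)
  g <- igraph::permute(network, match(igraph::V(network)$name, nodes))
  A <- igraph::as_adjacency_matrix(
    g, type = "both", sparse = TRUE,
    attr = if (weighted) "weight" else NULL)
  A <- methods::as(A, "generalMatrix")
  if (!weighted) A <- 1 * (A > 0)
  d <- Matrix::rowSums(A)
  L <- Matrix::Diagonal(x = d) - A
  dimnames(L) <- list(nodes, nodes)
  L
}

#' Regularised Laplacian kernel
#'
#' Computes `K = (I + sigma L)^-1`, the regularised Laplacian graph kernel.
#' `K` is symmetric positive definite and, because `L` has zero row sums,
#' its rows sum to one: diffusion through `K` conserves the total seed mass.
#' The system is solved (sparse Cholesky), never inverted explicitly, except
#' that the full inverse is formed when the explicit kernel matrix is
#' requested — use [diffuse()] to propagate a single seed vector without
#' materialising `K`.
#'
#' @param L A Laplacian matrix from [graph_laplacian()], or an igraph
#'   network (the unweighted Laplacian is then built internally).
#' @param sigma Regularisation weight, > 0. Small sigma keeps scores at
#'   their seeds; large sigma spreads them towards the component mean.
#' @return A dense symmetric matrix with the Laplacian's dimnames.
#' @examples
#' g <- igraph::make_graph(~ a - b)
#' regularized_laplacian_kernel(g, sigma = 1) # (1/3) * [[2,1],[1,2]]
#' @export
regularized_laplacian_kernel <- function(L, sigma = 1) {
  if (igraph::is_igraph(L)) L <- graph_laplacian(L)
  if (!(is.numeric(sigma) && length(sigma) == 1 && sigma > 0)) {
    stop("sigma must be a single positive number", call. = FALSE)
  }
  n <- nrow(L)
  M <- Matrix::Diagonal(n) + sigma * L
  K <- as.matrix(Matrix::solve(M))
  if (any(!is.finite(K))) {
    stop("kernel computation produced non-finite entries", call. = FALSE)
  }
  dimnames(K) <- dimnames(L)
  K
}

#' Diffuse a signed seed vector over the network
#'
#' Solves `(I + sigma L) f = s` for the steady-state diffusion scores
#' `f = K s`, with the seed vector `s` taken as dense over all nodes (zero
#' where unseeded). The solve uses a sparse factorisation, so the kernel
#' matrix is never formed.
#'
#' @param network An igraph network.
#' @param seeds A seed-vector tibble (`node`, `score`) from
#'   [build_seed_vector()], or a named numeric vector.
#' @param sigma Regularisation weight (> 0), default 1.
#' @param weighted Use edge confidences in the Laplacian?
#' @return A tibble with columns `node`, `seed_score`, `diffusion_score`,
#'   one row per network node, sorted by node.
#' @export
diffuse <- function(network, seeds, sigma = 1, weighted = FALSE) {
  L <- graph_laplacian(network, weighted = weighted)
  nodes <- rownames(L)
  s <- seed_dense(seeds, nodes)
  M <- Matrix::Diagonal(length(nodes)) + sigma * L
  f <- as.numeric(Matrix::solve(M, s))
  tibble::tibble(node = nodes, seed_score = s, diffusion_score = f)
}

seed_dense <- function(seeds, nodes) {
  if (is.data.frame(seeds)) {
    seeds <- stats::setNames(seeds$score, seeds$node)
  }
  if (is.null(names(seeds))) {
    stop("seeds must be a (node, score) tibble or a named numeric vector",
         call. = FALSE)
  }
  extra <- setdiff(names(seeds), nodes)
  if (length(extra) > 0) {
    stop("seed node(s) not in network: ",
         paste(utils::head(extra, 5), collapse = ", "), call. = FALSE)
  }
  s <- stats::setNames(numeric(length(nodes)), nodes)
  s[names(seeds)] <- as.numeric(seeds)
  unname(s)
}

#' Select the most positive and most negative diffusion scores
#'
#' Picks the `m = round(q * n)` nodes with the largest scores and the `m`
#' with the smallest, where `n` is the number of scored nodes. Ties at
#' either boundary are broken lexicographically by node identifier, so the
#' selection is deterministic.
#'
#' @param scores A tibble with columns `node` and `diffusion_score` (as
#'   returned by [diffuse()]), or a named numeric vector.
#' @param q Selection fraction, `0 < q < 0.5`.
#' @return A list with sorted character vectors `top_positive` and
#'   `top_negative`, and the count `m`.
#' @export
select_extremes <- function(scores, q = 0.01) {
  if (is.data.frame(scores)) {
    scores <- stats::setNames(scores$diffusion_score, scores$node)
  }
  if (!(q > 0 && q < 0.5)) stop("q must be in (0, 0.5)", call. = FALSE)
  n <- length(scores)
  m <- round(q * n)
  if (m < 1) {
    stop("selection is empty: round(q * ", n, ") = 0; increase q",
         call. = FALSE)
  }
  ids <- names(scores)
  pos_order <- order(-scores, ids)
  neg_order <- order(scores, ids)
  list(top_positive = sort(ids[pos_order[seq_len(m)]]),
       top_negative = sort(ids[neg_order[seq_len(m)]]),
       m = m)
}

#' Run diffusion and extreme-score selection in one step
#'
#' Convenience wrapper: [diffuse()] then [select_extremes()], returning a
#' `diffusion_result` object whose `tidy()` method gives the per-node table
#' with a `selected` marker (`"+"`, `"-"`, or `"."`).
#'
#' @inheritParams diffuse
#' @inheritParams select_extremes
#' @return An object of class `diffusion_result` with elements `scores`
#'   (per-node tibble), `top_positive`, `top_negative`, `m`, `sigma`, `q`.
#' @export
run_diffusion <- function(network, seeds, sigma = 1, q = 0.01,
                          weighted = FALSE) {
  scores <- diffuse(network, seeds, sigma = sigma, weighted = weighted)
  sel <- select_extremes(scores, q = q)
  structure(list(scores = scores,
                 top_positive = sel$top_positive,
                 top_negative = sel$top_negative,
                 m = sel$m, sigma = sigma, q = q,
                 weighted = weighted),
            class = "diffusion_result")
}

#' @export
print.diffusion_result <- function(x, ...) {
  cat(sprintf("Network diffusion (sigma = %g, %s Laplacian)\n", x$sigma,
              if (x$weighted) "weighted" else "unweighted"))
  cat(sprintf("  %d nodes; selected %d most positive and %d most negative (q = %g)\n",
              nrow(x$scores), x$m, x$m, x$q))
  rng <- range(x$scores$diffusion_score)
  cat(sprintf("  diffusion scores in [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

#' Per-node table of a diffusion result
#'
#' @param x A `diffusion_result`.
#' @param ... Unused.
#' @return A tibble `node`, `seed_score`, `diffusion_score`, `selected`
#'   (`"+"` for the most-positive set, `"-"` for the most-negative, `"."`
#'   otherwise).
#' @method tidy diffusion_result
#' @export
tidy.diffusion_result <- function(x, ...) {
  dplyr::mutate(x$scores, selected = dplyr::case_when(
    .data$node %in% x$top_positive ~ "+",
    .data$node %in% x$top_negative ~ "-",
    TRUE ~ "."))
}

#' @method glance diffusion_result
#' @export
glance.diffusion_result <- function(x, ...) {
  tibble::tibble(n_nodes = nrow(x$scores), m = x$m, sigma = x$sigma,
                 q = x$q, weighted = x$weighted,
                 total_seed = sum(x$scores$seed_score),
                 total_diffusion = sum(x$scores$diffusion_score))
}

#' Write a diffusion result as TSV
#'
#' Columns `node`, `seed_score`, `diffusion_score`, `selected`, sorted by
#' node for reproducible diffing.
#'
#' @param x A `diffusion_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_diffusion <- function(x, path) {
  readr::write_tsv(tidy(x), path, progress = FALSE)
  invisible(path)
}

#' Plot diffusion scores against seed scores
#'
#' @param object A `diffusion_result`.
#' @param ... Unused.
#' @return A ggplot object: seed vs diffusion score, selected nodes
#'   highlighted.
#' @method autoplot diffusion_result
#' @export
autoplot.diffusion_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$seed_score,
                                   y = .data$diffusion_score,
                                   colour = .data$selected)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(
      values = c("+" = "#b2182b", "-" = "#2166ac", "." = "grey60"),
      name = "selected") +
    ggplot2::labs(x = "seed score (signed -log10 p)",
                  y = "diffusion score") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
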
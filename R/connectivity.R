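#' Null distribution of induced edge counts for random node sets
#'
#' Draws `n_samples` node sets of size `k` from the network and returns the
#' number of edges each induces. Under the `"uniform"` null the `k` nodes are
#' drawn uniformly without replacement; under `"degree_matched"` the draw is
#' stratified by degree decile to match the decile composition of
#' `reference_nodes` (a sensitivity analysis for seed sets biased towards
#' hubs).
#'
#' @param network An igraph network.
#' @param k Node-set size, `2 <= k <= |V|`.
#' @param n_samples Number of null draws (>= 1).
#' @param null_model `"uniform"` or `"degree_matched"`.
#' @param rng_seed Integer seed; the draw is reproducible given this seed.
#' @param reference_nodes Required for `"degree_matched"`: the observed seed
#'   set whose degree-decile composition the null sets mimic.
#' @return Integer vector of length `n_samples`.
#' @export
null_edge_samples <- function(network, k, n_samples = 10000,
                              null_model = c("uniform", "degree_matched"),
                              rng_seed = 1, reference_nodes = NULL) {
  null_model <- match.arg(null_model)
  stopifnot(igraph::is_igraph(network), n_samples >= 1)
  nv <- igraph::vcount(network)
  if (k < 2 || k > nv) {
    stop("k must satisfy 2 <= k <= ", nv, ", got ", k, call. = FALSE)
  }
  A <- adjacency_dense(network)
  withr::with_seed(rng_seed, {
    if (null_model == "uniform") {
      vapply(seq_len(n_samples), function(i) {
        idx <- sample.int(nv, k)
        count_induced_edges(A, idx)
      }, integer(1))
    } else {
      if (is.null(reference_nodes)) {
        stop("degree_matched null requires `reference_nodes`", call. = FALSE)
      }
      deg <- igraph::degree(network)
      brk <- unique(stats::quantile(deg, probs = seq(0, 1, 0.1)))
      bin <- cut(deg, breaks = brk, include.lowest = TRUE, labels = FALSE)
      ref_idx <- match(reference_nodes, igraph::V(network)$name)
      if (anyNA(ref_idx)) {
        stop("reference_nodes must all be network members", call. = FALSE)
      }
      ref_counts <- table(bin[ref_idx])
      pool <- split(seq_len(nv), bin)
      vapply(seq_len(n_samples), function(i) {
        idx <- unlist(lapply(names(ref_counts), function(b) {
          sample(pool[[b]], ref_counts[[b]])
        }), use.names = FALSE)
        count_induced_edges(A, idx)
      }, integer(1))
    }
  })
}

#' Density-based expected induced edge count
#'
#' The expected number of edges induced by `k` uniformly random nodes equals
#' `choose(k, 2)` times the network density `2|E| / (|V| (|V|-1))`: each of
#' the `choose(k, 2)` node pairs is an edge with probability equal to the
#' density, by symmetry of uniform sampling.
#'
#' @param network An igraph network with at least 2 nodes.
#' @param k Node-set size (>= 2).
#' @return Expected edge count (a real number).
#' @export
expected_edges_analytic <- function(network, k) {
  stopifnot(igraph::is_igraph(network), k >= 2)
  nv <- igraph::vcount(network)
  if (nv < 2) stop("network must have at least 2 nodes", call. = FALSE)
  density <- 2 * igraph::ecount(network) / (nv * (nv - 1))
  choose(k, 2) * density
}

#' Empirical and analytic p-values for observed connectivity
#'
#' The empirical p-value uses the permutation-test add-one convention
#' `(1 + #\{samples >= observed\}) / (1 + n_samples)`, which can never be
#' zero. The analytic p-value is the upper tail `P(X >= observed)` of a
#' Poisson distribution with rate `null_mean`, a parametric tail for count
#' data that reaches far beyond Monte-Carlo resolution.
#'
#' @param observed Observed induced edge count.
#' @param null_samples Integer vector of null edge counts (non-empty).
#' @param null_mean Null mean edge count (defaults to `mean(null_samples)`).
#' @return A list with `p_empirical` and `p_analytic`.
#' @export
connectivity_pvalue <- function(observed, null_samples,
                                null_mean = mean(null_samples)) {
  if (length(null_samples) == 0) {
    stop("null_samples must be non-empty", call. = FALSE)
  }
  p_emp <- (1 + sum(null_samples >= observed)) / (1 + length(null_samples))
  p_ana <- stats::ppois(observed - 1, lambda = null_mean, lower.tail = FALSE)
  list(p_empirical = p_emp, p_analytic = min(p_ana, 1))
}

#' Seed-set connectivity test against random node sets
#'
#' Tests whether a seed set induces more edges in the network than equally
#' sized random node sets: the classic check that literature-derived genes
#' are functionally related rather than scattered. Reports the observed
#' induced edge count, the number of seed nodes with at least one induced
#' edge, the Monte-Carlo null mean and SD, the density-based analytic
#' expectation, and both empirical (add-one) and analytic (Poisson-tail)
#' p-values.
#'
#' @param network An igraph network.
#' @param seed_nodes Character vector of node identifiers (must all be in
#'   the network).
#' @param n_samples Number of null draws.
#' @param null_model `"uniform"` (default) or `"degree_matched"`.
#' @param rng_seed Integer seed for the null draws.
#' @return An object of class `connectivity_test`; see [tidy()] and
#'   [glance()] methods, and `print()`.
#' @examples
#' g <- generate_network(200, model = "er", param = 0.03, rng_seed = 1)
#' pm <- plant_module(g, m = 20, p_in = 0.5, rng_seed = 2)
#' run_connectivity_test(pm$network, pm$module_nodes, n_samples = 500,
#'                       rng_seed = 3)
#' @export
run_connectivity_test <- function(network, seed_nodes, n_samples = 10000,
                                  null_model = c("uniform", "degree_matched"),
                                  rng_seed = 1) {
  null_model <- match.arg(null_model)
  stopifnot(igraph::is_igraph(network))
  seed_nodes <- sort(unique(as.character(seed_nodes)))
  if (!all(seed_nodes %in% igraph::V(network)$name)) {
    stop("all seed_nodes must be network members", call. = FALSE)
  }
  k <- length(seed_nodes)
  sub <- induced_network(network, seed_nodes)
  observed <- igraph::ecount(sub)
  n_connected <- sum(igraph::degree(sub) > 0)
  samples <- null_edge_samples(network, k, n_samples, null_model,
                               rng_seed = rng_seed,
                               reference_nodes = seed_nodes)
  analytic_mean <- expected_edges_analytic(network, k)
  pv <- connectivity_pvalue(observed, samples)
  structure(list(
    observed_edges = observed,
    k = k,
    n_connected = n_connected,
    n_isolated = k - n_connected,
    expected_edges = mean(samples),
    expected_edges_analytic = analytic_mean,
    null_sd = stats::sd(samples),
    n_samples = n_samples,
    p_empirical = pv$p_empirical,
    p_analytic = pv$p_analytic,
    null_model = null_model,
    rng_seed = rng_seed,
    null_samples = samples
  ), class = "connectivity_test")
}

#' @export
print.connectivity_test <- function(x, ...) {
  cat("Seed-set connectivity test (", x$null_model, " null)\n", sep = "")
  cat(sprintf("  seed set: %d nodes, %d with >=1 induced edge\n",
              x$k, x$n_connected))
  cat(sprintf("  observed induced edges: %d (null mean %.2f, sd %.2f; analytic %.2f)\n",
              x$observed_edges, x$expected_edges, x$null_sd,
              x$expected_edges_analytic))
  cat(sprintf("  p_empirical = %.3g (%d samples, add-one), p_analytic = %.3g (Poisson tail)\n",
              x$p_empirical, x$n_samples, x$p_analytic))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a connectivity test into a one-row tibble
#'
#' @param x A `connectivity_test` object.
#' @param ... Unused.
#' @return A one-row tibble of the test's statistics.
#' @method tidy connectivity_test
#' @export
tidy.connectivity_test <- function(x, ...) {
  tibble::tibble(
    observed_edges = x$observed_edges,
    k = x$k,
    n_connected = x$n_connected,
    expected_edges = x$expected_edges,
    expected_edges_analytic = x$expected_edges_analytic,
    null_sd = x$null_sd,
    p_empirical = x$p_empirical,
    p_analytic = x$p_analytic,
    null_model = x$null_model,
    n_samples = x$n_samples,
    rng_seed = x$rng_seed
  )
}

#' @rdname tidy.connectivity_test
#' @method glance connectivity_test
#' @export
glance.connectivity_test <- function(x, ...) tidy.connectivity_test(x, ...)

# -- internal -----------------------------------------------------------------

# dense logical-as-numeric adjacency; fine at the desk scales used here
adjacency_dense <- function(network) {
  as.matrix(igraph::as_adjacency_matrix(network, type = "both",
                                        sparse = TRUE)) > 0
}

count_induced_edges <- function(A, idx) {
  as.integer(sum(A[idx, idx]) / 2)
}
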
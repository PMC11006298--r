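#' Generate a random benchmark network
#'
#' Produces an undirected simple graph with zero-padded node names
#' (`g0001`, `g0002`, ...). Two standard models are offered:
#' `"er"` (Erdos-Renyi `G(n, p)`, `param` = edge probability) and `"pa"`
#' (preferential attachment, `param` = edges added per new node), the latter
#' giving the heavy-tailed degree distribution typical of protein
#' interaction networks. All edge weights are 1.
#'
#' @param n Number of nodes (>= 10).
#' @param model `"pa"` (default) or `"er"`.
#' @param param Edge probability (ER) or edges per new node (PA).
#' @param rng_seed Integer seed; the graph is reproducible given it.
#' @return An igraph network.
#' @export
generate_network <- function(n, model = c("pa", "er"), param = 3,
                             rng_seed = 1) {
  model <- match.arg(model)
  if (n < 10) stop("n must be >= 10", call. = FALSE)
  if (model == "er" && (param < 0 || param > 1)) {
    stop("ER edge probability must be in [0, 1]", call. = FALSE)
  }
  if (model == "pa" && (param < 1 || param != round(param))) {
    stop("PA edges-per-node must be a positive integer", call. = FALSE)
  }
  g <- withr::with_seed(rng_seed, {
    if (model == "er") {
      igraph::sample_gnp(n, p = param, directed = FALSE)
    } else {
      igraph::simplify(igraph::sample_pa(n, m = param, directed = FALSE))
    }
  })
  igraph::V(g)$name <- node_names(n)
  igraph::E(g)$weight <- rep(1, igraph::ecount(g))
  igraph::graph_attr(g, "source") <- paste0("synthetic:", model)
  igraph::graph_attr(g, "cutoff") <- 0
  g
}

node_names <- function(n) {
  sprintf("g%0*d", max(4, nchar(n)), seq_len(n))
}

#' Plant a dense module into a network
#'
#' Chooses `m` nodes uniformly at random and adds each absent within-module
#' edge independently with probability `p_in`, creating the kind of densely
#' interconnected gene module that a seed-set connectivity test should
#' detect. Existing edges are kept, so the realised within-module edge
#' probability is `p_bg + p_in - p_bg * p_in` for background density
#' `p_bg`.
#'
#' @param network An igraph network.
#' @param m Module size (<= number of nodes).
#' @param p_in Within-module edge addition probability.
#' @param rng_seed Integer seed.
#' @return A list with elements `network` (augmented graph) and
#'   `module_nodes` (sorted character vector).
#' @export
plant_module <- function(network, m = 45, p_in = 0.3, rng_seed = 1) {
  stopifnot(igraph::is_igraph(network))
  nv <- igraph::vcount(network)
  if (m > nv) stop("m exceeds the number of nodes", call. = FALSE)
  if (p_in < 0 || p_in > 1) stop("p_in must be in [0, 1]", call. = FALSE)
  out <- withr::with_seed(rng_seed, {
    module <- sort(sample(igraph::V(network)$name, m))
    if (p_in > 0 && m >= 2) {
      pairs <- utils::combn(module, 2)
      keep <- stats::runif(ncol(pairs)) < p_in
      new_edges <- pairs[, keep, drop = FALSE]
      if (ncol(new_edges) > 0) {
        existing <- igraph::get_edge_ids(
          network, as.vector(new_edges), error = FALSE)
        add <- new_edges[, existing == 0, drop = FALSE]
        if (ncol(add) > 0) {
          network <- igraph::add_edges(network, as.vector(add),
                                       attr = list(weight = 1))
        }
      }
    }
    list(network = network, module_nodes = module)
  })
  out
}

#' Generate a DEG evidence table with planted signal
#'
#' Emulates a curated differential-expression evidence table: signal genes
#' (drawn from the planted module) receive small p-values from a
#' `Beta(beta_a, 1)` distribution and a coherent direction (UP with
#' probability `coherence`); background genes receive uniform p-values and
#' random directions. Rows with p >= 0.05 are dropped — as in a curated
#' table, only "significant" findings appear — and the surviving p-values
#' are binned into star tiers unless `tiers = FALSE`.
#'
#' @param module_nodes Character vector of module (signal) gene names.
#' @param background_nodes Character vector of non-module gene names.
#' @param n_signal Number of signal genes sampled from the module.
#' @param n_background Number of background genes sampled before the
#'   p < 0.05 filter (most are filtered out).
#' @param beta_a Beta shape for signal p-values, in (0, 1); smaller means
#'   stronger signal.
#' @param coherence Probability that a signal gene is UP, in `[0.5, 1]`.
#' @param rng_seed Integer seed.
#' @param tiers Report significance as star tiers (default) or numeric.
#' @return A list: `table` (tibble in the evidence-table dialect: `gene`,
#'   `direction`, `significance`, `source`) and `truth` (tibble with the
#'   pre-binning p-values and a `is_signal` flag).
#' @export
generate_deg_table <- function(module_nodes, background_nodes,
                               n_signal = length(module_nodes),
                               n_background = 100, beta_a = 0.05,
                               coherence = 0.9, rng_seed = 1,
                               tiers = TRUE) {
  if (n_signal > length(module_nodes)) {
    stop("n_signal exceeds the module size", call. = FALSE)
  }
  if (beta_a <= 0 || beta_a >= 1) stop("beta_a must be in (0, 1)",
                                       call. = FALSE)
  if (coherence < 0.5 || coherence > 1) {
    stop("coherence must be in [0.5, 1]", call. = FALSE)
  }
  if (n_background > length(background_nodes)) {
    stop("n_background exceeds the background pool", call. = FALSE)
  }
  withr::with_seed(rng_seed, {
    sig_genes <- sort(sample(module_nodes, n_signal))
    bg_genes <- sort(sample(background_nodes, n_background))
    truth <- tibble::tibble(
      gene = c(sig_genes, bg_genes),
      is_signal = rep(c(TRUE, FALSE), c(n_signal, n_background)),
      p_true = c(stats::rbeta(n_signal, beta_a, 1),
                 stats::runif(n_background)),
      direction = c(
        ifelse(stats::runif(n_signal) < coherence, "UP", "DOWN"),
        ifelse(stats::runif(n_background) < 0.5, "UP", "DOWN")))
    emitted <- dplyr::filter(truth, .data$p_true < 0.05)
    significance <- if (tiers) p_to_tier(emitted$p_true) else
      formatC(emitted$p_true, format = "g", digits = 6)
    tab <- tibble::tibble(
      gene = emitted$gene,
      direction = emitted$direction,
      significance = significance,
      source = ifelse(emitted$is_signal, "synthetic signal",
                      "synthetic background"))
    tab <- dplyr::arrange(tab, .data$gene)
    list(table = tab, truth = truth)
  })
}

# bin p < 0.05 into the star dialect used by curated evidence tables
p_to_tier <- function(p) {
  stopifnot(all(p < 0.05))
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", "*"))
}

#' Generate true and decoy pathway sets
#'
#' True pathways draw `ceiling(overlap_frac * size)` members from the
#' planted module and the remainder from the background; decoys draw all
#' members from the background. Set sizes are uniform on `size_range`.
#'
#' @param module_nodes Planted module gene names.
#' @param all_nodes All network node names.
#' @param n_true,n_decoy Numbers of true and decoy pathways.
#' @param size_range Integer vector of length 2, inclusive size bounds.
#' @param overlap_frac Fraction of each true pathway drawn from the module,
#'   in (0, 1].
#' @param rng_seed Integer seed.
#' @return A list: `collection` (tibble as from [read_gmt()]), `true_ids`,
#'   `decoy_ids`.
#' @export
generate_pathways <- function(module_nodes, all_nodes, n_true = 5,
                              n_decoy = 45, size_range = c(20, 80),
                              overlap_frac = 0.5, rng_seed = 1) {
  if (overlap_frac <= 0 || overlap_frac > 1) {
    stop("overlap_frac must be in (0, 1]", call. = FALSE)
  }
  background <- setdiff(all_nodes, module_nodes)
  max_need <- ceiling(overlap_frac * size_range[2])
  if (max_need > length(module_nodes)) {
    stop("module smaller than the required overlap (needs up to ",
         max_need, " members)", call. = FALSE)
  }
  withr::with_seed(rng_seed, {
    pool <- seq(size_range[1], size_range[2])
    sizes <- pool[sample.int(length(pool), n_true + n_decoy,
                             replace = TRUE)]
    make_set <- function(i) {
      size <- sizes[i]
      if (i <= n_true) {
        n_mod <- ceiling(overlap_frac * size)
        sort(c(sample(module_nodes, n_mod),
               sample(background, size - n_mod)))
      } else {
        sort(sample(background, size))
      }
    }
    ids <- c(sprintf("TRUE_PW_%02d", seq_len(n_true)),
             sprintf("DECOY_PW_%02d", seq_len(n_decoy)))
    collection <- tibble::tibble(
      set_id = ids,
      description = rep(c("module-overlapping pathway", "decoy pathway"),
                        c(n_true, n_decoy)),
      members = lapply(seq_along(ids), make_set))
    list(collection = collection,
         true_ids = ids[seq_len(n_true)],
         decoy_ids = ids[n_true + seq_len(n_decoy)])
  })
}

#' Simulate a complete input bundle with known ground truth
#'
#' One call producing everything the pipeline consumes — network with a
#' planted module, DEG evidence table, identity alias map, pathway
#' collection with true and decoy sets — plus the generation truth needed to
#' score recovery. With `dir` set, all artifacts are also written as plain
#' text (edge-list TSV, DEG TSV, alias TSV, GMT, truth JSON), byte
#' reproducibly for a given seed.
#'
#' @param n Network size (default 2000).
#' @param model,param Network model and parameter ([generate_network()]).
#' @param module_size,p_in Planted module size and density
#'   ([plant_module()]).
#' @param n_background,beta_a,coherence DEG table parameters
#'   ([generate_deg_table()]).
#' @param n_true,n_decoy,size_range,overlap_frac Pathway parameters
#'   ([generate_pathways()]).
#' @param rng_seed Integer master seed; component seeds are derived from it.
#' @param dir Optional output directory.
#' @return A list: `network`, `module_nodes`, `deg_table`, `deg_truth`,
#'   `pathways` (collection tibble), `true_ids`, `decoy_ids`, `params`.
#' @export
simulate_study <- function(n = 2000, model = "pa", param = 3,
                           module_size = 45, p_in = 0.3,
                           n_background = 100, beta_a = 0.05,
                           coherence = 0.9,
                           n_true = 5, n_decoy = 45,
                           size_range = c(20, 80), overlap_frac = 0.5,
                           rng_seed = 1, dir = NULL) {
  seeds <- derive_seeds(rng_seed, 4)
  g0 <- generate_network(n, model = model, param = param,
                         rng_seed = seeds[1])
  pm <- plant_module(g0, m = module_size, p_in = p_in, rng_seed = seeds[2])
  deg <- generate_deg_table(
    pm$module_nodes, setdiff(igraph::V(pm$network)$name, pm$module_nodes),
    n_signal = module_size, n_background = n_background, beta_a = beta_a,
    coherence = coherence, rng_seed = seeds[3])
  pw <- generate_pathways(pm$module_nodes, igraph::V(pm$network)$name,
                          n_true = n_true, n_decoy = n_decoy,
                          size_range = size_range,
                          overlap_frac = overlap_frac, rng_seed = seeds[4])
  bundle <- list(
    network = pm$network,
    module_nodes = pm$module_nodes,
    deg_table = deg$table,
    deg_truth = deg$truth,
    pathways = pw$collection,
    true_ids = pw$true_ids,
    decoy_ids = pw$decoy_ids,
    params = list(n = n, model = model, param = param,
                  module_size = module_size, p_in = p_in,
                  n_background = n_background, beta_a = beta_a,
                  coherence = coherence, n_true = n_true,
                  n_decoy = n_decoy, size_range = size_range,
                  overlap_frac = overlap_frac, rng_seed = rng_seed))
  if (!is.null(dir)) write_study(bundle, dir)
  bundle
}

# distinct sub-seeds below 2^31, deterministic in the master seed
derive_seeds <- function(rng_seed, k) {
  (as.integer(rng_seed) %% 100000L) * 10000L + 7L * seq_len(k)
}

write_study <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  suppressWarnings(
    write_edge_list(bundle$network, file.path(dir, "network.tsv")))
  readr::write_tsv(bundle$deg_table, file.path(dir, "deg_table.tsv"),
                   progress = FALSE)
  genes <- sort(unique(bundle$deg_table$gene))
  readr::write_tsv(tibble::tibble(symbol = genes, identifier = genes),
                   file.path(dir, "aliases.tsv"), progress = FALSE)
  write_gmt(bundle$pathways, file.path(dir, "pathways.gmt"))
  truth <- list(module_nodes = bundle$module_nodes,
                true_pathways = bundle$true_ids,
                decoy_pathways = bundle$decoy_ids,
                params = bundle$params)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
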
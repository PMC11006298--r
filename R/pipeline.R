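#' Run the full seed-to-pathways pipeline
#'
#' Chains the four analysis stages on one set of inputs: (1) build the
#' signed seed vector from the DEG evidence table; (2) test the mapped seed
#' set's connectivity against random node sets; (3) diffuse the seed scores
#' over the regularised Laplacian kernel and select the most positive and
#' most negative fractions; (4) run hypergeometric over-representation tests
#' of each selection against the pathway collection, with the overlap and
#' significance filters.
#'
#' @param network An igraph network.
#' @param deg_table DEG evidence tibble ([read_deg_table()]).
#' @param collection Pathway collection tibble ([read_gmt()]).
#' @param aliases Optional alias tibble ([read_alias_map()]).
#' @param combine Seed aggregation policy ([build_seed_vector()]).
#' @param n_samples Null draws for the connectivity test.
#' @param null_model Connectivity null model.
#' @param sigma Diffusion regularisation weight.
#' @param q Extreme-score selection fraction.
#' @param weighted Use edge confidences in the Laplacian?
#' @param min_overlap,alpha Enrichment pass filters.
#' @param rng_seed Integer seed for the connectivity null.
#' @return An object of class `ppi_pipeline`: a list with `seed_vector`,
#'   `unmapped`, `connectivity` (`connectivity_test`), `diffusion`
#'   (`diffusion_result`), `enrichment` (combined tibble over both
#'   directions) and `params`.
#' @examples
#' sim <- simulate_study(n = 300, module_size = 20, n_decoy = 10,
#'                       size_range = c(10, 30), rng_seed = 7)
#' res <- run_pipeline(sim$network, sim$deg_table, sim$pathways,
#'                     n_samples = 200, q = 0.05, rng_seed = 7)
#' res$connectivity$p_empirical
#' @export
run_pipeline <- function(network, deg_table, collection, aliases = NULL,
                         combine = "sum", n_samples = 10000,
                         null_model = "uniform", sigma = 1, q = 0.01,
                         weighted = FALSE, min_overlap = 3, alpha = 0.05,
                         rng_seed = 1) {
  seeds <- build_seed_vector(deg_table, network, aliases = aliases,
                             combine = combine)
  conn <- run_connectivity_test(network, seeds$node, n_samples = n_samples,
                                null_model = null_model,
                                rng_seed = rng_seed)
  diff <- run_diffusion(network, seeds, sigma = sigma, q = q,
                        weighted = weighted)
  universe <- sort(igraph::V(network)$name)
  enr_pos <- enrich(diff$top_positive, collection, universe,
                    direction = "positive", min_overlap = min_overlap,
                    alpha = alpha)
  enr_neg <- enrich(diff$top_negative, collection, universe,
                    direction = "negative", min_overlap = min_overlap,
                    alpha = alpha)
  structure(list(
    seed_vector = seeds,
    unmapped = attr(seeds, "unmapped"),
    connectivity = conn,
    diffusion = diff,
    enrichment = dplyr::bind_rows(enr_pos, enr_neg),
    params = list(combine = combine, n_samples = n_samples,
                  null_model = null_model, sigma = sigma, q = q,
                  weighted = weighted, min_overlap = min_overlap,
                  alpha = alpha, rng_seed = rng_seed)
  ), class = "ppi_pipeline")
}

#' @export
print.ppi_pipeline <- function(x, ...) {
  cat("Seed-to-pathways network analysis\n")
  cat(sprintf("  seeds: %d scored nodes (%d symbol(s) unmapped)\n",
              nrow(x$seed_vector), length(x$unmapped)))
  print(x$connectivity)
  print(x$diffusion)
  n_pass <- sum(x$enrichment$passes_filters)
  cat(sprintf("  enrichment: %d record(s) with overlap >= 1, %d passing filters\n",
              nrow(x$enrichment), n_pass))
  invisible(x)
}

#' Write all pipeline outputs to a directory
#'
#' Writes the seed vector, per-node diffusion table, connectivity summary
#' (JSON) and combined enrichment table, each in a deterministic order so
#' two runs with the same inputs and seed produce byte-identical files.
#'
#' @param x A `ppi_pipeline` object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_seed_vector(x$seed_vector, file.path(dir, "seed_vector.tsv"))
  write_diffusion(x$diffusion, file.path(dir, "diffusion.tsv"))
  conn <- tidy(x$connectivity)
  jsonlite::write_json(as.list(conn), file.path(dir, "connectivity.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  readr::write_tsv(x$enrichment, file.path(dir, "enrichment.tsv"),
                   progress = FALSE)
  invisible(dir)
}

#' Score pathway recovery against planted truth
#'
#' Given a pipeline result on a simulated bundle, counts how many true
#' (module-overlapping) pathways pass the enrichment filters in at least one
#' direction, and how many decoys pass in any direction.
#'
#' @param result A `ppi_pipeline` object.
#' @param true_ids,decoy_ids Pathway id vectors from [simulate_study()].
#' @return A one-row tibble: `n_true`, `true_recovered`, `n_decoy`,
#'   `decoys_passing`.
#' @export
score_recovery <- function(result, true_ids, decoy_ids) {
  passing <- unique(result$enrichment$pathway[result$enrichment$passes_filters])
  tibble::tibble(
    n_true = length(true_ids),
    true_recovered = length(intersect(true_ids, passing)),
    n_decoy = length(decoy_ids),
    decoys_passing = length(intersect(decoy_ids, passing)))
}

#' @importFrom rlang .data
NULL
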
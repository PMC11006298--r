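test_that("ER generator matches its edge-count expectation", {
  g0 <- generate_network(100, model = "er", param = 0, rng_seed = 1)
  expect_equal(igraph::ecount(g0), 0)
  expect_equal(igraph::vcount(g0), 100)

  counts <- vapply(1:25, function(s) {
    igraph::ecount(generate_network(300, model = "er", param = 0.02,
                                    rng_seed = s))
  }, numeric(1))
  expected <- choose(300, 2) * 0.02
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("PA generator has the constructive edge count and heavy tail", {
  g <- generate_network(500, model = "pa", param = 3, rng_seed = 2)
  expect_equal(igraph::ecount(g), 3 * 500 - 6) # 0 + 1 + 2 + 3(n-3)
  deg <- igraph::degree(g)
  expect_gt(max(deg), 3 * stats::median(deg))
  expect_true(igraph::is_simple(g))
})

test_that("generators validate their parameters", {
  expect_error(generate_network(5, model = "er", param = 0.1), "n must be")
  expect_error(generate_network(50, model = "er", param = 2), "probability")
  expect_error(generate_network(50, model = "pa", param = 0.5), "integer")
})

test_that("planted modules reach the requested density", {
  g <- generate_network(200, model = "er", param = 0.02, rng_seed = 3)
  clique <- plant_module(g, m = 10, p_in = 1, rng_seed = 4)
  sub <- induced_network(clique$network, clique$module_nodes)
  expect_equal(igraph::ecount(sub), choose(10, 2))

  unchanged <- plant_module(g, m = 10, p_in = 0, rng_seed = 4)
  expect_identical(as_edge_tibble(unchanged$network), as_edge_tibble(g))

  # union-probability expectation for module edges over replicates
  p_bg <- 0.005; p_in <- 0.06
  counts <- vapply(1:30, function(s) {
    gg <- generate_network(400, model = "er", param = p_bg, rng_seed = s)
    pm <- plant_module(gg, m = 45, p_in = p_in, rng_seed = 1000 + s)
    igraph::ecount(induced_network(pm$network, pm$module_nodes))
  }, numeric(1))
  expected <- choose(45, 2) * (p_bg + p_in - p_bg * p_in)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("DEG tables plant coherent small-p signal and drop p >= 0.05", {
  module <- sprintf("m%03d", 1:40)
  background <- sprintf("b%03d", 1:500)

  all_up <- generate_deg_table(module, background, n_signal = 40,
                               n_background = 0, coherence = 1,
                               rng_seed = 5)
  expect_true(all(all_up$table$direction == "UP"))
  expect_true(all(all_up$table$gene %in% module)) # no background rows
  expect_true(all(all_up$truth$p_true[match(all_up$table$gene,
                                            all_up$truth$gene)] < 0.05))

  # among emitted signal rows the *** fraction matches Beta(a,1):
  # P(p < 0.001 | p < 0.05) = (0.001/0.05)^a = 0.822 at a = 0.05
  frac <- vapply(1:50, function(s) {
    d <- generate_deg_table(module, background, n_signal = 40,
                            n_background = 0, beta_a = 0.05,
                            rng_seed = 100 + s)
    mean(d$table$significance == "***")
  }, numeric(1))
  expect_gte(mean(frac), 0.8)

  with_bg <- generate_deg_table(module, background, n_signal = 10,
                                n_background = 400, rng_seed = 6)
  bg_rows <- with_bg$table$gene %in% background
  expect_gt(sum(bg_rows), 0) # some uniform p land below 0.05
  expect_lt(sum(bg_rows), 80) # but only ~5%
  # numeric mode emits p-values directly
  num <- generate_deg_table(module, background, n_signal = 10,
                            n_background = 0, rng_seed = 7, tiers = FALSE)
  expect_true(all(is.finite(as.numeric(num$table$significance))))
})

test_that("generated artifacts pass the package's own readers cleanly", {
  dir <- withr::local_tempdir()
  sim <- simulate_study(n = 300, module_size = 20, n_background = 50,
                        n_true = 2, n_decoy = 3, size_range = c(10, 25),
                        rng_seed = 8, dir = dir)
  expect_no_warning({
    g <- read_edge_list(file.path(dir, "network.tsv"))
    deg <- read_deg_table(file.path(dir, "deg_table.tsv"))
    am <- read_alias_map(file.path(dir, "aliases.tsv"))
    gmt <- read_gmt(file.path(dir, "pathways.gmt"))
  })
  expect_equal(igraph::ecount(g), igraph::ecount(sim$network))
  expect_equal(nrow(deg), nrow(sim$deg_table))
  expect_equal(gmt$set_id, sim$pathways$set_id)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$module_nodes, sim$module_nodes)
  expect_true(all(sim$module_nodes %in% igraph::V(sim$network)$name))
  expect_length(intersect(truth$true_pathways, truth$decoy_pathways), 0)
})

test_that("pathway generation respects overlap and composition", {
  module <- sprintf("m%03d", 1:30)
  all_nodes <- c(module, sprintf("b%03d", 1:300))
  pw <- generate_pathways(module, all_nodes, n_true = 3, n_decoy = 4,
                          size_range = c(10, 20), overlap_frac = 0.5,
                          rng_seed = 9)
  for (id in pw$true_ids) {
    mem <- pw$collection$members[[match(id, pw$collection$set_id)]]
    expect_gte(length(intersect(mem, module)),
               ceiling(0.5 * length(mem)))
  }
  for (id in pw$decoy_ids) {
    mem <- pw$collection$members[[match(id, pw$collection$set_id)]]
    expect_length(intersect(mem, module), 0)
  }
  # full-overlap pathway of module size equals the module
  pw_full <- generate_pathways(module, all_nodes, n_true = 1, n_decoy = 0,
                               size_range = c(30, 30), overlap_frac = 1,
                               rng_seed = 10)
  expect_setequal(pw_full$collection$members[[1]], module)
  # overlap demands beyond the module size are rejected
  expect_error(
    generate_pathways(module[1:5], all_nodes, size_range = c(20, 80),
                      overlap_frac = 1, rng_seed = 1),
    "module smaller")
})

test_that("generators are bit-reproducible given their seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_study(n = 200, module_size = 15, n_true = 2, n_decoy = 3,
                 size_range = c(8, 15), rng_seed = 33, dir = d1)
  simulate_study(n = 200, module_size = 15, n_true = 2, n_decoy = 3,
                 size_range = c(8, 15), rng_seed = 33, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  d3 <- withr::local_tempdir()
  simulate_study(n = 200, module_size = 15, n_true = 2, n_decoy = 3,
                 size_range = c(8, 15), rng_seed = 34, dir = d3)
  expect_false(identical(readLines(file.path(d1, "network.tsv")),
                         readLines(file.path(d3, "network.tsv"))))
})
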
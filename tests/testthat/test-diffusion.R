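test_that("Laplacian construction on simple graphs", {
  g <- igraph::make_graph(~ a - b)
  L <- as.matrix(graph_laplacian(g))
  expect_equal(L, matrix(c(1, -1, -1, 1), 2,
                         dimnames = list(c("a", "b"), c("a", "b"))))

  e3 <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(e3)$name <- c("x", "y", "z")
  expect_equal(as.matrix(graph_laplacian(e3)),
               matrix(0, 3, 3, dimnames = list(c("x", "y", "z"),
                                               c("x", "y", "z"))))
})

test_that("Laplacian rows sum to zero and respect weights", {
  g <- generate_network(50, model = "er", param = 0.1, rng_seed = 7)
  L <- graph_laplacian(g)
  expect_lt(max(abs(Matrix::rowSums(L))), 1e-12)
  expect_equal(as.matrix(L), t(as.matrix(L)))

  gw <- igraph::make_graph(~ a - b)
  igraph::E(gw)$weight <- 0.7
  Lw <- as.matrix(graph_laplacian(gw, weighted = TRUE))
  expect_equal(Lw["a", "b"], -0.7)
  expect_equal(Lw["a", "a"], 0.7)
})

test_that("kernel of the edgeless graph is the identity", {
  e3 <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(e3)$name <- c("x", "y", "z")
  K <- regularized_laplacian_kernel(e3, sigma = 1)
  expect_equal(unname(K), diag(3))
})

test_that("two-node kernel and diffusion match the closed form", {
  g <- igraph::make_graph(~ a - b)
  K <- regularized_laplacian_kernel(g, sigma = 1)
  expect_equal(unname(K), matrix(c(2, 1, 1, 2) / 3, 2), tolerance = 1e-12)
  d <- diffuse(g, c(a = 3), sigma = 1)
  expect_equal(d$diffusion_score, c(2, 1), tolerance = 1e-12)
})

test_that("kernel properties hold on random fixtures", {
  for (seed in 1:4) {
    g <- generate_network(80, model = "er", param = 0.08, rng_seed = seed)
    K <- regularized_laplacian_kernel(g, sigma = 1)
    expect_lt(max(abs(K - t(K))), 1e-10)          # symmetry
    expect_lt(max(abs(rowSums(K) - 1)), 1e-8)     # K 1 = 1
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > 0))                       # positive definite
  }
})

test_that("sigma limits: identity at 0+, component mean at infinity", {
  g <- generate_network(100, model = "er", param = 0.05, rng_seed = 12)
  set.seed(13)
  s <- stats::setNames(rnorm(10), sample(igraph::V(g)$name, 10))
  f_small <- diffuse(g, s, sigma = 1e-9)
  s_dense <- stats::setNames(numeric(100), sort(igraph::V(g)$name))
  s_dense[names(s)] <- s
  expect_lt(max(abs(f_small$diffusion_score - unname(s_dense))), 1e-6)

  # restrict to the largest component for the sigma -> Inf limit
  comp <- igraph::components(g)
  big <- names(comp$membership)[comp$membership ==
                                  which.max(comp$csize)]
  gc <- induced_network(g, big)
  sc <- s[names(s) %in% big]
  f_big <- diffuse(gc, sc, sigma = 1e6)
  expect_lt(max(abs(f_big$diffusion_score - sum(sc) / length(big))), 1e-3)
})

test_that("diffusion conserves seed mass and is linear in zero", {
  g <- generate_network(150, model = "pa", param = 2, rng_seed = 3)
  set.seed(4)
  s <- stats::setNames(rnorm(20, sd = 2), sample(igraph::V(g)$name, 20))
  d <- diffuse(g, s, sigma = 1)
  expect_lt(abs(sum(d$diffusion_score) - sum(s)),
            1e-8 * abs(sum(s)) + 1e-12)
  d0 <- diffuse(g, stats::setNames(0, igraph::V(g)$name[1]))
  expect_true(all(d0$diffusion_score == 0))
})

test_that("diffusion is invariant to node labelling", {
  g <- generate_network(60, model = "er", param = 0.1, rng_seed = 8)
  s <- stats::setNames(c(2, -1, 3), igraph::V(g)$name[c(5, 20, 41)])
  d1 <- diffuse(g, s, sigma = 1)
  perm <- sample(igraph::vcount(g))
  g2 <- igraph::permute(g, perm)
  d2 <- diffuse(g2, s, sigma = 1)
  expect_equal(d1, d2) # both sorted by node name
})

test_that("diffusion stays inside connected components", {
  g1 <- generate_network(40, model = "er", param = 0.15, rng_seed = 5)
  g2 <- generate_network(40, model = "er", param = 0.15, rng_seed = 6)
  igraph::V(g2)$name <- sub("^g", "h", igraph::V(g2)$name)
  g <- igraph::disjoint_union(g1, g2)
  s <- stats::setNames(5, igraph::V(g1)$name[1])
  d <- diffuse(g, s, sigma = 1)
  other <- startsWith(d$node, "h")
  expect_lt(max(abs(d$diffusion_score[other])), 1e-10)
  expect_gt(sum(abs(d$diffusion_score[!other])), 1)
})

test_that("seed validation rejects unknown nodes and bad sigma", {
  g <- triangle_graph()
  expect_error(diffuse(g, c(zz = 1)), "not in network")
  expect_error(regularized_laplacian_kernel(g, sigma = 0), "sigma")
  expect_error(regularized_laplacian_kernel(g, sigma = -1), "sigma")
})

test_that("extreme-score selection sizes, ties and bounds", {
  scores <- stats::setNames(1:10, paste0("n", sprintf("%02d", 1:10)))
  sel <- select_extremes(scores, q = 0.2)
  expect_equal(sel$m, 2)
  expect_equal(sel$top_positive, c("n09", "n10"))
  expect_equal(sel$top_negative, c("n01", "n02"))

  # all-equal scores: lexicographically first m win on both sides
  eq <- stats::setNames(rep(1, 10), paste0("n", sprintf("%02d", 1:10)))
  sel_eq <- select_extremes(eq, q = 0.2)
  expect_equal(sel_eq$top_positive, c("n01", "n02"))
  expect_equal(sel_eq$top_negative, c("n01", "n02"))

  expect_error(select_extremes(scores, q = 0.6), "q must be")
  expect_error(select_extremes(scores[1:3], q = 0.01), "selection is empty")

  # 16,900 scores at q = 0.01 select 169 per tail
  big <- stats::setNames(rnorm(16900), sprintf("n%05d", 1:16900))
  expect_equal(select_extremes(big, q = 0.01)$m, 169)
})

test_that("run_diffusion tidies with selection markers", {
  g <- generate_network(100, model = "er", param = 0.05, rng_seed = 2)
  s <- stats::setNames(c(3, -2), igraph::V(g)$name[c(1, 50)])
  res <- run_diffusion(g, s, sigma = 1, q = 0.05)
  td <- tidy(res)
  expect_equal(sum(td$selected == "+"), res$m)
  expect_equal(sum(td$selected == "-"), res$m)
  expect_true(all(td$diffusion_score[td$selected == "+"] >=
                    max(td$diffusion_score[td$selected == "."])))
  expect_true(all(td$diffusion_score[td$selected == "-"] <=
                    min(td$diffusion_score[td$selected == "."])))
  g1 <- glance(res)
  expect_equal(g1$total_diffusion, g1$total_seed, tolerance = 1e-8)
  f <- withr::local_tempfile()
  write_diffusion(res, f)
  expect_equal(nrow(readr::read_tsv(f, show_col_types = FALSE)), 100)
  p <- ggplot2::autoplot(res)
  expect_s3_class(p, "ggplot")
})
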
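# Independent oracles and small fixture builders shared across tests.

# O(k^2) pair scan: induced edge count checked against the graph directly
pair_scan_edges <- function(network, nodes) {
  n <- 0L
  for (i in seq_along(nodes)) {
    for (j in seq_len(i - 1L)) {
      if (igraph::are_adjacent(network, nodes[i], nodes[j])) n <- n + 1L
    }
  }
  n
}

# exhaustive hypergeometric upper tail: enumerate all size-n draws
enum_hyper_tail <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K) # items 1..K are the category
  mean(hits >= k)
}

# exact rational hypergeometric upper tail via python fractions
python_hyper_tail <- function(cases) {
  inp <- paste(apply(cases, 1, paste, collapse = " "), collapse = "\n")
  script <- paste(
    "import sys",
    "from fractions import Fraction",
    "from math import comb",
    "for line in sys.stdin.read().splitlines():",
    "    k, K, n, N = map(int, line.split())",
    "    tot = sum(comb(K, i) * comb(N - K, n - i)",
    "              for i in range(k, min(K, n) + 1))",
    "    p = Fraction(tot, comb(N, n))",
    "    print(repr(float(p)))",
    sep = "\n")
  out <- system2("python", c("-c", shQuote(script)), input = inp,
                 stdout = TRUE)
  as.numeric(out)
}

# Poisson upper tail P(X >= x) by direct log-space term summation,
# independent of stats::ppois
poisson_tail_sum <- function(x, lambda) {
  i <- seq(x, x + 2000)
  sum(exp(-lambda + i * log(lambda) - lgamma(i + 1)))
}

# fixture: small STRING-style links file listing both orientations
write_string_fixture <- function(path,
                                 edges = data.frame(
                                   a = c("p1", "p2", "p1"),
                                   b = c("p2", "p3", "p4"),
                                   score = c(900, 650, 700))) {
  lines <- c("protein1 protein2 combined_score",
             paste(edges$a, edges$b, edges$score),
             paste(edges$b, edges$a, edges$score))
  writeLines(lines, path)
  path
}

triangle_graph <- function() {
  g <- igraph::make_graph(~ a - b, b - c, a - c)
  igraph::E(g)$weight <- 1
  g
}
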
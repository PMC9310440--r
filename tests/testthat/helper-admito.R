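# Shared test utilities: independent brute-force oracles and tiny fixtures.

# TRUE iff the directed graph has a cycle, by transitive-closure reachability
# (independent of the Kahn sort used by validate_dag).
bf_has_cycle <- function(nodes, edges) {
  n <- length(nodes)
  reach <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    reach[edges$parent[[i]], edges$child[[i]]] <- TRUE
  }
  for (k in nodes) for (i in nodes) {
    if (reach[i, k]) reach[i, ] <- reach[i, ] | reach[k, ]
  }
  any(diag(reach))
}

# TRUE iff `ord` is a topological order of the graph.
bf_is_topo_order <- function(ord, nodes, edges) {
  setequal(ord, nodes) && length(ord) == length(nodes) &&
    all(match(edges$parent, ord) < match(edges$child, ord))
}

random_small_graph <- function(n_nodes, p_edge = 0.35) {
  nodes <- LETTERS[seq_len(n_nodes)]
  pairs <- expand.grid(parent = nodes, child = nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$parent != pairs$child, ]
  keep <- stats::runif(nrow(pairs)) < p_edge
  edges <- pairs[keep, , drop = FALSE]
  edges$sign <- rep("promoting", nrow(edges))
  rownames(edges) <- NULL
  list(nodes = nodes, edges = edges)
}

# deterministic 20-record cohort fixture for counting oracles
fixture_cohort <- function() {
  mk <- admito_markers()
  set.seed(424242)
  x <- matrix(rbinom(20 * length(mk), 1, 0.4), nrow = 20,
              dimnames = list(NULL, mk))
  df <- data.frame(
    id = 1:20, x,
    diet = rep(admito_diets(), each = 4),
    age = sample(30:95, 20, replace = TRUE),
    fusion = apply(x, 1, derive_fusion),
    fission = apply(x, 1, derive_fission),
    AD = round(runif(20), 3)
  )
  as_cohort_table(df)
}

default_table2_rows <- function() {
  path <- system.file("extdata", "table2_golden.csv", package = "admito")
  read.csv(path, colClasses = "character")
}
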
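# Brute-force fixed-point oracle: sweeps all 2^n states and evaluates the
# update rules through adjacency-matrix algebra in R, independently of the
# package's propagation-based solver.
oracle_fixed_points <- function(model) {
  n <- length(model$nodes)
  stopifnot(n <= 16)
  S <- as.matrix(expand.grid(rep(list(0:1), n), KEEP.OUT.ATTRS = FALSE))
  colnames(S) <- model$nodes
  A <- matrix(0, n, n)
  I <- matrix(0, n, n)
  for (v in seq_len(n)) {
    A[model$act[[v]], v] <- 1
    I[model$inh[[v]], v] <- 1
  }
  ActM <- (S %*% A) > 0
  InhM <- (S %*% I) > 0
  F <- matrix(0L, nrow(S), n)
  for (v in seq_len(n)) {
    f <- if (model$fixed[v] >= 0) rep(model$fixed[v] == 1L, nrow(S))
    else if (length(model$inh[[v]]) == 0) ActM[, v]
    else if (length(model$act[[v]]) == 0) !InhM[, v]
    else if (model$op[v] == 1L) ActM[, v] & !InhM[, v]
    else ActM[, v] | !InhM[, v]
    F[, v] <- as.integer(f)
  }
  fp <- S[rowSums(F != S) == 0, , drop = FALSE]
  if (nrow(fp) > 1) fp <- fp[do.call(order, as.data.frame(fp)), , drop = FALSE]
  rownames(fp) <- NULL
  fp
}

# random self-contained signed network on n nodes (uses current RNG stream)
random_test_network <- function(n_nodes, n_edges = ceiling(1.7 * n_nodes)) {
  nodes <- sprintf("v%02d", seq_len(n_nodes))
  src <- vapply(seq_len(n_nodes), function(v) {
    sample(setdiff(seq_len(n_nodes), v), 1L)
  }, integer(1))
  edges <- data.frame(source = nodes[src], target = nodes,
                      sign = sample(c(1L, -1L), n_nodes, replace = TRUE),
                      stringsAsFactors = FALSE)
  key <- paste(edges$source, edges$target, edges$sign)
  while (nrow(edges) < n_edges) {
    st <- sample.int(n_nodes, 2L)
    cand <- data.frame(source = nodes[st[1]], target = nodes[st[2]],
                       sign = sample(c(1L, -1L), 1L), stringsAsFactors = FALSE)
    k <- paste(cand$source, cand$target, cand$sign)
    if (k %in% key) next
    edges <- rbind(edges, cand)
    key <- c(key, k)
  }
  pkn(edges)
}

# assembled model with a uniformly random link-operator assignment
random_test_model <- function(n_nodes, n_edges = ceiling(1.7 * n_nodes)) {
  m <- assemble_default_model(random_test_network(n_nodes, n_edges))
  lo <- which(m$op != 0L)
  if (length(lo) > 0) {
    m$op[lo] <- sample(1:2, length(lo), replace = TRUE)
    m$last_op[lo] <- m$op[lo]
  }
  m
}

# tiny deterministic two-gene toggle used across files: A *= B, B *= A
toggle_network <- function() {
  pkn(data.frame(source = c("A", "B"), target = c("B", "A"), sign = 1L,
                 stringsAsFactors = FALSE))
}
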
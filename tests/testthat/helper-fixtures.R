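# Shared fixtures, built in code.

# Random chain with coordinates in a box; not self-avoiding (fine for
# distance-threshold tests).
random_chain <- function(n, seed, box = 30) {
  set.seed(seed)
  residue_chain(paste0("rnd", seed),
                sample(c(strufun:::AA_ALPHABET, "X"), n, replace = TRUE),
                matrix(runif(3 * n, 0, box), n, 3))
}

# Brute-force contact edges: O(N^2) double loop, strict threshold.
brute_force_edges <- function(coords, threshold) {
  n <- nrow(coords)
  out <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (sqrt(sum((coords[i, ] - coords[j, ])^2)) < threshold) {
        out <- rbind(out, c(i - 1L, j - 1L))
      }
    }
  }
  if (is.null(out)) matrix(integer(0), ncol = 2) else out
}

# Path graph 0-1-2-...-(n-1)
path_graph <- function(n, id = "path") {
  contact_graph(id, n, cbind(0:(n - 2), 1:(n - 1)))
}

# Triangle graph
triangle_graph <- function() contact_graph("tri", 3L, rbind(c(0, 1), c(1, 2), c(0, 2)))

# Barbell: two K5 cliques joined by a 3-node path
barbell_graph <- function() {
  edges <- rbind(t(combn(0:4, 2)), t(combn(7:11, 2)),
                 c(4, 5), c(5, 6), c(6, 7))
  contact_graph("barbell", 12L, edges)
}

# Erdos-Renyi-ish random connected-ish graph
random_graph <- function(n, p = 0.3, seed = 1, id = paste0("g", seed)) {
  set.seed(seed)
  pairs <- t(combn(seq_len(n) - 1L, 2))
  keep <- runif(nrow(pairs)) < p
  contact_graph(id, n, pairs[keep, , drop = FALSE])
}

# Random DAG over n terms: term i (i > 1) gets 1-2 parents among 1..i-1.
random_dag <- function(n, seed, branch = "BPO") {
  set.seed(seed)
  ids <- sprintf("GO:T%04d", seq_len(n))
  parents <- setNames(vector("list", n), ids)
  for (k in 2:n) {
    np <- sample(1:2, 1)
    parents[[ids[k]]] <- sample(ids[seq_len(k - 1)], min(np, k - 1))
  }
  go_dag(ids, parents, branch = branch, root = ids[1])
}

# DFS transitive-closure oracle for true-path propagation.
dfs_closure <- function(table, dag) {
  rows <- list()
  for (i in seq_len(nrow(table))) {
    seen <- character(0)
    stack <- table$term_id[i]
    while (length(stack) > 0) {
      t <- stack[[1]]
      stack <- stack[-1]
      if (t %in% seen) next
      seen <- c(seen, t)
      stack <- c(stack, dag$parents[[t]])
    }
    rows[[i]] <- data.frame(protein_id = table$protein_id[i],
                            term_id = seen, stringsAsFactors = FALSE)
  }
  out <- unique(do.call(rbind, rows))
  out[order(out$protein_id, out$term_id), ]
}

# Independent dense GraphConv oracle: sigma(D^-1/2 (A+I) D^-1/2 X W),
# written as explicit loops over the normalised adjacency entries.
dense_conv_oracle <- function(X, A, W, activation = identity) {
  n <- nrow(A)
  At <- A + diag(n)
  deg <- rowSums(At)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      S[i, j] <- At[i, j] / sqrt(deg[i] * deg[j])
    }
  }
  activation(S %*% X %*% W)
}

# Small in-memory training dataset: real chains/graphs/features, labels
# with one motif-determined column plus random background columns.
make_tiny_dataset <- function(n = 10, seed = 1, n_labels = 4) {
  set.seed(seed)
  ids <- sprintf("T%03d", seq_len(n))
  flags <- rep(c(TRUE, FALSE), length.out = n)
  chains <- lapply(seq_len(n), function(i) {
    gen_chain(24, has_motif = flags[i], seed = seed * 1000 + i,
              motif_length = 8, protein_id = ids[i])
  })
  graphs <- lapply(chains, build_contact_map)
  names(graphs) <- ids
  wc <- walk_config(walks_per_node = 3L, epochs = 2L, seed = seed)
  features <- lapply(seq_len(n), function(i) {
    walks <- simulate_walks(graphs[[i]], wc)
    emb <- suppressWarnings(train_node_embeddings(walks, graphs[[i]]$n_nodes, wc))
    featurize_residues(chains[[i]], emb)
  })
  names(features) <- ids
  seqs <- lapply(chains, function(ch) {
    mock_embedding(paste(ch$aa, collapse = ""), seed = seed)
  })
  names(seqs) <- ids
  labels <- matrix(0L, n, n_labels,
                   dimnames = list(ids, sprintf("GO:L%02d", seq_len(n_labels))))
  labels[, 1] <- as.integer(flags)
  for (j in 2:n_labels) labels[, j] <- rbinom(n, 1, 0.5)
  splits <- split_dataset(ids, seed = seed)
  go_dataset(features, graphs, seqs, labels, splits)
}
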
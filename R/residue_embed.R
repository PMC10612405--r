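#' Configuration for biased random walks and skip-gram training
#'
#' Defaults follow the second-order (node2vec-style) walk settings used
#' throughout the pipeline: return parameter `p = 0.8`, in-out parameter
#' `q = 1.2`, walk length 30, and a 30-dimensional embedding that together
#' with the 20-column one-hot block gives the 1x50 residue feature.
#'
#' @param p Return parameter (> 0); smaller values make revisiting the
#'   previous node more likely (weight `1/p`).
#' @param q In-out parameter (> 0); smaller values push the walk outward
#'   (weight `1/q` for nodes not adjacent to the previous node).
#' @param walk_length Maximum walk length in nodes (>= 2).
#' @param walks_per_node Number of walks started from every node.
#' @param embed_dim Embedding dimension (default 30).
#' @param window Skip-gram context window.
#' @param epochs Skip-gram passes over the walk corpus.
#' @param negative Negative samples per positive pair.
#' @param alpha Initial skip-gram learning rate.
#' @param seed Integer seed; the full walk corpus and the trained vectors
#'   are reproducible from it.
#' @return A list of class `walk_config`.
#' @export
walk_config <- function(p = 0.8, q = 1.2, walk_length = 30L,
                        walks_per_node = 10L, embed_dim = 30L,
                        window = 5L, epochs = 5L, negative = 5L,
                        alpha = 0.025, seed = 1L) {
  stopifnot(p > 0, q > 0, walk_length >= 2L, walks_per_node >= 1L,
            embed_dim >= 1L, window >= 1L, epochs >= 1L)
  structure(
    list(p = p, q = q, walk_length = as.integer(walk_length),
         walks_per_node = as.integer(walks_per_node),
         embed_dim = as.integer(embed_dim), window = as.integer(window),
         epochs = as.integer(epochs), negative = as.integer(negative),
         alpha = alpha, seed = as.integer(seed)),
    class = "walk_config"
  )
}

#' Unnormalised biased-walk step weights
#'
#' For a walk that reached `curr` from `prev`, every neighbour `x` of
#' `curr` gets weight `1/p` if `x == prev` (shortest-path distance 0 from
#' `prev`), `1` if `x` is adjacent to `prev` (distance 1), and `1/q`
#' otherwise (distance 2). Non-neighbours of `curr` have weight 0 and are
#' omitted. On the first step (`prev = NULL`) weights are uniform.
#' Normalisation is performed by the sampler, not here.
#'
#' @param prev Previous node (0-based) or `NULL` for the first step.
#' @param curr Current node (0-based).
#' @param graph A [contact_graph()].
#' @param cfg A [walk_config()].
#' @return Named numeric vector of non-negative weights over the
#'   neighbours of `curr` (empty if `curr` is isolated).
#' @export
step_weights <- function(prev, curr, graph, cfg = walk_config()) {
  nb <- graph_neighbors(graph)[[curr + 1L]]
  if (length(nb) == 0L) return(stats::setNames(numeric(0), character(0)))
  if (is.null(prev)) {
    w <- rep(1, length(nb))
  } else {
    prev_nb <- graph_neighbors(graph)[[prev + 1L]]
    w <- vapply(nb, function(x) {
      if (x == prev) 1 / cfg$p
      else if (x %in% prev_nb) 1
      else 1 / cfg$q
    }, numeric(1))
  }
  stats::setNames(w, nb)
}

#' Simulate biased random walks over a contact graph
#'
#' Starts `walks_per_node` walks from every node and extends each up to
#' `walk_length` nodes with second-order biased steps; a walk reaching a
#' neighbour-less node terminates early. Fully reproducible from
#' `cfg$seed`.
#'
#' @param graph A [contact_graph()].
#' @param cfg A [walk_config()].
#' @return List of integer vectors of 0-based node ids.
#' @export
simulate_walks <- function(graph, cfg = walk_config()) {
  stopifnot(graph$n_nodes >= 1L)
  nb <- graph_neighbors(graph)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(cfg$seed)
  cpp_simulate_walks(nb, cfg$walk_length, cfg$walks_per_node, cfg$p, cfg$q)
}

#' Empirical next-step draws from a given walk state
#'
#' Draws `n` next steps from the state (`prev`, `curr`) using the same
#' sampler that [simulate_walks()] uses, for checking the sampled
#' transition law against the normalised step weights.
#'
#' @inheritParams step_weights
#' @param n Number of draws.
#' @param seed Seed for the draws.
#' @return Integer vector of sampled next nodes (0-based).
#' @export
sample_next_steps <- function(prev, curr, graph, cfg = walk_config(),
                              n = 1e5, seed = cfg$seed) {
  nb <- graph_neighbors(graph)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  cpp_next_steps(nb, if (is.null(prev)) -1L else as.integer(prev),
                 as.integer(curr), cfg$p, cfg$q, as.integer(n))
}

#' Train node embeddings from walks by skip-gram with negative sampling
#'
#' Single-threaded word2vec-style training over the walk corpus. Nodes
#' that never appear in any walk get a zero vector, with a warning.
#' Deterministic under a fixed `cfg$seed`.
#'
#' @param walks List of integer walks (0-based node ids), as produced by
#'   [simulate_walks()].
#' @param n_nodes Total number of nodes in the graph.
#' @param cfg A [walk_config()].
#' @return `n_nodes` x `embed_dim` numeric matrix, row `i` the vector of
#'   node `i - 1`.
#' @export
train_node_embeddings <- function(walks, n_nodes, cfg = walk_config()) {
  stopifnot(length(walks) > 0L)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(cfg$seed + 1L)
  emb <- cpp_sgns(walks, as.integer(n_nodes), cfg$embed_dim, cfg$window,
                  cfg$epochs, cfg$negative, cfg$alpha)
  visited <- rep(FALSE, n_nodes)
  for (w in walks) visited[w + 1L] <- TRUE
  if (any(!visited)) {
    warning(sprintf("%d node(s) never visited by any walk; zero vectors used",
                    sum(!visited)))
    emb[!visited, ] <- 0
  }
  emb
}

#' Residue feature matrix: walk embedding next to one-hot amino acid
#'
#' Row `i` is the walk embedding of node `i` concatenated with the
#' 20-column one-hot encoding of residue `i` (all-zero for the unknown
#' code `"X"`). With the default 30-dimensional embedding the rows are
#' the pipeline's 1x50 residue features.
#'
#' @param chain A [residue_chain()].
#' @param embeddings Numeric matrix, one row per residue (see
#'   [train_node_embeddings()]); rows of zeros are substituted for any
#'   residue it does not cover.
#' @return Object of class `residue_features`: list with `protein_id`,
#'   `matrix` (N x (embed_dim + 20)), and `embed_dim`.
#' @export
featurize_residues <- function(chain, embeddings) {
  n <- length(chain$aa)
  embeddings <- as.matrix(embeddings)
  if (nrow(embeddings) < n) {
    pad <- matrix(0, n - nrow(embeddings), ncol(embeddings))
    embeddings <- rbind(embeddings, pad)
  }
  onehot <- matrix(0, n, length(AA_ALPHABET),
                   dimnames = list(NULL, AA_ALPHABET))
  hit <- match(chain$aa, AA_ALPHABET)
  ok <- !is.na(hit)
  onehot[cbind(which(ok), hit[ok])] <- 1
  structure(
    list(protein_id = chain$protein_id,
         matrix = unname(cbind(embeddings[seq_len(n), , drop = FALSE], onehot)),
         embed_dim = ncol(embeddings)),
    class = "residue_features"
  )
}

#' Compute residue features for a chain end to end
#'
#' Convenience wrapper: contact graph -> walks -> skip-gram -> one-hot
#' fusion.
#'
#' @param chain A [residue_chain()].
#' @param graph Optional precomputed [contact_graph()].
#' @param cfg A [walk_config()].
#' @return A `residue_features` object (see [featurize_residues()]).
#' @export
residue_features <- function(chain, graph = NULL, cfg = walk_config()) {
  graph <- graph %||% build_contact_map(chain)
  walks <- simulate_walks(graph, cfg)
  emb <- train_node_embeddings(walks, graph$n_nodes, cfg)
  featurize_residues(chain, emb)
}

# Save/restore the global RNG state so seeded helpers do not disturb the
# caller's random stream.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
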
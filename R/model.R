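#' Model configuration
#'
#' Defaults follow the settings the method performs best with: two
#' GraphConv layers, two attention heads, pooling ratio 0.75, dropout
#' 0.3, learning rate 1e-4. Hidden sizes and batch size are
#' implementation defaults (128-unit node features, one 512-unit MLP
#' layer, batches of 32).
#'
#' @param conv_layers Number of convolution+pooling layers (2).
#' @param hidden_dim Node feature width after convolution.
#' @param pooling_ratio Fraction `k` of nodes kept by each pooling layer,
#'   in (0, 1]; `ceiling(k * N)` nodes are retained.
#' @param attention_heads Attention heads scoring nodes (>= 1).
#' @param dropout Dropout rate on the MLP hidden layer, in [0, 1).
#' @param modality_dropout Probability of zeroing the entire sequence
#'   block of the fused vector for a training example (inverted scaling
#'   at train time); 0 disables.
#' @param walk_dropout Per-entry dropout rate on the walk-embedding
#'   block (the first `embed_dim` columns) of the node features during
#'   training, inverted scaling. The walk embedding is trained per
#'   protein, so its coordinates are only comparable within a graph;
#'   entry-level dropout stops the classifier from keying on any one
#'   protein's embedding pattern while leaving the residue-identity
#'   channel intact. 0 disables.
#' @param aux_weight Weight of the auxiliary structure-only head's loss
#'   during training (deep supervision). The auxiliary head is a linear
#'   classifier on the structural readout alone; it gives the graph
#'   branch a direct gradient path so the much wider sequence channel
#'   cannot starve it during joint training. Predictions always come
#'   from the fused head; 0 disables.
#' @param learning_rate Adam learning rate.
#' @param epochs Training epochs.
#' @param batch_size Proteins per gradient step.
#' @param mlp_hidden Width of the classifier's hidden layer.
#' @param readout `"mean"` (mean-and-max concatenation, the default) or
#'   `"sum"` (sum-and-max).
#' @param conv_type Only `"graphconv"` (symmetric-normalised adjacency
#'   with self-loops) is implemented; other names are rejected.
#' @param seed Integer seed controlling initialisation, shuffling and
#'   dropout.
#' @return A list of class `model_config`.
#' @export
model_config <- function(conv_layers = 2L, hidden_dim = 128L,
                         pooling_ratio = 0.75, attention_heads = 2L,
                         dropout = 0.3, learning_rate = 1e-4,
                         modality_dropout = 0, walk_dropout = 0.5,
                         aux_weight = 1,
                         epochs = 50L, batch_size = 32L,
                         mlp_hidden = 512L,
                         readout = c("mean", "sum"),
                         conv_type = "graphconv", seed = 1L) {
  readout <- match.arg(readout)
  if (!identical(conv_type, "graphconv")) {
    stop("conv_type '", conv_type, "' is not implemented; use \"graphconv\"")
  }
  stopifnot(conv_layers >= 1L, hidden_dim >= 1L,
            pooling_ratio > 0, pooling_ratio <= 1,
            attention_heads >= 1L, dropout >= 0, dropout < 1,
            modality_dropout >= 0, modality_dropout < 1,
            walk_dropout >= 0, walk_dropout < 1, aux_weight >= 0,
            learning_rate > 0, epochs >= 1L, batch_size >= 1L)
  structure(
    list(conv_layers = as.integer(conv_layers),
         hidden_dim = as.integer(hidden_dim),
         pooling_ratio = pooling_ratio,
         attention_heads = as.integer(attention_heads),
         dropout = dropout, learning_rate = learning_rate,
         modality_dropout = modality_dropout, walk_dropout = walk_dropout,
         aux_weight = aux_weight,
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         mlp_hidden = as.integer(mlp_hidden), readout = readout,
         conv_type = conv_type, seed = as.integer(seed)),
    class = "model_config"
  )
}

# Symmetric-normalised adjacency with self-loops: D^-1/2 (A + I) D^-1/2.
norm_adjacency <- function(A) {
  At <- A + diag(nrow(A))
  dinv <- 1 / sqrt(rowSums(At))
  At * tcrossprod(dinv)
}

#' Graph convolution layer
#'
#' One propagation step `activation(D^-1/2 (A + I) D^-1/2 %*% features
#' %*% weights)`: self-loops are added to the adjacency, it is
#' symmetrically normalised by the loop-augmented degrees, and the
#' aggregated features are linearly transformed.
#'
#' @param features `N x F` numeric matrix (`N = n_nodes` of `graph`).
#' @param graph A [contact_graph()].
#' @param weights `F x F'` weight matrix.
#' @param activation Elementwise activation function (default identity).
#' @return `N x F'` matrix.
#' @export
graph_conv <- function(features, graph, weights, activation = identity) {
  features <- as.matrix(features)
  weights <- as.matrix(weights)
  if (nrow(features) != graph$n_nodes) {
    stop("feature rows (", nrow(features), ") != graph nodes (",
         graph$n_nodes, ")")
  }
  if (ncol(features) != nrow(weights)) {
    stop("feature width (", ncol(features), ") != weight rows (",
         nrow(weights), ")")
  }
  S <- norm_adjacency(adjacency_matrix(graph))
  activation(S %*% features %*% weights)
}

#' Self-attention node importance scores
#'
#' Each head is a graph convolution with output width one (a linear
#' scoring of the aggregated node features); the final per-node score is
#' the arithmetic mean over heads.
#'
#' @param features `N x F` matrix.
#' @param graph A [contact_graph()].
#' @param weights List of `F`-length numeric vectors, one per head.
#' @return Object of class `attention_scores`: list with `per_head`
#'   (`N x heads` matrix) and `mean` (length-`N` vector).
#' @export
attention_score <- function(features, graph, weights) {
  stopifnot(length(weights) >= 1L)
  per_head <- vapply(weights, function(a) {
    drop(graph_conv(features, graph, matrix(a, ncol = 1L)))
  }, numeric(graph$n_nodes))
  per_head <- matrix(per_head, nrow = graph$n_nodes)
  structure(list(per_head = per_head, mean = rowMeans(per_head)),
            class = "attention_scores")
}

#' Top-rank pooling
#'
#' Keeps the `ceiling(k * N)` nodes with the highest attention scores
#' (ties broken toward the lower node index), gates the retained feature
#' rows by the logistic sigmoid of the mean score, and induces the
#' subgraph on the retained nodes. (A positive gate preserves the sign
#' of node features, so the graph readout stays informative under
#' randomly initialised attention weights.) With `k = 1` all nodes are
#' retained and the graph is unchanged.
#'
#' @param features `N x F` matrix.
#' @param graph A [contact_graph()].
#' @param scores An [attention_score()] result (or a numeric vector of
#'   per-node scores).
#' @param k Pooling ratio in (0, 1].
#' @return List with `features` (gated `m x F`), `graph` (induced
#'   [contact_graph()]), `idx` (1-based retained indices in original
#'   order), and `gate` (the sigmoid-squashed scores applied).
#' @export
top_rank_pool <- function(features, graph, scores, k) {
  stopifnot(k > 0, k <= 1)
  z <- if (inherits(scores, "attention_scores")) scores$mean else as.numeric(scores)
  n <- graph$n_nodes
  stopifnot(length(z) == n, nrow(features) == n)
  m <- max(1L, as.integer(ceiling(k * n)))
  ord <- order(-z, seq_len(n))          # descending score, index tie-break
  idx <- sort(ord[seq_len(m)])          # original node order preserved
  gate <- 1 / (1 + exp(-z[idx]))
  Xout <- features[idx, , drop = FALSE] * gate
  A <- adjacency_matrix(graph)[idx, idx, drop = FALSE]
  pairs <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  sub <- contact_graph(graph$protein_id, m,
                       cbind(pairs[, 1L] - 1L, pairs[, 2L] - 1L))
  list(features = Xout, graph = sub, idx = idx, gate = gate)
}

#' Graph readout
#'
#' Permutation-invariant reduction of node features to one graph vector:
#' the column-wise mean (or sum) concatenated with the column-wise max,
#' width `2 * ncol(features)`.
#'
#' @param features `N x d` matrix with `N >= 1`.
#' @param method `"mean"` (default) or `"sum"`.
#' @return Numeric vector of length `2 d`.
#' @export
readout <- function(features, method = c("mean", "sum")) {
  method <- match.arg(method)
  features <- as.matrix(features)
  if (nrow(features) == 0L) stop("readout of an empty graph")
  agg <- if (method == "mean") colMeans(features) else colSums(features)
  c(agg, apply(features, 2L, max))
}

# ---- parameter initialisation -------------------------------------------

# Glorot-uniform init, seeded by the caller.
.glorot <- function(nin, nout) {
  r <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -r, r), nin, nout)
}

init_params <- function(in_dim, n_labels, cfg) {
  h <- cfg$hidden_dim
  W <- vector("list", cfg$conv_layers)
  a <- vector("list", cfg$conv_layers)
  for (l in seq_len(cfg$conv_layers)) {
    W[[l]] <- .glorot(if (l == 1L) in_dim else h, h)
    a[[l]] <- lapply(seq_len(cfg$attention_heads),
                     function(i) drop(.glorot(h, 1L)))
  }
  fused <- 2L * h + EMBED_DIM
  list(W = W, a = a,
       Wf1 = .glorot(fused, cfg$mlp_hidden),
       bf1 = numeric(cfg$mlp_hidden),
       Wf2 = .glorot(cfg$mlp_hidden, n_labels),
       bf2 = numeric(n_labels),
       Wa = .glorot(2L * h, n_labels),
       ba = numeric(n_labels))
}

# ---- forward / backward per protein -------------------------------------

# Structural branch forward with full caches for backprop.
# gdata: list(A = adjacency, S = normalised adjacency) for the input graph.
struct_forward <- function(X, gdata, params, cfg) {
  layers <- vector("list", cfg$conv_layers)
  H_in <- X
  A <- gdata$A
  S <- gdata$S
  struct <- numeric(2L * cfg$hidden_dim)
  for (l in seq_len(cfg$conv_layers)) {
    Q <- S %*% H_in
    P <- Q %*% params$W[[l]]
    H <- pmax(P, 0)
    SH <- S %*% H
    per_head <- vapply(params$a[[l]], function(av) drop(SH %*% av),
                       numeric(nrow(H)))
    per_head <- matrix(per_head, nrow = nrow(H))
    z <- rowMeans(per_head)
    n <- nrow(H)
    m <- max(1L, as.integer(ceiling(cfg$pooling_ratio * n)))
    ord <- order(-z, seq_len(n))
    idx <- sort(ord[seq_len(m)])
    gate <- 1 / (1 + exp(-z[idx]))
    Xp <- H[idx, , drop = FALSE]
    Xout <- Xp * gate
    s_l <- readout(Xout, cfg$readout)
    struct <- struct + s_l
    layers[[l]] <- list(H_in = H_in, S = S, A = A, Q = Q, P = P, H = H,
                        SH = SH, z = z, idx = idx, gate = gate,
                        Xp = Xp, Xout = Xout)
    if (l < cfg$conv_layers) {
      A <- A[idx, idx, drop = FALSE]
      S <- norm_adjacency(A)
      H_in <- Xout
    }
  }
  list(struct = struct, layers = layers)
}

# Backprop through the structural branch. d_struct: gradient wrt the
# summed readout vector. Returns gradients for W and a plus nothing else
# (input features are not trained).
struct_backward <- function(fwd, d_struct, params, cfg) {
  h <- cfg$hidden_dim
  gW <- lapply(params$W, function(w) array(0, dim(w)))
  ga <- lapply(params$a, function(hs) lapply(hs, function(v) numeric(length(v))))
  d_next_in <- NULL  # gradient wrt H_in of layer l+1 (= Xout of layer l)
  for (l in rev(seq_len(cfg$conv_layers))) {
    L <- fwd$layers[[l]]
    m <- length(L$idx)
    # readout backward
    dmean <- d_struct[seq_len(h)]
    dmax <- d_struct[h + seq_len(h)]
    dXout <- matrix(0, m, h)
    if (cfg$readout == "mean") {
      dXout <- dXout + matrix(dmean / m, m, h, byrow = TRUE)
    } else {
      dXout <- dXout + matrix(dmean, m, h, byrow = TRUE)
    }
    amax <- apply(L$Xout, 2L, which.max)
    dXout[cbind(amax, seq_len(h))] <- dXout[cbind(amax, seq_len(h))] + dmax
    if (!is.null(d_next_in)) dXout <- dXout + d_next_in
    # gating backward: Xout = Xp * gate (rows scaled)
    dXp <- dXout * L$gate
    dgate <- rowSums(dXout * L$Xp)
    dz <- numeric(length(L$z))
    dz[L$idx] <- dgate * L$gate * (1 - L$gate)
    # attention backward: z = rowMeans(SH %*% a_h over heads)
    heads <- length(params$a[[l]])
    dH <- matrix(0, nrow(L$H), h)
    dH[L$idx, ] <- dXp
    dz_head <- dz / heads
    for (hh in seq_len(heads)) {
      ga[[l]][[hh]] <- ga[[l]][[hh]] + drop(crossprod(L$SH, dz_head))
      dH <- dH + (L$S %*% (dz_head %o% params$a[[l]][[hh]]))
    }
    # conv backward: H = relu(Q W)
    dP <- dH * (L$P > 0)
    gW[[l]] <- gW[[l]] + crossprod(L$Q, dP)
    dQ <- dP %*% t(params$W[[l]])
    d_next_in <- as.matrix(L$S %*% dQ)   # = gradient wrt H_in of this layer
  }
  list(W = gW, a = ga)
}

# Full forward for one protein. Returns yhat plus caches.
# dropout_mask: list(input =, hidden =) inverted-dropout masks, or NULL
# (evaluation mode). Input dropout is applied to the fused vector.
protein_forward <- function(X, gdata, seq_vec, params, cfg,
                            ablate_structure = FALSE,
                            dropout_mask = NULL) {
  if (ablate_structure) {
    fwd <- NULL
    struct <- numeric(2L * cfg$hidden_dim)
  } else {
    fwd <- struct_forward(X, gdata, params, cfg)
    struct <- fwd$struct
  }
  fused <- c(struct, seq_vec)
  if (!is.null(dropout_mask)) fused <- fused * dropout_mask$input
  u1 <- drop(fused %*% params$Wf1) + params$bf1
  r1 <- pmax(u1, 0)
  r1d <- if (is.null(dropout_mask)) r1 else r1 * dropout_mask$hidden
  logits <- drop(r1d %*% params$Wf2) + params$bf2
  yhat <- 1 / (1 + exp(-logits))
  yhat_aux <- if (ablate_structure) NULL else {
    1 / (1 + exp(-(drop(struct %*% params$Wa) + params$ba)))
  }
  list(yhat = yhat, yhat_aux = yhat_aux, struct = struct, fused = fused,
       u1 = u1, r1 = r1, r1d = r1d, struct_fwd = fwd,
       dropout_mask = dropout_mask)
}

# Backward for one protein given dlogits; accumulates into grads (an
# environment holding the same shapes as params).
protein_backward <- function(fw, dlogits, params, cfg, grads,
                             ablate_structure = FALSE,
                             dlogits_aux = NULL) {
  grads$Wf2 <- grads$Wf2 + fw$r1d %o% dlogits
  grads$bf2 <- grads$bf2 + dlogits
  dr1d <- drop(params$Wf2 %*% dlogits)
  dr1 <- if (is.null(fw$dropout_mask)) dr1d else dr1d * fw$dropout_mask$hidden
  du1 <- dr1 * (fw$u1 > 0)
  grads$Wf1 <- grads$Wf1 + fw$fused %o% du1
  grads$bf1 <- grads$bf1 + du1
  if (!ablate_structure) {
    dfused <- drop(params$Wf1 %*% du1)
    if (!is.null(fw$dropout_mask)) dfused <- dfused * fw$dropout_mask$input
    d_struct <- dfused[seq_len(2L * cfg$hidden_dim)]
    if (isTRUE(getOption("strufun.detach_struct"))) d_struct <- d_struct * 0
    if (!is.null(dlogits_aux)) {
      grads$Wa <- grads$Wa + fw$struct %o% dlogits_aux
      grads$ba <- grads$ba + dlogits_aux
      d_struct <- d_struct + drop(params$Wa %*% dlogits_aux)
    }
    sg <- struct_backward(fw$struct_fwd, d_struct, params, cfg)
    for (l in seq_along(sg$W)) {
      grads$W[[l]] <- grads$W[[l]] + sg$W[[l]]
      for (hh in seq_along(sg$a[[l]])) {
        grads$a[[l]][[hh]] <- grads$a[[l]][[hh]] + sg$a[[l]][[hh]]
      }
    }
  }
  invisible(grads)
}

# ---- Adam ---------------------------------------------------------------

# Flatten/unflatten parameter lists so Adam state is one numeric vector.
.flatten <- function(p) {
  unlist(p, use.names = FALSE)
}

.unflatten <- function(vec, skeleton) {
  pos <- 0L
  take <- function(tpl) {
    if (is.list(tpl)) return(lapply(tpl, take))
    n <- length(tpl)
    out <- vec[(pos + 1L):(pos + n)]
    pos <<- pos + n
    if (is.matrix(tpl)) matrix(out, nrow(tpl), ncol(tpl)) else out
  }
  out <- take(skeleton)
  stopifnot(pos == length(vec))
  out
}

adam_state <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(theta, grad, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- beta1 * st$m + (1 - beta1) * grad
  st$v <- beta2 * st$v + (1 - beta2) * grad^2
  mhat <- st$m / (1 - beta1^st$t)
  vhat <- st$v / (1 - beta2^st$t)
  theta <- theta - lr * mhat / (sqrt(vhat) + eps)
  list(theta = theta, state = st)
}

# ---- training -----------------------------------------------------------

#' Assemble a training dataset
#'
#' Bundles the per-protein inputs the network consumes. All list
#' arguments are keyed by protein id; ids present in `labels` rows define
#' the dataset.
#'
#' @param features Named list of residue feature matrices (`N x 50`).
#' @param graphs Named list of [contact_graph()] objects.
#' @param seq_embeddings Named list of length-1024 numeric vectors (or
#'   [protein_embedding()] objects).
#' @param labels Binary protein x term matrix with dimnames (see
#'   [label_matrix()]).
#' @param splits List with character vectors `train`, `valid`, `test`.
#' @return A list of class `go_dataset`.
#' @export
go_dataset <- function(features, graphs, seq_embeddings, labels, splits) {
  ids <- rownames(labels)
  stopifnot(!is.null(ids), all(ids %in% names(features)),
            all(ids %in% names(graphs)))
  missing_emb <- setdiff(ids, names(seq_embeddings))
  if (length(missing_emb) > 0L) {
    stop("missing sequence embedding for: ",
         paste(utils::head(missing_emb, 5L), collapse = ", "))
  }
  seqv <- lapply(seq_embeddings, function(e) {
    if (inherits(e, "protein_embedding")) e$vector else as.numeric(e)
  })
  gdata <- lapply(graphs, function(g) {
    A <- adjacency_matrix(g)
    list(A = A, S = norm_adjacency(A))
  })
  feat <- lapply(features, function(f) {
    if (inherits(f, "residue_features")) f$matrix else as.matrix(f)
  })
  structure(list(ids = ids, features = feat, gdata = gdata,
                 seq = seqv, labels = labels, splits = splits),
            class = "go_dataset")
}

#' Train the function-prediction network
#'
#' Minimises the sum of per-label binary cross-entropies with Adam,
#' evaluating protein-centric Fmax on the validation split after each
#' epoch and keeping the best-scoring parameters. Fully reproducible
#' from `cfg$seed`.
#'
#' @param dataset A [go_dataset()].
#' @param cfg A [model_config()].
#' @param ablate_structure If `TRUE`, the structural branch is zeroed
#'   throughout (sequence-only control).
#' @param verbose Print per-epoch progress.
#' @return Object of class `go_model`: list with `params`, `cfg`,
#'   `terms`, `ablate_structure`, and `history` (epoch, loss, val_fmax).
#' @export
train_model <- function(dataset, cfg = model_config(),
                        ablate_structure = FALSE, verbose = FALSE) {
  terms <- colnames(dataset$labels)
  if (length(terms) == 0L) stop("empty label space")
  train_ids <- dataset$splits$train
  valid_ids <- dataset$splits$valid
  stopifnot(length(train_ids) >= 1L)
  in_dim <- ncol(dataset$features[[train_ids[1L]]])

  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(cfg$seed)
  params <- init_params(in_dim, length(terms), cfg)
  skeleton <- params
  st <- adam_state(length(.flatten(params)))

  best <- list(fmax = -Inf, params = params)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_fmax = numeric(0))
  keep_rate <- 1 - cfg$dropout

  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample(train_ids)
    total_loss <- 0
    nbatch <- ceiling(length(ord) / cfg$batch_size)
    for (b in seq_len(nbatch)) {
      ids <- ord[((b - 1L) * cfg$batch_size + 1L):min(b * cfg$batch_size,
                                                      length(ord))]
      grads <- lapply(params, function(p) {
        if (is.list(p)) lapply(p, function(q) {
          if (is.list(q)) lapply(q, function(r) r * 0) else q * 0
        }) else p * 0
      })
      for (id in ids) {
        X_in <- dataset$features[[id]]
        if (cfg$walk_dropout > 0 && !ablate_structure) {
          wkeep <- 1 - cfg$walk_dropout
          wd <- ncol(X_in) - length(AA_ALPHABET)
          if (wd > 0) {
            blk <- X_in[, seq_len(wd), drop = FALSE]
            mask_w <- (stats::runif(length(blk)) < wkeep) / wkeep
            X_in[, seq_len(wd)] <- blk * mask_w
          }
        }
        mask <- if (cfg$dropout > 0 || cfg$modality_dropout > 0) {
          seq_keep <- 1 - cfg$modality_dropout
          seq_on <- if (cfg$modality_dropout > 0) {
            (stats::runif(1) < seq_keep) / seq_keep
          } else 1
          hid <- if (cfg$dropout > 0) {
            (stats::runif(cfg$mlp_hidden) < keep_rate) / keep_rate
          } else rep(1, cfg$mlp_hidden)
          list(input = c(rep(1, 2L * cfg$hidden_dim),
                         rep(seq_on, EMBED_DIM)),
               hidden = hid)
        } else NULL
        fw <- protein_forward(X_in, dataset$gdata[[id]],
                              dataset$seq[[id]], params, cfg,
                              ablate_structure = ablate_structure,
                              dropout_mask = mask)
        y <- dataset$labels[id, ]
        eps <- 1e-12
        total_loss <- total_loss -
          sum(y * log(fw$yhat + eps) + (1 - y) * log(1 - fw$yhat + eps))
        dlogits <- (fw$yhat - y) / length(ids)
        dlogits_aux <- NULL
        if (!ablate_structure && cfg$aux_weight > 0) {
          total_loss <- total_loss - cfg$aux_weight *
            sum(y * log(fw$yhat_aux + eps) +
                  (1 - y) * log(1 - fw$yhat_aux + eps))
          dlogits_aux <- cfg$aux_weight * (fw$yhat_aux - y) / length(ids)
        }
        grads <- protein_backward(fw, dlogits, params, cfg, grads,
                                  ablate_structure = ablate_structure,
                                  dlogits_aux = dlogits_aux)
      }
      upd <- adam_step(.flatten(params), .flatten(grads), st,
                       cfg$learning_rate)
      st <- upd$state
      params <- .unflatten(upd$theta, skeleton)
    }
    val_fmax <- NA_real_
    if (length(valid_ids) > 0L) {
      sc <- .predict_ids(dataset, params, cfg, valid_ids, ablate_structure)
      truth <- dataset$labels[valid_ids, , drop = FALSE]
      val_fmax <- if (sum(truth) > 0L) fmax(sc, truth)$fmax else NA_real_
      if (!is.na(val_fmax) && val_fmax > best$fmax) {
        best <- list(fmax = val_fmax, params = params)
      }
    }
    history <- rbind(history,
                     data.frame(epoch = epoch,
                                loss = total_loss / length(ord),
                                val_fmax = val_fmax))
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  val Fmax %.3f",
                      epoch, total_loss / length(ord), val_fmax))
    }
  }
  final <- if (is.finite(best$fmax)) best$params else params
  structure(list(params = final, cfg = cfg, terms = terms,
                 ablate_structure = ablate_structure, history = history),
            class = "go_model")
}

.predict_ids <- function(dataset, params, cfg, ids, ablate_structure) {
  out <- matrix(0, length(ids), ncol(dataset$labels),
                dimnames = list(ids, colnames(dataset$labels)))
  for (i in seq_along(ids)) {
    fw <- protein_forward(dataset$features[[ids[i]]],
                          dataset$gdata[[ids[i]]],
                          dataset$seq[[ids[i]]], params, cfg,
                          ablate_structure = ablate_structure,
                          dropout_mask = NULL)
    out[i, ] <- fw$yhat
  }
  out
}

#' Predict GO-term scores
#'
#' @param model A trained [train_model()] result.
#' @param dataset A [go_dataset()].
#' @param ids Protein ids to score (default: the test split).
#' @return Score matrix (proteins x terms, values in (0, 1)).
#' @export
predict_scores <- function(model, dataset, ids = dataset$splits$test) {
  .predict_ids(dataset, model$params, model$cfg, ids,
               model$ablate_structure)
}

#' @export
print.go_model <- function(x, ...) {
  cat(sprintf("<go_model> %d labels, %d epochs trained%s\n",
              length(x$terms), nrow(x$history),
              if (x$ablate_structure) " (structure ablated)" else ""))
  invisible(x)
}

#' Write predictions as CAFA-style TSV
#'
#' Three columns: protein id, term id, score rounded to 3 decimals.
#'
#' @param scores Score matrix with dimnames.
#' @param path Output path.
#' @param min_score Rows below this score are omitted (default 0: keep all).
#' @return `path`, invisibly.
#' @export
write_predictions <- function(scores, path, min_score = 0) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(scores))) {
    keep <- which(scores[i, ] >= min_score)
    if (length(keep) == 0L) next
    writeLines(sprintf("%s\t%s\t%.3f", rownames(scores)[i],
                       colnames(scores)[keep], scores[i, keep]), con)
  }
  invisible(path)
}
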
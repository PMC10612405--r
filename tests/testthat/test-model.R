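test_that("graph convolution reduces to identity on trivial graphs", {
  # single node: A~ = D~ = 1, so output = input under identity weights
  g1 <- contact_graph("one", 1L, matrix(integer(0), ncol = 2))
  x <- matrix(c(1.5, -2, 0.3), 1, 3)
  expect_equal(graph_conv(x, g1, diag(3)), x, ignore_attr = TRUE)
  # two disconnected nodes: block identity
  g2 <- contact_graph("two", 2L, matrix(integer(0), ncol = 2))
  x2 <- matrix(rnorm(6), 2, 3)
  expect_equal(graph_conv(x2, g2, diag(3)), x2, ignore_attr = TRUE)
})

test_that("graph convolution matches the dense closed-form oracle", {
  set.seed(20)
  for (rep in 1:50) {
    n <- sample(2:8, 1)
    g <- random_graph(n, p = 0.5, seed = 1000 + rep)
    X <- matrix(rnorm(n * 4), n, 4)
    W <- matrix(rnorm(4 * 3), 4, 3)
    got <- graph_conv(X, g, W, activation = function(m) pmax(m, 0))
    want <- dense_conv_oracle(X, adjacency_matrix(g), W,
                              activation = function(m) pmax(m, 0))
    expect_lt(max(abs(got - want)), 1e-6)
  }
})

test_that("graph convolution rejects mismatched dimensions", {
  g <- path_graph(3)
  expect_error(graph_conv(matrix(0, 2, 4), g, diag(4)), "nodes")
  expect_error(graph_conv(matrix(0, 3, 4), g, diag(5)), "width")
})

test_that("attention scores average heads and are permutation-equivariant", {
  g <- random_graph(7, p = 0.4, seed = 2)
  X <- matrix(rnorm(7 * 5), 7, 5)
  a1 <- rnorm(5)
  # identical heads: mean equals either head
  sc <- attention_score(X, g, list(a1, a1))
  expect_equal(sc$mean, sc$per_head[, 1])
  # one head: degenerate mean
  sc1 <- attention_score(X, g, list(a1))
  expect_equal(sc1$mean, sc1$per_head[, 1])

  # relabeling nodes permutes scores identically
  set.seed(3)
  perm <- sample(7)  # perm[i] = new label of old node i-1... map edges
  e <- g$edges
  e2 <- cbind(perm[e[, 1] + 1] - 1L, perm[e[, 2] + 1] - 1L)
  g2 <- contact_graph("perm", 7L, e2)
  X2 <- X
  X2[perm, ] <- X
  a2 <- rnorm(5)
  s_orig <- attention_score(X, g, list(a1, a2))$mean
  s_perm <- attention_score(X2, g2, list(a1, a2))$mean
  expect_equal(s_perm[perm], s_orig)
})

test_that("top-rank pooling keeps the exhaustive-sort top nodes", {
  for (n in 2:10) {
    for (k in c(0.25, 0.5, 0.75, 1.0)) {
      g <- random_graph(n, p = 0.5, seed = n * 100 + round(k * 4))
      set.seed(n + round(k * 4))
      z <- sample(seq_len(n) / n)  # distinct scores
      X <- matrix(rnorm(n * 3), n, 3)
      out <- top_rank_pool(X, g, z, k)
      m <- ceiling(k * n)
      want_idx <- sort(order(z, decreasing = TRUE)[seq_len(m)])
      expect_identical(out$idx, want_idx)
      # gated features match the elementwise-product oracle
      oracle <- X[want_idx, , drop = FALSE] * plogis(z[want_idx])
      expect_equal(out$features, oracle)
      if (k == 1) {
        expect_identical(out$graph$edges, g$edges)  # identity on the graph
      }
    }
  }
})

test_that("top-rank pooling breaks ties toward the lower node index", {
  g <- path_graph(4)
  z <- c(0.5, 0.5, 0.5, 0.5)
  out <- top_rank_pool(matrix(1, 4, 2), g, z, 0.5)
  expect_identical(out$idx, c(1L, 2L))
})

test_that("pooling retains ceil(kN) nodes and never drops to zero", {
  g <- random_graph(9, p = 0.4, seed = 5)
  z <- rnorm(9)
  out <- top_rank_pool(matrix(0, 9, 2), g, z, 0.75)
  expect_length(out$idx, ceiling(0.75 * 9))
  tiny <- contact_graph("tiny", 2L, rbind(c(0L, 1L)))
  out2 <- top_rank_pool(matrix(0, 2, 2), tiny, c(1, 2), 0.1)
  expect_length(out2$idx, 1L)
})

test_that("pooled subgraphs are the induced subgraphs", {
  g <- random_graph(8, p = 0.5, seed = 6)
  z <- 8:1 / 8
  out <- top_rank_pool(matrix(0, 8, 2), g, z, 0.5)
  A <- adjacency_matrix(g)[out$idx, out$idx]
  expect_equal(adjacency_matrix(out$graph), A)
})

test_that("readout concatenates mean/sum with max and ignores row order", {
  x <- c(0.3, -1, 2)
  expect_equal(readout(matrix(x, 1, 3)), c(x, x))  # single node: x || x
  set.seed(7)
  M <- matrix(rnorm(15), 5, 3)
  r <- readout(M)
  oracle <- c(vapply(1:3, function(j) mean(M[, j]), 0),
              vapply(1:3, function(j) max(M[, j]), 0))
  expect_equal(r, oracle)
  rs <- readout(M, method = "sum")
  expect_equal(rs[1:3], colSums(M))
  for (i in 1:100) {
    expect_identical(readout(M[sample(5), ]), r)
  }
  expect_error(readout(matrix(0, 0, 3)), "empty")
})

test_that("hierarchical pooling shrinks node counts as ceil(k ceil(kN))", {
  ds <- make_tiny_dataset(n = 8, seed = 31)
  cfg <- model_config(hidden_dim = 8L, mlp_hidden = 16L, dropout = 0,
                      pooling_ratio = 0.5, epochs = 1L, seed = 1)
  set.seed(1)
  params <- strufun:::init_params(50L, ncol(ds$labels), cfg)
  id <- ds$ids[1]
  fwd <- strufun:::struct_forward(ds$features[[id]], ds$gdata[[id]],
                                  params, cfg)
  n0 <- nrow(ds$features[[id]])
  expect_length(fwd$layers[[1]]$idx, ceiling(0.5 * n0))
  expect_length(fwd$layers[[2]]$idx, ceiling(0.5 * ceiling(0.5 * n0)))
})

test_that("forward gives sigmoid-range scores, deterministically", {
  ds <- make_tiny_dataset(n = 10, seed = 17)
  cfg <- model_config(hidden_dim = 8L, mlp_hidden = 16L, epochs = 2L,
                      learning_rate = 1e-3, seed = 5)
  m <- train_model(ds, cfg)
  sc <- predict_scores(m, ds, ds$ids)
  expect_identical(dim(sc), c(length(ds$ids), ncol(ds$labels)))
  expect_true(all(sc > 0 & sc < 1))
  m2 <- train_model(ds, cfg)
  sc2 <- predict_scores(m2, ds, ds$ids)
  expect_identical(sc, sc2)
  expect_identical(m$history, m2$history)

  # scoring a batch equals scoring proteins one at a time
  one_at_a_time <- do.call(rbind, lapply(ds$ids, function(id) {
    predict_scores(m, ds, id)
  }))
  expect_equal(sc, one_at_a_time, tolerance = 1e-12)
})

test_that("training overfits a small dataset (loss collapses)", {
  ds <- make_tiny_dataset(n = 20, seed = 23)
  cfg <- model_config(hidden_dim = 16L, mlp_hidden = 32L, epochs = 200L,
                      learning_rate = 3e-3, dropout = 0, seed = 2)
  m <- train_model(ds, cfg)
  expect_lt(m$history$loss[200], 0.1 * m$history$loss[1])
})

test_that("backpropagation matches numerical finite differences", {
  set.seed(1)
  g <- random_graph(6, p = 0.5, seed = 12)
  X <- matrix(rnorm(6 * 5), 6, 5)
  sv <- rnorm(1024)
  y <- c(1, 0, 1)
  cfg <- model_config(hidden_dim = 4L, mlp_hidden = 8L, dropout = 0,
                      seed = 3)
  set.seed(3)
  params <- strufun:::init_params(5L, 3L, cfg)
  A <- adjacency_matrix(g)
  gd <- list(A = A, S = strufun:::norm_adjacency(A))
  lossfun <- function(p) {
    fw <- strufun:::protein_forward(X, gd, sv, p, cfg)
    -sum(y * log(fw$yhat + 1e-12) + (1 - y) * log(1 - fw$yhat + 1e-12))
  }
  fw <- strufun:::protein_forward(X, gd, sv, params, cfg)
  grads <- rapply(params, function(x) x * 0, how = "replace")
  grads <- strufun:::protein_backward(fw, fw$yhat - y, params, cfg, grads)
  flat <- strufun:::.flatten(params)
  gflat <- strufun:::.flatten(grads)
  # spot-check 60 random coordinates against central differences
  set.seed(9)
  for (i in sample(length(flat), 60)) {
    h <- 1e-5
    bump <- numeric(length(flat))
    bump[i] <- h
    num <- (lossfun(strufun:::.unflatten(flat + bump, params)) -
              lossfun(strufun:::.unflatten(flat - bump, params))) / (2 * h)
    expect_lt(abs(num - gflat[i]), 1e-4 * max(1, abs(num)))
  }
})

test_that("unsupported convolution variants are rejected up front", {
  expect_error(model_config(conv_type = "gat"), "not implemented")
  expect_error(model_config(conv_type = "nbr"), "not implemented")
})

test_that("training requires labels and embeddings", {
  ds <- make_tiny_dataset(n = 10, seed = 3)
  ds$labels <- ds$labels[, 0]
  expect_error(train_model(ds, model_config(epochs = 1L)), "label space")
  ds2 <- make_tiny_dataset(n = 10, seed = 3)
  expect_error(go_dataset(ds2$features, lapply(ds2$ids, function(i) NULL),
                          ds2$seq[-1], ds2$labels, ds2$splits))
})
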
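test_that("hierarchy post-processing propagates maxima upward", {
  dag <- go_dag(c("GO:R", "GO:M", "GO:L"),
                list(`GO:M` = "GO:R", `GO:L` = "GO:M"), "BPO", "GO:R")
  sc <- matrix(c(0.1, 0.2, 0.9), 1, 3,
               dimnames = list("P1", c("GO:R", "GO:M", "GO:L")))
  out <- hierarchical_postprocess(sc, dag)
  expect_equal(unname(out[1, ]), c(0.9, 0.9, 0.9))
  # already-consistent input is unchanged (idempotence)
  expect_equal(hierarchical_postprocess(out, dag), out)
})

test_that("post-processing equals the per-protein descendant-max oracle", {
  for (seed in c(2, 5, 8)) {
    dag <- random_dag(20, seed)
    set.seed(seed)
    sc <- matrix(runif(6 * 20), 6, 20,
                 dimnames = list(sprintf("P%d", 1:6), dag$terms))
    out <- hierarchical_postprocess(sc, dag)
    for (i in 1:6) {
      for (t in dag$terms) {
        fam <- c(t, dag_descendants(dag, t))
        expect_equal(out[i, t], max(sc[i, fam]))
      }
    }
    # parent >= child on every edge, every protein
    for (t in dag$terms) {
      for (p in dag$parents[[t]]) {
        expect_true(all(out[, p] >= out[, t]))
      }
    }
  }
})

test_that("fmax is exact on perfect and degenerate predictors", {
  truth <- matrix(c(1, 0, 0, 1, 1, 1, 0, 0), 2, 4)
  expect_equal(fmax(truth, truth)$fmax, 1)
  expect_equal(fmax(matrix(0, 2, 4), truth)$fmax, 0)
  expect_error(fmax(truth, matrix(0, 2, 4)), "true term")
})

test_that("fmax equals the brute-force threshold scan", {
  brute_fmax <- function(scores, truth) {
    best <- 0
    for (tau in seq(0.01, 1, 0.01)) {
      pred <- scores >= tau
      prec <- c()
      rec <- c()
      for (i in seq_len(nrow(scores))) {
        np <- sum(pred[i, ])
        nt <- sum(truth[i, ])
        tp <- sum(pred[i, ] & truth[i, ] > 0)
        if (np > 0) prec <- c(prec, tp / np)
        if (nt > 0) rec <- c(rec, tp / nt)
      }
      if (length(prec) == 0) next
      p <- mean(prec)
      r <- mean(rec)
      f <- if (p + r > 0) 2 * p * r / (p + r) else 0
      best <- max(best, f)
    }
    best
  }
  for (seed in 1:10) {
    set.seed(seed)
    sc <- matrix(round(runif(12), 2), 3, 4)
    truth <- matrix(rbinom(12, 1, 0.5), 3, 4)
    if (all(rowSums(truth) == 0)) truth[1, 1] <- 1
    expect_equal(fmax(sc, truth)$fmax, brute_fmax(sc, truth))
  }
})

test_that("fmax reports the smallest threshold achieving the maximum", {
  truth <- matrix(c(1, 0), 1, 2)
  sc <- matrix(c(0.9, 0.1), 1, 2)
  # any tau in (0.1, 0.9] is perfect; smallest grid point is 0.11
  res <- fmax(sc, truth)
  expect_equal(res$fmax, 1)
  expect_equal(res$threshold, 0.11)
})

test_that("auc matches the concordant-pair (Mann-Whitney) oracle", {
  # perfectly ranked pairs
  expect_equal(auc_aupr(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  for (seed in 1:5) {
    set.seed(seed)
    s <- runif(10)
    y <- rbinom(10, 1, 0.5)
    if (sum(y) %in% c(0, 10)) y[1:2] <- c(0, 1)
    pairs <- expand.grid(pos = which(y == 1), neg = which(y == 0))
    conc <- mean(ifelse(s[pairs$pos] > s[pairs$neg], 1,
                        ifelse(s[pairs$pos] == s[pairs$neg], 0.5, 0)))
    expect_equal(auc_aupr(s, y)$auc, conc)
  }
  expect_error(auc_aupr(runif(4), c(1, 1, 1, 1)), "both classes")
})

test_that("auc of label-independent scores is near 0.5", {
  set.seed(11)
  s <- runif(4000)
  y <- rbinom(4000, 1, 0.3)
  auc <- auc_aupr(s, y)$auc
  npos <- sum(y)
  nneg <- sum(1 - y)
  se <- sqrt((npos + nneg + 1) / (12 * npos * nneg))  # null MW std error
  expect_lt(abs(auc - 0.5), 3 * se)
})

test_that("aupr matches a step-curve oracle and handles ties", {
  s <- c(0.9, 0.8, 0.7, 0.6)
  y <- c(1, 0, 1, 0)
  # ranks: p@1 = 1 (rec 0.5), p@3 = 2/3 (rec 1.0)
  want <- 0.5 * 1 + 0.5 * (2 / 3)
  expect_equal(auc_aupr(s, y)$aupr, want)
})

test_that("evaluate reports perfect metrics for perfect predictions", {
  dag <- random_dag(8, 3)
  set.seed(3)
  truth <- matrix(rbinom(4 * 8, 1, 0.4), 4, 8,
                  dimnames = list(sprintf("P%d", 1:4), dag$terms))
  truth[1, 1] <- 1
  # make truth hierarchically consistent first
  truth <- hierarchical_postprocess(truth, dag)
  rep1 <- evaluate(truth, truth, dag)
  expect_equal(rep1$fmax, 1)
  expect_equal(rep1$auc, 1)
  expect_equal(rep1$aupr, 1)
  # deterministic: identical on rerun
  rep2 <- evaluate(truth, truth, dag)
  rep1$per_term <- rep2$per_term <- NULL
  expect_identical(unclass(rep1), unclass(rep2))
})

test_that("metrics are invariant to simultaneous row permutation", {
  dag <- random_dag(10, 7)
  set.seed(7)
  sc <- matrix(runif(50), 5, 10, dimnames = list(sprintf("P%d", 1:5), dag$terms))
  truth <- matrix(rbinom(50, 1, 0.4), 5, 10, dimnames = dimnames(sc))
  truth[1, 1] <- 1
  perm <- sample(5)
  r1 <- evaluate(sc, truth, dag)
  r2 <- evaluate(sc[perm, ], truth[perm, ], dag)
  expect_equal(r1$fmax, r2$fmax)
  expect_equal(r1$auc, r2$auc)
  expect_equal(r1$aupr, r2$aupr)
})

test_that("post-processing never lowers fmax for informative scores", {
  # Scores that rank true bits above false bits (as a trained predictor
  # produces): max-propagation can then only repair inconsistencies, not
  # introduce false positives above the operating thresholds.
  for (seed in 1:20) {
    dag <- random_dag(12, 100 + seed)
    set.seed(seed)
    truth <- matrix(rbinom(4 * 12, 1, 0.35), 4, 12,
                    dimnames = list(sprintf("P%d", 1:4), dag$terms))
    truth[1, 1] <- 1
    truth <- hierarchical_postprocess(truth, dag)
    noise <- matrix(runif(48, 0, 0.45), 4, 12)
    sc <- truth * (1 - noise) + (1 - truth) * noise
    dimnames(sc) <- dimnames(truth)
    raw <- fmax(sc, truth)$fmax
    post <- fmax(hierarchical_postprocess(sc, dag), truth)$fmax
    expect_gte(post + 1e-12, raw)
  }
})
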
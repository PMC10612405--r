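#' Hierarchy-consistent post-processing of predicted scores
#'
#' Replaces each term's score with the maximum over the term and all its
#' descendants present in the score matrix, per protein. The result
#' satisfies `parent >= child` for every `is_a` edge without lowering any
#' score, and the operation is idempotent.
#'
#' @param scores Protein x term score matrix with term ids as colnames.
#' @param dag A [go_dag()] resolving all score terms.
#' @return Score matrix of the same shape.
#' @export
hierarchical_postprocess <- function(scores, dag) {
  terms <- colnames(scores)
  stopifnot(!is.null(terms), all(terms %in% dag$terms))
  out <- scores
  for (t in terms) {
    fam <- intersect(c(t, dag_descendants(dag, t)), terms)
    if (length(fam) > 1L) {
      out[, t] <- do.call(pmax, as.data.frame(scores[, fam, drop = FALSE]))
    }
  }
  out
}

#' Protein-centric Fmax
#'
#' CAFA-style metric: thresholds tau = 0.01, 0.02, ..., 1.00 are swept;
#' at each tau a term is predicted when its score is at least tau.
#' Precision is averaged over proteins with at least one predicted term,
#' recall over proteins with at least one true term, and
#' `F = 2 p r / (p + r)` is maximised over tau (smallest tau on ties).
#'
#' @param scores Protein x term score matrix in [0, 1].
#' @param truth Binary matrix of the same shape.
#' @return List with `fmax` and `threshold` (the achieving tau).
#' @export
fmax <- function(scores, truth) {
  stopifnot(all(dim(scores) == dim(truth)))
  truth <- matrix(as.numeric(truth > 0), nrow(truth), ncol(truth))
  n_true <- rowSums(truth)
  if (all(n_true == 0)) stop("no protein has a true term")
  taus <- seq(0.01, 1, by = 0.01)
  best_f <- 0
  best_tau <- taus[1L]
  has_truth <- n_true > 0
  for (tau in taus) {
    pred <- scores >= tau
    n_pred <- rowSums(pred)
    covered <- n_pred > 0
    if (!any(covered)) next
    tp <- rowSums(pred * truth)
    prec <- mean((tp / n_pred)[covered])
    rec <- mean((tp[has_truth] / n_true[has_truth]))
    f <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    if (f > best_f + 1e-15) {
      best_f <- f
      best_tau <- tau
    }
  }
  list(fmax = best_f, threshold = best_tau)
}

#' Micro-averaged AUC and AUPR
#'
#' Flattens the protein x term matrices into one set of scored pairs.
#' AUC is the rank-based (Mann-Whitney) ROC area with mid-ranks for
#' ties; AUPR is the step-wise area under the precision-recall curve
#' (average precision over equal-score blocks).
#'
#' @param scores Score matrix (or vector).
#' @param truth Binary matrix (or vector) of the same shape, containing
#'   both classes.
#' @return List with `auc` and `aupr`.
#' @export
auc_aupr <- function(scores, truth) {
  s <- as.numeric(scores)
  y <- as.numeric(truth) > 0
  stopifnot(length(s) == length(y))
  npos <- sum(y)
  nneg <- sum(!y)
  if (npos == 0L || nneg == 0L) {
    stop("truth must contain both classes")
  }
  r <- rank(s)                              # mid-ranks for ties
  auc <- (sum(r[y]) - npos * (npos + 1) / 2) / (npos * nneg)
  # step-wise PR area over blocks of equal score, descending
  ord <- order(-s)
  s_sorted <- s[ord]
  y_sorted <- y[ord]
  block <- cumsum(!duplicated(s_sorted))
  tp_cum <- cumsum(y_sorted)
  n_cum <- seq_along(y_sorted)
  last <- !duplicated(block, fromLast = TRUE)  # block end positions
  tp_b <- tp_cum[last]
  n_b <- n_cum[last]
  prec <- tp_b / n_b
  rec <- tp_b / npos
  drec <- diff(c(0, rec))
  aupr <- sum(prec * drec)
  list(auc = auc, aupr = aupr)
}

#' Evaluate predictions against truth
#'
#' Applies [hierarchical_postprocess()] and computes protein-centric
#' Fmax plus micro-averaged AUC and AUPR, together with a per-term AUPR
#' table.
#'
#' @param scores Protein x term score matrix.
#' @param truth Binary matrix of the same shape.
#' @param dag A [go_dag()] (postprocessing skipped when `NULL`).
#' @return Object of class `eval_report`: list with `branch`, `fmax`,
#'   `fmax_threshold`, `auc`, `aupr`, and `per_term` (data frame).
#' @export
evaluate <- function(scores, truth, dag = NULL) {
  if (!is.null(dag)) scores <- hierarchical_postprocess(scores, dag)
  fm <- fmax(scores, truth)
  aa <- auc_aupr(scores, truth)
  per_term <- data.frame(term = colnames(scores),
                         aupr = vapply(seq_len(ncol(scores)), function(j) {
                           yj <- truth[, j]
                           if (sum(yj) == 0L || sum(yj) == length(yj)) {
                             return(NA_real_)
                           }
                           auc_aupr(scores[, j], yj)$aupr
                         }, numeric(1)),
                         stringsAsFactors = FALSE)
  structure(list(branch = if (is.null(dag)) NA_character_ else dag$branch,
                 fmax = fm$fmax, fmax_threshold = fm$threshold,
                 auc = aa$auc, aupr = aa$aupr, per_term = per_term),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s  Fmax %.3f (tau=%.2f)  AUC %.3f  AUPR %.3f\n",
              x$branch, x$fmax, x$fmax_threshold, x$auc, x$aupr))
  invisible(x)
}

#' Write an evaluation report as JSON (plus optional per-term TSV)
#'
#' @param report An [evaluate()] result.
#' @param path JSON output path.
#' @param per_term_path Optional TSV path for the per-term table.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path, per_term_path = NULL) {
  jsonlite::write_json(
    list(branch = report$branch, fmax = report$fmax,
         fmax_threshold = report$fmax_threshold,
         auc = report$auc, aupr = report$aupr),
    path, auto_unbox = TRUE, digits = NA
  )
  if (!is.null(per_term_path)) {
    utils::write.table(report$per_term, per_term_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Annotation-frequency baseline
#'
#' The naive predictor: every protein receives, for each term, the
#' fraction of training proteins annotated with that term.
#'
#' @param train_labels Binary training label matrix.
#' @param ids Protein ids to score.
#' @return Score matrix `length(ids)` x `ncol(train_labels)`.
#' @export
frequency_baseline <- function(train_labels, ids) {
  f <- colMeans(train_labels)
  matrix(f, length(ids), length(f), byrow = TRUE,
         dimnames = list(ids, colnames(train_labels)))
}
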
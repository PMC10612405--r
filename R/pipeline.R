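#' Pipeline configuration
#'
#' Paths and stage settings for the end-to-end run: contact maps from a
#' structure directory, residue embeddings, label construction from
#' OBO + annotations, training with an 8:1:1 train/validation/test split,
#' prediction and evaluation.
#'
#' @param bundle_dir Directory holding `structures/`, `sequences.fasta`,
#'   `ontology.obo`, `annotations.tsv`, `embeddings.tsv` (the layout
#'   [gen_dataset()] writes; real data may be arranged the same way).
#' @param out_dir Output directory for stage artifacts.
#' @param walk A [walk_config()].
#' @param model A [model_config()].
#' @param min_count Label-frequency threshold for [filter_labels()].
#' @param ratios Train/validation/test fractions (sum to 1).
#' @param contact_threshold Contact-map distance threshold in Angstrom.
#' @param branch Ontology branch to train on (default: the bundle's).
#' @param ablate_structure Zero the structural branch (control model).
#' @param seed Global seed; stage seeds derive from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(bundle_dir, out_dir,
                            walk = walk_config(),
                            model = model_config(),
                            min_count = 25L,
                            ratios = c(0.8, 0.1, 0.1),
                            contact_threshold = 10,
                            branch = NULL,
                            ablate_structure = FALSE,
                            seed = 1L) {
  stopifnot(abs(sum(ratios) - 1) < 1e-9, length(ratios) == 3L)
  structure(
    list(bundle_dir = bundle_dir, out_dir = out_dir, walk = walk,
         model = model, min_count = as.integer(min_count),
         ratios = ratios, contact_threshold = contact_threshold,
         branch = branch, ablate_structure = ablate_structure,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror [pipeline_config()] arguments; `walk:` and
#' `model:` sub-maps override [walk_config()] / [model_config()]
#' defaults.
#'
#' @param path YAML file.
#' @param seed Optional seed override (e.g. from a `--seed` flag).
#' @return A [pipeline_config()].
#' @export
pipeline_config_from_yaml <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  wc <- do.call(walk_config, y$walk %||% list())
  mc <- do.call(model_config, y$model %||% list())
  args <- y[setdiff(names(y), c("walk", "model"))]
  args$walk <- wc
  args$model <- mc
  if (!is.null(seed)) args$seed <- as.integer(seed)
  do.call(pipeline_config, args)
}

#' Split proteins into train/validation/test sets
#'
#' Seeded shuffle followed by a contiguous cut with largest-remainder
#' rounding (ties and leftovers go to the training set), so 10 proteins
#' at 8:1:1 give sizes (8, 1, 1). The same ids and seed always produce
#' the same partition.
#'
#' @param proteins Character vector of protein ids.
#' @param ratios Numeric fractions summing to 1 (train, valid, test).
#' @param seed Integer seed.
#' @return List with `train`, `valid`, `test` (disjoint, exhaustive).
#' @export
split_dataset <- function(proteins, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  n <- length(proteins)
  stopifnot(n >= 3L, abs(sum(ratios) - 1) < 1e-9)
  base <- floor(n * ratios)
  rem <- n * ratios - base
  left <- n - sum(base)
  if (left > 0L) {
    give <- order(-rem, seq_along(ratios))[seq_len(left)]
    base[give] <- base[give] + 1L
  }
  if (any(base == 0L)) stop("a split would be empty at n = ", n)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  shuffled <- sample(proteins)
  list(train = shuffled[seq_len(base[1L])],
       valid = shuffled[base[1L] + seq_len(base[2L])],
       test = shuffled[base[1L] + base[2L] + seq_len(base[3L])])
}

.stage_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

#' Contact-map stage
#'
#' Builds a contact graph for every structure in
#' `<bundle_dir>/structures/` and writes `<protein_id>.edges.tsv` files
#' under `<out_dir>/contact/`. Up-to-date outputs (newer than their
#' input) are skipped, so reruns resume.
#'
#' @param pcfg A [pipeline_config()].
#' @param verbose Log per-protein node/edge counts.
#' @return Invisible character vector of edge-file paths.
#' @export
run_contact <- function(pcfg, verbose = FALSE) {
  struct_dir <- file.path(pcfg$bundle_dir, "structures")
  files <- sort(list.files(struct_dir, pattern = "\\.(pdb|cif)$",
                           full.names = TRUE))
  if (length(files) == 0L) stop("no structures under ", struct_dir)
  out_dir <- file.path(pcfg$out_dir, "contact")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outs <- character(length(files))
  for (i in seq_along(files)) {
    id <- tools::file_path_sans_ext(basename(files[i]))
    out <- file.path(out_dir, paste0(id, ".edges.tsv"))
    outs[i] <- out
    if (file.exists(out) &&
        file.mtime(out) >= file.mtime(files[i])) {
      .stage_log(verbose, "contact: %s up to date", id)
      next
    }
    chain <- read_structure(files[i], protein_id = id)
    g <- build_contact_map(chain, threshold = pcfg$contact_threshold)
    write_edges(g, out)
    .stage_log(verbose, "contact: %s  %d nodes  %d edges", id,
               g$n_nodes, nrow(g$edges))
  }
  invisible(outs)
}

#' Residue-embedding stage
#'
#' For every contact graph: biased walks, skip-gram embedding, fusion
#' with the one-hot residue encoding. Writes per-protein
#' `<id>.emb.tsv` (node index + embedding) and `<id>.features.tsv`
#' (node index + 50 features) under `<out_dir>/embed/`, plus a JSON
#' sidecar recording the dimension split. Per-protein walk seeds derive
#' from the global seed and the protein id, so results do not depend on
#' processing order.
#'
#' @param pcfg A [pipeline_config()].
#' @param verbose Log progress.
#' @return Invisible character vector of feature-file paths.
#' @export
run_embed <- function(pcfg, verbose = FALSE) {
  contact_dir <- file.path(pcfg$out_dir, "contact")
  edge_files <- sort(list.files(contact_dir, pattern = "\\.edges\\.tsv$",
                                full.names = TRUE))
  if (length(edge_files) == 0L) {
    stop("no contact maps found; run the contact stage first")
  }
  seqs <- read_fasta(file.path(pcfg$bundle_dir, "sequences.fasta"))
  out_dir <- file.path(pcfg$out_dir, "embed")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outs <- character(length(edge_files))
  for (i in seq_along(edge_files)) {
    id <- sub("\\.edges\\.tsv$", "", basename(edge_files[i]))
    feat_path <- file.path(out_dir, paste0(id, ".features.tsv"))
    outs[i] <- feat_path
    if (file.exists(feat_path) &&
        file.mtime(feat_path) >= file.mtime(edge_files[i])) {
      .stage_log(verbose, "embed: %s up to date", id)
      next
    }
    g <- read_edges(edge_files[i])
    wc <- pcfg$walk
    wc$seed <- (pcfg$seed + .string_seed(id)) %% 2147483647L
    walks <- simulate_walks(g, wc)
    emb <- train_node_embeddings(walks, g$n_nodes, wc)
    aa <- strsplit(seqs[[id]], "")[[1L]]
    chain_stub <- structure(list(protein_id = id, aa = aa,
                                 ca = matrix(0, length(aa), 3L),
                                 atoms = NULL),
                            class = "residue_chain")
    feats <- featurize_residues(chain_stub, emb)
    utils::write.table(
      cbind(node = seq_len(g$n_nodes) - 1L, round(emb, 8)),
      file.path(out_dir, paste0(id, ".emb.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    utils::write.table(
      cbind(node = seq_len(g$n_nodes) - 1L, round(feats$matrix, 8)),
      feat_path, sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = FALSE)
    .stage_log(verbose, "embed: %s  %d nodes", id, g$n_nodes)
  }
  jsonlite::write_json(list(embed_dim = pcfg$walk$embed_dim,
                            onehot_dim = length(AA_ALPHABET)),
                       file.path(out_dir, "dimensions.json"),
                       auto_unbox = TRUE)
  invisible(outs)
}

# Load everything the model needs from bundle + stage outputs.
load_pipeline_dataset <- function(pcfg) {
  contact_dir <- file.path(pcfg$out_dir, "contact")
  embed_dir <- file.path(pcfg$out_dir, "embed")
  edge_files <- sort(list.files(contact_dir, pattern = "\\.edges\\.tsv$",
                                full.names = TRUE))
  if (length(edge_files) == 0L) stop("missing contact stage outputs")
  ids <- sub("\\.edges\\.tsv$", "", basename(edge_files))
  feat_files <- file.path(embed_dir, paste0(ids, ".features.tsv"))
  if (!all(file.exists(feat_files))) stop("missing embed stage outputs")

  graphs <- lapply(edge_files, read_edges)
  names(graphs) <- ids
  features <- lapply(feat_files, function(f) {
    m <- as.matrix(utils::read.table(f, sep = "\t"))
    unname(m[, -1L, drop = FALSE])
  })
  names(features) <- ids

  emb <- load_precomputed(file.path(pcfg$bundle_dir, "embeddings.tsv"))

  dags <- parse_obo(file.path(pcfg$bundle_dir, "ontology.obo"))
  branch <- pcfg$branch %||% names(dags)[1L]
  dag <- dags[[branch]]
  if (is.null(dag)) stop("branch ", branch, " not present in the ontology")

  ann <- read_annotations(file.path(pcfg$bundle_dir, "annotations.tsv"))
  ann <- filter_evidence(ann)
  ann <- propagate_true_path(ann, dag)
  space <- filter_labels(ann, dag, pcfg$min_count)
  if (length(space$terms) == 0L) {
    stop("label space is empty at min_count = ", pcfg$min_count)
  }
  labels <- label_matrix(ann, space, ids)
  splits <- split_dataset(ids, pcfg$ratios, pcfg$seed)
  ds <- go_dataset(features, graphs, emb, labels, splits)
  list(dataset = ds, dag = dag, space = space)
}

#' Training stage
#'
#' Builds the label space and dataset from the bundle and the contact /
#' embed stage outputs, trains one model for the configured branch, and
#' writes `model.rds`, `history.tsv`, the label space, and a JSON run
#' manifest under `<out_dir>/train/`.
#'
#' @param pcfg A [pipeline_config()].
#' @param verbose Log per-epoch progress.
#' @return The trained model, invisibly.
#' @export
run_train <- function(pcfg, verbose = FALSE) {
  loaded <- load_pipeline_dataset(pcfg)
  mc <- pcfg$model
  mc$seed <- pcfg$seed
  model <- train_model(loaded$dataset, mc,
                       ablate_structure = pcfg$ablate_structure,
                       verbose = verbose)
  out_dir <- file.path(pcfg$out_dir, "train")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, file.path(out_dir, "model.rds"))
  utils::write.table(model$history, file.path(out_dir, "history.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_label_space(loaded$space, file.path(out_dir, "label_space.tsv"))
  write_manifest(pcfg, file.path(out_dir, "manifest.json"))
  invisible(model)
}

#' Prediction stage
#'
#' Scores the test split with the trained model, applies the
#' hierarchy-consistency post-processing, and writes CAFA-style TSV
#' predictions under `<out_dir>/predict/`.
#'
#' @param pcfg A [pipeline_config()].
#' @return The post-processed score matrix, invisibly.
#' @export
run_predict <- function(pcfg) {
  model_path <- file.path(pcfg$out_dir, "train", "model.rds")
  if (!file.exists(model_path)) stop("missing train stage output (model.rds)")
  model <- readRDS(model_path)
  loaded <- load_pipeline_dataset(pcfg)
  scores <- predict_scores(model, loaded$dataset)
  scores <- hierarchical_postprocess(scores, loaded$dag)
  out_dir <- file.path(pcfg$out_dir, "predict")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_predictions(scores, file.path(out_dir, "predictions.tsv"))
  invisible(scores)
}

#' Evaluation stage
#'
#' Compares the test-split predictions against the true labels and
#' writes the evaluation report (JSON + per-term TSV) under
#' `<out_dir>/evaluate/`.
#'
#' @param pcfg A [pipeline_config()].
#' @return The [evaluate()] report, invisibly.
#' @export
run_evaluate <- function(pcfg) {
  pred_path <- file.path(pcfg$out_dir, "predict", "predictions.tsv")
  if (!file.exists(pred_path)) stop("missing predict stage output")
  loaded <- load_pipeline_dataset(pcfg)
  test_ids <- loaded$dataset$splits$test
  truth <- loaded$dataset$labels[test_ids, , drop = FALSE]
  scores <- read_predictions(pred_path, test_ids, loaded$space$terms)
  report <- evaluate(scores, truth, loaded$dag)
  out_dir <- file.path(pcfg$out_dir, "evaluate")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_eval_report(report, file.path(out_dir, "report.json"),
                    file.path(out_dir, "per_term.tsv"))
  invisible(report)
}

#' Read CAFA-style predictions back into a score matrix
#'
#' @param path Predictions TSV (protein, term, score).
#' @param proteins,terms Row/column order of the returned matrix.
#' @return Score matrix; absent pairs get 0.
#' @export
read_predictions <- function(path, proteins, terms) {
  df <- utils::read.table(path, sep = "\t", col.names = c("p", "t", "s"),
                          colClasses = c("character", "character",
                                         "numeric"))
  m <- matrix(0, length(proteins), length(terms),
              dimnames = list(proteins, terms))
  df <- df[df$p %in% proteins & df$t %in% terms, , drop = FALSE]
  m[cbind(match(df$p, proteins), match(df$t, terms))] <- df$s
  m
}

#' Run the full pipeline
#'
#' contact -> embed -> train -> predict -> evaluate on one bundle.
#'
#' @param pcfg A [pipeline_config()].
#' @param verbose Log stage progress.
#' @return The final [evaluate()] report.
#' @export
run_pipeline <- function(pcfg, verbose = FALSE) {
  run_contact(pcfg, verbose)
  run_embed(pcfg, verbose)
  run_train(pcfg, verbose)
  run_predict(pcfg)
  run_evaluate(pcfg)
}

# JSON run manifest: config, seed, and input-file checksums; enough to
# reproduce the run bit for bit.
write_manifest <- function(pcfg, path) {
  inputs <- c(file.path(pcfg$bundle_dir, "sequences.fasta"),
              file.path(pcfg$bundle_dir, "ontology.obo"),
              file.path(pcfg$bundle_dir, "annotations.tsv"),
              file.path(pcfg$bundle_dir, "embeddings.tsv"))
  inputs <- inputs[file.exists(inputs)]
  sums <- tools::md5sum(inputs)
  cfg <- unclass(pcfg)
  cfg$walk <- unclass(cfg$walk)
  cfg$model <- unclass(cfg$model)
  jsonlite::write_json(
    list(config = cfg, seed = pcfg$seed,
         input_md5 = as.list(sums)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
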
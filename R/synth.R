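#' Synthetic-dataset configuration
#'
#' The generator emulates the pipeline's real inputs at desk scale:
#' residue chains as self-avoiding walks with realistic consecutive
#' alpha-carbon spacing (3.8 A), a planted compact motif whose local
#' contact density exceeds the chain background, a small rooted GO-like
#' DAG, and annotations in which the motif determines a subtree of
#' labels. The motif also carries a characteristic residue composition
#' (as real structural motifs do); both signals live in the structural
#' branch of the model.
#'
#' @param n_proteins Number of proteins.
#' @param chain_length_range Integer (min, max) residues per chain
#'   (max below 1500, the advisory residue-count bound).
#' @param motif_length Residues in the planted motif segment.
#' @param motif_prevalence Fraction of proteins carrying the motif.
#' @param n_terms Terms in the toy ontology branch.
#' @param dag_depth Longest root-to-leaf path (edges).
#' @param label_noise Probability of flipping each leaf-level label bit.
#' @param common_rate_range,rare_rate_range,p_common Background (non-motif)
#'   terms mimic the frequency profile of true-path-completed GO labels:
#'   a fraction `p_common` are "shallow" terms annotated at a high rate
#'   drawn from `common_rate_range`, the rest are "specific" terms at a
#'   low rate from `rare_rate_range` (many of which then fall below the
#'   frequency filter, as in real data).
#' @param seq_signal_strength Magnitude of the optional planted signal in
#'   mock sequence embeddings (0 = sequence channel is pure noise).
#' @param seed Master seed; the full bundle is a deterministic function
#'   of this configuration.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_proteins = 300L,
                         chain_length_range = c(40L, 90L),
                         motif_length = 12L, motif_prevalence = 0.5,
                         n_terms = 30L, dag_depth = 5L,
                         label_noise = 0,
                         common_rate_range = c(0.55, 0.9),
                         rare_rate_range = c(0.03, 0.15),
                         p_common = 0.4,
                         seq_signal_strength = 0, seed = 1L) {
  stopifnot(n_proteins >= 2L, chain_length_range[1L] >= 10L,
            chain_length_range[2L] < 1500L,
            chain_length_range[1L] <= chain_length_range[2L],
            motif_length >= 4L, motif_length <= chain_length_range[1L],
            motif_prevalence > 0, motif_prevalence < 1,
            n_terms >= dag_depth + 1L, dag_depth >= 1L,
            label_noise >= 0, label_noise < 1)
  structure(
    list(n_proteins = as.integer(n_proteins),
         chain_length_range = as.integer(chain_length_range),
         motif_length = as.integer(motif_length),
         motif_prevalence = motif_prevalence,
         n_terms = as.integer(n_terms), dag_depth = as.integer(dag_depth),
         label_noise = label_noise,
         common_rate_range = common_rate_range,
         rare_rate_range = rare_rate_range,
         p_common = p_common,
         seq_signal_strength = seq_signal_strength,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

# Residue type of the planted motif segment: a single-residue
# low-complexity segment (cysteine-rich, in the spirit of real His-tag /
# polyQ-like segments), so the motif's compositional signature is
# unambiguous.
MOTIF_AA <- "C"

.unit_sphere <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

#' Generate a synthetic residue chain
#'
#' A self-avoiding 3D random walk with consecutive alpha-carbon spacing
#' drawn from 3.8 +/- 0.1 A and a hard-core exclusion between
#' non-consecutive residues. When `has_motif` is `TRUE`, a contiguous
#' segment is made compact by biasing its steps toward the segment
#' centroid at the same fixed step length (so spacing is preserved while
#' internal contact density at 10 A rises above the chain background),
#' and its residues are drawn from a characteristic motif alphabet.
#'
#' @param length Number of residues.
#' @param has_motif Plant the compact motif segment?
#' @param seed Integer seed; coordinates are deterministic given it.
#' @param motif_length Motif segment length (required if `has_motif`).
#' @param protein_id Id for the returned chain.
#' @return A [residue_chain()] with attributes `motif_range` (integer
#'   range, or `NULL`) and `has_motif`.
#' @export
gen_chain <- function(length, has_motif = FALSE, seed = 1L,
                      motif_length = 12L, protein_id = "synthetic") {
  stopifnot(length >= 2L, !has_motif || length >= motif_length)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  min_sep <- 3.6   # hard-core distance between non-consecutive residues
  motif_range <- NULL
  if (has_motif) {
    start <- sample.int(length - motif_length + 1L, 1L)
    motif_range <- start:(start + motif_length - 1L)
  }
  for (attempt in seq_len(50L)) {
    coords <- matrix(NA_real_, length, 3L)
    coords[1L, ] <- c(0, 0, 0)
    ok <- TRUE
    for (i in 2L:length) {
      placed <- FALSE
      in_motif <- !is.null(motif_range) && i %in% motif_range &&
        i > motif_range[1L]
      centroid <- if (in_motif) {
        colMeans(coords[motif_range[1L]:(i - 1L), , drop = FALSE])
      } else NULL
      for (try in seq_len(100L)) {
        dir <- .unit_sphere()
        if (in_motif) {
          pull <- centroid - coords[i - 1L, ]
          np <- sqrt(sum(pull^2))
          if (np > 1e-9) {
            # curvature bias: steer toward the motif centroid
            dir <- 0.9 * (pull / np) + dir
            dir <- dir / sqrt(sum(dir^2))
          }
        }
        step <- stats::runif(1, 3.72, 3.88)
        cand <- coords[i - 1L, ] + step * dir
        if (i > 2L) {
          d2 <- rowSums((coords[1:(i - 2L), , drop = FALSE] -
                           matrix(cand, i - 2L, 3L, byrow = TRUE))^2)
          if (min(d2) < min_sep^2) next
        }
        coords[i, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed) {
        ok <- FALSE
        break
      }
    }
    if (ok) break
    if (attempt == 50L) stop("self-avoiding chain generation failed")
  }
  aa <- sample(AA_ALPHABET, length, replace = TRUE)
  if (!is.null(motif_range)) {
    aa[motif_range] <- sample(MOTIF_AA, length(motif_range), replace = TRUE)
  }
  chain <- residue_chain(protein_id, aa, coords)
  attr(chain, "motif_range") <- motif_range
  attr(chain, "has_motif") <- has_motif
  chain
}

#' Generate a toy GO-like ontology branch
#'
#' A rooted DAG: a spine of `depth` edges fixes the longest
#' root-to-leaf path, remaining terms attach to random earlier terms
#' (with an occasional second parent, keeping the graph acyclic). Term
#' ids look like GO ids but use a synthetic namespace prefix.
#'
#' @param n_terms Total terms (>= depth + 1).
#' @param depth Longest path length in edges.
#' @param seed Integer seed.
#' @param branch Branch tag for the resulting DAG.
#' @return A [go_dag()] with attribute `spine` (the term ids on the
#'   deepest chain, root first).
#' @export
gen_ontology <- function(n_terms, depth = 3L, seed = 1L, branch = "BPO") {
  stopifnot(n_terms >= depth + 1L)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  ids <- sprintf("GO:S%06d", seq_len(n_terms))
  parents <- stats::setNames(vector("list", n_terms), ids)
  term_depth <- stats::setNames(integer(n_terms), ids)
  # spine fixes the longest path
  spine <- ids[1:(depth + 1L)]
  for (k in 2:(depth + 1L)) {
    parents[[ids[k]]] <- ids[k - 1L]
    term_depth[[ids[k]]] <- k - 1L
  }
  if (n_terms > depth + 1L) {
    for (k in (depth + 2L):n_terms) {
      # attach below a random earlier term of depth < depth limit
      cand <- ids[seq_len(k - 1L)]
      cand <- cand[term_depth[cand] < depth]
      p1 <- sample(cand, 1L)
      ps <- p1
      if (stats::runif(1) < 0.25) {
        cand2 <- setdiff(cand, p1)
        if (length(cand2) > 0L) ps <- c(ps, sample(cand2, 1L))
      }
      parents[[ids[k]]] <- ps
      term_depth[[ids[k]]] <- max(term_depth[ps]) + 1L
    }
  }
  dag <- go_dag(ids, parents, branch = branch, root = ids[1L])
  attr(dag, "spine") <- spine
  dag
}

#' Generate annotations with a planted structure-to-function signal
#'
#' The deepest spine term is the "motif leaf": motif-bearing proteins
#' (and, at `noise = 0`, only they) are annotated with it. Every other
#' non-root term gets a background annotation rate drawn once — from
#' `common_rate_range` with probability `p_common` (shallow, frequently
#' annotated terms) or from `rare_rate_range` otherwise (specific, rare
#' terms) — and applied independently per protein. Each leaf-level bit
#' is then flipped with probability `noise`, and the table is true-path
#' propagated.
#'
#' @param motif_flags Named logical vector (protein id -> carries motif).
#' @param dag A [gen_ontology()] DAG (its `spine` attribute defines the
#'   motif subtree).
#' @param noise Per-bit flip probability in [0, 1).
#' @param seed Integer seed.
#' @param common_rate_range,rare_rate_range,p_common Background-rate
#'   model (see [synth_config()]).
#' @return A propagated [annotation_table()] with attribute
#'   `motif_terms` (the motif leaf and its ancestors).
#' @export
gen_annotations <- function(motif_flags, dag, noise = 0, seed = 1L,
                            common_rate_range = c(0.55, 0.9),
                            rare_rate_range = c(0.03, 0.15),
                            p_common = 0.5) {
  stopifnot(length(dag$terms) > 0L, !is.null(names(motif_flags)))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  proteins <- names(motif_flags)
  spine <- attr(dag, "spine")
  motif_leaf <- spine[length(spine)]
  background <- setdiff(dag$terms, c(dag$root, spine))
  common <- stats::runif(length(background)) < p_common
  rates <- stats::setNames(
    ifelse(common,
           stats::runif(length(background), common_rate_range[1L],
                        common_rate_range[2L]),
           stats::runif(length(background), rare_rate_range[1L],
                        rare_rate_range[2L])),
    background
  )
  terms <- c(motif_leaf, background)
  M <- matrix(0L, length(proteins), length(terms),
              dimnames = list(proteins, terms))
  M[, motif_leaf] <- as.integer(motif_flags)
  for (t in background) {
    M[, t] <- as.integer(stats::runif(length(proteins)) < rates[[t]])
  }
  if (noise > 0) {
    flips <- matrix(stats::runif(base::length(M)) < noise, nrow(M), ncol(M))
    M <- (M + flips) %% 2L
  }
  hits <- which(M == 1L, arr.ind = TRUE)
  tab <- annotation_table(proteins[hits[, 1L]], terms[hits[, 2L]],
                          rep("IDA", nrow(hits)))
  out <- propagate_true_path(tab, dag)
  attr(out, "motif_terms") <- c(motif_leaf, dag_ancestors(dag, motif_leaf))
  out
}

#' Generate a complete on-disk synthetic bundle
#'
#' Writes, under `dir`: `structures/<id>.pdb` (alpha-carbon traces),
#' `sequences.fasta`, `ontology.obo`, `annotations.tsv`,
#' `embeddings.tsv` (mock sequence embeddings), and `meta.json`
#' (configuration and motif flags). Regenerating from the same
#' configuration yields byte-identical files.
#'
#' @param cfg A [synth_config()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly; side effect: the bundle on disk.
#' @export
gen_dataset <- function(cfg, dir) {
  dir.create(file.path(dir, "structures"), recursive = TRUE,
             showWarnings = FALSE)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(cfg$seed)
  n <- cfg$n_proteins
  ids <- sprintf("SYN%04d", seq_len(n))
  lengths <- sample(cfg$chain_length_range[1L]:cfg$chain_length_range[2L],
                    n, replace = TRUE)
  n_motif <- max(1L, round(cfg$motif_prevalence * n))
  motif_flags <- stats::setNames(rep(FALSE, n), ids)
  motif_flags[sample.int(n, n_motif)] <- TRUE
  chain_seeds <- sample.int(2147483646L, n)
  dag_seed <- sample.int(2147483646L, 1L)
  ann_seed <- sample.int(2147483646L, 1L)
  dir_seed <- sample.int(2147483646L, 1L)

  sequences <- character(n)
  for (i in seq_len(n)) {
    chain <- gen_chain(lengths[i], motif_flags[[i]], chain_seeds[i],
                       cfg$motif_length, protein_id = ids[i])
    write_chain_pdb(chain, file.path(dir, "structures",
                                     paste0(ids[i], ".pdb")))
    sequences[i] <- paste(chain$aa, collapse = "")
  }
  names(sequences) <- ids
  write_fasta(sequences, file.path(dir, "sequences.fasta"))

  dag <- gen_ontology(cfg$n_terms, cfg$dag_depth, dag_seed)
  write_obo(stats::setNames(list(dag), dag$branch),
            file.path(dir, "ontology.obo"))

  ann <- gen_annotations(motif_flags, dag, cfg$label_noise, ann_seed,
                         cfg$common_rate_range, cfg$rare_rate_range,
                         cfg$p_common)
  write_annotations(ann, file.path(dir, "annotations.tsv"))

  set.seed(dir_seed)
  direction <- stats::rnorm(1024L)
  direction <- direction / sqrt(sum(direction^2))
  emb <- lapply(ids, function(id) {
    e <- mock_embedding(sequences[[id]], seed = cfg$seed,
                        motif_flag = motif_flags[[id]],
                        direction = direction,
                        strength = cfg$seq_signal_strength)
    e$protein_id <- id
    e
  })
  names(emb) <- ids
  write_embeddings(emb, file.path(dir, "embeddings.tsv"))

  jsonlite::write_json(
    list(config = unclass(cfg),
         proteins = ids,
         motif_flags = as.list(motif_flags),
         motif_terms = attr(ann, "motif_terms"),
         branch = dag$branch),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE
  )
  invisible(dir)
}

#' Write a residue chain as a PDB file (alpha-carbon trace)
#'
#' @param chain A [residue_chain()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chain_pdb <- function(chain, path) {
  resid3 <- ifelse(chain$aa == "X", "UNK",
                   unname(AA_ONE_TO_THREE[chain$aa]))
  n <- length(chain$aa)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(chain$ca)),
                   resno = seq_len(n),
                   resid = resid3,
                   elety = rep("CA", n),
                   chain = rep("A", n),
                   o = rep(1, n), b = rep(0, n))
  invisible(path)
}
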
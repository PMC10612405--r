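EMBED_DIM <- 1024L

#' Per-protein sequence embedding
#'
#' The classifier consumes one 1024-dimensional vector per protein,
#' summarising its sequence (the output contract of ELMo-style protein
#' language models). Providers are pluggable: a precomputed-matrix reader,
#' a deterministic mock for tests and synthetic data, or an external tool
#' writing the same tabular format. Swapping providers changes values,
#' never shapes.
#'
#' @param protein_id Character scalar.
#' @param vector Numeric vector of length 1024, all finite.
#' @param provider One of `"precomputed"`, `"mock"`, `"external"`.
#' @return An object of class `protein_embedding`.
#' @export
protein_embedding <- function(protein_id, vector,
                              provider = c("precomputed", "mock", "external")) {
  provider <- match.arg(provider)
  vector <- as.numeric(vector)
  if (length(vector) != EMBED_DIM) {
    stop(sprintf("embedding for '%s' has length %d, expected %d",
                 protein_id, length(vector), EMBED_DIM))
  }
  if (!all(is.finite(vector))) {
    stop(sprintf("embedding for '%s' contains non-finite values", protein_id))
  }
  structure(list(protein_id = protein_id, vector = vector,
                 provider = provider),
            class = "protein_embedding")
}

#' Read precomputed sequence embeddings
#'
#' Reads a whitespace-separated table with a protein id in the first
#' column followed by 1024 floats. Every row is length-checked; a wrong
#' width is a hard error naming the offending protein.
#'
#' @param path Path to the table.
#' @return Named list of [protein_embedding()] objects keyed by protein id.
#' @export
load_precomputed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1L]]
    id <- parts[1L]
    vec <- suppressWarnings(as.numeric(parts[-1L]))
    if (length(vec) != EMBED_DIM || anyNA(vec)) {
      stop(sprintf("embedding row for '%s' has width %d, expected %d",
                   id, length(vec), EMBED_DIM))
    }
    out[[id]] <- protein_embedding(id, vec, provider = "precomputed")
  }
  out
}

#' Write sequence embeddings in the precomputed tabular format
#'
#' @param embeddings Named list of [protein_embedding()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(embeddings, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (e in embeddings) {
    writeLines(paste(e$protein_id,
                     paste(formatC(e$vector, format = "g", digits = 17),
                           collapse = " ")), con)
  }
  invisible(path)
}

#' Deterministic mock sequence embedding
#'
#' Produces a pseudo-random 1024-vector seeded by a hash of the sequence
#' and the seed, so the same call always returns the same vector and
#' different sequences get different vectors. An optional planted signal
#' adds `strength * direction` for motif-bearing proteins, giving
#' synthetic data a learnable sequence channel.
#'
#' @param sequence Non-empty amino-acid string.
#' @param seed Integer seed.
#' @param motif_flag Whether this protein carries the planted motif.
#' @param direction Unit-norm 1024-vector defining the signal direction
#'   (required when `strength > 0`).
#' @param strength Signal magnitude added along `direction` for motif
#'   proteins (default 0: pure noise).
#' @return A [protein_embedding()] with provider `"mock"`.
#' @export
mock_embedding <- function(sequence, seed = 1L, motif_flag = FALSE,
                           direction = NULL, strength = 0) {
  stopifnot(nzchar(sequence))
  h <- .string_seed(paste0(sequence, "#", seed))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(h)
  vec <- stats::rnorm(EMBED_DIM)
  if (isTRUE(motif_flag) && strength > 0) {
    stopifnot(length(direction) == EMBED_DIM)
    vec <- vec + strength * direction
  }
  protein_embedding(paste0("seq", h), vec, provider = "mock")
}

#' Pool per-residue embeddings to one protein vector
#'
#' Column-wise average of an N x 1024 residue-level matrix (the
#' parameter-free reduction of residue-level language-model output to a
#' single protein vector).
#'
#' @param residue_matrix Numeric matrix, one row per residue, 1024 columns.
#' @param method Only `"mean"` is implemented.
#' @return Numeric vector of length 1024.
#' @export
residue_to_protein_pool <- function(residue_matrix, method = "mean") {
  method <- match.arg(method, "mean")
  residue_matrix <- as.matrix(residue_matrix)
  stopifnot(nrow(residue_matrix) >= 1L)
  colMeans(residue_matrix)
}

# Stable 31-bit polynomial string hash, used to derive seeds from ids.
.string_seed <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 17
  for (b in bytes) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA path.
#' @return Named character vector of sequences keyed by record id.
#' @export
read_fasta <- function(path) {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  stats::setNames(toupper(vapply(recs, `[[`, character(1), 1L)), names(recs))
}

#' Write protein sequences to a FASTA file
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  seqinr::write.fasta(as.list(unname(sequences)), names(sequences),
                      file.out = path, nbchar = 60)
  invisible(path)
}
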
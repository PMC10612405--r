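#' @useDynLib strufun, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Canonical one-letter amino-acid alphabet; column order of the one-hot block.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA_THREE_TO_ONE <- c(
  ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F", GLY = "G",
  HIS = "H", ILE = "I", LYS = "K", LEU = "L", MET = "M", ASN = "N",
  PRO = "P", GLN = "Q", ARG = "R", SER = "S", THR = "T", VAL = "V",
  TRP = "W", TYR = "Y"
)

AA_ONE_TO_THREE <- stats::setNames(names(AA_THREE_TO_ONE), AA_THREE_TO_ONE)

#' Construct a residue chain
#'
#' A residue chain is the per-protein record the rest of the pipeline works
#' from: an ordered run of residues, each with a one-letter amino-acid code
#' and an alpha-carbon coordinate in Angstrom. Unknown or non-canonical
#' residues are coded `"X"`.
#'
#' @param protein_id Character scalar identifying the protein.
#' @param aa Character vector of one-letter residue codes (canonical 20 or
#'   `"X"`).
#' @param ca Numeric matrix with one row per residue and columns x, y, z
#'   (Angstrom).
#' @param atoms Optional list, one entry per residue, each a numeric matrix
#'   of all-atom coordinates (used by the `any_any` contact-map mode).
#' @return An object of class `residue_chain`.
#' @export
residue_chain <- function(protein_id, aa, ca, atoms = NULL) {
  stopifnot(is.character(protein_id), length(protein_id) == 1L)
  aa <- toupper(as.character(aa))
  ca <- as.matrix(ca)
  storage.mode(ca) <- "double"
  if (nrow(ca) != length(aa)) {
    stop("`aa` and `ca` describe different numbers of residues")
  }
  if (length(aa) < 2L) stop("a residue chain needs at least 2 residues")
  if (!all(is.finite(ca))) stop("non-finite alpha-carbon coordinate")
  bad <- !(aa %in% c(AA_ALPHABET, "X"))
  if (any(bad)) {
    stop("unrecognised residue code(s): ", paste(unique(aa[bad]), collapse = ", "))
  }
  if (!is.null(atoms)) {
    stopifnot(is.list(atoms), length(atoms) == length(aa))
    atoms <- lapply(atoms, function(m) {
      m <- as.matrix(m)
      storage.mode(m) <- "double"
      m
    })
  }
  structure(
    list(protein_id = protein_id, aa = aa, ca = ca, atoms = atoms),
    class = "residue_chain"
  )
}

#' @export
length.residue_chain <- function(x) length(x$aa)

#' @export
print.residue_chain <- function(x, ...) {
  cat(sprintf("<residue_chain> %s: %d residues\n", x$protein_id, length(x$aa)))
  invisible(x)
}

#' Read a protein structure file into a residue chain
#'
#' Reads ATOM records from a PDB or mmCIF file (format chosen by extension
#' unless given) and extracts one alpha-carbon per residue, in residue-number
#' order. Only the first model is used; where alternate locations exist the
#' `'A'` altloc is preferred. Residues without an alpha-carbon are skipped
#' with a warning.
#'
#' @param path Path to a `.pdb` or `.cif` file.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (by extension).
#' @param chain Optional chain identifier; defaults to the first chain found.
#' @param protein_id Identifier for the returned chain; defaults to the file
#'   base name.
#' @param keep_atoms If `TRUE`, retain all-atom coordinates per residue
#'   (needed for `build_contact_map(mode = "any_any")`).
#' @return A [residue_chain()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           chain = NULL, protein_id = NULL,
                           keep_atoms = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  pdb <- if (format == "pdb") {
    bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  } else {
    bio3d::read.cif(path, multi = FALSE, verbose = FALSE)
  }
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (!is.null(chain)) at <- at[at$chain %in% chain, , drop = FALSE]
  else if (length(unique(at$chain)) > 1L) {
    at <- at[at$chain == at$chain[1L], , drop = FALSE]
  }
  # altloc: keep blank or 'A'
  if (!is.null(at$alt)) {
    keep <- is.na(at$alt) | at$alt %in% c("", "A")
    at <- at[keep, , drop = FALSE]
  }
  if (nrow(at) == 0L) stop("no ATOM records found in ", path)

  resno <- at$resno
  ord <- order(resno)
  at <- at[ord, , drop = FALSE]
  ids <- unique(at$resno)

  aa <- character(0)
  ca <- NULL
  atoms <- list()
  skipped <- 0L
  for (r in ids) {
    rows <- at[at$resno == r, , drop = FALSE]
    ca_row <- rows[rows$elety == "CA", , drop = FALSE]
    if (nrow(ca_row) == 0L) {
      skipped <- skipped + 1L
      next
    }
    code <- AA_THREE_TO_ONE[rows$resid[1L]]
    if (is.na(code)) code <- "X"
    aa <- c(aa, unname(code))
    ca <- rbind(ca, as.numeric(ca_row[1L, c("x", "y", "z")]))
    if (keep_atoms) {
      atoms[[length(atoms) + 1L]] <-
        unname(as.matrix(rows[, c("x", "y", "z")]))
    }
  }
  if (skipped > 0L) {
    warning(sprintf("%s: skipped %d residue(s) lacking an alpha-carbon",
                    path, skipped))
  }
  if (length(aa) == 0L) stop("no residues with alpha-carbons in ", path)
  residue_chain(
    protein_id = protein_id %||% tools::file_path_sans_ext(basename(path)),
    aa = aa, ca = ca, atoms = if (keep_atoms) atoms else NULL
  )
}

#' Construct a contact graph
#'
#' @param protein_id Character scalar.
#' @param n_nodes Number of residues/nodes.
#' @param edges Two-column integer matrix of 0-based node index pairs
#'   (undirected; stored with i < j, no self-edges).
#' @return An object of class `contact_graph`.
#' @export
contact_graph <- function(protein_id, n_nodes, edges) {
  n_nodes <- as.integer(n_nodes)
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges) > 0L) {
    if (any(edges < 0L) || any(edges >= n_nodes)) {
      stop("edge index out of range")
    }
    if (any(edges[, 1L] == edges[, 2L])) stop("self-edges are not stored")
    swap <- edges[, 1L] > edges[, 2L]
    edges[swap, ] <- edges[swap, 2:1]
    edges <- unique(edges)
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  structure(
    list(protein_id = protein_id, n_nodes = n_nodes, edges = edges),
    class = "contact_graph"
  )
}

#' @export
print.contact_graph <- function(x, ...) {
  cat(sprintf("<contact_graph> %s: %d nodes, %d edges\n",
              x$protein_id, x$n_nodes, nrow(x$edges)))
  invisible(x)
}

#' Build a residue contact graph from a chain
#'
#' Two residues are in contact when their distance is strictly less than
#' `threshold` Angstrom: the alpha-carbon distance in `ca_ca` mode, or the
#' minimum over all atom pairs in `any_any` mode. Pairs at exactly the
#' threshold are not contacts.
#'
#' @param chain A [residue_chain()].
#' @param threshold Contact threshold in Angstrom (default 10).
#' @param mode `"ca_ca"` (default) or `"any_any"`.
#' @param exclude_within Drop contacts between residues at sequence
#'   separation `|i - j| <= exclude_within` (default 0: keep all, including
#'   consecutive neighbours).
#' @return A [contact_graph()] over nodes `0..N-1` in chain order.
#' @export
build_contact_map <- function(chain, threshold = 10, mode = c("ca_ca", "any_any"),
                              exclude_within = 0L) {
  mode <- match.arg(mode)
  stopifnot(inherits(chain, "residue_chain"), threshold > 0)
  n <- length(chain$aa)
  if (mode == "ca_ca") {
    d <- as.matrix(stats::dist(chain$ca))
  } else {
    if (is.null(chain$atoms)) {
      stop("chain has no all-atom coordinates; use mode = \"ca_ca\"")
    }
    d <- matrix(Inf, n, n)
    for (i in seq_len(n - 1L)) {
      ai <- chain$atoms[[i]]
      for (j in (i + 1L):n) {
        aj <- chain$atoms[[j]]
        # min pairwise atom distance between residues i and j
        dd <- sqrt(outer(rowSums(ai^2), rowSums(aj^2), "+") - 2 * tcrossprod(ai, aj))
        d[i, j] <- d[j, i] <- min(dd)
      }
    }
  }
  contact <- d < threshold
  contact[lower.tri(contact, diag = TRUE)] <- FALSE
  idx <- which(contact, arr.ind = TRUE)
  if (exclude_within > 0L && nrow(idx) > 0L) {
    idx <- idx[abs(idx[, 1L] - idx[, 2L]) > exclude_within, , drop = FALSE]
  }
  contact_graph(chain$protein_id, n, idx - 1L)
}

#' Fraction of residue pairs in contact
#'
#' @param graph A [contact_graph()] with at least 2 nodes.
#' @return `|edges| / (N (N - 1) / 2)`, in `[0, 1]`.
#' @export
contact_density <- function(graph) {
  stopifnot(inherits(graph, "contact_graph"), graph$n_nodes >= 2L)
  nrow(graph$edges) / (graph$n_nodes * (graph$n_nodes - 1L) / 2)
}

#' Neighbour lists of a contact graph
#'
#' @param graph A [contact_graph()].
#' @return List of length `n_nodes`; element `i` holds the 0-based
#'   neighbours of node `i - 1`, sorted.
#' @export
graph_neighbors <- function(graph) {
  nb <- vector("list", graph$n_nodes)
  for (i in seq_len(graph$n_nodes)) nb[[i]] <- integer(0)
  e <- graph$edges
  for (r in seq_len(nrow(e))) {
    i <- e[r, 1L] + 1L
    j <- e[r, 2L] + 1L
    nb[[i]] <- c(nb[[i]], e[r, 2L])
    nb[[j]] <- c(nb[[j]], e[r, 1L])
  }
  lapply(nb, sort)
}

#' Dense adjacency matrix of a contact graph
#'
#' @param graph A [contact_graph()].
#' @param self_loops Add the identity (used by the convolution layer).
#' @return An `n_nodes` x `n_nodes` 0/1 matrix.
#' @export
adjacency_matrix <- function(graph, self_loops = FALSE) {
  n <- graph$n_nodes
  A <- matrix(0, n, n)
  e <- graph$edges
  if (nrow(e) > 0L) {
    A[cbind(e[, 1L] + 1L, e[, 2L] + 1L)] <- 1
    A[cbind(e[, 2L] + 1L, e[, 1L] + 1L)] <- 1
  }
  if (self_loops) A <- A + diag(n)
  A
}

#' Write / read a contact graph as an edge-list TSV
#'
#' Files hold two 0-based integer columns `node_i`, `node_j` with a header
#' line `# n_nodes=<N>` so edgeless graphs round-trip.
#'
#' @param graph A [contact_graph()].
#' @param path Output path (conventionally `<protein_id>.edges.tsv`).
#' @return `write_edges` returns `path` invisibly; `read_edges` returns a
#'   [contact_graph()].
#' @export
write_edges <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# protein_id=%s n_nodes=%d", graph$protein_id,
                     graph$n_nodes), con)
  writeLines("node_i\tnode_j", con)
  if (nrow(graph$edges) > 0L) {
    writeLines(sprintf("%d\t%d", graph$edges[, 1L], graph$edges[, 2L]), con)
  }
  invisible(path)
}

#' @rdname write_edges
#' @export
read_edges <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1L]
  pid <- sub("^# protein_id=(\\S+) n_nodes=\\d+$", "\\1", hdr)
  n <- as.integer(sub("^.* n_nodes=(\\d+)$", "\\1", hdr))
  body <- lines[-(1:2)]
  edges <- if (length(body) == 0L) {
    matrix(integer(0), ncol = 2L)
  } else {
    do.call(rbind, lapply(strsplit(body, "\t", fixed = TRUE), as.integer))
  }
  contact_graph(pid, n, edges)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
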
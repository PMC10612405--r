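# GAF evidence codes trusted as experimental for label extraction.
# "TA" is accepted as an alias of TAS.
DEFAULT_EVIDENCE <- c("IDA", "IPI", "EXP", "IGI", "IMP", "IEP", "IC", "TAS")

GO_NAMESPACES <- c(biological_process = "BPO",
                   cellular_component = "CCO",
                   molecular_function = "MFO")

#' Construct a GO-branch DAG
#'
#' One branch of the ontology as a rooted DAG over `is_a` edges. The
#' structure is validated: acyclic, and every term can reach the root.
#'
#' @param terms Character vector of term ids.
#' @param parents Named list mapping each term to its `is_a` parents
#'   (character vectors; the root has none).
#' @param branch Branch tag, e.g. `"BPO"`, `"CCO"`, `"MFO"`.
#' @param root Root term id.
#' @return An object of class `go_dag`.
#' @export
go_dag <- function(terms, parents, branch, root) {
  terms <- sort(unique(as.character(terms)))
  stopifnot(root %in% terms)
  parents <- parents[terms[terms %in% names(parents)]]
  parents <- lapply(parents, function(p) sort(unique(as.character(p))))
  # drop parent links pointing outside the branch
  parents <- lapply(parents, function(p) p[p %in% terms])
  cyc <- .find_cycle(terms, parents)
  if (!is.null(cyc)) {
    stop("ontology contains a cycle: ", paste(cyc, collapse = " -> "))
  }
  dag <- structure(list(terms = terms, parents = parents,
                        branch = branch, root = root),
                   class = "go_dag")
  unreachable <- terms[vapply(terms, function(t) {
    !(root %in% c(t, dag_ancestors(dag, t)))
  }, logical(1))]
  if (length(unreachable) > 0L) {
    stop("term(s) with no path to root: ", paste(unreachable, collapse = ", "))
  }
  dag
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("<go_dag> %s: %d terms, root %s\n",
              x$branch, length(x$terms), x$root))
  invisible(x)
}

# Kahn topological check; returns a cycle (as a vector of term ids) or NULL.
.find_cycle <- function(terms, parents) {
  indeg <- stats::setNames(integer(length(terms)), terms)
  children <- stats::setNames(vector("list", length(terms)), terms)
  for (t in names(parents)) {
    for (p in parents[[t]]) {
      if (!p %in% terms) next
      indeg[[t]] <- indeg[[t]] + 1L
      children[[p]] <- c(children[[p]], t)
    }
  }
  queue <- terms[indeg == 0L]
  seen <- 0L
  while (length(queue) > 0L) {
    u <- queue[[1L]]
    queue <- queue[-1L]
    seen <- seen + 1L
    for (v in children[[u]]) {
      indeg[[v]] <- indeg[[v]] - 1L
      if (indeg[[v]] == 0L) queue <- c(queue, v)
    }
  }
  if (seen == length(terms)) return(NULL)
  sort(terms[indeg > 0L])
}

#' Ancestors / descendants of a term over is_a edges
#'
#' @param dag A [go_dag()].
#' @param term Term id.
#' @return Character vector of strict ancestors (or descendants); empty
#'   for the root (or a leaf).
#' @export
dag_ancestors <- function(dag, term) {
  out <- character(0)
  frontier <- dag$parents[[term]] %||% character(0)
  while (length(frontier) > 0L) {
    out <- union(out, frontier)
    frontier <- unique(unlist(lapply(frontier, function(t) dag$parents[[t]]),
                              use.names = FALSE))
    frontier <- setdiff(frontier, out)
  }
  sort(out)
}

#' @rdname dag_ancestors
#' @export
dag_descendants <- function(dag, term) {
  kids <- .children_map(dag)
  out <- character(0)
  frontier <- kids[[term]] %||% character(0)
  while (length(frontier) > 0L) {
    out <- union(out, frontier)
    frontier <- unique(unlist(lapply(frontier, function(t) kids[[t]]),
                              use.names = FALSE))
    frontier <- setdiff(frontier, out)
  }
  sort(out)
}

.children_map <- function(dag) {
  kids <- stats::setNames(vector("list", length(dag$terms)), dag$terms)
  for (t in names(dag$parents)) {
    for (p in dag$parents[[t]]) kids[[p]] <- c(kids[[p]], t)
  }
  kids
}

#' Parse an OBO 1.2 ontology file into per-branch DAGs
#'
#' Reads `[Term]` stanzas, keeping `is_a` edges only; obsolete terms are
#' excluded. Terms are grouped by namespace into the three GO branches.
#' A cycle is a hard error naming the terms involved.
#'
#' @param path Path to an OBO 1.2 file.
#' @return Named list of [go_dag()] objects keyed by branch
#'   (`"BPO"`, `"CCO"`, `"MFO"`), only branches present in the file.
#' @export
parse_obo <- function(path) {
  lines <- readLines(path)
  term_starts <- grep("^\\[Term\\]\\s*$", lines)
  if (length(term_starts) == 0L) stop("no [Term] stanzas in ", path)
  stanza_ends <- c(term_starts[-1L] - 1L, length(lines))
  recs <- list()
  for (k in seq_along(term_starts)) {
    block <- lines[term_starts[k]:stanza_ends[k]]
    stop_at <- grep("^\\[", block[-1L])
    if (length(stop_at) > 0L) block <- block[seq_len(stop_at[1L])]
    get1 <- function(key) {
      m <- grep(paste0("^", key, ":"), block, value = TRUE)
      if (length(m) == 0L) return(NA_character_)
      trimws(sub(paste0("^", key, ":\\s*"), "", m[1L]))
    }
    id <- get1("id")
    if (is.na(id)) next
    obsolete <- identical(get1("is_obsolete"), "true")
    ns <- get1("namespace")
    isa_lines <- grep("^is_a:", block, value = TRUE)
    isa <- sub("^is_a:\\s*(\\S+).*$", "\\1", isa_lines)
    recs[[id]] <- list(id = id, namespace = ns, is_a = isa,
                       obsolete = obsolete)
  }
  recs <- Filter(function(r) !r$obsolete, recs)
  ns_all <- vapply(recs, function(r) r$namespace %||% NA_character_,
                   character(1))
  out <- list()
  for (ns in intersect(names(GO_NAMESPACES), unique(ns_all))) {
    ids <- names(recs)[ns_all == ns]
    parents <- lapply(recs[ids], function(r) intersect(r$is_a, ids))
    names(parents) <- ids
    roots <- ids[vapply(parents, length, integer(1)) == 0L]
    if (length(roots) != 1L) {
      stop(sprintf("branch %s has %d roots (expected 1)", ns, length(roots)))
    }
    out[[GO_NAMESPACES[[ns]]]] <- go_dag(ids, parents,
                                         branch = GO_NAMESPACES[[ns]],
                                         root = roots)
  }
  out
}

#' Write per-branch DAGs as an OBO 1.2 file
#'
#' Used to serialise synthetic ontologies for round-trip tests and
#' pipeline bundles.
#'
#' @param dags Named list of [go_dag()] objects keyed by branch tag.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dags, path) {
  ns_of <- stats::setNames(names(GO_NAMESPACES), GO_NAMESPACES)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (branch in names(dags)) {
    dag <- dags[[branch]]
    for (t in dag$terms) {
      writeLines("[Term]", con)
      writeLines(paste0("id: ", t), con)
      writeLines(paste0("name: ", t), con)
      writeLines(paste0("namespace: ", ns_of[[branch]]), con)
      for (p in dag$parents[[t]] %||% character(0)) {
        writeLines(paste0("is_a: ", p, " ! ", p), con)
      }
      writeLines("", con)
    }
  }
  invisible(path)
}

#' Construct an annotation table
#'
#' @param protein_id,term_id,evidence_code Equal-length character vectors.
#' @return `data.frame` with class `annotation_table`.
#' @export
annotation_table <- function(protein_id = character(0),
                             term_id = character(0),
                             evidence_code = character(0)) {
  df <- data.frame(protein_id = as.character(protein_id),
                   term_id = as.character(term_id),
                   evidence_code = as.character(evidence_code),
                   stringsAsFactors = FALSE)
  class(df) <- c("annotation_table", "data.frame")
  df
}

#' Read annotations from GAF 2.x or a 3-column TSV
#'
#' GAF files (detected by a `!gaf-version` header or `.gaf` extension) use
#' columns 2 (protein), 5 (term), 7 (evidence code); otherwise the file is
#' read as a headerless 3-column TSV `protein_id<TAB>term_id<TAB>code`.
#'
#' @param path Input path.
#' @return An [annotation_table()].
#' @export
read_annotations <- function(path) {
  lines <- readLines(path)
  is_gaf <- grepl("\\.gaf$", path, ignore.case = TRUE) ||
    any(startsWith(lines, "!gaf-version"))
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (length(lines) == 0L) return(annotation_table())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (is_gaf) {
    annotation_table(vapply(fields, `[`, character(1), 2L),
                     vapply(fields, `[`, character(1), 5L),
                     vapply(fields, `[`, character(1), 7L))
  } else {
    annotation_table(vapply(fields, `[`, character(1), 1L),
                     vapply(fields, `[`, character(1), 2L),
                     vapply(fields, `[`, character(1), 3L))
  }
}

#' Write an annotation table as 3-column TSV
#'
#' @param table An [annotation_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(table, path) {
  utils::write.table(as.data.frame(table)[, c("protein_id", "term_id",
                                              "evidence_code")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Keep annotations with trusted evidence codes
#'
#' @param table An [annotation_table()].
#' @param allowed Character vector of accepted codes; the default is the
#'   experimental/curated set IDA, IPI, EXP, IGI, IMP, IEP, IC, TAS
#'   (with `"TA"` accepted as an alias of TAS).
#' @return Filtered [annotation_table()].
#' @export
filter_evidence <- function(table, allowed = DEFAULT_EVIDENCE) {
  code <- ifelse(table$evidence_code == "TA", "TAS", table$evidence_code)
  out <- table[code %in% allowed, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("annotation_table", "data.frame")
  out
}

#' True-path-rule label completion
#'
#' Annotation to a term implies annotation to every ancestor: the table is
#' closed upward over `is_a` edges. Terms not resolvable in the DAG are
#' dropped with a warning. Idempotent; propagated rows carry the evidence
#' code of the row that generated them.
#'
#' @param table An [annotation_table()].
#' @param dag A [go_dag()].
#' @return Propagated [annotation_table()] with one row per
#'   (protein, term) pair.
#' @export
propagate_true_path <- function(table, dag) {
  known <- table$term_id %in% dag$terms
  if (any(!known)) {
    warning(sprintf("dropped %d annotation(s) to terms absent from the DAG",
                    sum(!known)))
    table <- table[known, , drop = FALSE]
  }
  if (nrow(table) == 0L) return(annotation_table())
  anc_cache <- lapply(stats::setNames(unique(table$term_id),
                                      unique(table$term_id)),
                      function(t) dag_ancestors(dag, t))
  rows <- vector("list", nrow(table))
  for (i in seq_len(nrow(table))) {
    terms <- c(table$term_id[i], anc_cache[[table$term_id[i]]])
    rows[[i]] <- data.frame(protein_id = table$protein_id[i],
                            term_id = terms,
                            evidence_code = table$evidence_code[i],
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[, c("protein_id", "term_id")]), , drop = FALSE]
  out <- out[order(out$protein_id, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("annotation_table", "data.frame")
  out
}

#' Build the label space by term-frequency filtering
#'
#' Counts, after true-path completion, how many distinct proteins each
#' term annotates and keeps terms at or above `min_count`, excluding the
#' branch root (it annotates everything). Order is lexicographic by term
#' id, making the column layout deterministic.
#'
#' @param table A propagated [annotation_table()].
#' @param dag A [go_dag()].
#' @param min_count Minimum number of distinct annotated proteins.
#' @return Object of class `label_space`: list with `branch`, `terms`
#'   (ordered), and `index` (term -> column).
#' @export
filter_labels <- function(table, dag, min_count = 25L) {
  stopifnot(min_count >= 1L)
  tab <- table[table$term_id %in% dag$terms & table$term_id != dag$root, ,
               drop = FALSE]
  counts <- tapply(tab$protein_id, tab$term_id,
                   function(p) length(unique(p)))
  keep <- sort(names(counts)[counts >= min_count])
  structure(list(branch = dag$branch, terms = keep,
                 index = stats::setNames(seq_along(keep), keep)),
            class = "label_space")
}

#' @export
print.label_space <- function(x, ...) {
  cat(sprintf("<label_space> %s: %d terms\n", x$branch, length(x$terms)))
  invisible(x)
}

#' Binary protein x term label matrix
#'
#' @param table A propagated [annotation_table()].
#' @param space A [filter_labels()] label space.
#' @param proteins Ordered character vector of protein ids (rows).
#' @return Binary matrix `length(proteins)` x `length(space$terms)` with
#'   dimnames; hierarchically consistent when `table` is propagated.
#' @export
label_matrix <- function(table, space, proteins) {
  m <- matrix(0L, length(proteins), length(space$terms),
              dimnames = list(proteins, space$terms))
  tab <- table[table$protein_id %in% proteins &
                 table$term_id %in% space$terms, , drop = FALSE]
  if (nrow(tab) > 0L) {
    m[cbind(match(tab$protein_id, proteins),
            match(tab$term_id, space$terms))] <- 1L
  }
  m
}

#' Write / read a label space as ordered TSV
#'
#' @param space A label space.
#' @param path File path.
#' @return `write_label_space` returns `path` invisibly; `read_label_space`
#'   a `label_space`.
#' @export
write_label_space <- function(space, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# branch=", space$branch), con)
  writeLines(space$terms, con)
  invisible(path)
}

#' @rdname write_label_space
#' @export
read_label_space <- function(path) {
  lines <- readLines(path)
  branch <- sub("^# branch=", "", lines[1L])
  terms <- lines[-1L]
  structure(list(branch = branch, terms = terms,
                 index = stats::setNames(seq_along(terms), terms)),
            class = "label_space")
}
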
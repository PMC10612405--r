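test_that("minimal OBO parses and obsolete terms are excluded", {
  path <- withr::local_tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: root",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "name: child",
    "namespace: biological_process", "is_a: GO:0000001 ! root", "",
    "[Term]", "id: GO:0000003", "name: gone",
    "namespace: biological_process", "is_a: GO:0000001 ! root",
    "is_obsolete: true", ""
  ), path)
  dags <- parse_obo(path)
  expect_named(dags, "BPO")
  dag <- dags$BPO
  expect_setequal(dag$terms, c("GO:0000001", "GO:0000002"))
  expect_identical(dag$root, "GO:0000001")
  expect_identical(dag$parents[["GO:0000002"]], "GO:0000001")
})

test_that("OBO writer/parser round-trips random DAGs exactly", {
  for (seed in c(2, 7, 19)) {
    dag <- random_dag(50, seed)
    path <- withr::local_tempfile(fileext = ".obo")
    write_obo(list(BPO = dag), path)
    back <- parse_obo(path)$BPO
    expect_identical(back$terms, dag$terms)
    expect_identical(back$root, dag$root)
    for (t in dag$terms) {
      expect_identical(back$parents[[t]] %||% character(0),
                       dag$parents[[t]] %||% character(0))
    }
  }
})

test_that("cycles are a hard error naming the terms involved", {
  parents <- list(`GO:B` = "GO:A", `GO:C` = c("GO:B", "GO:D"),
                  `GO:D` = "GO:C")
  expect_error(go_dag(c("GO:A", "GO:B", "GO:C", "GO:D"), parents,
                      "BPO", "GO:A"),
               "cycle.*GO:C")
})

test_that("evidence filtering keeps the trusted codes, TA aliased to TAS", {
  tab <- annotation_table(c("P1", "P1", "P2", "P2", "P3"),
                          paste0("GO:000000", 1:5),
                          c("IDA", "IEA", "TAS", "TA", "ISS"))
  out <- filter_evidence(tab)
  expect_identical(out$protein_id, c("P1", "P2", "P2"))
  expect_identical(out$evidence_code, c("IDA", "TAS", "TA"))
  expect_identical(nrow(filter_evidence(annotation_table())), 0L)

  # random rows equal the independent per-row membership check
  set.seed(5)
  codes <- sample(c("IDA", "IPI", "EXP", "IGI", "IMP", "IEP", "IC", "TAS",
                    "IEA", "ISS", "ND"), 100, replace = TRUE)
  tab <- annotation_table(sprintf("P%03d", 1:100), rep("GO:1", 100), codes)
  kept <- filter_evidence(tab)
  oracle <- vapply(codes, function(cd) {
    cd %in% c("IDA", "IPI", "EXP", "IGI", "IMP", "IEP", "IC", "TAS")
  }, logical(1))
  expect_identical(kept$protein_id, tab$protein_id[oracle])
})

test_that("true-path propagation closes chains and is idempotent", {
  dag <- go_dag(c("GO:R", "GO:M", "GO:L"),
                list(`GO:M` = "GO:R", `GO:L` = "GO:M"), "BPO", "GO:R")
  tab <- annotation_table("P1", "GO:L", "IDA")
  prop <- propagate_true_path(tab, dag)
  expect_identical(nrow(prop), 3L)
  expect_setequal(prop$term_id, c("GO:R", "GO:M", "GO:L"))
  prop2 <- propagate_true_path(prop, dag)
  expect_identical(as.data.frame(prop2), as.data.frame(prop))
})

test_that("propagation equals the DFS transitive-closure oracle", {
  for (seed in 1:20) {
    dag <- random_dag(sample(10:50, 1), seed)
    set.seed(seed + 1000)
    n_ann <- 30
    tab <- annotation_table(sample(sprintf("P%02d", 1:10), n_ann, TRUE),
                            sample(dag$terms, n_ann, TRUE),
                            rep("IDA", n_ann))
    prop <- propagate_true_path(tab, dag)
    oracle <- dfs_closure(tab, dag)
    expect_identical(prop$protein_id, oracle$protein_id)
    expect_identical(prop$term_id, oracle$term_id)
  }
})

test_that("unresolvable terms are dropped with a warning", {
  dag <- go_dag(c("GO:R", "GO:M"), list(`GO:M` = "GO:R"), "BPO", "GO:R")
  tab <- annotation_table(c("P1", "P2"), c("GO:M", "GO:NOPE"),
                          c("IDA", "IDA"))
  expect_warning(prop <- propagate_true_path(tab, dag), "absent")
  expect_setequal(unique(prop$protein_id), "P1")
})

test_that("label-space filtering thresholds counts and excludes the root", {
  dag <- go_dag(c("GO:R", "GO:A", "GO:B"),
                list(`GO:A` = "GO:R", `GO:B` = "GO:R"), "BPO", "GO:R")
  tab <- annotation_table(c("P1", "P2", "P3", "P4"),
                          c("GO:A", "GO:A", "GO:A", "GO:B"),
                          rep("IDA", 4))
  prop <- propagate_true_path(tab, dag)
  space <- filter_labels(prop, dag, min_count = 2L)
  expect_identical(space$terms, "GO:A")
  # min_count = 1 keeps all annotated non-root terms
  all_sp <- filter_labels(prop, dag, min_count = 1L)
  expect_setequal(all_sp$terms, c("GO:A", "GO:B"))
  expect_false(dag$root %in% all_sp$terms)
})

test_that("label filtering equals count-then-threshold and is monotone", {
  for (seed in c(3, 9)) {
    dag <- random_dag(25, seed)
    set.seed(seed)
    tab <- annotation_table(sample(sprintf("P%02d", 1:20), 80, TRUE),
                            sample(dag$terms, 80, TRUE), rep("IDA", 80))
    prop <- propagate_true_path(tab, dag)
    for (mc in c(1L, 3L, 6L)) {
      space <- filter_labels(prop, dag, mc)
      counts <- sapply(split(prop$protein_id, prop$term_id),
                       function(p) length(unique(p)))
      oracle <- sort(setdiff(names(counts)[counts >= mc], dag$root))
      expect_identical(space$terms, oracle)
    }
    # monotone: raising min_count never adds terms
    s1 <- filter_labels(prop, dag, 2L)$terms
    s2 <- filter_labels(prop, dag, 5L)$terms
    expect_true(all(s2 %in% s1))
  }
})

test_that("label matrices are hierarchically consistent with correct counts", {
  dag <- random_dag(20, 4)
  set.seed(4)
  tab <- annotation_table(sample(sprintf("P%02d", 1:15), 60, TRUE),
                          sample(dag$terms, 60, TRUE), rep("IDA", 60))
  prop <- propagate_true_path(tab, dag)
  space <- filter_labels(prop, dag, 2L)
  proteins <- sprintf("P%02d", 1:15)
  m <- label_matrix(prop, space, proteins)
  expect_identical(dim(m), c(15L, length(space$terms)))
  # column sums at least min_count (counted over all annotated proteins)
  expect_true(all(colSums(m) >= 2L |
                    colSums(m) == 0L))  # proteins outside `proteins` impossible here
  # child column <= parent column elementwise for every is_a edge in space
  for (t in space$terms) {
    for (p in intersect(dag$parents[[t]], space$terms)) {
      expect_true(all(m[, t] <= m[, p]))
    }
  }
  # protein with no annotations gets an all-zero row
  m2 <- label_matrix(prop, space, c(proteins, "P99"))
  expect_true(all(m2["P99", ] == 0))
})

test_that("label spaces and annotation tables round-trip through disk", {
  dag <- random_dag(15, 6)
  set.seed(6)
  tab <- annotation_table(sample(sprintf("P%02d", 1:10), 30, TRUE),
                          sample(dag$terms, 30, TRUE), rep("IDA", 30))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotations(tab, path)
  back <- read_annotations(path)
  expect_identical(as.data.frame(back), as.data.frame(tab))

  prop <- propagate_true_path(tab, dag)
  space <- filter_labels(prop, dag, 1L)
  sp_path <- withr::local_tempfile(fileext = ".tsv")
  write_label_space(space, sp_path)
  back_sp <- read_label_space(sp_path)
  expect_identical(back_sp$terms, space$terms)
  expect_identical(back_sp$branch, space$branch)
})

test_that("GAF files are read via the standard columns", {
  path <- withr::local_tempfile(fileext = ".gaf")
  writeLines(c("!gaf-version: 2.2",
               paste("UniProtKB", "P12345", "GENE1", "", "GO:0000001",
                     "PMID:1", "IDA", "", "P", "", "", "protein", "",
                     "20200101", "UniProt", sep = "\t"),
               paste("UniProtKB", "P67890", "GENE2", "", "GO:0000002",
                     "PMID:2", "IEA", "", "P", "", "", "protein", "",
                     "20200101", "UniProt", sep = "\t")), path)
  tab <- read_annotations(path)
  expect_identical(tab$protein_id, c("P12345", "P67890"))
  expect_identical(tab$term_id, c("GO:0000001", "GO:0000002"))
  expect_identical(tab$evidence_code, c("IDA", "IEA"))
})
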
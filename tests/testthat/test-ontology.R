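chain_dag <- function() {
  ontology_dag(c("root", "A", "B"),
               data.frame(child = c("A", "B"), parent = c("root", "A")))
}

diamond_dag <- function() {
  # root <- L, root <- R, L <- bottom, R <- bottom
  ontology_dag(c("root", "L", "R", "bottom"),
               data.frame(child = c("L", "R", "bottom", "bottom"),
                          parent = c("root", "root", "L", "R")))
}

ann <- function(gene, term, ev = "EXP") {
  data.frame(gene_id = gene, term_id = term, evidence = ev,
             stringsAsFactors = FALSE)
}

test_that("propagation closes over ancestors and is idempotent", {
  dag <- chain_dag()
  a <- propagate(dag, annotation_set(ann("g1", "B")))
  expect_setequal(a$propagated$g1, c("B", "A", "root"))

  a2 <- propagate(dag, annotation_set(ann("g1", "root")))
  expect_setequal(a2$propagated$g1, "root")

  d <- diamond_dag()
  a3 <- propagate(d, annotation_set(ann("g1", "bottom")))
  expect_setequal(a3$propagated$g1, c("bottom", "L", "R", "root"))
  expect_equal(sum(a3$propagated$g1 == "root"), 1L)  # once, not per path

  # idempotence: re-propagating the propagated set changes nothing
  rec2 <- data.frame(gene_id = "g1", term_id = a3$propagated$g1,
                     evidence = "EXP")
  a4 <- propagate(d, annotation_set(rec2))
  expect_setequal(a4$propagated$g1, a3$propagated$g1)

  expect_error(propagate(dag, annotation_set(ann("g1", "nope"))),
               "nope")
  expect_warning(propagate(dag, annotation_set(ann("g1", "nope")),
                           lenient = TRUE), "nope")
})

test_that("DAG validation rejects cycles and orphans", {
  expect_error(ontology_dag(c("a", "b"),
                            data.frame(child = c("a", "b"),
                                       parent = c("b", "a"))),
               "cycle|root")
  expect_error(ontology_dag(c("root", "a", "b"),
                            data.frame(child = "a", parent = "root")),
               "root")
})

test_that("positive set derivation respects inheritance and evidence filters", {
  dag <- ontology_dag(c("root", "T", "Tchild", "U"),
                      data.frame(child = c("T", "Tchild", "U"),
                                 parent = c("root", "T", "root")))
  records <- rbind(ann("g1", "T"), ann("g2", "T"), ann("g3", "Tchild"),
                   ann("g4", "U"), ann("g5", "root"))
  a <- annotation_set(records)
  # direct + inherited membership; g3 included via the descendant
  expect_setequal(derive_positive_set(dag, a, "T"), c("g1", "g2", "g3"))
  # gene reachable only through an IEA-coded annotation is excluded
  a_iea <- annotation_set(rbind(ann("g1", "T"), ann("g3", "Tchild", "IEA")))
  expect_setequal(derive_positive_set(dag, a_iea, "T",
                                      evidence_blacklist = "IEA"), "g1")
  expect_error(derive_positive_set(dag, a, "missing"), "unknown")
  expect_warning(out <- derive_positive_set(dag, annotation_set(
    ann("g4", "U")), "T"), "no genes")
  expect_length(out, 0)
})

test_that("negative terms use the positive-fraction rule; negatives avoid non-negative terms", {
  dag <- ontology_dag(c("root", "P", "N1", "N2"),
                      data.frame(child = c("P", "N1", "N2"),
                                 parent = c("root", "root", "root")))
  # N1: 10 genes, none positive; N2: 10 genes, 1 positive (10%)
  rec <- rbind(
    ann(paste0("p", 1:5), "P"),
    ann(paste0("a", 1:10), "N1"),
    ann(c("p1", paste0("b", 1:9)), "N2"))
  a <- propagate(dag, annotation_set(rec))
  res <- derive_negative_set(dag, a, positives = paste0("p", 1:5),
                             p_threshold = 0.05)
  expect_true("N1" %in% res$negative_terms)
  expect_false("N2" %in% res$negative_terms)  # 1/10 > 5%
  expect_false(dag$root %in% res$negative_terms)
  # b-genes are only in the non-negative N2 -> excluded; a-genes kept
  expect_setequal(res$negatives, paste0("a", 1:10))

  # a gene directly in a negative term but propagated into a
  # non-negative term is excluded
  dag2 <- ontology_dag(c("root", "P", "Nsub"),
                       data.frame(child = c("P", "Nsub"),
                                  parent = c("root", "P")))
  rec2 <- rbind(ann(paste0("p", 1:10), "P"), ann("x1", "Nsub"))
  a2 <- propagate(dag2, annotation_set(rec2))
  res2 <- suppressWarnings(
    derive_negative_set(dag2, a2, positives = paste0("p", 1:10),
                        p_threshold = 0.05))
  expect_true("Nsub" %in% res2$negative_terms)  # 0/1 positives in it
  expect_false("x1" %in% res2$negatives)  # propagates into P
})

test_that("negative-term set grows monotonically with the P threshold", {
  set.seed(4)
  gen <- generate_ontology(n_terms = 15, depth = 3, n_genes = 80,
                           annotation_density = 0.1, seed = 4)
  pos <- names(gen$annotations$propagated)[1:10]
  prev <- character()
  for (p in c(0, 0.05, 0.2, 0.5, 1)) {
    cur <- suppressWarnings(
      derive_negative_set(gen$dag, gen$annotations, pos, p))$negative_terms
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("OBO and GAF readers round-trip a small ontology", {
  obo <- c("format-version: 1.2", "",
           "[Term]", "id: GO:0000001", "name: root", "",
           "[Term]", "id: GO:0000002", "is_a: GO:0000001 ! root", "",
           "[Term]", "id: GO:0000003",
           "relationship: part_of GO:0000002 ! mid", "",
           "[Term]", "id: GO:0000004", "is_obsolete: true")
  f_obo <- withr::local_tempfile(lines = obo, fileext = ".obo")
  dag <- read_obo(f_obo)
  expect_setequal(dag$terms, c("GO:0000001", "GO:0000002", "GO:0000003"))
  expect_equal(dag$root, "GO:0000001")
  expect_setequal(dag$ancestors[["GO:0000003"]],
                  c("GO:0000002", "GO:0000001"))
  # part_of edges can be excluded
  expect_error(read_obo(f_obo, use_part_of = FALSE), "root")

  gaf <- c("!gaf-version: 2.0",
           "g1\tGO:0000003\tEXP", "g2\tGO:0000002\tIEA")
  f_gaf <- withr::local_tempfile(lines = gaf, fileext = ".tsv")
  a <- read_gaf(f_gaf)
  expect_equal(nrow(a$records), 2L)
  tr <- suppressWarnings(  # negative set legitimately empty here
    derive_training_set(dag, a, "GO:0000002",
                        evidence_blacklist = "IEA"))
  expect_setequal(tr$positives, "g1")
})
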
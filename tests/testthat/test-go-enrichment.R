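# Ontology/annotation ingestion and module GO enrichment.

toy_obo_lines <- function() c(
  "format-version: 1.2", "",
  "[Term]", "id: GO:0000001", "name: root process",
  "namespace: biological_process", "",
  "[Term]", "id: GO:0000002", "name: branch process",
  "namespace: biological_process", "is_a: GO:0000001 ! root process", "",
  "[Term]", "id: GO:0000003", "name: leaf process",
  "namespace: biological_process", "is_a: GO:0000002 ! branch process", "",
  "[Term]", "id: GO:0000004", "name: part process",
  "namespace: biological_process",
  "relationship: part_of GO:0000002 ! branch process", "",
  "[Term]", "id: GO:0000009", "name: molecular thing",
  "namespace: molecular_function", "")

gaf_line <- function(gene, term, evidence = "IDA", qualifier = "") {
  paste("SYN", gene, gene, qualifier, term, "SYN:1", evidence, "", "P", "",
        "", "protein", "taxon:0", "20200101", "SYN", "", "", sep = "\t")
}

test_that("evidence-code exclusion and NOT qualifiers filter annotations", {
  obo <- write_tmp(toy_obo_lines(), ext = ".obo")
  gaf <- write_tmp(c("!gaf-version: 2.1",
                     gaf_line("gA", "GO:0000003", evidence = "IPI"),
                     gaf_line("gB", "GO:0000003", evidence = "IDA"),
                     gaf_line("gC", "GO:0000003", qualifier = "NOT"),
                     vapply(sprintf("h%02d", 1:6),
                            function(g) gaf_line(g, "GO:0000002"), "")),
                   ext = ".gaf")
  idx <- load_ontology(obo, gaf, min_genes = 1, max_genes = 500)
  expect_equal(idx$genes[["GO:0000003"]], "gB") # IPI and NOT lines dropped
  # up-propagation: gB reaches branch and root; part_of term genes none
  expect_true("gB" %in% idx$genes[["GO:0000002"]])
  expect_true("gB" %in% idx$genes[["GO:0000001"]])
  # non-BP terms are dropped entirely
  expect_false("GO:0000009" %in% idx$terms$id)
})

test_that("part_of participates in propagation when enabled", {
  obo <- write_tmp(toy_obo_lines(), ext = ".obo")
  gaf <- write_tmp(c("!gaf-version: 2.1", gaf_line("gP", "GO:0000004")),
                   ext = ".gaf")
  idx <- load_ontology(obo, gaf, min_genes = 1, max_genes = 500)
  expect_true("gP" %in% idx$genes[["GO:0000002"]])
  idx2 <- load_ontology(obo, gaf, include_part_of = FALSE,
                        min_genes = 1, max_genes = 500)
  expect_false("gP" %in% idx2$genes[["GO:0000002"]])
})

test_that("usable terms respect the 5-500 size filter after propagation", {
  obo <- write_tmp(toy_obo_lines(), ext = ".obo")
  gaf <- write_tmp(c("!gaf-version: 2.1",
                     vapply(sprintf("g%02d", 1:3),
                            function(g) gaf_line(g, "GO:0000003"), ""),
                     vapply(sprintf("h%02d", 1:4),
                            function(g) gaf_line(g, "GO:0000002"), "")),
                   ext = ".gaf")
  idx <- load_ontology(obo, gaf)
  # leaf has 3 genes (< 5): excluded; branch has 7 after propagation: usable
  expect_false("GO:0000003" %in% idx$usable)
  expect_true("GO:0000002" %in% idx$usable)
  # parent gene sets always contain child gene sets
  for (t in idx$terms$id) {
    for (p in idx$parents[[t]]) {
      expect_true(all(idx$genes[[t]] %in% idx$genes[[p]]))
    }
  }
})

test_that("cyclic ontologies are rejected", {
  cyc <- c("format-version: 1.2", "",
           "[Term]", "id: GO:0000001", "name: a",
           "namespace: biological_process", "is_a: GO:0000002", "",
           "[Term]", "id: GO:0000002", "name: b",
           "namespace: biological_process", "is_a: GO:0000001", "")
  gaf <- write_tmp(c("!gaf-version: 2.1", gaf_line("g1", "GO:0000001")),
                   ext = ".gaf")
  expect_error(load_ontology(write_tmp(cyc, ext = ".obo"), gaf), "cycle")
})

test_that("toy-ontology writers round-trip through the OBO/GAF readers", {
  labels <- setNames(rep(1:2, each = 20), sprintf("g%04d", 1:40))
  onto <- make_ontology(labels, seed = 3)
  obo <- tempfile(fileext = ".obo"); gaf <- tempfile(fileext = ".gaf")
  write_toy_obo(onto, obo)
  write_toy_gaf(onto, gaf)
  idx <- load_ontology(obo, gaf)
  expect_setequal(idx$terms$id, onto$index$terms$id)
  expect_identical(idx$genes, onto$index$genes)
  expect_identical(idx$usable, onto$index$usable)
  expect_equal(idx$ic, onto$index$ic)
})

test_that("module enrichment reproduces the exact hypergeometric example", {
  # background of 20 genes, one usable term covering 5 of them, and a
  # 4-gene module drawn entirely from the term
  genes <- sprintf("g%02d", 1:20)
  obo <- write_tmp(toy_obo_lines(), ext = ".obo")
  gaf <- write_tmp(c("!gaf-version: 2.1",
                     vapply(genes[1:5],
                            function(g) gaf_line(g, "GO:0000003"), ""),
                     # off-background genes inflate the branch over the
                     # size cap so only the leaf stays usable
                     vapply(sprintf("h%02d", 1:12),
                            function(g) gaf_line(g, "GO:0000002"), ""),
                     vapply(genes, function(g) gaf_line(g, "GO:0000001"), "")),
                   ext = ".gaf")
  idx <- load_ontology(obo, gaf, min_genes = 5, max_genes = 15)
  expect_equal(idx$usable, "GO:0000003") # root and branch exceed the cap
  rec <- module_enrichment(genes[1:4], idx, genes)
  expect_equal(rec$p, 5 / 4845, tolerance = 1e-12)
  expect_equal(rec$p, hyper_tail_enumerate(20, 5, 4, 4), tolerance = 1e-12)
  expect_equal(rec$q, rec$p) # single usable term
  expect_equal(rec$score, -log10(rec$p))

  # disjoint module: p = 1
  rec2 <- module_enrichment(genes[6:9], idx, genes)
  expect_equal(rec2$p, 1)
  # empty module: empty record table
  expect_equal(nrow(module_enrichment(character(), idx, genes)), 0)
})

test_that("BH q-values are monotone along the p-value ranking", {
  fx <- small_fixture(seed = 17)
  idx <- fx$ontology$index
  rec <- module_enrichment(fx$planted[[1]], idx, igraph::V(fx$network)$name)
  expect_false(is.unsorted(rec$p))
  expect_false(is.unsorted(cummax(rec$q))) # q never drops below a later max
  expect_true(all(rec$q >= rec$p))
})

test_that("solution scores keep the per-term maximum across modules", {
  r1 <- data.frame(term = c("T1", "T2"), p = c(0.01, 0.5),
                   q = c(0.02, 0.5), score = -log10(c(0.01, 0.5)))
  r2 <- data.frame(term = c("T1", "T3"), p = c(0.001, 0.2),
                   q = c(0.002, 0.2), score = -log10(c(0.001, 0.2)))
  s <- solution_term_scores(list(r1, r2), terms = c("T1", "T2", "T3", "T4"))
  expect_equal(s$score[s$term == "T1"], 3)
  expect_equal(s$q[s$term == "T1"], 0.002)
  expect_equal(s$score[s$term == "T4"], 0) # absent everywhere: score 0
  expect_true(is.na(s$q[s$term == "T4"]))
  # single module: identity
  s1 <- solution_term_scores(list(r1), terms = c("T1", "T2"))
  expect_equal(s1$score, r1$score)
})
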
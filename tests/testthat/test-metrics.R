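# Module-level EHR, Resnik similarity, redundancy reduction, intra-module
# homogeneity and robustness summaries.

test_that("module-level EHR is the EV/HG ratio with NA when undefined", {
  rec <- function(terms, q) data.frame(term = terms, p = q, q = q,
                                       score = -log10(pmax(q, 1e-300)))
  records <- list(
    m1 = rec(sprintf("T%02d", 1:8), rep(0.01, 8)),       # 8 HG terms
    m2 = rec(c("T01", "T90"), c(0.01, 0.9)),             # 1 HG term
    m3 = rec("T91", 0.9))                                # 0 HG terms
  ev <- sprintf("T%02d", 1:7)                            # 7 of m1's EV
  m <- module_ehr(records, ev)
  expect_equal(unname(m["m1"]), 7 / 8)
  expect_equal(unname(m["m2"]), 1)
  expect_true(is.na(m["m3"]))

  # top-k mean: ranked (1, 0.875); k beyond the module count repeats the mean
  tk <- mehr_top_k(m, k_max = 4)
  expect_equal(tk, c(1, mean(c(1, 7 / 8)), mean(c(1, 7 / 8)),
                     mean(c(1, 7 / 8))))
  # single defined module: every k returns its value
  expect_equal(unique(mehr_top_k(c(a = 0.6, b = NA))), 0.6)
})

test_that("Resnik similarity follows the information content of ancestors", {
  labels <- setNames(rep(1:2, each = 20), sprintf("g%04d", 1:40))
  onto <- make_ontology(labels, seed = 5)
  idx <- onto$index
  root <- "GO:9000000"
  expect_equal(idx$ic[[root]], 0)
  expect_equal(resnik_similarity(root, onto$truth$term[1], idx), 0)
  t1 <- onto$truth$term[1]
  expect_equal(resnik_similarity(t1, t1, idx), idx$ic[[t1]])
  expect_gte(resnik_similarity(t1, onto$truth$term[2], idx), 0)

  # hand-built corpus: siblings under a parent holding 10 of 20 genes have
  # similarity -ln(0.5)
  terms <- data.frame(id = c("R", "P", "A", "B"),
                      name = c("root", "parent", "a", "b"))
  parents <- list(R = character(), P = "R", A = "P", B = "P")
  ann <- rbind(
    data.frame(gene = sprintf("g%02d", 1:20), term = "R"),
    data.frame(gene = sprintf("g%02d", 1:10), term = "P"),
    data.frame(gene = sprintf("g%02d", 1:5), term = "A"),
    data.frame(gene = sprintf("g%02d", 6:10), term = "B"))
  idx2 <- dominoR:::build_ontology_index(terms, parents, ann)
  expect_equal(resnik_similarity("A", "B", idx2), -log(0.5), tolerance = 1e-12)
  sm <- similarity_matrix(c("A", "B", "R"), idx2)
  expect_true(isSymmetric(sm))
  expect_equal(sm["A", "A"], idx2$ic[["A"]])
})

test_that("redundancy reduction drops the worse-p member of similar pairs", {
  terms <- c("t1", "t2", "t3")
  sim <- matrix(c(9, 5, 0.5,
                  5, 9, 5,
                  0.5, 5, 9), 3, 3, dimnames = list(terms, terms))
  p <- c(t1 = 1e-6, t2 = 1e-3, t3 = 1e-5)
  # chain trace: both high-sim pairs involve t2, the worst p; survivors t1, t3
  expect_setequal(reduce_redundant(terms, p, sim, cutoff = 4), c("t1", "t3"))
  # everything below the cutoff: identity
  expect_setequal(reduce_redundant(terms, p, sim, cutoff = 6), terms)
  # two near-identical terms: the smaller p survives
  expect_equal(reduce_redundant(c("t1", "t2"), c(1e-6, 1e-3),
                                sim[1:2, 1:2], cutoff = 4), "t1")
})

test_that("reduction output has no pair above the cutoff; richness is monotone", {
  set.seed(8)
  n <- 12
  terms <- sprintf("t%02d", 1:n)
  base <- matrix(runif(n * n, 0, 5), n, n, dimnames = list(terms, terms))
  sim <- (base + t(base)) / 2
  diag(sim) <- 6
  p <- setNames(runif(n), terms)
  for (cutoff in c(1, 2, 3, 4)) {
    kept <- reduce_redundant(terms, p, sim, cutoff)
    if (length(kept) > 1) {
      s <- sim[kept, kept]; diag(s) <- -Inf
      expect_lte(max(s), cutoff)
    }
  }
  rich <- biological_richness(terms, p, sim, cutoffs = seq(1, 4, 0.5))
  expect_false(is.unsorted(rich)) # lower cutoffs merge more
})

test_that("intra-module homogeneity is the relative edge density", {
  # module keeps 2 of its 3 pairs; solution keeps 5 of 15: score 2.0
  terms <- sprintf("e%d", 1:6)
  sim <- matrix(0, 6, 6, dimnames = list(terms, terms))
  above <- rbind(c(1, 2), c(1, 3), c(4, 5), c(4, 6), c(5, 6))
  for (r in seq_len(nrow(above))) {
    sim[above[r, 1], above[r, 2]] <- 3
    sim[above[r, 2], above[r, 1]] <- 3
  }
  diag(sim) <- 5
  h <- intra_module_homogeneity(list(terms[1:3]), terms, sim, cutoff = 2)
  expect_equal(h$module_scores, 2)
  expect_equal(h$solution_score, 2)
  # a module spanning the whole solution scores exactly 1
  h1 <- intra_module_homogeneity(list(terms), terms, sim, cutoff = 2)
  expect_equal(h1$solution_score, 1)
  # modules with fewer than two EV terms score 0
  h0 <- intra_module_homogeneity(list(terms[1]), terms, sim, cutoff = 2)
  expect_equal(h0$module_scores, 0)
  # invariance to module order
  ha <- intra_module_homogeneity(list(terms[1:3], terms[4:6]), terms, sim, 2)
  hb <- intra_module_homogeneity(list(terms[4:6], terms[1:3]), terms, sim, 2)
  expect_equal(ha$solution_score, hb$solution_score)
})

test_that("precision/recall/F1 and AUPR behave on degenerate rankings", {
  prf <- dominoR:::prf
  expect_equal(unname(prf(c("a", "b"), c("a", "b"))), c(1, 1, 1))
  expect_equal(unname(prf(character(), c("a"))[2]), 0) # recall 0
  expect_equal(unname(prf(c("a", "b"), c("b", "c"))[1]), 0.5)

  aupr <- dominoR:::aupr_from_frequency
  # a positive ranked first contributes precision 1 at rank 1
  freq <- c(good = 1, bad1 = 0.5, bad2 = 0.2)
  expect_equal(aupr(freq, "good"), 1)
  # prevalence lower bound: positives ranked last
  freq2 <- c(bad1 = 1, bad2 = 0.9, good = 0.1)
  a <- aupr(freq2, "good")
  expect_gte(a, 1 / 3 - 1e-12)
  expect_lte(a, 1)
  expect_true(is.na(aupr(freq, character()))) # no positives: undefined
})

test_that("robustness recall rises with the subsampling fraction on signal", {
  fx <- make_planted_fixture(seed = 42)
  slices <- build_slices(fx$network)
  idx <- fx$ontology$index
  sol <- run_domino(fx$network, slices, fx$profile)
  recs <- lapply(sol$modules, module_enrichment, index = idx,
                 background = igraph::V(fx$network)$name)
  real <- solution_term_scores(recs, terms = idx$usable)
  positives <- real$term[!is.na(real$q) & real$q <= 0.05]
  rob <- robustness(fx$network, slices, fx$profile, idx,
                    positives = positives, fractions = c(0.6, 0.9),
                    n_iter = 10, seed = 7)
  expect_true(all(rob$recall >= 0 & rob$recall <= 1, na.rm = TRUE))
  expect_true(all(rob$aupr >= 0 & rob$aupr <= 1, na.rm = TRUE))
  # monotone trend within noise at desk scale
  expect_gte(rob$recall[rob$fraction == 0.9],
             rob$recall[rob$fraction == 0.6] - 0.15)
  # full-fraction sanity: subsampling nothing reproduces the positives
  rob1 <- robustness(fx$network, slices, fx$profile, idx,
                     positives = positives, fractions = 1.0,
                     n_iter = 1, seed = 7)
  expect_equal(rob1$recall, 1)
  expect_equal(rob1$precision, 1)
  expect_equal(rob1$f1, 1)
  # empty positive set: report undefined
  rob0 <- robustness(fx$network, slices, fx$profile, idx,
                     positives = character(), fractions = 0.9,
                     n_iter = 2, seed = 7)
  expect_true(is.na(rob0$f1))
})
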
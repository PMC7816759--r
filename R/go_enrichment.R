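# GO Biological Process enrichment of modules with the network as
# background: ontology/annotation ingestion (OBO + GAF), evidence-code
# exclusion, is_a/part_of up-propagation, the 5-500 gene usable-term filter,
# per-module hypergeometric tests and solution-level term scores.

DEFAULT_EXCLUDED_EVIDENCE <- c("IPI", "IEP", "IGI", "IMP", "HMP", "HGI", "HEP")

# Minimal OBO 1.2 reader: [Term] stanzas with id/name/namespace/is_a/
# relationship part_of/is_obsolete.  Returns a term table plus parent lists.
parse_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- which(trimws(lines) == "[Term]")
  if (length(starts) == 0) stop("no [Term] stanzas in OBO file: ", path)
  bounds <- c(starts, length(lines) + 1L)
  ids <- character(); names_ <- character(); ns <- character()
  obsolete <- logical(); isa <- list(); partof <- list()
  stanza_end <- function(block) {
    nxt <- grep("^\\[", trimws(block))
    if (length(nxt)) block[seq_len(nxt[1] - 1)] else block
  }
  for (s in seq_along(starts)) {
    block <- stanza_end(lines[(starts[s] + 1):(bounds[s + 1] - 1)])
    getf <- function(key) sub(paste0("^", key, ":\\s*"), "",
                              grep(paste0("^", key, ":"), block, value = TRUE))
    id <- getf("id")
    if (length(id) != 1) stop("OBO term stanza without a single id near line ",
                              starts[s])
    ids <- c(ids, id)
    nm <- getf("name"); names_ <- c(names_, if (length(nm)) nm[1] else NA_character_)
    n1 <- getf("namespace"); ns <- c(ns, if (length(n1)) n1[1] else NA_character_)
    obsolete <- c(obsolete, any(grepl("^is_obsolete:\\s*true", block)))
    isa[[id]] <- sub("\\s*!.*$", "", getf("is_a"))
    rel <- grep("^relationship:\\s*part_of\\s", block, value = TRUE)
    partof[[id]] <- sub("\\s*!.*$", "",
                        sub("^relationship:\\s*part_of\\s+", "", rel))
  }
  list(terms = data.frame(id = ids, name = names_, namespace = ns,
                          obsolete = obsolete, stringsAsFactors = FALSE),
       is_a = isa, part_of = partof)
}

# GAF 2.x reader.  Keeps db object id (col 2), qualifier (4), GO id (5),
# evidence code (7) and aspect (9); lines starting with '!' are comments.
parse_gaf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  if (length(lines) == 0) {
    return(data.frame(gene = character(), qualifier = character(),
                      term = character(), evidence = character(),
                      aspect = character(), stringsAsFactors = FALSE))
  }
  toks <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(toks) < 9)
  if (length(short)) stop("malformed GAF line (fewer than 9 columns): line ",
                          short[1])
  data.frame(gene = vapply(toks, `[[`, "", 2),
             qualifier = vapply(toks, `[[`, "", 4),
             term = vapply(toks, `[[`, "", 5),
             evidence = vapply(toks, `[[`, "", 7),
             aspect = vapply(toks, `[[`, "", 9),
             stringsAsFactors = FALSE)
}

# Shared index builder used by load_ontology() and the toy-ontology
# generator.  `parents` maps each term to its parent terms (is_a, plus
# part_of when enabled); `annotations` holds direct gene-term pairs.
build_ontology_index <- function(terms, parents, annotations,
                                 min_genes = 5, max_genes = 500) {
  ids <- terms$id
  parents <- lapply(setNames(ids, ids), function(t) {
    intersect(unique(parents[[t]]), ids)
  })
  # Kahn toposort; cycles are a structural error.
  indeg <- vapply(parents, length, 1L)
  children <- list()
  for (t in ids) for (p in parents[[t]]) children[[p]] <- c(children[[p]], t)
  queue <- ids[indeg == 0]
  topo <- character()
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    topo <- c(topo, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0) queue <- c(queue, ch)
    }
  }
  if (length(topo) != length(ids)) stop("ontology DAG contains a cycle")
  roots <- ids[vapply(parents, length, 1L) == 0]
  # ancestors (proper, excluding self), memoized along topological order
  ancestors <- setNames(vector("list", length(ids)), ids)
  for (t in topo) {
    anc <- parents[[t]]
    for (p in parents[[t]]) anc <- union(anc, ancestors[[p]])
    ancestors[[t]] <- anc
  }
  annotations <- annotations[annotations$term %in% ids &
                               nzchar(annotations$gene), , drop = FALSE]
  gene_sets <- setNames(vector("list", length(ids)), ids)
  if (nrow(annotations)) {
    up <- lapply(seq_len(nrow(annotations)), function(i) {
      t <- annotations$term[i]
      data.frame(gene = annotations$gene[i], term = c(t, ancestors[[t]]),
                 stringsAsFactors = FALSE)
    })
    up <- do.call(rbind, up)
    by_term <- split(up$gene, up$term)
    for (t in names(by_term)) gene_sets[[t]] <- sort(unique(by_term[[t]]))
  }
  gene_sets <- lapply(gene_sets, function(g) if (is.null(g)) character() else g)
  n_genes <- vapply(gene_sets, length, 1L)
  corpus <- sort(unique(annotations$gene))
  ic <- ifelse(n_genes > 0, -log(n_genes / length(corpus)), Inf)
  usable <- ids[n_genes >= min_genes & n_genes <= max_genes]
  structure(list(terms = terms, parents = parents, ancestors = ancestors,
                 genes = gene_sets, n_genes = n_genes,
                 ic = setNames(as.numeric(ic), ids),
                 corpus = corpus, roots = roots, usable = sort(usable)),
            class = "ontology_index")
}

#' Load a GO ontology and annotation corpus
#'
#' Reads an OBO 1.2 ontology and a GAF 2.x annotation file, keeps only the
#' requested namespace (Biological Process by default), drops NOT-qualified
#' annotation lines and lines with excluded evidence codes, up-propagates
#' annotations to ancestors via is_a (and, optionally, part_of), and marks
#' as *usable* the terms with 5-500 annotated genes after propagation.
#' Term information content is `-ln(n_genes(t) / n_corpus)` (nats), so the
#' root, annotated to the whole corpus, has IC 0.
#'
#' @param obo_path OBO ontology file.
#' @param gaf_path GAF annotation file.
#' @param excluded_codes evidence codes to drop (default IPI, IEP, IGI, IMP,
#'   HMP, HGI and HEP: annotations derived from physical interaction,
#'   expression pattern, genetic interaction or mutant phenotype, which
#'   would bias network-based enrichment).
#' @param include_part_of propagate across part_of relations within the
#'   namespace as well (default TRUE).
#' @param namespace ontology namespace to keep (default
#'   `"biological_process"`).
#' @param min_genes,max_genes usable-term size filter, computed on the full
#'   annotation corpus (defaults 5 and 500).
#' @return An `ontology_index`: term table, parent/ancestor lists,
#'   propagated gene sets, IC values, the annotation corpus and the usable
#'   term ids.
#' @export
load_ontology <- function(obo_path, gaf_path,
                          excluded_codes = DEFAULT_EXCLUDED_EVIDENCE,
                          include_part_of = TRUE,
                          namespace = "biological_process",
                          min_genes = 5, max_genes = 500) {
  obo <- parse_obo(obo_path)
  keep <- !obo$terms$obsolete & !is.na(obo$terms$namespace) &
    obo$terms$namespace == namespace
  if (!any(keep)) stop("no terms in namespace '", namespace, "'")
  terms <- obo$terms[keep, c("id", "name"), drop = FALSE]
  parents <- lapply(setNames(terms$id, terms$id), function(t) {
    p <- obo$is_a[[t]]
    if (include_part_of) p <- c(p, obo$part_of[[t]])
    p
  })
  ann <- parse_gaf(gaf_path)
  ann <- ann[ann$aspect == "P", , drop = FALSE]
  ann <- ann[!grepl("(^|\\|)NOT($|\\|)", ann$qualifier), , drop = FALSE]
  ann <- ann[!(ann$evidence %in% excluded_codes), , drop = FALSE]
  build_ontology_index(terms, parents, ann[, c("gene", "term")],
                       min_genes = min_genes, max_genes = max_genes)
}

#' @export
print.ontology_index <- function(x, ...) {
  cat("ontology_index:", nrow(x$terms), "terms (", length(x$usable),
      "usable ),", length(x$corpus), "annotated genes\n")
  invisible(x)
}

#' GO enrichment of one module
#'
#' Hypergeometric over-representation test of every usable term, with the
#' network's gene set as background: population = background, successes =
#' term genes on the background, draws = the module.  q-values are
#' BH-corrected across terms within the module.
#'
#' @param module character vector of gene ids (intersected with the
#'   background).
#' @param index an `ontology_index`.
#' @param background background gene set (the network's nodes).
#' @return Data frame sorted by p: `term`, `p`, `q`,
#'   `score` (`-log10(p)`), `k`, `K`, `n`, `N`.
#' @export
module_enrichment <- function(module, index, background) {
  module <- intersect(module, background)
  terms <- index$usable
  if (length(module) == 0 || length(terms) == 0) {
    return(data.frame(term = character(), p = numeric(), q = numeric(),
                      score = numeric(), k = integer(), K = integer(),
                      n = integer(), N = integer()))
  }
  N <- length(background)
  n <- length(module)
  K <- vapply(terms, function(t) length(intersect(index$genes[[t]], background)), 1L)
  k <- vapply(terms, function(t) length(intersect(index$genes[[t]], module)), 1L)
  p <- mapply(function(K, k) hypergeom_tail(N, K, n, k), K, k)
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(term = terms, p = p, q = q, score = -log10(p),
                    k = k, K = K, n = n, N = N, row.names = NULL)
  out[order(out$p, out$term), , drop = FALSE]
}

#' Solution-level term scores
#'
#' For every usable term, the solution's enrichment score is the maximum
#' `-log10(p)` over the solution's modules, and the retained q-value is the
#' minimum over modules.  Terms reported by no module score 0 (so that
#' permutation nulls are well defined for every term).
#'
#' @param records list of per-module enrichment tables from
#'   [module_enrichment()].
#' @param terms the universe of term ids (defaults to the union of terms in
#'   `records`); pass `index$usable` so empty solutions still yield a row
#'   per term.
#' @return Data frame `term`, `score`, `q` (q is NA for terms never
#'   reported).
#' @export
solution_term_scores <- function(records, terms = NULL) {
  if (is.null(terms)) {
    terms <- sort(unique(unlist(lapply(records, `[[`, "term"))))
  }
  score <- setNames(rep(0, length(terms)), terms)
  q <- setNames(rep(NA_real_, length(terms)), terms)
  for (rec in records) {
    idx <- match(rec$term, terms)
    ok <- !is.na(idx)
    score[idx[ok]] <- pmax(score[idx[ok]], rec$score[ok])
    q[idx[ok]] <- pmin(q[idx[ok]], rec$q[ok], na.rm = TRUE)
  }
  data.frame(term = terms, score = unname(score), q = unname(q),
             row.names = NULL)
}

#' Resnik semantic similarity of two terms
#'
#' Information content (nats) of the most informative common ancestor of
#' the two terms (a term counts among its own ancestors).  Terms without a
#' common ancestor have similarity 0.
#'
#' @param t1,t2 term ids present in the index.
#' @param index an `ontology_index`.
#' @return Similarity in nats; `sim(t, t) = IC(t)`.
#' @export
resnik_similarity <- function(t1, t2, index) {
  stopifnot(t1 %in% names(index$ancestors), t2 %in% names(index$ancestors))
  common <- intersect(c(t1, index$ancestors[[t1]]),
                      c(t2, index$ancestors[[t2]]))
  common <- common[is.finite(index$ic[common])]
  if (length(common) == 0) return(0)
  max(index$ic[common])
}

#' Pairwise Resnik similarity matrix
#'
#' @param terms term ids.
#' @param index an `ontology_index`.
#' @return Symmetric matrix with `sim(t, t) = IC(t)` on the diagonal.
#' @export
similarity_matrix <- function(terms, index) {
  n <- length(terms)
  m <- matrix(0, n, n, dimnames = list(terms, terms))
  for (i in seq_len(n)) {
    for (j in i:n) {
      s <- resnik_similarity(terms[i], terms[j], index)
      m[i, j] <- s; m[j, i] <- s
    }
  }
  m
}
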
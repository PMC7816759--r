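# Seeded generators for planted-community networks, activity profiles and
# toy ontologies, so every pipeline stage is testable without external
# downloads.  Generator defaults define the reference study conditions used
# throughout the test-suite and the acceptance script.

#' Generate a stochastic-block-model gene network
#'
#' Communities are planted with within-block edge probability `p_in` and
#' between-block probability `p_out`; nodes are relabeled with synthetic
#' gene ids (`g0001`, ...).  By default every block's induced subgraph must
#' be connected (so planted modules are valid connected ground truth); the
#' draw is retried up to `max_retries` times, then errors.
#'
#' @param n_nodes total number of nodes.
#' @param n_communities number of equal-size blocks (`n_nodes` must be
#'   divisible evenly enough; remainders go to the last block).
#' @param p_in,p_out within/between edge probabilities (`p_in > p_out`).
#' @param seed RNG seed.
#' @param connected_blocks require each block to induce a connected
#'   subgraph (default TRUE).
#' @param max_retries retry bound for the connectivity requirement.
#' @return List with `network` (igraph) and `labels` (named integer
#'   community membership).
#' @export
make_network <- function(n_nodes, n_communities, p_in, p_out, seed = 42,
                         connected_blocks = TRUE, max_retries = 50) {
  stopifnot(p_in > p_out, n_communities >= 1, n_nodes >= n_communities)
  base <- n_nodes %/% n_communities
  sizes <- rep(base, n_communities)
  sizes[n_communities] <- sizes[n_communities] + n_nodes - sum(sizes)
  pref <- matrix(p_out, n_communities, n_communities)
  diag(pref) <- p_in
  ids <- sprintf("g%04d", seq_len(n_nodes))
  labels <- setNames(rep(seq_len(n_communities), sizes), ids)
  draw <- function() {
    g <- igraph::sample_sbm(n_nodes, pref.matrix = pref, block.sizes = sizes)
    igraph::V(g)$name <- ids
    g
  }
  g <- with_seed(seed, {
    for (try in seq_len(max_retries)) {
      g <- draw()
      if (!connected_blocks) break
      ok <- all(vapply(seq_len(n_communities), function(c) {
        igraph::is_connected(igraph::induced_subgraph(g, ids[labels == c]))
      }, TRUE))
      if (ok) break
      g <- NULL
    }
    if (is.null(g)) stop("could not draw connected blocks in ", max_retries,
                         " attempts; raise p_in or the retry bound")
    g
  })
  list(network = g, labels = labels)
}

#' Generate an activity profile with planted signal
#'
#' Genes in the planted sets draw their q-value from `Uniform(0,
#' q_active_max)` with probability `signal_rate`; all other genes (and
#' non-signal planted genes) draw from `Uniform(0, 1)`.  p-values are set
#' equal to q-values, so the fixture does not re-derive an FDR correction.
#' With an empty planted set the profile is a pure null.
#'
#' @param network the gene network (profiles cover its nodes).
#' @param planted character vector (or list of vectors) of planted genes.
#' @param q_active_max upper bound of the signal q-values (default 0.01,
#'   comfortably under the 0.05 activity threshold).
#' @param signal_rate probability that a planted gene carries signal
#'   (default 0.8).
#' @param seed RNG seed.
#' @return An [activity_profile()].
#' @export
make_activity <- function(network, planted = character(),
                          q_active_max = 0.01, signal_rate = 0.8,
                          seed = 42) {
  genes <- igraph::V(network)$name
  planted <- unique(unlist(planted))
  with_seed(seed, {
    q <- stats::runif(length(genes))
    pl <- which(genes %in% planted)
    hit <- pl[stats::runif(length(pl)) <= signal_rate]
    q[hit] <- stats::runif(length(hit), 0, q_active_max)
    activity_profile(genes, q, q)
  })
}

#' Generate a toy ontology aligned with planted communities
#'
#' Builds a small is_a DAG — one root, two branch terms, one leaf term per
#' community plus background leaves — with direct annotations: each
#' community leaf is annotated to `coverage` of its community's genes plus
#' a few random noise genes (topped up to the usable-term minimum of 5);
#' background leaves get random gene samples.  The root accumulates the
#' whole corpus through up-propagation, hence has information content 0.
#'
#' @param labels named community membership (from [make_network()]).
#' @param n_background_terms number of background leaf terms (default 5).
#' @param seed RNG seed.
#' @param coverage fraction of each community annotated to its leaf
#'   (default 0.9).
#' @param n_noise_genes random extra genes per community leaf (default 2).
#' @param background_size_range size range of background leaves
#'   (default 10-30).
#' @return List of class `toy_ontology`: `index` (an `ontology_index`),
#'   `truth` (data frame community -> aligned term), `terms`, `parents`,
#'   `annotations` (the raw DAG and direct annotations, reused by the OBO/
#'   GAF writers).
#' @export
make_ontology <- function(labels, n_background_terms = 5, seed = 42,
                          coverage = 0.9, n_noise_genes = 2,
                          background_size_range = c(10, 30)) {
  genes <- names(labels)
  comms <- sort(unique(labels))
  tid <- function(k) sprintf("GO:9%06d", k)
  root <- tid(0)
  branch_comm <- tid(1); branch_bg <- tid(2)
  terms <- data.frame(
    id = c(root, branch_comm, branch_bg),
    name = c("synthetic biological process root",
             "community-aligned processes", "background processes"),
    stringsAsFactors = FALSE)
  parents <- list()
  parents[[root]] <- character()
  parents[[branch_comm]] <- root
  parents[[branch_bg]] <- root
  ann <- list()
  truth <- data.frame(community = integer(), term = character())
  with_seed(seed, {
    for (c in comms) {
      t <- tid(10 + c)
      terms <- rbind(terms, data.frame(id = t,
                                        name = sprintf("community %d process", c)))
      parents[[t]] <- branch_comm
      members <- genes[labels == c]
      core <- sample(members, max(1, round(coverage * length(members))))
      noise <- sample(setdiff(genes, members), n_noise_genes)
      set <- unique(c(core, noise))
      if (length(set) < 5) {
        set <- unique(c(set, sample(setdiff(genes, set), 5 - length(set))))
      }
      ann[[length(ann) + 1L]] <- data.frame(gene = set, term = t)
      truth <- rbind(truth, data.frame(community = c, term = t))
    }
    for (b in seq_len(n_background_terms)) {
      t <- tid(500 + b)
      terms <- rbind(terms, data.frame(id = t,
                                        name = sprintf("background process %d", b)))
      parents[[t]] <- branch_bg
      sz <- sample(background_size_range[1]:background_size_range[2], 1)
      ann[[length(ann) + 1L]] <- data.frame(gene = sample(genes, sz), term = t)
    }
    # anchor the corpus: annotate every gene directly to the root so IC is
    # well defined for all genes and the root covers the corpus
    ann[[length(ann) + 1L]] <- data.frame(gene = genes, term = root)
  })
  annotations <- do.call(rbind, ann)
  index <- build_ontology_index(terms, parents, annotations)
  structure(list(index = index, truth = truth, terms = terms,
                 parents = parents, annotations = annotations),
            class = "toy_ontology")
}

#' Write a toy ontology as OBO 1.2 / GAF 2.1 text
#'
#' The written pair round-trips through [load_ontology()] (annotations are
#' emitted with evidence code IDA, aspect P).
#'
#' @param onto a `toy_ontology`.
#' @param obo_path,gaf_path output paths.
#' @export
write_toy_obo <- function(onto, obo_path) {
  out <- c("format-version: 1.2", "ontology: synthetic-bp", "")
  for (i in seq_len(nrow(onto$terms))) {
    id <- onto$terms$id[i]
    out <- c(out, "[Term]",
             paste0("id: ", id),
             paste0("name: ", onto$terms$name[i]),
             "namespace: biological_process",
             vapply(onto$parents[[id]], function(p) paste0("is_a: ", p), ""),
             "")
  }
  writeLines(out, obo_path)
  invisible(obo_path)
}

#' @rdname write_toy_obo
#' @export
write_toy_gaf <- function(onto, gaf_path) {
  a <- onto$annotations
  lines <- paste("SYN", a$gene, a$gene, "", a$term, "SYN:0000001", "IDA", "",
                 "P", "", "", "protein", "taxon:0000", "20200101", "SYN", "", "",
                 sep = "\t")
  writeLines(c("!gaf-version: 2.1", lines), gaf_path)
  invisible(gaf_path)
}

#' Build the default planted fixture
#'
#' The reference test-bed: a 500-node SBM network of 25 communities of 20
#' nodes (`p_in = 0.3`, `p_out = 0.001`), one planted community whose genes
#' carry activity signal at rate 0.8 against a 5% active background, and a
#' toy ontology with one leaf term aligned to each community.  With
#' `signal_rate = 0` the fixture is a pure null.
#'
#' @param seed master seed (default 42); network, activity and ontology
#'   derive their own sub-seeds from it.
#' @param n_nodes,n_communities,p_in,p_out network parameters.
#' @param n_planted number of planted communities (default 1).
#' @param signal_rate,q_active_max activity parameters.
#' @return List of class `planted_fixture`: `network`, `labels`, `planted`
#'   (list of node sets), `profile`, `ontology` (a `toy_ontology`),
#'   `truth_terms` (term ids aligned with planted communities).
#' @export
make_planted_fixture <- function(seed = 42, n_nodes = 500,
                                 n_communities = 25, p_in = 0.3,
                                 p_out = 0.001, n_planted = 1,
                                 signal_rate = 0.8, q_active_max = 0.01) {
  net <- make_network(n_nodes, n_communities, p_in, p_out,
                      seed = derive_seed(seed, 1))
  planted_comms <- seq_len(n_planted)
  planted <- lapply(planted_comms, function(c) {
    names(net$labels)[net$labels == c]
  })
  profile <- make_activity(net$network, planted,
                           q_active_max = q_active_max,
                           signal_rate = signal_rate,
                           seed = derive_seed(seed, 2))
  onto <- make_ontology(net$labels, seed = derive_seed(seed, 3))
  truth_terms <- onto$truth$term[match(planted_comms, onto$truth$community)]
  structure(list(network = net$network, labels = net$labels,
                 planted = planted, profile = profile, ontology = onto,
                 truth_terms = truth_terms, seed = seed),
            class = "planted_fixture")
}

#' @describeIn make_planted_fixture pure-null variant (no planted signal).
#' @export
make_null_fixture <- function(seed = 42, ...) {
  make_planted_fixture(seed = seed, n_planted = 1, signal_rate = 0, ...)
}
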
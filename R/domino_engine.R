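# Steps 1-3 of the pipeline: slice relevance detection, sub-slice
# extraction, Newman-Girvan repartition of large non-significant sub-slices,
# and the final Bonferroni-gated module selection.

#' Pipeline parameters
#'
#' All thresholds of the module-detection pipeline are inclusive (`<=`),
#' applied uniformly.
#'
#' @param active_q q-value cutoff flagging active genes (default 0.05).
#' @param theta linear-threshold activation threshold (default 0.5).
#' @param epsilon PCST penalty offset; non-free edges cost `1 - epsilon`
#'   (default 1e-4).
#' @param relevance_q lenient FDR cutoff accepting a slice as relevant
#'   (default 0.3).
#' @param final_q Bonferroni cutoff for final modules (default 0.05).
#' @param ng_max_size sub-slices larger than this that fail the
#'   mid-pipeline over-representation check are repartitioned (default 10).
#' @param active_fraction_floor slice testability floor: fraction of all
#'   network-active genes a slice must hold (default 0.1).
#' @param subslice_p raw hypergeometric p cutoff of the mid-pipeline
#'   over-representation check (default 0.05).
#' @return A list of class `domino_params`.
#' @export
domino_params <- function(active_q = 0.05, theta = 0.5, epsilon = 1e-4,
                          relevance_q = 0.3, final_q = 0.05,
                          ng_max_size = 10, active_fraction_floor = 0.1,
                          subslice_p = 0.05) {
  stopifnot(relevance_q > 0, relevance_q <= 1, theta > 0, epsilon > 0,
            epsilon < 1, final_q > 0, ng_max_size >= 1,
            active_fraction_floor >= 0, active_fraction_floor <= 1)
  structure(list(active_q = active_q, theta = theta, epsilon = epsilon,
                 relevance_q = relevance_q, final_q = final_q,
                 ng_max_size = ng_max_size,
                 active_fraction_floor = active_fraction_floor,
                 subslice_p = subslice_p),
            class = "domino_params")
}

#' Minimum active fraction for slice testability
#'
#' `alpha = min(0.7, (n_active / n_nodes) * (1 + 100 / n_nodes))`.
#' Slices with only a few active nodes are excluded from relevance testing
#' so they do not dilute the FDR correction.
#'
#' @param n_active_network number of active genes on the network.
#' @param n_nodes_network number of network nodes (> 0).
#' @return The fraction alpha in `[0, 0.7]`.
#' @export
compute_alpha <- function(n_active_network, n_nodes_network) {
  stopifnot(n_nodes_network > 0)
  min(0.7, (n_active_network / n_nodes_network) *
        (1 + 100 / n_nodes_network))
}

#' Is a slice testable for relevance?
#'
#' A slice enters the relevance test if it holds at least
#' `active_fraction_floor` of all network-active genes, or its own active
#' fraction is at least [compute_alpha()].
#'
#' @param slice character vector of slice nodes.
#' @param active network-active gene set.
#' @param n_active_network,n_nodes_network network-wide counts.
#' @param active_fraction_floor floor on the share of all active genes
#'   (default 0.1).
#' @return Logical.
#' @export
slice_testable <- function(slice, active, n_active_network, n_nodes_network,
                           active_fraction_floor = 0.1) {
  if (n_active_network == 0) return(FALSE)
  n_in <- length(intersect(slice, active))
  alpha <- compute_alpha(n_active_network, n_nodes_network)
  (n_in / n_active_network >= active_fraction_floor) ||
    (n_in / length(slice) >= alpha)
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` from a
#' population of `N` containing `K` successes.
#'
#' @param N population size; @param K successes in the population;
#' @param n draws; @param k observed successes.
#' @return The tail p-value.
#' @export
hypergeom_tail <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || k > n || n > N || k > K || K > N) {
    stop("hypergeom_tail: bounds violated (need 0 <= k <= n <= N, k <= K <= N)")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Detect relevant slices
#'
#' Testable slices (see [slice_testable()]) receive a hypergeometric tail
#' p-value for active-gene over-representation (population = network nodes,
#' successes = network-active genes, draws = slice size); p-values are
#' BH-corrected across testable slices only and slices with
#' `q <= relevance_q` are kept.
#'
#' @param slices a `slice_set`.
#' @param active network-active gene set.
#' @param n_nodes_network number of network nodes.
#' @param params a [domino_params()].
#' @return Data frame with one row per slice: `slice` (index), `size`,
#'   `n_active`, `testable`, `p`, `q`, `relevant`.
#' @export
detect_relevant_slices <- function(slices, active, n_nodes_network,
                                   params = domino_params()) {
  n_act <- length(active)
  size <- lengths(slices)
  n_in <- vapply(slices, function(s) length(intersect(s, active)), 1L)
  testable <- vapply(slices, slice_testable, TRUE, active = active,
                     n_active_network = n_act,
                     n_nodes_network = n_nodes_network,
                     active_fraction_floor = params$active_fraction_floor)
  p <- rep(NA_real_, length(slices))
  q <- rep(NA_real_, length(slices))
  if (any(testable)) {
    p[testable] <- mapply(function(sz, k) hypergeom_tail(n_nodes_network, n_act, sz, k),
                          size[testable], n_in[testable])
    q[testable] <- stats::p.adjust(p[testable], method = "BH")
  }
  data.frame(slice = seq_along(slices), size = size, n_active = n_in,
             testable = testable, p = p, q = q,
             relevant = !is.na(q) & q <= params$relevance_q)
}

#' Newman-Girvan repartition of a sub-slice
#'
#' Iteratively removes the edge of maximum betweenness centrality
#' (recomputed after every removal; ties broken by lexicographic edge
#' order).  After each removal the modularity `M_i` of the partition induced
#' by the current connected components is evaluated on the original
#' sub-slice graph, and the loop stops as soon as
#' `log(n_subslice) / log(n_nodes_network) <= M_i`.  If all edges are
#' removed without meeting the criterion, the singleton components are
#' returned.
#'
#' @param subgraph the sub-slice's induced subgraph (connected).
#' @param n_nodes_network number of nodes of the whole network.
#' @return List of character vectors (the parts).
#' @export
ng_partition <- function(subgraph, n_nodes_network) {
  n_sub <- igraph::vcount(subgraph)
  stopifnot(n_sub >= 2, n_nodes_network >= 2)
  threshold <- log(n_sub) / log(n_nodes_network)
  nodes <- igraph::V(subgraph)$name
  work <- subgraph
  repeat {
    if (igraph::ecount(work) == 0) {
      message("Newman-Girvan criterion never met; returning singletons")
      return(as.list(nodes))
    }
    eb <- igraph::edge_betweenness(work, directed = FALSE)
    cand <- which(eb >= max(eb) - 1e-10)
    if (length(cand) > 1) {
      el <- igraph::as_edgelist(work, names = TRUE)[cand, , drop = FALSE]
      lab <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
      cand <- cand[order(lab)][1]
    }
    work <- igraph::delete_edges(work, cand[1])
    memb <- igraph::components(work)$membership
    m_i <- igraph::modularity(subgraph, memb[nodes])
    if (threshold <= m_i) {
      return(unname(split(nodes, memb[nodes])))
    }
  }
}

#' Run the module-detection pipeline
#'
#' Executes steps 1-3 on a sliced network: relevant-slice detection,
#' PCST refinement of each relevant slice into a sub-slice, Newman-Girvan
#' repartition of sub-slices that have more than `ng_max_size` nodes and
#' fail a lenient (raw `p <= subslice_p`) over-representation check, and the
#' final strict test in which each putative module's hypergeometric p-value
#' is Bonferroni-corrected by the number of putative modules and kept at
#' `q <= final_q`.  Final modules are sorted by q, then decreasing size,
#' then lexicographically.  The whole run is deterministic.
#'
#' @param network the gene network (igraph).
#' @param slices a `slice_set` built from the same network.
#' @param profile an [activity_profile()].
#' @param params a [domino_params()].
#' @return A `domino_solution`: list with `modules` (list of sorted gene-id
#'   vectors), `stats` (per-module data frame with size, active count, HG p
#'   and Bonferroni q), `diagnostics` (per-stage counts), `params`,
#'   `n_active`, `n_nodes`.
#' @export
run_domino <- function(network, slices, profile, params = domino_params()) {
  n_nodes <- igraph::vcount(network)
  act <- active_set(profile, network, threshold = params$active_q)
  n_active <- length(act)
  diag <- list(n_slices = length(slices), n_active = n_active,
               n_testable = 0L, n_relevant = 0L,
               sub_slice_sizes = integer(), n_putative = 0L)
  empty <- function() {
    structure(list(modules = list(),
                   stats = data.frame(module = character(), size = integer(),
                                      n_active = integer(), p = numeric(),
                                      q = numeric()),
                   diagnostics = diag, params = unclass(params),
                   n_active = n_active, n_nodes = n_nodes),
              class = "domino_solution")
  }
  if (n_active == 0 || length(slices) == 0) return(empty())

  rel <- detect_relevant_slices(slices, act, n_nodes, params)
  diag$n_testable <- sum(rel$testable)
  diag$n_relevant <- sum(rel$relevant)
  if (!any(rel$relevant)) return(empty())

  sub_slices <- list()
  for (i in rel$slice[rel$relevant]) {
    sg <- igraph::induced_subgraph(network, slices[[i]])
    seeds <- intersect(slices[[i]], act)
    prop <- propagate_influence(sg, seeds, theta = params$theta)
    inst <- build_pcst_instance(sg, seeds, prop, n_active, n_nodes,
                                epsilon = params$epsilon)
    sub_slices[[length(sub_slices) + 1L]] <- solve_pcst(inst)$nodes
  }
  diag$sub_slice_sizes <- lengths(sub_slices)

  putative <- list()
  for (ss in sub_slices) {
    k <- length(intersect(ss, act))
    p_hg <- hypergeom_tail(n_nodes, n_active, length(ss), k)
    if (length(ss) > params$ng_max_size && p_hg > params$subslice_p) {
      parts <- ng_partition(igraph::induced_subgraph(network, ss), n_nodes)
      putative <- c(putative, parts)
    } else {
      putative <- c(putative, list(ss))
    }
  }
  diag$n_putative <- length(putative)
  if (length(putative) == 0) return(empty())

  p <- vapply(putative, function(m) {
    hypergeom_tail(n_nodes, n_active, length(m), length(intersect(m, act)))
  }, 1)
  q <- pmin(1, p * length(putative)) # Bonferroni over putative modules
  keep <- which(q <= params$final_q)
  if (length(keep) == 0) return(empty())

  mods <- lapply(putative[keep], sort)
  sizes <- lengths(mods)
  first_gene <- vapply(mods, `[`, "", 1)
  ord <- order(q[keep], -sizes, first_gene)
  mods <- mods[ord]
  stats <- data.frame(
    module = sprintf("module_%d", seq_along(mods)),
    size = sizes[ord],
    n_active = vapply(mods, function(m) length(intersect(m, act)), 1L),
    p = p[keep][ord],
    q = q[keep][ord])
  names(mods) <- stats$module
  structure(list(modules = mods, stats = stats, diagnostics = diag,
                 params = unclass(params), n_active = n_active,
                 n_nodes = n_nodes),
            class = "domino_solution")
}

#' @export
print.domino_solution <- function(x, ...) {
  cat("domino_solution:", length(x$modules), "final module(s);",
      x$n_active, "active of", x$n_nodes, "nodes\n")
  if (length(x$modules)) print(x$stats, row.names = FALSE)
  invisible(x)
}
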
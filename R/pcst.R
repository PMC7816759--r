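# Step 2a machinery: linear-threshold influence propagation to assign node
# prizes, and a prize-collecting Steiner tree (PCST) solver to extract the
# most active connected core (sub-slice) of a relevant slice.

#' Linear-threshold influence propagation within a slice
#'
#' Synchronous iterations of the linear threshold model: the influence of a
#' node with degree `k` on each of its neighbors is `1/k` (degrees taken
#' within the slice subgraph, where propagation runs).  An inactive node
#' activates at the first iteration where the summed influence of its
#' currently active neighbors strictly exceeds `theta`; activated nodes stay
#' active; the process stops when no new node activates.
#'
#' @param subgraph the slice's induced subgraph (igraph).
#' @param seeds character vector of input-active nodes (must lie in the
#'   subgraph).
#' @param theta activation threshold (default 0.5, strict `>`).
#' @return Named integer vector of activation iterations: 0 for seeds,
#'   positive for propagation-activated nodes; never-activated nodes are
#'   absent.
#' @export
propagate_influence <- function(subgraph, seeds, theta = 0.5) {
  nodes <- igraph::V(subgraph)$name
  if (!all(seeds %in% nodes)) stop("seeds must be nodes of the subgraph")
  deg <- igraph::degree(subgraph)
  adj <- igraph::as_adj_list(subgraph)
  adj <- lapply(adj, function(v) v$name)
  level <- setNames(rep(NA_integer_, length(nodes)), nodes)
  level[seeds] <- 0L
  l <- 0L
  repeat {
    l <- l + 1L
    active <- names(level)[!is.na(level)]
    inactive <- names(level)[is.na(level)]
    if (length(inactive) == 0) break
    newly <- character()
    for (v in inactive) {
      nb <- intersect(adj[[v]], active)
      if (length(nb) && sum(1 / deg[nb]) > theta) newly <- c(newly, v)
    }
    if (length(newly) == 0) break
    level[newly] <- l
  }
  level[!is.na(level)]
}

#' Build a PCST instance for a slice
#'
#' Node prizes follow the influence-propagation decay `p(v) = beta^l` for a
#' node activated at iteration `l` (seeds get `beta^0 = 1`) and 0 for nodes
#' never activated, with decay base
#' `beta = max(0, 1 - 3 * n_active_network / n_nodes_network)`.
#' Edge penalties are 0 for edges incident to an input-active (seed) node
#' and `1 - epsilon` otherwise.
#'
#' @param subgraph the slice's induced subgraph.
#' @param seeds input-active nodes within the slice.
#' @param propagation result of [propagate_influence()] on this subgraph.
#' @param n_active_network,n_nodes_network network-wide active and total
#'   node counts (beta is a property of the whole dataset, not the slice).
#' @param epsilon penalty offset (default 1e-4).
#' @return A `pcst_instance`: list with `graph`, named `prizes`, per-edge
#'   `costs` (ordered as `igraph::E(graph)`), `beta`, `epsilon`.
#' @export
build_pcst_instance <- function(subgraph, seeds, propagation,
                                n_active_network, n_nodes_network,
                                epsilon = 1e-4) {
  stopifnot(n_nodes_network > 0)
  beta <- max(0, 1 - 3 * n_active_network / n_nodes_network)
  nodes <- igraph::V(subgraph)$name
  prizes <- setNames(rep(0, length(nodes)), nodes)
  if (length(propagation)) {
    prizes[names(propagation)] <- beta^as.numeric(propagation)
  }
  el <- igraph::as_edgelist(subgraph, names = TRUE)
  touches_seed <- (el[, 1] %in% seeds) | (el[, 2] %in% seeds)
  costs <- ifelse(touches_seed, 0, 1 - epsilon)
  structure(list(graph = subgraph, prizes = prizes, costs = costs,
                 beta = beta, epsilon = epsilon),
            class = "pcst_instance")
}

#' Construct a PCST instance from explicit prizes and costs
#'
#' Low-level constructor used for testing the solver on arbitrary instances.
#'
#' @param graph igraph; @param prizes named non-negative node prizes;
#' @param costs non-negative per-edge costs ordered as `igraph::E(graph)`.
#' @return A `pcst_instance`.
#' @export
pcst_instance <- function(graph, prizes, costs) {
  nodes <- igraph::V(graph)$name
  stopifnot(all(nodes %in% names(prizes)),
            length(costs) == igraph::ecount(graph),
            all(prizes >= 0), all(costs >= 0))
  structure(list(graph = graph, prizes = prizes[nodes], costs = costs,
                 beta = NA_real_, epsilon = NA_real_),
            class = "pcst_instance")
}

# Prim MST cost of a supernode subset on a dense cost matrix (Inf = absent).
prim_cost <- function(C, S) {
  if (length(S) < 2) return(0)
  inT <- S[1]; out <- S[-1]
  total <- 0
  while (length(out)) {
    best <- Inf; bi <- 0L
    for (j in seq_along(out)) {
      d <- min(C[out[j], inT])
      if (d < best) { best <- d; bi <- j }
    }
    if (!is.finite(best)) return(Inf) # disconnected
    total <- total + best
    inT <- c(inT, out[bi]); out <- out[-bi]
  }
  total
}

# Exact optimum over connected supernode subsets via canonical
# branch-and-bound enumeration (minimum-index rule), with an upper bound
# that assumes every future supernode can be attached at the cheapest edge
# cost in the graph.
pcst_exact_super <- function(P, C) {
  k <- length(P)
  adj <- lapply(seq_len(k), function(i) which(is.finite(C[i, ])))
  cmin <- min(C[is.finite(C)])
  uniform <- {
    w <- C[is.finite(C)]
    max(w) - min(w) < 1e-12
  }
  best_obj <- max(P)
  best_set <- which.max(P)
  mst_of <- function(S) {
    if (uniform) (length(S) - 1) * cmin else prim_cost(C, S)
  }
  # upper bound on any extension of S: with uniform costs every future node
  # pays exactly cmin, so its net gain is max(0, P - cmin) on top of obj(S);
  # with general costs a future node can lower the spanning cost of S, so
  # only the (always non-negative) MST term may be dropped from the bound.
  gain <- if (uniform) pmax(0, P - cmin) else P
  bound <- function(obj_prize, S, allowed) {
    base <- if (uniform) obj_prize - mst_of(S) else obj_prize
    base + sum(gain[allowed])
  }
  recurse <- function(S, ext, allowed, obj_prize) {
    # S connected by construction; evaluate
    obj <- obj_prize - mst_of(S)
    if (obj > best_obj + 1e-12) {
      best_obj <<- obj; best_set <<- S
    }
    if (length(ext) == 0) return()
    if (bound(obj_prize, S, allowed) <= best_obj + 1e-12) return()
    while (length(ext)) {
      u <- ext[1]; ext <- ext[-1]
      allowed_u <- setdiff(allowed, u)
      new_nb <- setdiff(adj[[u]], c(S, ext, u))
      new_nb <- intersect(new_nb, allowed_u)
      recurse(c(S, u), c(ext, new_nb), allowed_u, obj_prize + P[u])
      allowed <- allowed_u # exclude u from all later branches
      if (bound(obj_prize, S, allowed) <= best_obj + 1e-12) return()
    }
  }
  for (v0 in seq_len(k)) {
    allowed <- (seq_len(k))[seq_len(k) > v0]
    recurse(v0, intersect(adj[[v0]], allowed), allowed, P[v0])
  }
  list(set = sort(best_set), objective = best_obj)
}

# Greedy heuristic for larger contracted instances: every supernode starts
# as its own candidate tree; repeatedly merge the pair of adjacent trees
# whose cheapest connecting edge yields the largest positive improvement of
# the better tree's objective.
pcst_greedy_super <- function(P, edges) {
  k <- length(P)
  ea <- as.integer(edges$a); eb <- as.integer(edges$b)
  root <- seq_len(k)
  find <- function(i) { while (root[i] != i) i <- root[i]; i }
  obj <- P
  repeat {
    ra <- vapply(ea, find, 1L)
    rb <- vapply(eb, find, 1L)
    live <- ra != rb
    if (!any(live)) break
    merged <- obj[ra] + obj[rb] - edges$w
    gain <- merged - pmax(obj[ra], obj[rb])
    gain[!live] <- -Inf
    bi <- which.max(gain)
    if (gain[bi] <= 1e-12) break
    i <- ra[bi]; j <- rb[bi]
    root[j] <- i
    obj[i] <- merged[bi]
  }
  roots <- vapply(seq_len(k), find, 1L)
  best_root <- roots[which.max(obj[roots])]
  list(set = sort(which(roots == best_root)), objective = obj[best_root])
}

#' Solve a prize-collecting Steiner tree instance
#'
#' Maximizes `sum(prizes in T) - sum(costs of edges in T)` over connected
#' subtrees `T` of the instance graph.  Zero-cost edges are first contracted
#' into supernodes (sound because prizes are non-negative); on the
#' contracted graph the solver is exact (branch-and-bound over connected
#' supernode subsets) up to `exact_limit` supernodes and falls back to a
#' greedy tree-merging heuristic above that.  Always returns at least the
#' best single node.
#'
#' @param instance a `pcst_instance`.
#' @param exact_limit maximum contracted size for the exact search
#'   (default 12).
#' @return List with `nodes` (sorted gene ids of a connected node set) and
#'   `objective`.
#' @export
solve_pcst <- function(instance, exact_limit = 12L) {
  g <- instance$graph
  nodes <- igraph::V(g)$name
  if (length(nodes) == 0) stop("PCST instance over an empty graph")
  prizes <- instance$prizes[nodes]
  costs <- instance$costs
  el <- igraph::as_edgelist(g, names = TRUE)
  zero <- costs <= 1e-12
  gz <- igraph::graph_from_data_frame(
    data.frame(from = el[zero, 1], to = el[zero, 2], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  memb <- igraph::components(gz)$membership[nodes]
  k <- max(memb)
  P <- as.numeric(tapply(prizes, memb, sum))
  members <- split(nodes, memb)

  pick <- function(set, objective) {
    list(nodes = sort(unlist(members[set], use.names = FALSE)),
         objective = unname(objective))
  }
  if (!any(!zero)) return(pick(which.max(P), max(P)))

  a <- memb[el[!zero, 1]]; b <- memb[el[!zero, 2]]; w <- costs[!zero]
  inter <- a != b
  if (!any(inter)) return(pick(which.max(P), max(P)))
  a <- a[inter]; b <- b[inter]; w <- w[inter]
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi)
  wmin <- tapply(w, key, min)
  first <- !duplicated(key)
  sedges <- data.frame(a = lo[first], b = hi[first],
                       w = as.numeric(wmin[key[first]]))

  if (k <= exact_limit) {
    C <- matrix(Inf, k, k)
    C[cbind(sedges$a, sedges$b)] <- sedges$w
    C[cbind(sedges$b, sedges$a)] <- sedges$w
    res <- pcst_exact_super(P, C)
  } else {
    res <- pcst_greedy_super(P, sedges)
  }
  pick(res$set, res$objective)
}
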
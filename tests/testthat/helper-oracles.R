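# Independent oracles and small graph builders shared across the suite.
# The oracles deliberately use different algorithms (and data structures)
# than the package implementation they validate.

# --- hypergeometric oracles -------------------------------------------------

# upper-tail probability from the combinatorial identity
hyper_tail_formula <- function(N, K, n, k) {
  js <- seq(k, min(n, K))
  if (k > min(n, K)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# brute-force enumeration over all C(N, n) draws (tiny N only)
hyper_tail_enumerate <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k) # successes = items 1..K
}

# --- PCST oracle -------------------------------------------------------------

# Exact PCST optimum by exhaustive enumeration of connected node subsets of
# the raw graph (bitmask connectivity DP).  Spanning cost: for the binary
# {0, c} penalty scheme, c * (#free-edge components - 1); for general
# penalties (tiny n only) a Kruskal MST per subset.
pcst_oracle <- function(graph, prizes, costs) {
  n <- igraph::vcount(graph)
  stopifnot(n <= 14)
  nodes <- igraph::V(graph)$name
  el <- igraph::as_edgelist(graph, names = FALSE)
  p <- as.numeric(prizes[nodes])
  nb <- integer(n)   # all-edge neighbor bitmasks
  fnb <- integer(n)  # zero-cost-edge neighbor bitmasks
  for (e in seq_len(nrow(el))) {
    i <- el[e, 1]; j <- el[e, 2]
    nb[i] <- bitwOr(nb[i], bitwShiftL(1L, j - 1L))
    nb[j] <- bitwOr(nb[j], bitwShiftL(1L, i - 1L))
    if (costs[e] <= 1e-12) {
      fnb[i] <- bitwOr(fnb[i], bitwShiftL(1L, j - 1L))
      fnb[j] <- bitwOr(fnb[j], bitwShiftL(1L, i - 1L))
    }
  }
  pos <- costs[costs > 1e-12]
  binary <- length(pos) == 0 || (max(pos) - min(pos)) < 1e-12
  cpos <- if (length(pos)) pos[1] else 0
  bit <- bitwShiftL(1L, seq_len(n) - 1L)
  nmask <- sum(bit)
  bits_of <- function(mask) which(bitwAnd(mask, bit) != 0L)
  # connectivity DP: a multi-node set is connected iff some member can be
  # removed leaving a connected set it is adjacent to
  conn <- logical(nmask)
  conn[bit] <- TRUE
  ord <- order(vapply(seq_len(nmask), function(m) sum(bitwAnd(m, bit) != 0L), 1L))
  for (m in ord) {
    if (conn[m]) next
    vs <- bits_of(m)
    if (length(vs) < 2) next
    for (v in vs) {
      rest <- bitwAnd(m, bitwNot(bit[v]))
      if (conn[rest] && bitwAnd(nb[v], rest) != 0L) { conn[m] <- TRUE; break }
    }
  }
  free_components <- function(mask) {
    k <- 0L
    while (mask != 0L) {
      k <- k + 1L
      r <- bitwAnd(mask, -mask) # lowest bit
      repeat {
        grow <- r
        for (v in bits_of(r)) grow <- bitwOr(grow, bitwAnd(fnb[v], mask))
        if (grow == r) break
        r <- grow
      }
      mask <- bitwAnd(mask, bitwNot(r))
    }
    k
  }
  kruskal_cost <- function(mask) {
    vs <- bits_of(mask)
    comp <- setNames(seq_along(vs), vs)
    inmask <- bitwAnd(bit[el[, 1]], mask) != 0L & bitwAnd(bit[el[, 2]], mask) != 0L
    es <- which(inmask)[order(costs[which(inmask)])]
    total <- 0
    for (e in es) {
      a <- as.character(el[e, 1]); b <- as.character(el[e, 2])
      if (comp[a] != comp[b]) {
        total <- total + costs[e]
        comp[comp == comp[b]] <- comp[a]
      }
    }
    total
  }
  best <- -Inf; best_mask <- 0L
  for (m in seq_len(nmask)) {
    if (!conn[m]) next
    vs <- bits_of(m)
    cost <- if (binary) cpos * (free_components(m) - 1L) else kruskal_cost(m)
    obj <- sum(p[vs]) - cost
    if (obj > best + 1e-12) { best <- obj; best_mask <- m }
  }
  list(objective = best, nodes = sort(nodes[bits_of(best_mask)]))
}

# random PCST instance with the {0, 1 - eps} penalty scheme
random_pcst_instance <- function(seed, n_min = 6, n_max = 12, eps = 1e-4) {
  set.seed(seed)
  n <- sample(n_min:n_max, 1)
  repeat {
    g <- igraph::sample_gnp(n, 0.35)
    if (igraph::ecount(g) >= 1) break
  }
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
  seeds <- igraph::V(g)$name[runif(n) < 0.3]
  prizes <- setNames(runif(n), igraph::V(g)$name)
  el <- igraph::as_edgelist(g, names = TRUE)
  costs <- ifelse(el[, 1] %in% seeds | el[, 2] %in% seeds, 0, 1 - eps)
  list(instance = pcst_instance(g, prizes, costs),
       graph = g, prizes = prizes, costs = costs)
}

# --- graph builders ----------------------------------------------------------

# two k-cliques joined by a single bridge edge
clique_pair <- function(k, prefix = c("a", "b")) {
  ids <- lapply(prefix, function(p) sprintf("%s%02d", p, seq_len(k)))
  edges <- do.call(rbind, lapply(ids, function(v) t(utils::combn(v, 2))))
  edges <- rbind(edges, c(ids[[1]][1], ids[[2]][1]))
  igraph::graph_from_data_frame(as.data.frame(edges), directed = FALSE)
}

# named Erdos-Renyi graph
named_gnp <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("n%03d", seq_len(n))
  g
}

# path graph over the given node names
path_graph <- function(nodes) {
  igraph::graph_from_data_frame(
    data.frame(from = nodes[-length(nodes)], to = nodes[-1]),
    directed = FALSE)
}

# star: center plus leaves
star_graph <- function(center, leaves) {
  igraph::graph_from_data_frame(
    data.frame(from = center, to = leaves), directed = FALSE)
}

write_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# small planted fixture used by several suites (cheaper than the default)
small_fixture <- function(seed = 11) {
  make_planted_fixture(seed = seed, n_nodes = 200, n_communities = 10,
                       p_in = 0.35, p_out = 0.002)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
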
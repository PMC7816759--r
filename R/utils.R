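#' @keywords internal
"_PACKAGE"

#' @importFrom stats p.adjust phyper runif setNames
#' @importFrom utils head modifyList
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Derive a per-task seed from a master seed
#'
#' Deterministic mixing of a master seed with a task index, used so that
#' permutation `i` of an empirical-pipeline run gets its own seed and the
#' result is independent of execution order or worker count.  Always returns
#' a positive integer below 2^31.
#'
#' @param master master seed (single integer).
#' @param index task index (single non-negative integer).
#' @return An integer seed.
#' @export
derive_seed <- function(master, index) {
  m <- as.double(master) %% 2147483647
  i <- as.double(index) %% 2147483647
  s <- (m * 48271 + i * 16807 + 12345) %% 2147483629
  as.integer(s + 1)
}

# Canonical md5 fingerprint of a network: sorted node names plus sorted
# unordered edge pairs.  Used to tie cached slice files to their network.
network_fingerprint <- function(network) {
  stopifnot(igraph::is_igraph(network))
  el <- igraph::as_edgelist(network, names = TRUE)
  pairs <- if (nrow(el)) {
    sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "\t"))
  } else character()
  tf <- tempfile(fileext = ".fp")
  on.exit(unlink(tf))
  writeLines(c(sort(igraph::V(network)$name), pairs), tf)
  unname(tools::md5sum(tf))
}

# Jaccard index between two sets of gene ids.
jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(NA_real_)
  length(intersect(a, b)) / u
}
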
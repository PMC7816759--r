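# Step 0 of the pipeline: one-time partitioning of the network into
# disjoint, highly connected "slices", cached to a text file so the
# (comparatively expensive) partition is reused across datasets.

#' Partition a network into slices
#'
#' Runs resolution-parameterized Louvain community detection (generalized
#' modularity with a multiplier on the expected-edge term; low resolution
#' favors large communities).  Each community's induced subgraph is
#' decomposed into connected components and every component with at least
#' `min_slice_size` nodes becomes a slice.  Slices are computed on the
#' unweighted topology even if edge weights were read (weights only matter
#' for filtering at read time).
#'
#' @param network the gene network (igraph).
#' @param resolution Louvain resolution parameter `r > 0` (default 0.15).
#' @param min_slice_size minimum number of nodes in a slice (default 4,
#'   i.e. components of more than three nodes).
#' @param seed seed for the Louvain node-visit order; recorded in the slice
#'   cache header for reproducibility.
#' @return A `slice_set`: list of character vectors of gene ids with
#'   attributes `fingerprint`, `seed` and `resolution`.
#' @export
build_slices <- function(network, resolution = 0.15, min_slice_size = 4,
                         seed = 42) {
  stopifnot(resolution > 0)
  if (igraph::vcount(network) == 0) stop("cannot slice an empty network")
  comm <- with_seed(seed,
    igraph::cluster_louvain(network, weights = NA, resolution = resolution))
  memb <- igraph::membership(comm)
  slices <- list()
  for (cid in sort(unique(memb))) {
    sub <- igraph::induced_subgraph(network, names(memb)[memb == cid])
    cmp <- igraph::components(sub)
    for (k in seq_len(cmp$no)) {
      nodes <- names(cmp$membership)[cmp$membership == k]
      if (length(nodes) >= min_slice_size) {
        slices[[length(slices) + 1L]] <- sort(nodes)
      }
    }
  }
  if (length(slices) == 0) warning("network produced zero slices")
  slices <- slices[order(vapply(slices, `[`, "", 1))]
  structure(slices,
            fingerprint = network_fingerprint(network),
            seed = as.integer(seed), resolution = as.numeric(resolution),
            class = "slice_set")
}

#' Write a slice set to its cache file
#'
#' Header lines record the source-network fingerprint, the seed and the
#' resolution; then one slice per line, tab-separated gene ids.
#'
#' @param slices a `slice_set` from [build_slices()].
#' @param path output path.
#' @export
write_slices <- function(slices, path) {
  hdr <- c(
    paste0("#network_fingerprint=", attr(slices, "fingerprint")),
    paste0("#seed=", attr(slices, "seed")),
    paste0("#resolution=", attr(slices, "resolution"))
  )
  body <- vapply(slices, function(s) paste(s, collapse = "\t"), "")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a cached slice set
#'
#' @param path slice cache file written by [write_slices()].
#' @param network optional network to validate against; a fingerprint
#'   mismatch emits a warning (the cache is then likely stale).
#' @return A `slice_set`.
#' @export
read_slices <- function(path, network = NULL) {
  if (!file.exists(path)) stop("slice file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  field <- function(name) {
    ln <- hdr[startsWith(hdr, paste0("#", name, "="))]
    if (length(ln) != 1) stop("corrupted slice file (missing ", name, "): ", path)
    sub(paste0("^#", name, "="), "", ln)
  }
  fp <- field("network_fingerprint")
  seed <- suppressWarnings(as.integer(field("seed")))
  res <- suppressWarnings(as.numeric(field("resolution")))
  if (is.na(seed) || is.na(res)) stop("corrupted slice file header: ", path)
  slices <- lapply(body, function(l) strsplit(l, "\t", fixed = TRUE)[[1]])
  if (any(lengths(slices) == 0)) stop("corrupted slice file (empty slice line): ", path)
  if (!is.null(network) && !identical(fp, unname(network_fingerprint(network)))) {
    warning("slice file fingerprint does not match the supplied network")
  }
  structure(slices, fingerprint = fp, seed = seed, resolution = res,
            class = "slice_set")
}

#' @export
print.slice_set <- function(x, ...) {
  cat("slice_set:", length(x), "slices, sizes",
      if (length(x)) paste(range(lengths(x)), collapse = "-") else "-",
      "\n  resolution", attr(x, "resolution"), "seed", attr(x, "seed"), "\n")
  invisible(x)
}
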
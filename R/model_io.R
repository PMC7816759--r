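# Readers, writers and core containers: gene networks, activity profiles,
# module files.  Gene identifiers are opaque strings and are never remapped;
# the network, the score table and the annotation corpus are expected to
# share one identifier namespace.

#' Read an undirected gene interaction network
#'
#' Accepts 2-column edge lists (`a<TAB>b`), 3-column weighted edge lists
#' (`a<TAB>b<TAB>weight`) and the SIF dialect (`a interaction b`, detected by
#' a non-numeric middle token).  Self-loops are removed and duplicate edges
#' are collapsed regardless of orientation.  Gzip-compressed files are read
#' transparently.
#'
#' @param path path to the network file.
#' @param min_edge_weight optional confidence cutoff; edges with weight less
#'   than or equal to this value are dropped before deduplication (strict
#'   `weight > min_edge_weight` retention, matching the usual treatment of
#'   STRING confidence scores).
#' @return An undirected [igraph::igraph] with a `name` vertex attribute and,
#'   for weighted input, a `weight` edge attribute (maximum weight of the
#'   collapsed duplicates).
#' @export
read_network <- function(path, min_edge_weight = NULL) {
  if (!file.exists(path)) stop("network file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) stop("empty network file: ", path)
  toks <- strsplit(trimws(lines), "[\t ]+")
  nf <- lengths(toks)
  bad <- which(nf < 2 | nf > 3)
  if (length(bad)) {
    stop("malformed network line ", lineno[bad[1]], ": '", lines[bad[1]], "'")
  }
  from <- vapply(toks, `[[`, "", 1)
  to <- character(length(toks))
  weight <- rep(NA_real_, length(toks))
  for (i in seq_along(toks)) {
    tk <- toks[[i]]
    if (nf[i] == 2) {
      to[i] <- tk[2]
    } else {
      w <- suppressWarnings(as.numeric(tk[3]))
      if (!is.na(w)) { # weighted edge list
        to[i] <- tk[2]
        weight[i] <- w
      } else {         # SIF: a <interaction-type> b
        to[i] <- tk[3]
      }
    }
  }
  if (!is.null(min_edge_weight)) {
    drop <- !is.na(weight) & weight <= min_edge_weight
    from <- from[!drop]; to <- to[!drop]; weight <- weight[!drop]
  }
  loop <- from == to
  from <- from[!loop]; to <- to[!loop]; weight <- weight[!loop]
  if (length(from) == 0) stop("network has no edges after filtering: ", path)
  a <- pmin(from, to); b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  first <- !duplicated(key)
  g <- igraph::graph_from_data_frame(
    data.frame(from = a[first], to = b[first], stringsAsFactors = FALSE),
    directed = FALSE
  )
  if (any(!is.na(weight))) {
    wmax <- tapply(weight, key, function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
    igraph::E(g)$weight <- as.numeric(wmax[key[first]])
  }
  g
}

#' Write a network edge list
#'
#' Tab-separated, two columns, plus a weight column when the graph carries
#' edge weights.  [read_network()] on the output reproduces the graph.
#'
#' @param network an igraph network.
#' @param path output path.
#' @export
write_network <- function(network, path) {
  el <- igraph::as_edgelist(network, names = TRUE)
  if ("weight" %in% igraph::edge_attr_names(network)) {
    lines <- paste(el[, 1], el[, 2], format(igraph::E(network)$weight, trim = TRUE),
                   sep = "\t")
  } else {
    lines <- paste(el[, 1], el[, 2], sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Construct an activity profile
#'
#' An activity profile records, per gene, a raw p-value and an FDR q-value
#' from an upstream omics analysis (differential expression, gene-level GWAS
#' association, ...).  Genes with `qval <= activity_threshold` form the
#' binary active set consumed by the module-detection pipeline.
#'
#' @param gene character vector of gene ids (unique).
#' @param pval p-values in `[0, 1]`.
#' @param qval q-values in `[0, 1]`; when `NULL`, Benjamini-Hochberg q-values
#'   are computed over all listed genes.
#' @param activity_threshold q-value cutoff defining active genes
#'   (inclusive; default 0.05).
#' @return A `data.frame` of class `activity_profile` with columns `gene`,
#'   `pval`, `qval` and an `activity_threshold` attribute.
#' @export
activity_profile <- function(gene, pval, qval = NULL, activity_threshold = 0.05) {
  gene <- as.character(gene)
  if (anyDuplicated(gene)) stop("duplicate gene ids in activity profile")
  pval <- as.numeric(pval)
  if (length(pval) != length(gene)) stop("gene/pval length mismatch")
  if (any(is.na(pval)) || any(pval < 0 | pval > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  if (is.null(qval)) {
    qval <- stats::p.adjust(pval, method = "BH")
  } else {
    qval <- as.numeric(qval)
    if (any(is.na(qval)) || any(qval < 0 | qval > 1)) {
      stop("q-values must lie in [0, 1]")
    }
    if (any(qval < pval)) {
      warning(sum(qval < pval),
              " gene(s) have q-value < p-value; check the score table")
    }
  }
  out <- data.frame(gene = gene, pval = pval, qval = qval,
                    stringsAsFactors = FALSE)
  attr(out, "activity_threshold") <- activity_threshold
  class(out) <- c("activity_profile", "data.frame")
  out
}

#' Read a per-gene activity score table
#'
#' Expects a delimited table with a header and columns gene id, p-value and
#' (optionally) q-value, in that order.  Missing q-values are filled in with
#' Benjamini-Hochberg correction over all listed genes.
#'
#' @param path path to the score table.
#' @param activity_threshold q-value cutoff stored on the profile.
#' @return An [activity_profile()].
#' @export
read_activity <- function(path, activity_threshold = 0.05) {
  if (!file.exists(path)) stop("activity file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("activity table needs at least gene and p-value columns")
  qv <- if (ncol(tab) >= 3) as.numeric(tab[[3]]) else NULL
  activity_profile(tab[[1]], as.numeric(tab[[2]]), qv,
                   activity_threshold = activity_threshold)
}

#' Write an activity score table
#'
#' @param profile an [activity_profile()].
#' @param path output path.
#' @export
write_activity <- function(profile, path) {
  utils::write.table(
    data.frame(gene = profile$gene, pval = profile$pval, qval = profile$qval),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Active gene set of a profile on a network
#'
#' Genes with q-value at or below the activity threshold, intersected with
#' the network's node set.  Scored genes absent from the network are dropped
#' with a logged count (they still participate in score permutation, see
#' [permute_profile()]).
#'
#' @param profile an [activity_profile()].
#' @param network the gene network (igraph).
#' @param threshold q-value cutoff; defaults to the profile's
#'   `activity_threshold` attribute.
#' @return Character vector of active gene ids present in the network.
#' @export
active_set <- function(profile, network,
                       threshold = attr(profile, "activity_threshold")) {
  if (is.null(threshold)) threshold <- 0.05
  act <- profile$gene[profile$qval <= threshold]
  on_net <- intersect(act, igraph::V(network)$name)
  n_off <- length(act) - length(on_net)
  if (n_off > 0) {
    message(n_off, " active gene(s) absent from the network were dropped")
  }
  on_net
}

#' Write the modules of a solution
#'
#' One module per line, tab-separated gene ids, plus (optionally) a JSON
#' report with per-module statistics and pipeline diagnostics.
#'
#' @param solution a `domino_solution` (see [run_domino()]).
#' @param path path of the modules text file.
#' @param report_path optional path for the JSON report.
#' @export
write_modules <- function(solution, path, report_path = NULL) {
  lines <- vapply(solution$modules, function(m) paste(sort(m), collapse = "\t"), "")
  writeLines(lines, path)
  if (!is.null(report_path)) {
    rep <- list(
      n_modules = length(solution$modules),
      modules = lapply(solution$modules, sort),
      stats = solution$stats,
      diagnostics = solution$diagnostics,
      params = solution$params
    )
    jsonlite::write_json(rep, report_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read a modules file
#'
#' @param path modules file written by [write_modules()].
#' @return List of character vectors of gene ids (empty list for an empty
#'   file).
#' @export
read_modules <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]])
}
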
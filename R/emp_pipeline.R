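# The EMpirical Pipeline (EMP): permutation null distributions of
# per-GO-term enrichment scores, empirical significance, empirically
# validated (EV) terms and the empirical-to-hypergeometric ratio (EHR).

#' Permute an activity profile
#'
#' Reassigns the (p, q) score records to gene ids by a uniform random
#' permutation over *all* scored genes — including genes absent from the
#' network, so the number of active genes that land on the network varies
#' across permutations, as it does when scores are shuffled dataset-wide.
#' The multiset of score pairs is preserved.
#'
#' @param profile an [activity_profile()].
#' @return A permuted [activity_profile()] with the same threshold.
#' @export
permute_profile <- function(profile) {
  idx <- sample.int(nrow(profile))
  activity_profile(profile$gene, profile$pval[idx], profile$qval[idx],
                   activity_threshold = attr(profile, "activity_threshold"))
}

# One permutation/real run: detection + enrichment + solution-level scores
# over the usable-term universe.  Returns a named numeric vector of scores
# (0 for terms no module reports) plus the per-term best q as an attribute.
solution_scores <- function(network, slices, profile, index, params) {
  sol <- run_domino(network, slices, profile, params)
  background <- igraph::V(network)$name
  records <- lapply(sol$modules, module_enrichment, index = index,
                    background = background)
  tab <- solution_term_scores(records, terms = index$usable)
  structure(setNames(tab$score, tab$term), q = setNames(tab$q, tab$term),
            n_modules = length(sol$modules))
}

#' Build per-term permutation null distributions
#'
#' Repeats `n_permutations` times: permute the activity scores, run the
#' detection pipeline, score every usable term by its maximal `-log10(p)`
#' over the permuted solution's modules (0 when no module reports it).
#' Each permutation derives its own seed from the master seed and its
#' index, so the null store is independent of execution order or worker
#' count.
#'
#' @param network,slices,profile,index,params as in [run_domino()] /
#'   [module_enrichment()].
#' @param n_permutations number of permutation runs (the reference protocol
#'   uses 5000; 100-1000 are practical desk-scale presets).
#' @param seed master seed.
#' @return A `null_distribution`: list with `scores` (terms x permutations
#'   matrix), `n_permutations`, `seed`.
#' @export
build_null <- function(network, slices, profile, index,
                       params = domino_params(), n_permutations = 100,
                       seed = 42) {
  stopifnot(n_permutations >= 1)
  terms <- index$usable
  scores <- matrix(0, nrow = length(terms), ncol = n_permutations,
                   dimnames = list(terms, NULL))
  for (i in seq_len(n_permutations)) {
    pp <- with_seed(derive_seed(seed, i), permute_profile(profile))
    s <- suppressMessages(solution_scores(network, slices, pp, index, params))
    scores[, i] <- s[terms]
  }
  structure(list(scores = scores, n_permutations = n_permutations,
                 seed = seed),
            class = "null_distribution")
}

#' Write / read a null-distribution store
#'
#' The store is a TSV matrix (terms x permutations) plus a JSON manifest
#' recording the seed and the number of permutations.
#'
#' @param null a `null_distribution`; @param dir store directory.
#' @export
write_null <- function(null, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(null$scores, file.path(dir, "null_scores.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  jsonlite::write_json(list(n_permutations = null$n_permutations,
                            seed = null$seed),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_null
#' @export
read_null <- function(dir) {
  m <- as.matrix(utils::read.delim(file.path(dir, "null_scores.tsv"),
                                   row.names = 1, check.names = FALSE))
  colnames(m) <- NULL
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"))
  structure(list(scores = m, n_permutations = mf$n_permutations,
                 seed = mf$seed),
            class = "null_distribution")
}

#' Empirical significance of an enrichment score
#'
#' `e(t) = 1 - F_t(s)` estimated as the fraction of null scores at least as
#' large as `s` (ties count as extreme, a conservative reading).  With
#' `plus_one = TRUE` the estimate is `(1 + count) / (n + 1)`, which never
#' returns an exact zero.
#'
#' @param s real enrichment score(s), `-log10(p)` scale.
#' @param null numeric vector of null scores for the term.
#' @param plus_one use the add-one estimator (default FALSE).
#' @return Empirical significance in `[0, 1]`.
#' @export
empirical_significance <- function(s, null, plus_one = FALSE) {
  stopifnot(length(null) >= 1)
  cnt <- vapply(s, function(x) sum(null >= x), 1)
  if (plus_one) (1 + cnt) / (length(null) + 1) else cnt / length(null)
}

#' Empirically validated terms and the EHR of a solution
#'
#' A term is an *HG term* if its best BH q-value on the real data is at or
#' below `hg_q`; it is an *EV term* if it is an HG term and its empirical
#' significance against the permutation null is at or below `emp_sig`.
#' The solution's EHR is `|EV| / |HG|`, reported as `NA` when no term
#' passes the HG test.
#'
#' @param real data frame from [solution_term_scores()] on the real data
#'   (columns `term`, `score`, `q`).
#' @param null a `null_distribution` over the same term universe.
#' @param hg_q HG q-value cutoff (default 0.05).
#' @param emp_sig empirical significance cutoff (default 0.05).
#' @param plus_one passed to [empirical_significance()].
#' @return An `emp_result`: list with `table` (per-term `term`, `score`,
#'   `q`, `e`, `hg_term`, `ev_term`), `ehr`, `ev_terms`, `hg_terms`.
#' @export
ev_terms <- function(real, null, hg_q = 0.05, emp_sig = 0.05,
                     plus_one = FALSE) {
  stopifnot(inherits(null, "null_distribution"))
  idx <- match(real$term, rownames(null$scores))
  if (any(is.na(idx))) stop("real scores contain terms absent from the null store")
  e <- vapply(seq_len(nrow(real)), function(i) {
    empirical_significance(real$score[i], null$scores[idx[i], ],
                           plus_one = plus_one)
  }, 1)
  hg <- !is.na(real$q) & real$q <= hg_q
  ev <- hg & e <= emp_sig
  tab <- data.frame(term = real$term, score = real$score, q = real$q, e = e,
                    hg_term = hg, ev_term = ev)
  ehr <- if (sum(hg) == 0) NA_real_ else sum(ev) / sum(hg)
  structure(list(table = tab, ehr = ehr,
                 ev_terms = tab$term[ev], hg_terms = tab$term[hg]),
            class = "emp_result")
}

#' @export
print.emp_result <- function(x, ...) {
  cat("emp_result:", length(x$hg_terms), "HG terms,", length(x$ev_terms),
      "EV terms; EHR =", format(x$ehr, digits = 4), "\n")
  invisible(x)
}

#' Run the full empirical pipeline on a dataset
#'
#' Convenience wrapper: builds the permutation null, runs the detection and
#' enrichment on the real data, and returns the EV/EHR summary together
#' with the real solution and its per-module enrichment tables.
#'
#' @inheritParams build_null
#' @param hg_q,emp_sig,plus_one passed to [ev_terms()].
#' @return List with `solution`, `module_records`, `real` (solution term
#'   scores), `null`, `emp` (an `emp_result`).
#' @export
run_emp <- function(network, slices, profile, index,
                    params = domino_params(), n_permutations = 100,
                    seed = 42, hg_q = 0.05, emp_sig = 0.05,
                    plus_one = FALSE) {
  null <- build_null(network, slices, profile, index, params,
                     n_permutations, seed)
  sol <- run_domino(network, slices, profile, params)
  background <- igraph::V(network)$name
  records <- lapply(sol$modules, module_enrichment, index = index,
                    background = background)
  real <- solution_term_scores(records, terms = index$usable)
  emp <- ev_terms(real, null, hg_q = hg_q, emp_sig = emp_sig,
                  plus_one = plus_one)
  list(solution = sol, module_records = records, real = real, null = null,
       emp = emp)
}
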
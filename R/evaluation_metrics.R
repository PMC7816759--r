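# Solution-evaluation criteria beyond the EHR: module-level EHR,
# biological richness after Resnik-similarity redundancy reduction,
# intra-module homogeneity, and robustness to gene subsampling.

#' Module-level EHR
#'
#' Per module, the ratio between the number of its EV terms and its HG
#' terms, where a module's HG terms are the terms passing the
#' hypergeometric test on that module and its EV terms are those of them
#' that were empirically validated at solution level.  Modules without HG
#' terms get `NA` and are excluded from ranking.
#'
#' @param records list of per-module enrichment tables
#'   ([module_enrichment()]).
#' @param ev_ids solution-level EV term ids ([ev_terms()]).
#' @param hg_q per-module HG q cutoff (default 0.05).
#' @return Named numeric vector of mEHR values (NA where undefined).
#' @export
module_ehr <- function(records, ev_ids, hg_q = 0.05) {
  v <- vapply(records, function(rec) {
    hg <- rec$term[!is.na(rec$q) & rec$q <= hg_q]
    if (length(hg) == 0) return(NA_real_)
    length(intersect(hg, ev_ids)) / length(hg)
  }, 1)
  if (is.null(names(v)) && length(v)) names(v) <- paste0("module_", seq_along(v))
  v
}

#' Top-k mean of module-level EHR
#'
#' Modules are ranked by mEHR (undefined values dropped) and, for each
#' `k = 1..k_max`, the mean over the `min(k, n)` top modules is reported.
#'
#' @param mehr named vector from [module_ehr()].
#' @param k_max largest k (default 20).
#' @return Numeric vector of length `k_max` (all NA when no module has a
#'   defined mEHR).
#' @export
mehr_top_k <- function(mehr, k_max = 20) {
  v <- sort(mehr[!is.na(mehr)], decreasing = TRUE)
  if (length(v) == 0) return(rep(NA_real_, k_max))
  vapply(seq_len(k_max), function(k) mean(v[seq_len(min(k, length(v)))]), 1)
}

#' Reduce a term set to non-redundant representatives
#'
#' Greedy redundancy reduction in the style of REVIGO's dispensability
#' procedure: while any pair of surviving terms has Resnik similarity above
#' the cutoff, take the most similar pair and drop the member with the
#' larger (worse) enrichment p-value; at equal p, drop the lower-IC (more
#' general) term.  The survivors have no pair above the cutoff.
#'
#' @param terms term ids.
#' @param p their best enrichment p-values (same order).
#' @param sim similarity matrix over at least these terms.
#' @param cutoff similarity cutoff (the reference sweep is 1.0-4.0).
#' @param ic optional named IC vector for the tie-break.
#' @return Character vector of surviving term ids.
#' @export
reduce_redundant <- function(terms, p, sim, cutoff, ic = NULL) {
  stopifnot(length(terms) == length(p))
  alive <- terms
  pv <- setNames(p, terms)
  while (length(alive) > 1) {
    s <- sim[alive, alive, drop = FALSE]
    diag(s) <- -Inf
    mx <- max(s)
    if (mx <= cutoff) break
    hit <- which(s >= mx - 1e-12, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    lab <- paste(alive[hit[, 1]], alive[hit[, 2]])
    pair <- alive[hit[order(lab)[1], ]]
    drop <- if (pv[pair[1]] > pv[pair[2]]) pair[1]
      else if (pv[pair[2]] > pv[pair[1]]) pair[2]
      else if (!is.null(ic) && ic[pair[1]] < ic[pair[2]]) pair[1]
      else pair[2]
    alive <- setdiff(alive, drop)
  }
  alive
}

#' Biological richness of a solution
#'
#' Number of non-redundant EV terms after [reduce_redundant()], swept over
#' similarity cutoffs.  Lower cutoffs merge more aggressively, so richness
#' is non-decreasing in the cutoff.
#'
#' @param ev_ids EV term ids.
#' @param p their best enrichment p-values.
#' @param sim similarity matrix.
#' @param cutoffs sweep (default `seq(1, 4, by = 0.5)`).
#' @param ic optional IC vector for tie-breaks.
#' @return Named numeric vector: richness per cutoff.
#' @export
biological_richness <- function(ev_ids, p, sim, cutoffs = seq(1, 4, by = 0.5),
                                ic = NULL) {
  vapply(setNames(cutoffs, format(cutoffs)), function(co) {
    length(reduce_redundant(ev_ids, p, sim, co, ic = ic))
  }, 1)
}

#' Intra-module homogeneity
#'
#' Build the complete GO graph over the solution's EV terms, weighted by
#' pairwise Resnik similarity, and delete edges below the cutoff.  A
#' module's score is its relative edge density: the fraction of surviving
#' edges among its own EV-term pairs, divided by the same fraction for the
#' whole solution.  Modules (or solutions) with fewer than two EV terms, or
#' a solution with no surviving edges, score 0.  The solution score is the
#' mean over modules.
#'
#' @param module_ev list of per-module EV term vectors (each module's HG
#'   terms intersected with the solution EV set).
#' @param solution_ev solution-level EV term ids.
#' @param sim similarity matrix covering the EV terms.
#' @param cutoff similarity cutoff.
#' @return List with `module_scores` and `solution_score`.
#' @export
intra_module_homogeneity <- function(module_ev, solution_ev, sim, cutoff) {
  zero <- list(module_scores = rep(0, length(module_ev)), solution_score = 0)
  n_s <- length(solution_ev)
  if (n_s < 2) return(zero)
  surv <- function(terms) {
    s <- sim[terms, terms, drop = FALSE]
    keep <- s >= cutoff
    (sum(keep) - length(terms)) / 2 # off-diagonal surviving pairs
  }
  dens <- function(terms) {
    n <- length(terms)
    if (n < 2) return(NA_real_)
    surv(terms) / choose(n, 2)
  }
  d_sol <- dens(solution_ev)
  if (d_sol == 0) return(zero)
  ms <- vapply(module_ev, function(tm) {
    tm <- intersect(tm, solution_ev)
    d <- dens(tm)
    if (is.na(d)) 0 else d / d_sol
  }, 1)
  list(module_scores = ms,
       solution_score = if (length(ms)) mean(ms) else 0)
}

#' Homogeneity sweep over similarity cutoffs
#'
#' @inheritParams intra_module_homogeneity
#' @param cutoffs sweep (default `seq(1, 4, by = 0.5)`).
#' @return Named numeric vector of solution scores per cutoff.
#' @export
homogeneity_sweep <- function(module_ev, solution_ev, sim,
                              cutoffs = seq(1, 4, by = 0.5)) {
  vapply(setNames(cutoffs, format(cutoffs)), function(co) {
    intra_module_homogeneity(module_ev, solution_ev, sim, co)$solution_score
  }, 1)
}

# precision/recall/F1 of a predicted term set against a positive set.
# Empty predictions: precision undefined (NA), recall 0, F1 0.
prf <- function(predicted, positives) {
  tp <- length(intersect(predicted, positives))
  precision <- if (length(predicted) == 0) NA_real_ else tp / length(predicted)
  recall <- if (length(positives) == 0) NA_real_ else tp / length(positives)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) 0
    else 2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

# Step-wise area under the precision-recall curve for terms ranked by
# detection frequency (descending; ties by term id), positives fixed:
# AP = sum over ranks of (R_i - R_{i-1}) * P_i.
aupr_from_frequency <- function(freq, positives) {
  freq <- freq[freq > 0]
  if (length(positives) == 0) return(NA_real_)
  if (length(freq) == 0) return(0)
  ord <- order(-freq, names(freq))
  hits <- names(freq)[ord] %in% positives
  tp <- cumsum(hits)
  prec <- tp / seq_along(tp)
  rec <- tp / length(positives)
  sum(diff(c(0, rec)) * prec)
}

#' Robustness of a solution to gene subsampling
#'
#' For each subsampling fraction, repeatedly retains a uniform random
#' fraction of the scored genes (non-sampled genes are treated as missing),
#' reruns detection and enrichment, and takes the run's HG terms (best BH q
#' at or below `hg_q`) as the predicted set.  Precision, recall and F1
#' against the full-run EV terms are averaged over iterations; AUPR is
#' computed over terms ranked by their detection frequency across the
#' iterations with the full-run EV terms as positives (step-wise summation,
#' no trapezoids).  The fraction of non-empty predictions (runs with at
#' least one HG term) is also reported.
#'
#' @param network,slices,profile,index,params as in [run_domino()].
#' @param positives full-run EV term ids (the gold standard).
#' @param fractions subsampling fractions (default 0.6, 0.7, 0.8, 0.9).
#' @param n_iter iterations per fraction (reference protocol: 100).
#' @param seed master seed; each (fraction, iteration) derives its own.
#' @param hg_q HG q cutoff for predictions (default 0.05).
#' @return A `robustness_report` data frame: one row per fraction with
#'   `fraction`, `precision`, `recall`, `f1`, `aupr`,
#'   `non_empty_fraction`; all NA when `positives` is empty.
#' @export
robustness <- function(network, slices, profile, index,
                       params = domino_params(), positives,
                       fractions = c(0.6, 0.7, 0.8, 0.9), n_iter = 100,
                       seed = 42, hg_q = 0.05) {
  undefined <- length(positives) == 0
  rows <- lapply(seq_along(fractions), function(fi) {
    f <- fractions[fi]
    stopifnot(f > 0, f <= 1)
    prfs <- matrix(NA_real_, nrow = n_iter, ncol = 3)
    freq <- setNames(rep(0, length(index$usable)), index$usable)
    non_empty <- 0L
    for (it in seq_len(n_iter)) {
      keep <- with_seed(derive_seed(seed, fi * 100003 + it),
                        sample.int(nrow(profile), round(f * nrow(profile))))
      sub <- activity_profile(profile$gene[keep], profile$pval[keep],
                              profile$qval[keep],
                              attr(profile, "activity_threshold"))
      s <- suppressMessages(
        solution_scores(network, slices, sub, index, params))
      qv <- attr(s, "q")
      predicted <- names(qv)[!is.na(qv) & qv <= hg_q]
      freq[predicted] <- freq[predicted] + 1
      if (length(predicted)) non_empty <- non_empty + 1L
      prfs[it, ] <- prf(predicted, positives)
    }
    data.frame(fraction = f,
               precision = if (undefined) NA_real_ else mean(prfs[, 1], na.rm = TRUE),
               recall = if (undefined) NA_real_ else mean(prfs[, 2]),
               f1 = if (undefined) NA_real_ else mean(prfs[, 3]),
               aupr = if (undefined) NA_real_ else aupr_from_frequency(freq / n_iter, positives),
               non_empty_fraction = non_empty / n_iter)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("robustness_report", "data.frame")
  out
}
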
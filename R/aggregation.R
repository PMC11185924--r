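# Rank aggregation: combine per-patient ranked drug lists into one consensus
# top-k list per subtype, minimizing the mean Spearman footrule distance with
# a Cross-Entropy Monte Carlo optimizer (with an exhaustive oracle for small
# universes).

new_consensus <- function(items, objective, k, converged, n_iterations, params = list()) {
  structure(list(items = items, objective = objective, k = as.integer(k),
                 converged = converged, n_iterations = as.integer(n_iterations),
                 params = params),
            class = "consensus_list")
}

#' @export
print.consensus_list <- function(x, ...) {
  cat(sprintf("<consensus_list> k = %d, objective = %.4g, %s after %d iteration(s)\n",
              x$k, x$objective,
              if (isTRUE(x$converged)) "converged" else "stopped", x$n_iterations))
  cat(paste(sprintf("%2d. %s", seq_along(x$items), x$items), collapse = "\n"), "\n")
  invisible(x)
}

#' Tidy a consensus list
#' @param x A `consensus_list`.
#' @param ... Unused.
#' @return A tibble with columns `rank`, `item`.
#' @export
tidy.consensus_list <- function(x, ...) {
  tibble::tibble(rank = seq_along(x$items), item = x$items)
}

#' One-row summary of a consensus list
#' @param x A `consensus_list`.
#' @param ... Unused.
#' @export
glance.consensus_list <- function(x, ...) {
  tibble::tibble(k = x$k, objective = x$objective, converged = x$converged,
                 n_iterations = x$n_iterations)
}

#' Extract per-owner ranked item lists from a score table
#'
#' @param scores A tibble from [score_cohort()] (columns `sample_id`,
#'   `drug_id`, `rank`).
#' @return A named list of character vectors, best drug first.
#' @export
ranked_lists_from_scores <- function(scores) {
  stopifnot(all(c("sample_id", "drug_id", "rank") %in% names(scores)))
  scores <- dplyr::arrange(scores, .data$sample_id, .data$rank)
  split(scores$drug_id, scores$sample_id)
}

#' Mean Spearman footrule distance of a candidate top-k list
#'
#' For each input ranking, the distance is the sum over the union of the
#' candidate and that ranking's top-k of `|position in candidate - position in
#' input|`, where an item absent from a top-k list takes position `k + 1`.
#' The objective is the mean distance across input lists; it is zero iff the
#' candidate reproduces every input list's top-k exactly.
#'
#' @param candidate Character vector of k items (ordered, best first).
#' @param input_lists List of character vectors (full or truncated rankings,
#'   best first).
#' @param k Consensus length; defaults to `length(candidate)`.
#' @return Non-negative number.
#' @export
footrule_objective <- function(candidate, input_lists, k = length(candidate)) {
  if (anyDuplicated(candidate)) abort("`candidate` must not contain duplicates.")
  dists <- vapply(input_lists, function(lst) {
    top <- lst[seq_len(min(k, length(lst)))]
    union_items <- union(candidate, top)
    pos_c <- match(union_items, candidate)
    pos_c[is.na(pos_c)] <- k + 1L
    pos_l <- match(union_items, top)
    pos_l[is.na(pos_l)] <- k + 1L
    sum(abs(pos_c - pos_l))
  }, numeric(1))
  mean(dists)
}

#' Cross-Entropy Monte Carlo rank aggregation
#'
#' Maintains an (universe x k) column-stochastic probability matrix,
#' initialized uniform. Each iteration samples `n_samples` candidate k-lists
#' without replacement from the matrix, evaluates [footrule_objective()],
#' re-estimates the matrix from the position frequencies of the best
#' `rho` fraction (the elite), and smooths:
#' `P_new = w * P_elite + (1 - w) * P_old`. Stops after `max_iterations`, or
#' after `tolerance` consecutive iterations without improvement of the
#' best-ever objective. The best-ever candidate is then polished with a
#' deterministic transposition/exchange local search (which can only improve
#' the objective) and returned.
#'
#' @param input_lists List of character vectors (rankings, best first); all
#'   lists must share one item universe.
#' @param k Length of the consensus list.
#' @param n_samples Candidates per iteration (default `10 * universe size`).
#' @param rho Elite fraction in (0, 1), default 0.1.
#' @param smoothing Smoothing weight `w` in (0, 1], default 0.7.
#' @param max_iterations Iteration cap, default 200.
#' @param tolerance Iterations without improvement before stopping,
#'   default 15.
#' @param seed Optional seed; the optimization is deterministic given it.
#' @return A `consensus_list`.
#' @export
ce_aggregate <- function(input_lists, k, n_samples = NULL, rho = 0.1,
                         smoothing = 0.7, max_iterations = 200L,
                         tolerance = 15L, seed = NULL) {
  if (length(input_lists) == 0L) abort("Need at least one input list.")
  universe <- sort(unique(unlist(input_lists, use.names = FALSE)))
  n <- length(universe)
  if (k > n) abort(sprintf("k = %d exceeds the item universe (%d items).", k, n))
  if (!(rho > 0 && rho < 1)) abort("`rho` must be in (0, 1).")
  if (!(smoothing > 0 && smoothing <= 1)) abort("`smoothing` must be in (0, 1].")
  maybe_set_seed(seed)
  n_samples <- as.integer(n_samples %||% (10L * n))
  n_elite <- max(1L, ceiling(rho * n_samples))

  # pre-truncate inputs to their top-k and precompute integer positions
  tops <- lapply(input_lists, function(lst) match(universe, lst[seq_len(min(k, length(lst)))]))
  tops <- lapply(tops, function(p) { p[is.na(p)] <- k + 1L; p })
  objective_int <- function(cand_idx) {
    pos_c <- rep.int(k + 1L, n)
    pos_c[cand_idx] <- seq_len(k)
    tot <- 0
    for (p in tops) {
      in_union <- pos_c <= k | p <= k
      tot <- tot + sum(abs(pos_c[in_union] - p[in_union]))
    }
    tot / length(tops)
  }

  # deterministic first-improvement local search on a candidate: position
  # transpositions plus replacement of a kept item by an unused one. The CE
  # matrix can collapse prematurely onto a near-optimal order (e.g. one
  # adjacent transposition off); polishing the best-ever candidate removes
  # those residues and never worsens the objective.
  polish <- function(idx) {
    repeat {
      improved <- FALSE
      cur <- objective_int(idx)
      for (i in seq_len(k - 1L)) {
        for (j in seq.int(i + 1L, k)) {
          cand <- idx
          cand[c(i, j)] <- cand[c(j, i)]
          o <- objective_int(cand)
          if (o < cur - 1e-12) {
            idx <- cand
            cur <- o
            improved <- TRUE
          }
        }
      }
      for (i in seq_len(k)) {
        for (u in setdiff(seq_len(n), idx)) {
          cand <- idx
          cand[i] <- u
          o <- objective_int(cand)
          if (o < cur - 1e-12) {
            idx <- cand
            cur <- o
            improved <- TRUE
          }
        }
      }
      if (!improved) return(idx)
    }
  }

  P <- matrix(1 / n, nrow = n, ncol = k)
  best_idx <- NULL
  best_obj <- Inf
  stall <- 0L
  iter <- 0L
  converged <- FALSE
  while (iter < max_iterations) {
    iter <- iter + 1L
    cands <- matrix(0L, nrow = n_samples, ncol = k)
    objs <- numeric(n_samples)
    for (b in seq_len(n_samples)) {
      avail <- rep.int(TRUE, n)
      idx <- integer(k)
      for (j in seq_len(k)) {
        pr <- P[, j] * avail
        s <- sum(pr)
        if (s <= 0) pr <- avail / sum(avail) else pr <- pr / s
        pick <- sample.int(n, 1L, prob = pr)
        idx[j] <- pick
        avail[pick] <- FALSE
      }
      cands[b, ] <- idx
      objs[b] <- objective_int(idx)
    }
    elite <- order(objs)[seq_len(n_elite)]
    if (objs[elite[1L]] < best_obj) {
      best_obj <- objs[elite[1L]]
      best_idx <- cands[elite[1L], ]
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= tolerance) { converged <- TRUE; break }
    }
    P_elite <- matrix(0, nrow = n, ncol = k)
    for (b in elite) {
      P_elite[cbind(cands[b, ], seq_len(k))] <- P_elite[cbind(cands[b, ], seq_len(k))] + 1
    }
    P_elite <- P_elite / n_elite
    P <- smoothing * P_elite + (1 - smoothing) * P
    if (best_obj == 0) { converged <- TRUE; break }
  }
  best_idx <- polish(best_idx)
  best_obj <- objective_int(best_idx)
  new_consensus(universe[best_idx], best_obj, k, converged, iter,
                params = list(n_samples = n_samples, rho = rho,
                              smoothing = smoothing,
                              max_iterations = max_iterations,
                              tolerance = tolerance, seed = seed))
}

#' Exhaustive rank aggregation (test oracle)
#'
#' Enumerates every ordered k-list over the item universe and returns the
#' global optimum of [footrule_objective()], ties broken lexicographically.
#' Guarded to at most `max_candidates` enumerated lists.
#'
#' @inheritParams ce_aggregate
#' @param max_candidates Enumeration guard (default 1e6).
#' @return A `consensus_list` with the global optimum.
#' @export
exhaustive_aggregate <- function(input_lists, k, max_candidates = 1e6) {
  universe <- sort(unique(unlist(input_lists, use.names = FALSE)))
  n <- length(universe)
  if (k > n) abort(sprintf("k = %d exceeds the item universe (%d items).", k, n))
  n_cand <- prod(seq.int(n, n - k + 1L))
  if (n_cand > max_candidates) {
    abort(sprintf("Enumeration of %.3g ordered %d-lists exceeds the guard (%.3g); use ce_aggregate().",
                  n_cand, k, max_candidates))
  }
  tops <- lapply(input_lists, function(lst) match(universe, lst[seq_len(min(k, length(lst)))]))
  tops <- lapply(tops, function(p) { p[is.na(p)] <- k + 1L; p })
  objective_int <- function(cand_idx) {
    pos_c <- rep.int(k + 1L, n)
    pos_c[cand_idx] <- seq_len(k)
    tot <- 0
    for (p in tops) {
      in_union <- pos_c <= k | p <= k
      tot <- tot + sum(abs(pos_c[in_union] - p[in_union]))
    }
    tot / length(tops)
  }
  best_obj <- Inf
  best_idx <- NULL
  n_eval <- 0L
  # depth-first enumeration in lexicographic order; strict improvement keeps
  # the lexicographically first optimum
  idx <- integer(k)
  used <- rep.int(FALSE, n)
  recurse <- function(depth) {
    if (depth > k) {
      n_eval <<- n_eval + 1L
      obj <- objective_int(idx)
      if (obj < best_obj) { best_obj <<- obj; best_idx <<- idx[seq_len(k)] }
      return(invisible(NULL))
    }
    for (i in seq_len(n)) {
      if (!used[i]) {
        idx[depth] <<- i
        used[i] <<- TRUE
        recurse(depth + 1L)
        used[i] <<- FALSE
      }
    }
  }
  recurse(1L)
  new_consensus(universe[best_idx], best_obj, k, TRUE, 1L,
                params = list(method = "exhaustive", n_evaluated = n_eval))
}

#' Consensus of the worst drugs (bottom-k aggregation)
#'
#' Reverses every input ranking and aggregates, yielding the consensus of the
#' drugs found at the bottom of the per-patient lists (a useful negative-control
#' list).
#'
#' @inheritParams ce_aggregate
#' @param k Length of the bottom consensus (default 50).
#' @param ... Passed on to [ce_aggregate()].
#' @export
aggregate_bottom <- function(input_lists, k = 50L, ...) {
  ce_aggregate(lapply(input_lists, rev), k = k, ...)
}

#' Subtype-specific and shared drugs between two consensus lists
#'
#' @param consensus_a,consensus_b `consensus_list` objects (or plain character
#'   vectors).
#' @return A list with `only_a`, `only_b`, `shared`, each preserving consensus
#'   order (shared drugs in `consensus_a`'s order).
#' @export
subtype_specific <- function(consensus_a, consensus_b) {
  a <- if (inherits(consensus_a, "consensus_list")) consensus_a$items else consensus_a
  b <- if (inherits(consensus_b, "consensus_list")) consensus_b$items else consensus_b
  list(only_a = setdiff(a, b), only_b = setdiff(b, a), shared = intersect(a, b))
}
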
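#' Control settings for the stepwise regime search
#'
#' The forward and backward phases fit many candidate paintings per step.
#' Candidates are ranked on the profile likelihood evaluated over the alpha
#' grid (the grid is shared across candidates, so tree decompositions are
#' reused); the winning candidate is then refit with full refinement of
#' alpha before the acceptance test against the incumbent, keeping the
#' accepted-AICc trace on a single, fully optimized objective.  Set
#' `candidate_refine = TRUE` to refine every candidate instead (slower,
#' same tie-breaking rules).
#'
#' @param candidate_refine refine alpha for every candidate, not only the
#'   grid winner.
#' @param aicc_tol ties in candidate AICc closer than this are broken
#'   deterministically (smallest postorder edge index for shifts, sorted
#'   label pair for merges).
#' @param rank_grid number of log-spaced alpha points used when ranking
#'   candidates (the winner is always refit on the full grid with
#'   refinement before the acceptance test).
#' @param max_steps cap on accepted forward shifts (default unlimited).
#'   Truncation can only raise the search AICc, so capped searches remain
#'   conservative in model comparisons.
#' @param max_merges cap on accepted backward merges (default unlimited).
#' @param ... overrides for the underlying [fit_ou()] control.
#' @return a control list.
#' @export
search_control <- function(candidate_refine = FALSE, aicc_tol = 1e-6,
                           rank_grid = 24L, max_steps = Inf,
                           max_merges = Inf, ...) {
  c(list(candidate_refine = candidate_refine, aicc_tol = aicc_tol,
         rank_grid = rank_grid, max_steps = max_steps,
         max_merges = max_merges),
    utils::modifyList(default_fit_control(), list(...)))
}

# AICc of a candidate painting for ranking purposes: coarse-grid profile
# likelihood only, no parameter extraction
candidate_aicc <- function(cache, painting, x, ctl) {
  if (isTRUE(ctl$candidate_refine)) {
    f <- fit_ou(cache$tree, painting, x,
                control = utils::modifyList(ctl, list(refine = TRUE)),
                cache = cache)
    return(f$aicc)
  }
  grid <- exp(seq(log(ctl$alpha_bounds[1]), log(ctl$alpha_bounds[2]),
                  length.out = ctl$rank_grid))
  ll <- max(profile_grid(cache, painting, x, grid))
  aicc(ll, length(regime_labels(painting)) + 2L, cache$ntip)
}

# shared state: shifts are (edge index -> label); painting derived on demand
shift_painting <- function(tree, shifts, root_label = "R0") {
  if (!length(shifts)) return(ou1_painting(tree, root_label))
  painting_from_shifts(tree, as.integer(names(shifts)),
                       unlist(shifts, use.names = FALSE), root_label)
}

fit_candidate <- function(cache, painting, traits, ctl, refine) {
  fit_ou(cache$tree, painting, traits,
         control = utils::modifyList(ctl, list(refine = refine)),
         cache = cache)
}

#' Forward phase: stepwise addition of regime shifts
#'
#' Starts from a single-peak OU model.  At each step every edge that is not
#' already a shift origin is tried as the origin of a new regime (painting
#' the edge and all descendant edges not claimed by a more recent shift);
#' the candidate with the lowest AICc is accepted if it strictly improves
#' on the incumbent, otherwise the phase stops.  Deterministic: AICc ties
#' are broken by the smallest postorder edge index.
#'
#' @param tree a `phylo` chronogram.
#' @param traits named numeric trait vector (log kg).
#' @param control a [search_control()] list.
#' @param cache optional [tree_cache()].
#' @return a `surface_result` with the forward painting, fit, and trace.
#' @export
forward_phase <- function(tree, traits, control = search_control(),
                          cache = NULL) {
  cache <- as_cache(tree, cache)
  if (cache$ntip < 4L) stop("need at least 4 tips for the search")
  x <- check_traits(cache$tree, traits)
  traits <- setNames(as.numeric(x), names(x))

  shifts <- list()
  root_label <- "R0"
  incumbent <- fit_candidate(cache, shift_painting(cache$tree, shifts,
                                                   root_label),
                             traits, control, refine = TRUE)
  trace <- data.frame(step = 0L, edge = NA_integer_, label = root_label,
                      aicc = incumbent$aicc)
  step <- 0L
  repeat {
    if (length(shifts) >= control$max_steps) break
    step <- step + 1L
    new_label <- sprintf("R%d", step)
    free_edges <- setdiff(seq_len(nrow(cache$tree$edge)),
                          as.integer(names(shifts)))
    # the next fit has one more optimum; stop if AICc would be undefined
    if (cache$ntip <= (length(shifts) + 2L) + 2L + 1L || !length(free_edges))
      break
    cand_aicc <- rep(NA_real_, length(free_edges))
    for (j in seq_along(free_edges)) {
      sh <- shifts
      sh[[as.character(free_edges[j])]] <- new_label
      cand_aicc[j] <- tryCatch(
        candidate_aicc(cache, shift_painting(cache$tree, sh, root_label),
                       traits, control),
        error = function(e) stop("candidate shift on edge ", free_edges[j],
                                 ": ", conditionMessage(e)))
    }
    best_val <- min(cand_aicc)
    tied <- free_edges[cand_aicc <= best_val + control$aicc_tol]
    best_edge <- tied[which.min(cache$po_index[tied])]
    sh <- shifts
    sh[[as.character(best_edge)]] <- new_label
    best_fit <- fit_candidate(cache, shift_painting(cache$tree, sh,
                                                    root_label),
                              traits, control, refine = TRUE)
    if (best_fit$aicc < incumbent$aicc) {
      shifts <- sh
      incumbent <- best_fit
      trace <- rbind(trace, data.frame(step = step, edge = best_edge,
                                       label = new_label,
                                       aicc = incumbent$aicc))
    } else break
  }
  painting <- shift_painting(cache$tree, shifts, root_label)
  structure(list(painting = painting, fit = incumbent,
                 forward_trace = trace, backward_trace = NULL,
                 convergent = convergent_regimes(cache$tree, painting),
                 shifts = shifts, root_label = root_label),
            class = "surface_result")
}

#' Backward phase: collapse convergent regimes
#'
#' Given the forward painting, evaluates every pairwise merge of distinct
#' regime labels (repainting one label as the other) and accepts the merge
#' with the lowest AICc when it strictly improves on the incumbent,
#' iterating to no improvement.  Surviving labels whose edges are not
#' contiguous are reported as convergent.  Merge ties are broken by the
#' sorted label pair; when the root regime is merged its label survives.
#'
#' @param tree a `phylo` chronogram.
#' @param traits named numeric trait vector.
#' @param forward a `surface_result` from [forward_phase()], or any
#'   `regime_painting` to start from.
#' @param control a [search_control()] list.
#' @param cache optional [tree_cache()].
#' @return a `surface_result` with merged painting, final fit, both traces.
#' @export
backward_phase <- function(tree, traits, forward,
                           control = search_control(), cache = NULL) {
  cache <- as_cache(tree, cache)
  painting <- if (inherits(forward, "surface_result")) forward$painting
              else forward
  incumbent <- if (inherits(forward, "surface_result")) forward$fit
               else fit_candidate(cache, painting, traits, control, TRUE)
  trace <- data.frame(step = integer(0), merged = character(0),
                      into = character(0), aicc = numeric(0))
  step <- 0L
  repeat {
    if (step >= control$max_merges) break
    labs <- regime_labels(painting)
    if (length(labs) < 2L) break
    pairs <- utils::combn(labs, 2L, simplify = FALSE)
    cand <- vapply(pairs, function(pr) {
      keep <- if (painting$root_regime %in% pr) painting$root_regime
              else pr[1L]
      drop_ <- setdiff(pr, keep)
      candidate_aicc(cache, merge_regimes(painting, drop_, keep),
                     traits, control)
    }, numeric(1))
    best_val <- min(cand)
    tied <- which(cand <= best_val + control$aicc_tol)
    # ties: lexicographically first sorted label pair
    key <- vapply(pairs[tied], function(pr) paste(sort(pr), collapse = "|"),
                  character(1))
    pick <- pairs[tied][[order(key)[1L]]]
    keep <- if (painting$root_regime %in% pick) painting$root_regime
            else pick[1L]
    drop_ <- setdiff(pick, keep)
    merged <- merge_regimes(painting, drop_, keep)
    best_fit <- fit_candidate(cache, merged, traits, control, refine = TRUE)
    if (best_fit$aicc < incumbent$aicc) {
      step <- step + 1L
      painting <- merged
      incumbent <- best_fit
      trace <- rbind(trace, data.frame(step = step, merged = drop_,
                                       into = keep, aicc = incumbent$aicc))
    } else break
  }
  fwd_trace <- if (inherits(forward, "surface_result"))
    forward$forward_trace else NULL
  structure(list(painting = painting, fit = incumbent,
                 forward_trace = fwd_trace, backward_trace = trace,
                 convergent = convergent_regimes(cache$tree, painting)),
            class = "surface_result")
}

#' Stepwise regime search with convergence detection
#'
#' Runs the forward shift-addition phase from a single-peak model, then the
#' backward merge phase that detects convergent regimes.  The final AICc is
#' never above the forward-phase AICc, which is never above the
#' single-peak AICc.
#'
#' @inheritParams forward_phase
#' @return a `surface_result`: `painting`, `fit`, `forward_trace`,
#'   `backward_trace`, `convergent` (labels with more than one origin).
#' @export
surface_search <- function(tree, traits, control = search_control(),
                           cache = NULL) {
  cache <- as_cache(tree, cache)
  fwd <- forward_phase(tree, traits, control, cache)
  backward_phase(tree, traits, fwd, control, cache)
}

#' @export
print.surface_result <- function(x, ...) {
  p <- length(regime_labels(x$painting))
  cat(sprintf("Stepwise regime search: %d regime(s), AICc = %.4f\n",
              p, x$fit$aicc))
  if (!is.null(x$forward_trace))
    cat(sprintf("  forward: %d accepted shift(s)\n",
                nrow(x$forward_trace) - 1L))
  if (!is.null(x$backward_trace))
    cat(sprintf("  backward: %d merge(s)\n", nrow(x$backward_trace)))
  if (length(x$convergent))
    cat("  convergent regimes:", paste(x$convergent, collapse = ", "), "\n")
  invisible(x)
}

#' Structured log lines for a search trace
#'
#' @param result a `surface_result`.
#' @return character vector, one line per recorded step.
#' @export
search_trace_lines <- function(result) {
  out <- character(0)
  ft <- result$forward_trace
  if (!is.null(ft))
    out <- c(out, sprintf("forward\tstep=%d\tedge=%s\tlabel=%s\taicc=%.6f",
                          ft$step, ifelse(is.na(ft$edge), "-", ft$edge),
                          ft$label, ft$aicc))
  bt <- result$backward_trace
  if (!is.null(bt) && nrow(bt))
    out <- c(out, sprintf("backward\tstep=%d\tmerge=%s->%s\taicc=%.6f",
                          bt$step, bt$merged, bt$into, bt$aicc))
  out
}
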
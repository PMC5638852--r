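#' Parameter-recovery harness
#'
#' Simulates two-regime OU data on pure-birth chronograms (root age 70 Ma,
#' phylogenetic half-life 1 Ma, stationary SD 0.3 log-kg, optima 1 log-unit
#' apart) and refits the generating painting, summarising how well the rate
#' of adaptation and the optima are recovered.
#'
#' @param n_tips tips per replicate tree.
#' @param reps number of replicates.
#' @param seed base seed; replicate r uses seeds derived from `seed + r`.
#' @param delta_theta separation between the two optima (log kg).
#' @return list with `median_alpha_hat`, `true_alpha`, `median_theta_error`
#'   (mean absolute error of the two optima, median across reps), and the
#'   per-rep vectors.
#' @export
recovery_harness <- function(n_tips = 128, reps = 50, seed = 1L,
                             delta_theta = 1.0) {
  alpha <- log(2)            # half-life 1 Ma
  s2 <- 2 * alpha * 0.3^2    # stationary SD 0.3
  a_hat <- th_err <- numeric(reps)
  for (r in seq_len(reps)) {
    tr <- sim_pure_birth(n_tips, 70, seed = seed * 1000L + r)
    p <- clade_shift_painting(tr, target = round(n_tips / 5))
    x <- simulate_ou(tr, p,
                     list(alpha = alpha, sigma2 = s2,
                          thetas = c(base = 0, shift = delta_theta)),
                     0, seed = seed * 2000L + r)
    f <- fit_ou(tr, p, x)
    a_hat[r] <- f$params$alpha
    th_err[r] <- mean(abs(f$params$thetas[c("base", "shift")] -
                            c(0, delta_theta)))
  }
  list(median_alpha_hat = median(a_hat), true_alpha = alpha,
       median_theta_error = median(th_err),
       alpha_hat = a_hat, theta_error = th_err)
}

# deterministic mid-sized clade shift: the internal node whose clade size
# is closest to `target` (smallest node id on ties).  Root children are
# excluded: a shift on a root-child edge is likelihood-equivalent to the
# complementary shift (the root regime enters only through the vanishing
# root weight), so "the" shift edge would be ill-defined there.
clade_shift_painting <- function(tree, target) {
  ntip <- ape::Ntip(tree)
  root_kids <- tree$edge[tree$edge[, 1L] == ntip + 1L, 2L]
  nodes <- setdiff((ntip + 2L):(ntip + tree$Nnode), root_kids)
  sizes <- vapply(nodes, function(nd)
    length(ape::extract.clade(tree, nd)$tip.label), integer(1))
  nd <- nodes[which.min(abs(sizes - target))]
  painting_from_shifts(tree, which(tree$edge[, 2L] == nd), "shift", "base")
}

#' Shift-detection harness
#'
#' Simulates a single regime shift of `delta_sd` stationary SDs on a
#' mid-sized clade and asks whether the stepwise search places a shift on
#' exactly that stem edge.
#'
#' @inheritParams recovery_harness
#' @param delta_sd optimum separation in units of stationary SD.
#' @param control [search_control()]; the default caps the forward phase,
#'   which cannot affect detection of the (dominant) true shift.
#' @return list with `recovery_rate` and the per-rep logical vector.
#' @export
shift_detection_harness <- function(n_tips = 128, reps = 50, seed = 1L,
                                    delta_sd = 3,
                                    control = search_control(max_steps = 3)) {
  alpha <- log(2); sd_st <- 0.3; s2 <- 2 * alpha * sd_st^2
  hit <- logical(reps)
  for (r in seq_len(reps)) {
    tr <- sim_pure_birth(n_tips, 70, seed = seed * 3000L + r)
    p <- clade_shift_painting(tr, target = round(n_tips / 5))
    true_edge <- shift_origin_edges(tr, p)
    x <- simulate_ou(tr, p,
                     list(alpha = alpha, sigma2 = s2,
                          thetas = c(base = 0, shift = delta_sd * sd_st)),
                     0, seed = seed * 4000L + r)
    res <- surface_search(tr, x, control)
    hit[r] <- true_edge %in% res$forward_trace$edge
  }
  list(recovery_rate = mean(hit), hits = hit)
}

# edges where a painting's regimes originate (parent edge differs)
shift_origin_edges <- function(tree, painting) {
  parent_edge <- rep(NA_integer_, ape::Ntip(tree) + tree$Nnode)
  parent_edge[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  which(vapply(seq_len(nrow(tree$edge)), function(e) {
    pe <- parent_edge[tree$edge[e, 1L]]
    up <- if (is.na(pe)) painting$root_regime else painting$edge_regime[pe]
    painting$edge_regime[e] != up
  }, logical(1)))
}

#' False-shift harness
#'
#' Simulates single-peak OU data (no shifts) and measures how often the
#' first forward step of the stepwise search accepts a spurious shift.
#'
#' @inheritParams recovery_harness
#' @return list with `false_shift_rate` and the per-rep logical vector.
#' @export
false_shift_harness <- function(n_tips = 64, reps = 30, seed = 1L) {
  alpha <- log(2); s2 <- 2 * alpha * 0.3^2
  fp <- logical(reps)
  for (r in seq_len(reps)) {
    tr <- sim_pure_birth(n_tips, 70, seed = seed * 5000L + r)
    x <- simulate_ou(tr, ou1_painting(tr),
                     list(alpha = alpha, sigma2 = s2, thetas = c(OU1 = 0)),
                     0, seed = seed * 6000L + r)
    res <- forward_phase(tr, x, search_control(max_steps = 1))
    fp[r] <- nrow(res$forward_trace) > 1L
  }
  list(false_shift_rate = mean(fp), accepted = fp)
}

#' Search-dominance harness
#'
#' On paper-like synthetic datasets, fits Brownian motion, the single-peak
#' model and the chimpanzee-ancestor hypothesis, runs the stepwise search,
#' and measures how often the search result has the lowest AICc of all
#' four — the qualitative model-comparison claim of the analysis.
#'
#' @param seeds integer vector of dataset seeds.
#' @param n_tips dataset size.
#' @param control [search_control()] for the stepwise search.
#' @return list with `dominance_rate`, per-seed logicals, and the list of
#'   comparison tables.
#' @export
dominance_harness <- function(seeds = 1:20, n_tips = 87,
                              control = search_control(max_steps = 25)) {
  anchors <- list(
    hylobatid_tips = c("Hylobates_lar", "Symphalangus_syndactylus",
                       "Nomascus_leucogenys", "Hoolock_hoolock"),
    hominoid_tips = c("Homo_sapiens", "Hylobates_lar"),
    pan_tips = c("Pan_troglodytes", "Pan_paniscus"),
    stem_fossils = c("Proconsul_africanus", "Proconsul_major",
                     "Ekembo_heseloni", "Ekembo_nyanzae"))
  ok <- logical(length(seeds))
  tables <- vector("list", length(seeds))
  for (i in seq_along(seeds)) {
    d <- make_paper_like_dataset(n_tips, seed = seeds[i])
    rep <- run_analysis(d$tree, d$traits, anchors = anchors,
                        control = control)
    tables[[i]] <- rep$comparison
    su <- rep$comparison$aicc[rep$comparison$model == "Surface"]
    ok[i] <- all(su <= rep$comparison$aicc + 1e-9)
  }
  list(dominance_rate = mean(ok), dominated = ok, tables = tables)
}
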
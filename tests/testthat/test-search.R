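test_that("constant traits never justify a shift", {
  tr <- random_chronogram(10, seed = 201)
  x <- setNames(rep(1.2, 10), tr$tip.label)
  res <- forward_phase(tr, x)
  expect_equal(nrow(res$forward_trace), 1L)
  expect_identical(regime_labels(res$painting), "R0")
  full <- surface_search(tr, x)
  expect_equal(length(regime_labels(full$painting)), 1L)
})

test_that("a strong clade shift is found on its stem edge first", {
  tr <- sim_pure_birth(48, 70, seed = 211)
  alpha <- log(2); s2 <- 2 * alpha * 0.3^2
  p <- oulandscape:::clade_shift_painting(tr, target = 12)
  e <- oulandscape:::shift_origin_edges(tr, p)
  x <- simulate_ou(tr, p, list(alpha = alpha, sigma2 = s2,
                               thetas = c(base = 0, shift = 3 * 0.3)),
                   0, seed = 212)
  res <- forward_phase(tr, x, search_control(max_steps = 1))
  expect_equal(res$forward_trace$edge[2L], e)
})

test_that("accepted AICc trace is strictly decreasing", {
  d <- make_paper_like_dataset(60, seed = 221)
  res <- surface_search(d$tree, d$traits, search_control(max_steps = 8))
  fw <- res$forward_trace$aicc
  expect_true(all(diff(fw) < 0))
  if (!is.null(res$backward_trace) && nrow(res$backward_trace))
    expect_true(all(diff(c(fw[length(fw)], res$backward_trace$aicc)) < 0))
  # composition ordering: final <= forward <= OU1
  expect_lte(res$fit$aicc, fw[length(fw)] + 1e-9)
  expect_lte(fw[length(fw)], fw[1L] + 1e-9)
})

test_that("backward phase merges regimes that share a true optimum", {
  tr <- sim_pure_birth(64, 70, seed = 231)
  alpha <- log(2); s2 <- 2 * alpha * 0.25^2
  sizes <- vapply(65:(64 + tr$Nnode), function(nd)
    length(ape::extract.clade(tr, nd)$tip.label), integer(1))
  nodes <- 65:(64 + tr$Nnode)
  cand <- nodes[sizes >= 8 & sizes <= 16]
  # two disjoint clades pushed to the same optimum
  pick <- c()
  for (nd in cand) {
    tips <- ape::extract.clade(tr, nd)$tip.label
    ok <- TRUE
    for (q in pick)
      if (length(intersect(tips, ape::extract.clade(tr, q)$tip.label)))
        ok <- FALSE
    if (ok) pick <- c(pick, nd)
    if (length(pick) == 2L) break
  }
  expect_length(pick, 2L)
  edges <- vapply(pick, function(nd) which(tr$edge[, 2L] == nd), integer(1))
  truth <- painting_from_shifts(tr, edges, c("c1", "c2"), "base")
  x <- simulate_ou(tr, truth,
                   list(alpha = alpha, sigma2 = s2,
                        thetas = c(base = 0, c1 = 1.2, c2 = 1.2)),
                   0, seed = 232)
  # hand backward the forward-style painting with the two regimes distinct
  res <- backward_phase(tr, x, truth)
  tip_reg <- function(painting, tip)
    painting$edge_regime[which(tr$edge[, 2L] == match(tip, tr$tip.label))]
  t1 <- ape::extract.clade(tr, pick[1])$tip.label[1]
  t2 <- ape::extract.clade(tr, pick[2])$tip.label[1]
  expect_identical(tip_reg(res$painting, t1), tip_reg(res$painting, t2))
  expect_true(tip_reg(res$painting, t1) %in% res$convergent)
  f_truth <- fit_ou(tr, truth, x)
  expect_lte(res$fit$aicc, f_truth$aicc)
})

test_that("merging everything reproduces the single-peak fit exactly", {
  tr <- random_chronogram(14, seed = 241)
  set.seed(242)
  x <- setNames(rnorm(14, 0, 0.5), tr$tip.label)
  p2 <- random_two_regime(tr, seed = 243)
  merged <- merge_regimes(p2, "shifted", "base")
  f_ou1 <- fit_ou(tr, ou1_painting(tr, "base"), x)
  f_merged <- fit_ou(tr, merged, x)
  expect_equal(f_merged$loglik, f_ou1$loglik, tolerance = 1e-10)
})

test_that("search result is invariant to tip label permutation", {
  d <- make_paper_like_dataset(55, seed = 251)
  tr <- d$tree; x <- d$traits
  ctl <- search_control(max_steps = 5)
  r1 <- surface_search(tr, x, ctl)
  # rename every tip consistently in tree and traits: results must be
  # identical up to the renaming
  set.seed(252)
  new_names <- sprintf("sp%03d", sample(ape::Ntip(tr)))
  tr2 <- tr
  tr2$tip.label <- new_names
  x2 <- setNames(unname(x[tr$tip.label]), new_names)
  r2 <- surface_search(tr2, x2, ctl)
  expect_equal(r1$fit$aicc, r2$fit$aicc, tolerance = 1e-9)
  expect_identical(r1$painting$edge_regime, r2$painting$edge_regime)
})

test_that("search trace lines are structured and complete", {
  d <- make_paper_like_dataset(55, seed = 261)
  res <- surface_search(d$tree, d$traits, search_control(max_steps = 3))
  lines <- search_trace_lines(res)
  expect_true(all(grepl("^(forward|backward)\t", lines)))
  expect_gte(length(lines), nrow(res$forward_trace))
})
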
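test_that("newick reading derives ages and flags non-contemporaneous tips", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  ages <- node_ages(tr)
  expect_equal(unname(ages[match(c("A", "B", "C"), tr$tip.label)]),
               c(0, 0, 0))
  expect_equal(max(ages), 2)  # root age
  expect_true(is_contemporaneous(tr))

  # branch lengths force A and C above the present set by the deepest tip B
  tr2 <- read_newick("((A:1,B:2):1,C:2);")
  ages2 <- node_ages(tr2)
  expect_equal(unname(ages2[match(c("A", "B", "C"), tr2$tip.label)]),
               c(1, 0, 1))
  expect_false(is_contemporaneous(tr2))
})

test_that("newick parsing errors are explicit", {
  expect_error(read_newick("((A:1,B:1):1,C:2;"), "character")
  expect_error(read_newick("(A:1,B:1)):1;"), "character 10")
  expect_error(read_newick("((A:1,B:1):1,C:2)"), "terminator")
  expect_error(read_newick("((A,B):1,C:2);"), "branch length")
})

test_that("write/read round-trips topology and branch lengths", {
  set.seed(3)
  for (s in 1:5) {
    tr <- random_chronogram(20, seed = s)
    back <- read_newick(write_newick(tr))
    expect_equal(sort(back$tip.label), sort(tr$tip.label))
    d1 <- ape::cophenetic.phylo(tr)
    d2 <- ape::cophenetic.phylo(back)[rownames(d1), colnames(d1)]
    expect_lt(max(abs(d1 - d2)), 1e-9)
  }
  # the 87-tip synthetic chronogram round-trips too
  d <- make_paper_like_dataset(87, seed = 2)
  back <- read_newick(write_newick(d$tree))
  da <- ape::cophenetic.phylo(d$tree)
  db <- ape::cophenetic.phylo(back)[rownames(da), colnames(da)]
  expect_lt(max(abs(da - db)), 1e-8)
})

test_that("grafting splits the attachment edge at the attachment age", {
  # hominoid-stem style edge spanning ages (5, 20)
  tr <- read_newick("((A:5,B:5):15,C:20);")
  pl <- fossil_placement("Pliobates_cataloniae", 11.6, "mrca:A+B",
                         ghost = 1.0)
  expect_equal(pl$attach_age, 12.6)
  out <- graft_fossil(tr, pl)
  ages <- node_ages(out)
  i <- match("Pliobates_cataloniae", out$tip.label)
  expect_equal(unname(ages[i]), 11.6)
  pend <- out$edge.length[which(out$edge[, 2L] == i)]
  expect_equal(pend, 1.0)
  parent <- out$edge[which(out$edge[, 2L] == i), 1L]
  expect_equal(unname(ages[parent]), 12.6)
})

test_that("grafting validates ghost length, edge span, duplicate names", {
  tr <- read_newick("((A:5,B:5):15,C:20);")
  expect_error(fossil_placement("X", 10, "A", ghost = 0), "ghost")
  expect_error(graft_fossil(tr, fossil_placement("X", 10, "A", 1)),
               "outside edge span")   # attach 11 > age(parent A)=5
  expect_error(graft_fossil(tr, fossil_placement("A", 3, "mrca:A+B", 1)),
               "duplicate")
})

test_that("stacked grafts keep all ages consistent with branch lengths", {
  tr <- read_newick("((A:5,B:5):15,C:20);")
  out <- graft_fossil(tr, fossil_placement("F1", 11, "mrca:A+B", 1))
  out <- graft_fossil(out, fossil_placement("F2", 8, "mrca:A+B", 1))
  # brute-force age recomputation from root-to-node path sums
  depth <- ape::node.depth.edgelength(out)
  ages <- max(depth[seq_len(ape::Ntip(out))]) - depth
  for (e in seq_len(nrow(out$edge)))
    expect_equal(ages[out$edge[, 2L]][e],
                 ages[out$edge[, 1L]][e] - out$edge.length[e],
                 tolerance = 1e-9)
  expect_equal(unname(ages[match(c("F1", "F2"), out$tip.label)]), c(11, 8))
})

test_that("grafting preserves patristic distances among original tips", {
  set.seed(9)
  tr <- random_chronogram(12, seed = 9)
  d0 <- ape::cophenetic.phylo(tr)
  ages <- node_ages(tr)
  e <- which(tr$edge[, 2L] == ape::getMRCA(tr, tr$tip.label[1:3]))
  child <- tr$edge[e, 2L]
  mid <- mean(c(ages[child], ages[tr$edge[e, 1L]]))
  out <- graft_fossil(tr, fossil_placement("fossil", mid - 0.05, child,
                                           ghost = 0.05))
  d1 <- ape::cophenetic.phylo(out)[rownames(d0), colnames(d0)]
  expect_lt(max(abs(d1 - d0)), 1e-9)
})

test_that("sister pruning drops the second of near-equal cherries", {
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  m <- c(A = 10, B = 9, C = 10, D = 5)
  out <- prune_similar_sisters(tr, m, ratio = 0.8)
  expect_identical(attr(out, "dropped"), "B")   # 0.9 > 0.8
  expect_true(all(c("C", "D") %in% out$tip.label))  # 0.5 <= 0.8
})

test_that("sister pruning honors protection and missing-mass errors", {
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  m <- c(A = 10, B = 9, C = 10, D = 9.5)
  out <- prune_similar_sisters(tr, m, protected = c("B", "D"))
  expect_equal(ape::Ntip(out), 4L)
  expect_error(prune_similar_sisters(tr, m[-2]), "B")
})

test_that("sister pruning matches exhaustive cherry enumeration", {
  for (s in 1:5) {
    tr <- random_chronogram(50, seed = 100 + s)
    set.seed(200 + s)
    m <- setNames(exp(rnorm(50, 1, 1)), tr$tip.label)
    prot <- sample(tr$tip.label, 5)
    out <- prune_similar_sisters(tr, m, ratio = 0.8, protected = prot)
    expected <- oracle_prune(tr, m, 0.8, prot)
    expect_setequal(attr(out, "dropped"), expected)
    expect_equal(ape::Ntip(out), 50L - length(expected))
    expect_true(all(prot %in% out$tip.label))
  }
})

test_that("random reduction respects protection and is seed-reproducible", {
  tr <- random_chronogram(30, seed = 4)
  prot <- tr$tip.label[1:10]
  r1 <- reduce_to_n(tr, 15, protected = prot, seed = 7)
  r2 <- reduce_to_n(tr, 15, protected = prot, seed = 7)
  expect_identical(write_newick(r1), write_newick(r2))
  expect_equal(ape::Ntip(r1), 15L)
  expect_true(all(prot %in% r1$tip.label))
  expect_error(reduce_to_n(tr, 5, protected = prot, seed = 1),
               "unprotected")
})

test_that("trait tables and placement configs read with validation", {
  f <- tempfile()
  writeLines(c("species\tmass_kg\tn", "A\t10\t3", "B\t5\t1"), f)
  tab <- read_trait_table(f)
  expect_equal(tab$mass_kg, c(10, 5))
  writeLines(c("species\tweight", "A\t10"), f)
  expect_error(read_trait_table(f), "mass_kg")
  writeLines(c("species\tmass_kg", "A\t10", "A\t11"), f)
  expect_error(read_trait_table(f), "duplicate")

  hp <- hominoid_fossil_placements()
  expect_equal(nrow(hp), 21L)
  expect_true(all(c("tip_label", "tip_age", "attach_child", "ghost") %in%
                    names(hp)))
  expect_equal(hp$tip_age[hp$tip_label == "Pliobates_cataloniae"], 11.6)
  expect_error(read_fossil_placements(f), "missing column")
})
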
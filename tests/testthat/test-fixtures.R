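test_that("the embedded mass table carries the published rows verbatim", {
  tab <- hominin_fixture()
  expect_equal(nrow(tab), 24L)
  row <- function(sp) tab[tab$species == sp, ]
  af <- row("Au. afarensis")
  expect_equal(af$mass_kg, 39.10)
  expect_equal(af$first_appearance_ma, 3.77)
  expect_equal(af$n, 12L)
  expect_equal(row("Pan troglodytes")$mass_kg, 45.00)
  expect_equal(row("H. neanderthalensis")$mass_kg, 75.40)
  expect_equal(row("Pliobates cataloniae")$first_appearance_ma, 11.60)
  expect_equal(row("Proconsul major")$mass_kg, 75.00)
  expect_identical(row("H. sapiens")$family, "Hominidae")
})

test_that("dual-estimate taxa switch between scaling variants", {
  large <- hominin_fixture("large")
  small <- hominin_fixture("small")
  o <- function(tab) tab$mass_kg[tab$species == "Orrorin tugenensis"]
  a <- function(tab) tab$mass_kg[tab$species == "Ar. ramidus"]
  expect_equal(o(large), 46.5)
  expect_equal(o(small), 35.8)
  expect_equal(a(large), 50.8)
  expect_equal(a(small), 32.1)
  # all other rows are identical between variants
  other <- !(large$species %in% c("Orrorin tugenensis", "Ar. ramidus"))
  expect_identical(large$mass_kg[other], small$mass_kg[other])
})

test_that("hominin and fossil flags follow the published taxonomy", {
  tab <- hominin_fixture()
  expect_true(tab$is_hominin[tab$species == "H. sapiens"])
  expect_false(tab$is_hominin[tab$species == "Pan troglodytes"])
  expect_false(tab$is_fossil[tab$species == "Pan paniscus"])
  expect_true(tab$is_fossil[tab$species == "Sivapithecus indicus"])
  expect_equal(sum(tab$is_fossil), 21L)
  expect_equal(sum(tab$is_hominin & tab$is_fossil), 13L)
})

test_that("the synthetic dataset reproduces the study structure", {
  d <- make_paper_like_dataset(87, seed = 5)
  expect_equal(ape::Ntip(d$tree), 87L)
  expect_equal(sum(d$data$is_fossil), 30L)
  expect_equal(sum(!d$data$is_fossil), 57L)
  # generating optima are the published regime optima
  kg <- exp(d$params$thetas)
  expect_equal(unname(kg["m"]), 45.23)
  expect_equal(unname(kg["a"]), 1.36)
  expect_equal(unname(kg["h"]), 6.95)
  expect_equal(unname(kg["c"]), 126.16)
  # rate of adaptation set by the published half-life
  expect_equal(half_life(d$params$alpha), 0.88)
  # painting invariants: every edge labeled, thetas cover labels
  expect_true(all(regime_labels(d$painting) %in% names(d$params$thetas)))
  expect_equal(length(d$painting$edge_regime), nrow(d$tree$edge))
  # key memberships mirror the published regime table
  reg <- setNames(d$data$regime, d$data$species)
  expect_equal(unname(reg["Pan_troglodytes"]), "m")
  expect_equal(unname(reg["Orrorin_tugenensis"]), "m")
  expect_equal(unname(reg["Proconsul_africanus"]), "m")
  expect_equal(unname(reg["Australopithecus_afarensis"]), "b")
  expect_equal(unname(reg["Homo_erectus"]), "e")
  expect_equal(unname(reg["Homo_heidelbergensis"]), "j")
  expect_equal(unname(reg["Proconsul_major"]), "c")
  expect_equal(unname(reg["Papio_anubis"]), "k")
  expect_equal(unname(reg["Hylobates_lar"]), "h")
  # convergence present in the generating landscape
  expect_true(all(c("h", "m", "c", "e", "b") %in%
                    convergent_regimes(d$tree, d$painting)))
  # non-contemporaneous: fossil tips end above the present
  ages <- node_ages(d$tree)
  expect_gt(ages[match("Pliobates_cataloniae", d$tree$tip.label)], 11.5)
  expect_lt(abs(ages[match("Homo_sapiens", d$tree$tip.label)]), 1e-8)
})

test_that("fitting the generating painting recovers the true optima", {
  errs <- numeric(8)
  for (r in 1:8) {
    d <- make_paper_like_dataset(87, seed = 300 + r)
    f <- fit_ou(d$tree, d$painting, d$traits)
    common <- intersect(names(f$params$thetas), names(d$params$thetas))
    errs[r] <- median(abs(f$params$thetas[common] -
                            d$params$thetas[common]))
  }
  expect_lt(median(errs), 0.25)
})
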
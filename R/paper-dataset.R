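#' Extant primate backbone of the synthetic dataset
#'
#' Hand-calibrated hominoid, Papio and backbone nodes (divergence dates in
#' the range of published consensus estimates) joined to seeded pure-birth
#' radiations for the strepsirrhine, New World monkey, atelid and Old World
#' monkey clades.  Root age 70 Ma.
#'
#' @param n_strep,n_nwm,n_atelid,n_owm tip counts of the random clades.
#' @return a `phylo` chronogram (clade memberships in attribute `clades`).
#' @keywords internal
extant_backbone <- function(n_strep, n_nwm, n_atelid, n_owm) {
  sub_str <- function(n, crown, prefix) {
    tr <- ape::rphylo(n, birth = 1, death = 0)
    depth <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length * crown / depth
    tr$tip.label <- sprintf("%s_sp%02d", prefix, seq_len(n))
    sub("; *$", "", ape::write.tree(tr, digits = 12))
  }
  strep <- sub_str(n_strep, 50, "Strep")
  nwm <- sub_str(n_nwm, 20, "Nwm")
  atelid <- sub_str(n_atelid, 12, "Ateles")
  owm <- sub_str(n_owm, 15, "Owm")
  hominoid <- paste0(
    "((((Homo_sapiens:8.0,(Pan_troglodytes:2.5,Pan_paniscus:2.5):5.5):2.0,",
    "(Gorilla_gorilla:1.2,Gorilla_beringei:1.2):8.8):6.5,",
    "(Pongo_abelii:4.0,Pongo_pygmaeus:4.0):12.5):3.0,",
    "(Symphalangus_syndactylus:8.0,(Hylobates_lar:6.0,",
    "(Nomascus_leucogenys:4.0,Hoolock_hoolock:4.0):2.0):2.0):11.5)")
  newick <- sprintf(
    "(%s:20,((%s:13,%s:5):18,(((Papio_anubis:2,Papio_cynocephalus:2):18,%s:5):11,%s:11.5):12):27);",
    strep, atelid, nwm, owm, hominoid)
  tree <- read_newick(newick)
  attr(tree, "clades") <- list(
    strepsirrhine = grep("^Strep_", tree$tip.label, value = TRUE),
    nwm = grep("^Nwm_", tree$tip.label, value = TRUE),
    atelid = grep("^Ateles_", tree$tip.label, value = TRUE),
    owm = grep("^Owm_", tree$tip.label, value = TRUE),
    papio = c("Papio_anubis", "Papio_cynocephalus"),
    hylobatid = c("Symphalangus_syndactylus", "Hylobates_lar",
                  "Nomascus_leucogenys", "Hoolock_hoolock"),
    hominid = c("Homo_sapiens", "Pan_troglodytes", "Pan_paniscus",
                "Gorilla_gorilla", "Gorilla_beringei", "Pongo_abelii",
                "Pongo_pygmaeus"))
  tree
}

# generating regime painting of the assembled synthetic tree (shifts on
# edges above the nodes listed; see the vignette for the landscape layout)
paper_truth_painting <- function(tree) {
  mr <- function(...) ape::getMRCA(tree, c(...))
  at <- grep("^Ateles_", tree$tip.label, value = TRUE)
  shift_nodes <- c(
    h1 = mr("Papio_anubis", "Homo_sapiens"),      # catarrhine crown
    h2 = mr(at),                                   # atelid crown
    k  = mr("Papio_anubis", "Papio_cynocephalus"),
    b1 = mr("Homo_sapiens", "Pongo_abelii"),       # hominid crown
    e1 = mr("Pongo_abelii", "Pongo_pygmaeus"),
    c1 = mr("Gorilla_gorilla", "Gorilla_beringei"),
    c2 = match("Proconsul_major", tree$tip.label),
    m1 = mr("Homo_sapiens", "Gorilla_gorilla"),    # African hominid crown
    m2 = match("Proconsul_africanus", tree$tip.label),
    b2 = mr("Homo_sapiens", "Australopithecus_afarensis"),
    e2 = mr("Homo_sapiens", "Homo_erectus"),
    j1 = mr("Homo_sapiens", "Homo_heidelbergensis"),
    e3 = match("Homo_sapiens", tree$tip.label),
    e4 = match("Ekembo_nyanzae", tree$tip.label),
    e5 = match("Dryopithecus_fontani", tree$tip.label))
  labels <- sub("[0-9]+$", "", names(shift_nodes))
  edges <- vapply(shift_nodes, function(nd) edge_below(tree, nd), integer(1))
  painting_from_shifts(tree, edges, labels, root_label = "a")
}

#' Generate a paper-like 87-tip primate body-mass dataset
#'
#' Builds a synthetic dataset with the structure of the published primate
#' analysis: an extant backbone of 57 species (hand-calibrated hominoid and
#' Papio nodes plus pure-birth radiations, root age 70 Ma), 21 hominoid and
#' hominin fossils grafted at their first-appearance dates with ghost
#' lineages, 9 non-hominoid fossil primates, and a generating adaptive
#' landscape with two broad optima (1.36 and 6.95 kg) shared by almost all
#' non-hominid lineages plus a set of hominid-clade optima (29.68, 45.23,
#' 59.85, 94.96, 126.16 kg) and a terrestrial-baboon optimum (17.65 kg).
#' The rate of adaptation corresponds to a phylogenetic half-life of
#' 0.88 Ma, and the stationary SD is 0.35 log-kg; traits (log kg) are drawn
#' from the exact OU transition density.
#'
#' @param n_tips total tip count; 87 reproduces the published data-set
#'   size.  At least 51 (30 fossils plus the 13 named extant anchors plus
#'   two tips per random clade).
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of it.
#' @return list with `tree` (chronogram), `painting` (generating
#'   `regime_painting`), `traits` (named log-kg vector), `params` (true
#'   `alpha`, `sigma2`, `thetas`, `root_state`), and `data`, a per-species
#'   table (mass_kg, female_mass_kg, mass_small_kg, n, family, is_fossil,
#'   is_hominin, probable, regime) used by the dataset-variant filters.
#' @export
make_paper_like_dataset <- function(n_tips = 87, seed = 1L) {
  if (n_tips < 51) stop("n_tips must be >= 51 (30 fossils + 13 anchors + 8)")
  free <- n_tips - 43L
  ns <- max(2L, round(free * 13 / 44))
  nn <- max(2L, round(free * 10 / 44))
  na <- max(2L, round(free * 5 / 44))
  nc <- free - ns - nn - na
  if (nc < 2L) { ns <- ns - (2L - nc); nc <- 2L }

  with_local_seed(seed, {
    tree <- extant_backbone(ns, nn, na, nc)
    clades <- attr(tree, "clades")

    # hominoid + hominin fossils at explicit backbone placements
    hp <- hominoid_fossil_placements()
    for (i in seq_len(nrow(hp)))
      tree <- graft_fossil(tree, fossil_placement(
        hp$tip_label[i], hp$tip_age[i], hp$attach_child[i], hp$ghost[i]))

    # non-hominoid fossils located by age inside their host clades
    host_node <- function(host) switch(
      host,
      strepsirrhine = ape::getMRCA(tree, clades$strepsirrhine),
      anthropoid = ape::getMRCA(tree, c("Homo_sapiens", "Ateles_sp01")),
      platyrrhine = ape::getMRCA(tree, c(clades$atelid[1], clades$nwm[1])),
      cercopithecoid = ape::getMRCA(tree, c("Papio_anubis",
                                            clades$owm[1])))
    np <- nonhominoid_fossil_placements()
    for (i in seq_len(nrow(np))) {
      e <- find_edge_at_age(tree, host_node(np$host[i]),
                            np$tip_age[i] + np$ghost[i])
      tree <- graft_fossil(tree, fossil_placement(
        np$tip_label[i], np$tip_age[i], tree$edge[e, 2L], np$ghost[i]))
    }
    stopifnot(ape::Ntip(tree) == n_tips)

    painting <- paper_truth_painting(tree)
    alpha <- log(2) / 0.88
    sigma2 <- 2 * alpha * 0.35^2
    thetas <- log(c(a = 1.36, b = 29.68, c = 126.16, e = 59.85,
                    h = 6.95, j = 94.96, k = 17.65, m = 45.23))
    params <- list(alpha = alpha, sigma2 = sigma2, thetas = thetas,
                   root_state = thetas[["a"]])
    traits <- simulate_ou(tree, painting, params, params$root_state,
                          seed = NULL)

    data <- paper_dataset_metadata(tree, painting, traits)
    list(tree = tree, painting = painting, traits = traits,
         params = params, data = data)
  })
}

# per-species metadata table driving the dataset-variant filters; called
# inside the generator's seeded block (sample sizes and dimorphism factors
# consume the stream)
paper_dataset_metadata <- function(tree, painting, traits) {
  fix <- hominin_fixture()
  np <- nonhominoid_fossil_placements()
  tips <- tree$tip.label
  mass <- exp(traits[tips])

  is_fossil <- tips %in% c(fix$tip_label[fix$is_fossil], np$tip_label)
  is_hominin <- tips %in% fix$tip_label[fix$is_hominin]
  probable <- tips == "Paranthropus_boisei"

  n <- setNames(rep(NA_integer_, length(tips)), tips)
  fi <- match(tips, fix$tip_label)
  n[!is.na(fi)] <- fix$n[fi[!is.na(fi)]]
  n[tips %in% np$tip_label] <- 1L
  n[is.na(n) & is_fossil] <- 1L          # proconsulids: unpublished, rare
  extant_unset <- is.na(n)
  n[extant_unset] <- sample(3:60, sum(extant_unset), replace = TRUE)

  family <- rep("Primates", length(tips))
  family[!is.na(fi)] <- fix$family[fi[!is.na(fi)]]
  family[grepl("^(Gorilla|Pongo|Pan_|Homo_)", tips)] <- "Hominidae"
  family[grepl("^(Hylobates|Symphalangus|Nomascus|Hoolock)", tips)] <-
    "Hylobatidae"
  family[grepl("^(Papio|Owm_)", tips)] <- "Cercopithecidae"
  family[grepl("^Ateles_", tips)] <- "Atelidae"
  family[grepl("^Nwm_", tips)] <- "Cebidae"
  family[grepl("^Strep_", tips)] <- "Strepsirrhini"

  # female masses: dimorphism factor for extant and well-sampled taxa;
  # single-individual fossil averages double as female values; the poorly
  # sampled early hominins have no female estimate at all
  no_female <- tips %in% c("Orrorin_tugenensis", "Ardipithecus_ramidus",
                           "Australopithecus_anamensis",
                           "Australopithecus_sediba",
                           "Paranthropus_boisei", "Homo_habilis")
  female <- mass * runif(length(tips), 0.75, 0.98)
  single <- is_fossil & n <= 1L
  female[single] <- mass[single]
  female[no_female] <- NA_real_

  # the two dual-estimate taxa carry the alternative (human-scaling)
  # estimate as the printed small/large ratio applied to the drawn mass
  fix_small <- hominin_fixture()
  ratio <- setNames(fix_small$mass_small_kg / fix_small$mass_kg,
                    fix_small$tip_label)
  mass_small <- rep(NA_real_, length(tips))
  has_small <- tips %in% names(ratio)[!is.na(ratio)]
  mass_small[has_small] <- mass[tips[has_small]] *
    ratio[tips[has_small]]

  # regime of each tip = regime of its pendant edge
  pend <- vapply(seq_along(tips), function(i)
    painting$edge_regime[edge_below(tree, i)], character(1))

  data.frame(species = tips, mass_kg = unname(mass),
             female_mass_kg = unname(female),
             mass_small_kg = mass_small, n = unname(n), family = family,
             is_fossil = is_fossil, is_hominin = is_hominin,
             probable = probable, regime = pend,
             stringsAsFactors = FALSE)
}
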
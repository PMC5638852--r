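#' Hominin and fossil body-mass table
#'
#' The published body-mass averages, first-appearance dates, sample sizes
#' and family designations for the fossil hominins, Miocene apes and
#' comparative taxa used throughout this package, shipped as a plain-text
#' fixture.  *Orrorin tugenensis* and *Ardipithecus ramidus* carry two
#' estimates each, depending on whether a modern-human or chimpanzee
#' scaling pattern is assumed: the chimpanzee-based (larger) estimates are
#' the default, the human-based ones are returned by `estimates = "small"`.
#'
#' @param estimates `"large"` (chimpanzee-scaling, default) or `"small"`
#'   (human-scaling) body-mass estimates for the two dual-estimate taxa.
#' @return data.frame with columns `species` (printed name), `tip_label`
#'   (tree-safe name), `mass_kg`, `mass_small_kg` (NA except for the two
#'   dual-estimate taxa), `first_appearance_ma`, `n` (sample size, NA where
#'   unpublished), `family`, plus derived flags `is_hominin` and
#'   `is_fossil`.
#' @export
hominin_fixture <- function(estimates = c("large", "small")) {
  estimates <- match.arg(estimates)
  path <- system.file("extdata", "table1_hominin_fossil_masses.tsv",
                      package = "oulandscape", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (estimates == "small") {
    swap <- !is.na(tab$mass_small_kg)
    tab$mass_kg[swap] <- tab$mass_small_kg[swap]
  }
  hominin_genera <- c("Orrorin", "Ardipithecus", "Australopithecus",
                      "Paranthropus", "Homo")
  genus <- sub("_.*$", "", tab$tip_label)
  tab$is_hominin <- genus %in% hominin_genera
  tab$is_fossil <- !(tab$tip_label %in%
                       c("Homo_sapiens", "Pan_troglodytes", "Pan_paniscus"))
  tab
}

#' Fossil placements for the composite primate chronogram
#'
#' Encodes where each fossil joins the extant backbone, following the
#' published verbal placements: the proconsuloids (*Proconsul*, *Ekembo*)
#' diverge from the hominoid stem before the hylobatid divergence,
#' *Pliobates* is a late small-bodied stem ape, *Dryopithecus* originates
#' before the *Gorilla* lineage followed by *Hispanopithecus*,
#' *Sivapithecus* sits on the *Pongo* stem, and the hominins form a ladder
#' on the human stem ordered by first appearance.  Ghost lineages default
#' to 1 Ma above the first-appearance date; the handful of other values
#' keep genus pairs monophyletic or respect proposed relationships
#' (*H. floresiensis* diverges with the habiline grade, well before its
#' late first appearance).
#'
#' @return data.frame with columns `tip_label`, `tip_age`, `attach_child`
#'   (a [resolve_node()] spec on the backbone), `ghost`.
#' @export
hominoid_fossil_placements <- function() {
  read_fossil_placements(system.file(
    "extdata", "hominoid_fossil_placements.tsv",
    package = "oulandscape", mustWork = TRUE))
}


#' Non-hominoid fossil primates of the synthetic dataset
#'
#' The analysis also carries a set of non-hominoid fossil primates whose
#' ages and placements are not printed in the embedded mass table; the
#' values here are synthetic stand-ins in the right stratigraphic order
#' (see the package vignette).  `host` names the clade each fossil joins;
#' the exact edge is located at graft time by age.
#'
#' @return data.frame with columns `tip_label`, `tip_age`, `ghost`, `host`
#'   (one of `"strepsirrhine"`, `"anthropoid"`, `"platyrrhine"`,
#'   `"cercopithecoid"`), and `regime` (the generating regime of the tip).
#' @export
nonhominoid_fossil_placements <- function() {
  utils::read.delim(system.file(
    "extdata", "nonhominoid_fossil_placements_synthetic.tsv",
    package = "oulandscape", mustWork = TRUE), stringsAsFactors = FALSE)
}

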
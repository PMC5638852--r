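#' Painting for the chimpanzee-sized hominoid-ancestor hypothesis
#'
#' Encodes the alternative in which the last common ancestor of all
#' hominoids already lived in a chimpanzee-sized regime and the hylobatids
#' evolved their small mass by dwarfism: starting from a reference painting
#' (normally the best painting found by the stepwise search), the hominoid
#' stem and backbone down to the chimpanzee lineage are repainted with the
#' chimpanzee regime, the hylobatid clade (stem and crown) receives a
#' derived small-bodied regime, and every other regime assignment is kept.
#' The chimpanzee-sized optimum is estimated, not pinned: the hypothesis
#' constrains the painting topology only.
#'
#' @param tree a `phylo` chronogram.
#' @param base_painting reference `regime_painting` to edit.
#' @param hylobatid_tips,hominoid_tips,pan_tips tip labels anchoring the
#'   hylobatid clade, the hominoid clade, and the chimpanzee lineage; tips
#'   absent from the tree are ignored, but each anchor needs at least one
#'   present tip (hylobatids and pan need their MRCA context, see Details).
#' @param stem_fossils tips (typically proconsuloids and other stem apes)
#'   whose attachments on the hominoid stem are crossed when extending the
#'   chimpanzee regime back to before their divergences.
#' @param chimp_label,dwarf_label labels used for the two edited regimes;
#'   `chimp_label = NULL` reuses the regime of the pan tips' pendant edges
#'   so the backbone joins the chimpanzee regime itself.
#' @return a `regime_painting`.
#' @export
build_anc_pan_painting <- function(tree, base_painting,
                                   hylobatid_tips, hominoid_tips, pan_tips,
                                   stem_fossils = character(),
                                   chimp_label = NULL,
                                   dwarf_label = "hylobatid_dwarf") {
  present <- function(tips) intersect(tips, tree$tip.label)
  hyl <- present(hylobatid_tips)
  hom <- present(hominoid_tips)
  pan <- present(pan_tips)
  missing <- c(if (!length(hyl)) "hylobatid_tips",
               if (length(hom) < 2L) "hominoid_tips",
               if (!length(pan)) "pan_tips")
  if (length(missing))
    stop("missing anchors: ", paste(missing, collapse = ", "))

  er <- base_painting$edge_regime
  ntip <- ape::Ntip(tree)
  node_of <- function(tips) if (length(tips) == 1L)
    match(tips, tree$tip.label) else ape::getMRCA(tree, tips)

  # chimpanzee regime label: the one the pan pendant edges carry
  pan_edges <- vapply(match(pan, tree$tip.label),
                      function(nd) edge_below(tree, nd), integer(1))
  chimp <- chimp_label %||% er[pan_edges[1L]]

  hom_node <- node_of(hom)
  pan_node <- node_of(pan)

  # backbone: path from the hominoid crown to the pan lineage's origin
  path_edges <- function(from_node, to_node) {
    out <- integer(0)
    node <- to_node
    while (node != from_node) {
      e <- edge_below(tree, node)
      if (is.na(e)) stop("anchors are not nested as hominoid > pan")
      out <- c(out, e)
      node <- tree$edge[e, 1L]
    }
    out
  }
  er[path_edges(hom_node, pan_node)] <- chimp

  # stem: walk rootward from the hominoid crown while the sister lineages
  # peeled off are stem fossils only
  node <- hom_node
  repeat {
    e <- edge_below(tree, node)
    if (is.na(e)) break
    er[e] <- chimp
    parent <- tree$edge[e, 1L]
    sibs <- setdiff(tree$edge[tree$edge[, 1L] == parent, 2L], node)
    sib_tips <- unlist(lapply(sibs, function(s)
      if (s <= ntip) tree$tip.label[s]
      else ape::extract.clade(tree, s)$tip.label))
    if (!all(sib_tips %in% stem_fossils)) break
    node <- parent
  }

  # hylobatid dwarf regime: stem edge plus the whole crown clade
  hyl_node <- node_of(hyl)
  hyl_edges <- edge_below(tree, hyl_node)
  if (hyl_node > ntip) {
    desc <- which(tree$edge[, 1L] %in%
                    c(hyl_node, phangorn_descendants(tree, hyl_node)))
    hyl_edges <- c(hyl_edges, desc)
  }
  er[unique(hyl_edges)] <- dwarf_label

  regime_painting(tree, er, base_painting$root_regime)
}

# internal: all internal descendants of a node (tips excluded)
phangorn_descendants <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  out <- integer(0)
  stack <- tree$edge[tree$edge[, 1L] == node, 2L]
  while (length(stack)) {
    nd <- stack[[1L]]; stack <- stack[-1L]
    if (nd > ntip) {
      out <- c(out, nd)
      stack <- c(stack, tree$edge[tree$edge[, 1L] == nd, 2L])
    }
  }
  out
}

#' Specify a fixed evolutionary hypothesis
#'
#' @param name one of `"BM"`, `"OU1"`, `"AncPan"`, `"custom"`.
#' @param ... hypothesis parameters: `AncPan` needs the anchor arguments of
#'   [build_anc_pan_painting()] plus `base_painting`; `custom` needs a
#'   `painting`.
#' @return a `hypothesis_spec` list.
#' @export
hypothesis_spec <- function(name = c("BM", "OU1", "AncPan", "custom"), ...) {
  name <- match.arg(name)
  structure(c(list(name = name), list(...)), class = "hypothesis_spec")
}

#' Fit a fixed evolutionary hypothesis
#'
#' Dispatches to the Brownian-motion fit or to the multi-optimum OU fit
#' with the painting the hypothesis prescribes.  Deterministic.
#'
#' @param tree a `phylo` chronogram.
#' @param traits named numeric trait vector (log kg).
#' @param spec a [hypothesis_spec()].
#' @param cache optional [tree_cache()].
#' @param control [fit_ou()] control overrides.
#' @return an `ou_fit`.
#' @export
fit_hypothesis <- function(tree, traits, spec, cache = NULL,
                           control = list()) {
  stopifnot(inherits(spec, "hypothesis_spec"))
  cache <- as_cache(tree, cache)
  painting <- switch(
    spec$name,
    BM = return(fit_bm(tree, traits, cache = cache)),
    OU1 = ou1_painting(tree),
    AncPan = build_anc_pan_painting(
      tree, spec$base_painting, spec$hylobatid_tips, spec$hominoid_tips,
      spec$pan_tips, spec$stem_fossils %||% character()),
    custom = spec$painting)
  fit_ou(tree, painting, traits, control = control, cache = cache)
}
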
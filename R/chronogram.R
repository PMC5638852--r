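#' Validate a time-calibrated tree
#'
#' A chronogram here is an `ape` `phylo` tree whose branch lengths are in
#' absolute time (Ma).  Fossil tips are allowed, so the tree need not be
#' ultrametric: a fossil tip simply ends above age zero.  Node ages are
#' always derived from branch lengths, with the present (age 0) defined by
#' the deepest tip.
#'
#' @param tree a `phylo` object.
#' @return the tree, invisibly, after checking the chronogram invariants
#'   (rooted, unique tip labels, at least two tips, all branch lengths
#'   present and strictly positive).
#' @export
validate_chronogram <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' tree")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (anyNA(tree$edge.length)) stop("tree has missing branch lengths")
  if (any(tree$edge.length <= 0)) stop("all branch lengths must be > 0")
  # rooted in the descent sense: exactly one parentless node, every other
  # node with exactly one parent (a multifurcating root is fine)
  kids <- tree$edge[, 2L]
  if (anyDuplicated(kids)) stop("tree must be rooted (node with 2 parents)")
  n_all <- ape::Ntip(tree) + tree$Nnode
  if (length(setdiff(seq_len(n_all), kids)) != 1L)
    stop("tree must be rooted (not singly connected)")
  if (ape::Ntip(tree) < 2L) stop("at least two tips required")
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  }
  invisible(tree)
}

#' Node ages in Ma before present
#'
#' Ages are derived from root-to-node path lengths; the root age equals the
#' maximum root-to-tip path length, so the deepest (extant) tips sit at age
#' zero and fossil tips end above zero.
#'
#' @param tree a `phylo` chronogram.
#' @return numeric vector of ages indexed by node id (tips first, then
#'   internal nodes).
#' @export
node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth[seq_len(ape::Ntip(tree))]) - depth
}

#' Is the chronogram ultrametric (no fossil tips)?
#'
#' @param tree a `phylo` chronogram.
#' @param tol age tolerance in Ma.
#' @return logical scalar.
#' @export
is_contemporaneous <- function(tree, tol = 1e-8) {
  all(abs(node_ages(tree)[seq_len(ape::Ntip(tree))]) < tol)
}

#' Read a Newick tree with mandatory branch lengths
#'
#' Thin wrapper over [ape::read.tree()] that rejects trees with missing
#' branch lengths (no silent defaults) and reports the character offset of
#' structural errors (unbalanced parentheses, missing terminal semicolon).
#'
#' @param text Newick string; exactly one tree.
#' @return a validated `phylo` chronogram.
#' @export
read_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "")[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("malformed Newick: unmatched ')' at character ", i)
    }
  }
  if (depth > 0L)
    stop("malformed Newick: ", depth, " unclosed '(' at character ",
         length(chars))
  if (!grepl(";", text, fixed = TRUE))
    stop("malformed Newick: no ';' terminator at character ", length(chars))
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("malformed Newick: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("malformed Newick: parser returned no tree")
  if (is.null(tree$edge.length))
    stop("missing branch lengths: every edge must carry a length")
  if (ape::Ntip(tree) + tree$Nnode - 1L != length(tree$edge.length) ||
      anyNA(tree$edge.length))
    stop("missing branch lengths: every edge must carry a length")
  validate_chronogram(tree)
  tree
}

#' Write a chronogram as a Newick string
#'
#' @param tree a `phylo` chronogram.
#' @param digits significant digits for branch lengths.
#' @return Newick string (round-trips through [read_newick()] to identical
#'   topology and branch lengths up to float formatting).
#' @export
write_newick <- function(tree, digits = 12L) {
  ape::write.tree(tree, digits = digits)
}

#' Describe the placement of a fossil tip
#'
#' A fossil enters the tree at its first-appearance date, attached to an
#' existing edge by a ghost lineage that accounts for unsampled history
#' (1 Ma by default).  The attachment edge is identified by its child node,
#' via a [resolve_node()] spec so placements survive node renumbering.
#'
#' @param name fossil tip label.
#' @param tip_age first appearance date, Ma.
#' @param attach_child node spec for the child node of the attachment edge.
#' @param ghost ghost-lineage length in Ma; the attachment node sits at
#'   `tip_age + ghost`.
#' @return a `fossil_placement` list.
#' @export
fossil_placement <- function(name, tip_age, attach_child, ghost = 1.0) {
  stopifnot(is.character(name), length(name) == 1L, tip_age >= 0)
  if (ghost <= 0) stop("ghost length must be > 0 (pendant edges need length)")
  structure(list(name = name, tip_age = tip_age,
                 attach_child = attach_child, ghost = ghost,
                 attach_age = tip_age + ghost),
            class = "fossil_placement")
}

#' Graft a fossil tip onto a chronogram
#'
#' Splits the attachment edge at the attachment age with a new internal
#' node and hangs the fossil tip from it by its ghost lineage.  All other
#' edges, and hence all pre-existing patristic distances, are unchanged.
#'
#' @param tree a `phylo` chronogram.
#' @param placement a [fossil_placement()].
#' @return the enlarged chronogram.
#' @export
graft_fossil <- function(tree, placement) {
  stopifnot(inherits(placement, "fossil_placement"))
  validate_chronogram(tree)
  if (placement$name %in% tree$tip.label)
    stop("duplicate tip name: ", placement$name)
  child <- resolve_node(tree, placement$attach_child)
  e <- edge_below(tree, child)
  if (is.na(e)) stop("attachment child is the root; no edge above it")
  ages <- node_ages(tree)
  parent <- tree$edge[e, 1L]
  a <- placement$attach_age
  if (!(a > ages[child] && a < ages[parent]))
    stop(sprintf(
      "attachment age %.4f outside edge span (%.4f, %.4f) above '%s'",
      a, ages[child], ages[parent],
      if (child <= ape::Ntip(tree)) tree$tip.label[child] else
        paste0("node ", child)))

  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  # renumber: tips keep 1..ntip, new tip = ntip+1, old internals shift by 1,
  # new internal node appended last
  map <- function(x) ifelse(x <= ntip, x, x + 1L)
  new_tip <- ntip + 1L
  new_int <- ntip + 1L + nnode + 1L

  edge <- cbind(map(tree$edge[, 1L]), map(tree$edge[, 2L]))
  len <- tree$edge.length
  # split edge e: parent -> v, v -> child; pendant v -> fossil
  edge[e, ] <- c(map(parent), new_int)
  len[e] <- ages[parent] - a
  edge <- rbind(edge,
                c(new_int, map(child)),
                c(new_int, new_tip))
  len <- c(len, a - ages[child], placement$ghost)

  out <- list(edge = edge, edge.length = len,
              tip.label = c(tree$tip.label, placement$name),
              Nnode = nnode + 1L)
  class(out) <- "phylo"
  out <- ape::reorder.phylo(out, "cladewise")
  validate_chronogram(out)
  out
}

#' Graft several fossils in sequence
#'
#' @param tree a `phylo` chronogram.
#' @param placements list of [fossil_placement()] objects, applied in order
#'   (later placements may attach to pendant edges created by earlier ones).
#' @return the enlarged chronogram.
#' @export
graft_fossils <- function(tree, placements) {
  for (p in placements) tree <- graft_fossil(tree, p)
  tree
}

#' Drop the second member of near-equal-mass sister pairs
#'
#' Applies a taxon-reduction rule for dense extant samples: for every
#' cherry (two-tip sister pair) in the input tree whose members are both
#' unprotected, if the lighter species is more than `ratio` times the mass
#' of the heavier one the pair is considered redundant and the second
#' member is dropped.  "Second" is the later tip in the tree's stored child
#' order, a deterministic stand-in for an unspecified ordering.  The rule is
#' evaluated on the cherries of the input tree in a single post-order pass;
#' cherries created by the removals themselves are not re-examined.
#'
#' @param tree a `phylo` chronogram.
#' @param masses_kg named numeric vector of body masses (kg) covering all
#'   tips (raw kg, not log).
#' @param ratio similarity threshold; pairs with mass ratio strictly above
#'   it lose their second member.  Default 0.8.
#' @param protected character vector of tip labels never dropped (e.g.
#'   hominids and fossil taxa).
#' @return the pruned chronogram, with attribute `"dropped"` listing the
#'   removed tips.
#' @export
prune_similar_sisters <- function(tree, masses_kg, ratio = 0.8,
                                  protected = character()) {
  validate_chronogram(tree)
  missing <- setdiff(tree$tip.label, names(masses_kg))
  if (length(missing))
    stop("missing mass for species: ", paste(missing, collapse = ", "))
  ntip <- ape::Ntip(tree)
  tree_po <- ape::reorder.phylo(tree, "postorder")
  drop <- character()
  internal <- unique(tree_po$edge[, 1L])
  for (v in internal) {  # postorder over internal nodes
    kids <- tree_po$edge[tree_po$edge[, 1L] == v, 2L]
    if (length(kids) != 2L || any(kids > ntip)) next
    lab <- tree$tip.label[kids]  # stored child order of the input tree
    if (any(lab %in% protected)) next
    m <- masses_kg[lab]
    if (min(m) / max(m) > ratio) drop <- c(drop, lab[2L])
  }
  out <- if (length(drop)) ape::drop.tip(tree, drop) else tree
  attr(out, "dropped") <- drop
  out
}

#' Read a species trait table
#'
#' Delimited text with a header; requires columns `species` and `mass_kg`,
#' with `female_mass_kg` and `n` (sample size) optional.
#'
#' @param path file path.
#' @param sep field separator (tab by default).
#' @return data.frame with at least `species` and `mass_kg`.
#' @export
read_trait_table <- function(path, sep = "\t") {
  tab <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  need <- setdiff(c("species", "mass_kg"), names(tab))
  if (length(need))
    stop("trait table missing column(s): ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$species))
    stop("duplicate species in trait table")
  if (any(!is.finite(tab$mass_kg)) || any(tab$mass_kg <= 0))
    stop("mass_kg must be finite and positive")
  tab
}

#' Read a fossil-placement config
#'
#' Delimited text with header columns `tip_label`, `tip_age`,
#' `attach_child` (a [resolve_node()] spec) and `ghost`.
#'
#' @param path file path.
#' @return data.frame of placements, usable with [graft_fossils()] after
#'   conversion via [fossil_placement()].
#' @export
read_fossil_placements <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- setdiff(c("tip_label", "tip_age", "attach_child", "ghost"),
                  names(tab))
  if (length(need))
    stop("placement config missing column(s): ",
         paste(need, collapse = ", "))
  tab
}

#' Randomly reduce a tree to a target tip count
#'
#' Reproduces a random thinning step: unprotected tips are removed by
#' seeded uniform sampling until `n_target` tips remain.
#'
#' @param tree a `phylo` chronogram.
#' @param n_target desired tip count.
#' @param protected tips never removed.
#' @param seed integer seed controlling which tips are sampled.
#' @return the reduced chronogram.
#' @export
reduce_to_n <- function(tree, n_target, protected = character(), seed = 1L) {
  validate_chronogram(tree)
  n <- ape::Ntip(tree)
  if (n_target >= n) return(tree)
  pool <- setdiff(tree$tip.label, protected)
  k <- n - n_target
  if (length(pool) < k)
    stop("cannot reach ", n_target, " tips: only ", length(pool),
         " unprotected tips")
  drop <- with_local_seed(seed, sample(pool, k))
  ape::drop.tip(tree, drop)
}
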
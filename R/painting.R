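#' Construct a regime painting
#'
#' A regime painting assigns every edge of a chronogram to a selective
#' regime.  Shifts happen at edge origins, so a painted edge is homogeneous.
#' A regime may occupy non-adjacent edges, which is how convergence is
#' represented.
#'
#' @param tree a `phylo` chronogram.
#' @param edge_regime character vector of regime labels, one per row of
#'   `tree$edge`.
#' @param root_regime label of the regime in force at the root.
#' @return a `regime_painting` object.
#' @export
regime_painting <- function(tree, edge_regime, root_regime) {
  validate_chronogram(tree)
  stopifnot(is.character(edge_regime),
            length(edge_regime) == nrow(tree$edge),
            !anyNA(edge_regime),
            is.character(root_regime), length(root_regime) == 1L)
  structure(list(edge_regime = edge_regime, root_regime = root_regime),
            class = "regime_painting")
}

#' Regime labels of a painting
#'
#' @param painting a `regime_painting`.
#' @return sorted character vector of labels (always includes the root
#'   regime).
#' @export
regime_labels <- function(painting) {
  sort(unique(c(painting$root_regime, painting$edge_regime)))
}

#' Single-regime painting
#'
#' @param tree a `phylo` chronogram.
#' @param label the single regime label.
#' @return a `regime_painting` with every edge in one regime.
#' @export
ou1_painting <- function(tree, label = "OU1") {
  regime_painting(tree, rep(label, nrow(tree$edge)), label)
}

#' Painting from a set of regime shifts
#'
#' Builds the painting induced by placing shifts at the origins of the
#' named edges: each edge takes the label of the most recent shift on its
#' root-to-edge path, or the root regime if none.
#'
#' @param tree a `phylo` chronogram.
#' @param shift_edges integer vector of edge indices (rows of `tree$edge`)
#'   where shifts originate.
#' @param shift_labels regime labels of those shifts (same length).
#' @param root_label regime in force at the root.
#' @return a `regime_painting`.
#' @export
painting_from_shifts <- function(tree, shift_edges, shift_labels,
                                 root_label = "root") {
  stopifnot(length(shift_edges) == length(shift_labels))
  if (anyDuplicated(shift_edges)) stop("duplicate shift edges")
  tree_cw <- ape::reorder.phylo(tree, "cladewise")
  ord <- attr(tree_cw, "order_map") %||% match(
    paste(tree_cw$edge[, 1L], tree_cw$edge[, 2L]),
    paste(tree$edge[, 1L], tree$edge[, 2L]))
  lab <- character(nrow(tree$edge))
  shift_of_edge <- rep(NA_character_, nrow(tree$edge))
  shift_of_edge[shift_edges] <- shift_labels
  # label of the edge below each node, filled in cladewise (parent-first)
  node_lab <- rep(NA_character_, ape::Ntip(tree) + tree$Nnode)
  root <- ape::Ntip(tree) + 1L
  node_lab[root] <- root_label
  for (i in seq_len(nrow(tree_cw$edge))) {
    e <- ord[i]
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    lab[e] <- if (!is.na(shift_of_edge[e])) shift_of_edge[e] else node_lab[p]
    node_lab[ch] <- lab[e]
  }
  regime_painting(tree, lab, root_label)
}

#' Paint shifts given by node specs
#'
#' Convenience constructor for hypothesis paintings: shifts are placed on
#' the edges above the nodes named by [resolve_node()] specs, so clades can
#' be addressed by their member tips instead of volatile node ids.
#'
#' @param tree a `phylo` chronogram.
#' @param shifts data.frame with columns `child` (node specs) and `label`.
#' @param root_label regime in force at the root.
#' @return a `regime_painting`.
#' @export
painting_from_spec <- function(tree, shifts, root_label) {
  if (nrow(shifts) == 0L) return(ou1_painting(tree, root_label))
  edges <- vapply(shifts$child, function(s) {
    e <- edge_below(tree, resolve_node(tree, s))
    if (is.na(e)) stop("shift spec names the root: ", s)
    e
  }, integer(1))
  painting_from_shifts(tree, edges, shifts$label, root_label)
}

#' Origins and convergence of regimes
#'
#' An origin of a regime is an edge carrying its label whose parent edge
#' (or the root, for root-adjacent edges and the root regime) carries a
#' different label.  Regimes with more than one origin occupy non-adjacent
#' parts of the tree and are convergent.
#'
#' @param tree a `phylo` chronogram.
#' @param painting a `regime_painting`.
#' @return named integer vector of origin counts per regime label.
#' @export
regime_origins <- function(tree, painting) {
  n_all <- ape::Ntip(tree) + tree$Nnode
  parent_edge <- rep(NA_integer_, n_all)
  parent_edge[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  counts <- setNames(integer(length(regime_labels(painting))),
                     regime_labels(painting))
  counts[painting$root_regime] <- 1L  # the root itself founds its regime
  for (e in seq_len(nrow(tree$edge))) {
    pe <- parent_edge[tree$edge[e, 1L]]
    up <- if (is.na(pe)) painting$root_regime else painting$edge_regime[pe]
    if (painting$edge_regime[e] != up)
      counts[painting$edge_regime[e]] <- counts[painting$edge_regime[e]] + 1L
  }
  counts
}

#' Convergent regimes of a painting
#'
#' @inheritParams regime_origins
#' @return character vector of labels reached by more than one independent
#'   origin.
#' @export
convergent_regimes <- function(tree, painting) {
  o <- regime_origins(tree, painting)
  names(o)[o > 1L]
}

#' Merge two regime labels
#'
#' Repaints every edge labelled `from` with the label `to` (the root label
#' is remapped too if it equals `from`).
#'
#' @param painting a `regime_painting`.
#' @param from,to regime labels.
#' @return the merged `regime_painting`.
#' @export
merge_regimes <- function(painting, from, to) {
  er <- painting$edge_regime
  er[er == from] <- to
  rr <- if (painting$root_regime == from) to else painting$root_regime
  structure(list(edge_regime = er, root_regime = rr),
            class = "regime_painting")
}

#' Serialize a painting to its text format
#'
#' One line per edge, `<child-spec>\t<label>`, where the child spec is the
#' tip label for terminal edges and the child-node identifier `node:<id>`
#' for internal edges (hand-written files may use `mrca:` specs instead),
#' plus a final `root\t<label>` line.
#'
#' @param tree a `phylo` chronogram.
#' @param painting a `regime_painting`.
#' @param path file to write; if `NULL` the lines are returned.
#' @return character lines, invisibly when written to file.
#' @export
write_painting <- function(tree, painting, path = NULL) {
  ntip <- ape::Ntip(tree)
  desc_pair <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    paste0("node:", node)
  }
  lines <- vapply(seq_len(nrow(tree$edge)), function(e)
    paste(desc_pair(tree$edge[e, 2L]), painting$edge_regime[e], sep = "\t"),
    character(1))
  lines <- c(lines, paste("root", painting$root_regime, sep = "\t"))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Read a painting from its text format
#'
#' @param tree the `phylo` chronogram the painting refers to.
#' @param path file, or `lines` given directly.
#' @param lines character vector alternative to `path`.
#' @return a `regime_painting`.
#' @export
read_painting <- function(tree, path = NULL, lines = NULL) {
  if (is.null(lines)) lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) stop("malformed painting line ", bad[1L])
  keys <- vapply(parts, `[[`, character(1), 1L)
  vals <- vapply(parts, `[[`, character(1), 2L)
  root_i <- which(keys == "root")
  if (length(root_i) != 1L) stop("painting needs exactly one 'root' line")
  er <- rep(NA_character_, nrow(tree$edge))
  for (i in setdiff(seq_along(keys), root_i)) {
    e <- edge_below(tree, resolve_node(tree, keys[i]))
    if (is.na(e)) stop("painting line names the root: ", keys[i])
    er[e] <- vals[i]
  }
  if (anyNA(er))
    stop("painting does not cover every edge (", sum(is.na(er)),
         " unlabelled)")
  regime_painting(tree, er, vals[root_i])
}
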
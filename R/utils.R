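#' @keywords internal
"_PACKAGE"

#' @importFrom stats optimize rnorm runif setNames var sd median quantile
#' @importFrom utils head read.delim write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resolve a node specification to a node id
#'
#' Node specifications identify tree nodes in configs and painting files
#' without relying on internal node numbering, which changes whenever a tip
#' is grafted or dropped.  A spec is either a tip label, a string
#' `"mrca:tipA+tipB"` naming the most recent common ancestor of two (or
#' more, `+`-separated) tips, or a bare node id given as an integer.
#'
#' @param tree a `phylo` tree.
#' @param spec character scalar (tip label or `"mrca:..."` spec) or integer
#'   node id.
#' @return integer node id.
#' @export
resolve_node <- function(tree, spec) {
  if (is.numeric(spec)) {
    id <- as.integer(spec)
    if (id < 1L || id > ape::Ntip(tree) + tree$Nnode)
      stop("node id out of range: ", id)
    return(id)
  }
  stopifnot(is.character(spec), length(spec) == 1L)
  if (startsWith(spec, "node:"))
    return(resolve_node(tree, as.integer(sub("^node:", "", spec))))
  if (startsWith(spec, "mrca:")) {
    tips <- strsplit(sub("^mrca:", "", spec), "+", fixed = TRUE)[[1L]]
    missing <- setdiff(tips, tree$tip.label)
    if (length(missing))
      stop("mrca spec names unknown tips: ", paste(missing, collapse = ", "))
    if (length(tips) < 2L) stop("mrca spec needs at least two tips")
    return(ape::getMRCA(tree, tips))
  }
  hit <- match(spec, tree$tip.label)
  if (is.na(hit)) stop("unknown tip label: ", spec)
  hit
}

# Edge index (row of tree$edge) whose child is `node`; NA for the root.
edge_below <- function(tree, node) {
  idx <- which(tree$edge[, 2L] == node)
  if (!length(idx)) return(NA_integer_)
  idx
}

# Walk from `from_node` toward the tips (always taking the first stored
# child) until an edge whose age interval strictly contains `age` is found.
# Used to place fossils inside clades generated at random, where exact node
# ages are not known in advance.  Starts with the stem edge of `from_node`
# when `include_stem`.
find_edge_at_age <- function(tree, from_node, age, include_stem = TRUE) {
  ages <- node_ages(tree)
  node <- from_node
  if (include_stem) {
    e <- edge_below(tree, node)
    if (!is.na(e)) {
      p <- tree$edge[e, 1L]
      if (ages[p] > age && age > ages[node]) return(e)
    }
  }
  repeat {
    if (node <= ape::Ntip(tree)) stop("no edge at age ", age, " on this path")
    kids <- tree$edge[tree$edge[, 1L] == node, 2L]
    node <- kids[1L]
    e <- edge_below(tree, node)
    p <- tree$edge[e, 1L]
    if (ages[p] > age && age > ages[node]) return(e)
  }
}

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so simulation calls do not perturb outer streams.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
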
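#' Dataset variants of the body-mass analysis
#'
#' Applies the published robustness filters to a dataset bundle (tree +
#' per-species table), returning the pruned tree and the trait vector to
#' analyse:
#' \describe{
#'   \item{complete}{all species, chimpanzee-scaling estimates for the two
#'     dual-estimate early hominins.}
#'   \item{small_estimates}{human-scaling (smaller) estimates for
#'     *Orrorin* and *Ardipithecus*.}
#'   \item{no_eurasian_apes}{drops the European and Asian Miocene hominids
#'     (*Dryopithecus*, *Hispanopithecus*, *Sivapithecus*).}
#'   \item{well_sampled}{keeps only hominins whose mass average rests on
#'     more than two individuals and is reliably attributed (drops the
#'     `probable`-flagged taxon), and drops all non-hominin fossils.}
#'   \item{females_only}{swaps in female masses; species without a female
#'     estimate are dropped (single-individual fossil averages double as
#'     female values).}
#'   \item{extant_only}{drops every fossil tip.}
#' }
#'
#' @param dataset list with `tree` and `data` as produced by
#'   [make_paper_like_dataset()] (`data` columns: species, mass_kg,
#'   female_mass_kg, mass_small_kg, n, is_fossil, is_hominin, probable).
#' @param variant one of the names above.
#' @return list with `tree`, `traits` (named log-kg vector), `data`
#'   (filtered table), `variant`.
#' @export
build_variant <- function(dataset,
                          variant = c("complete", "small_estimates",
                                      "no_eurasian_apes", "well_sampled",
                                      "females_only", "extant_only")) {
  variant <- tryCatch(match.arg(variant), error = function(e)
    stop("unknown variant '", variant[1L], "'; choices: complete, ",
         "small_estimates, no_eurasian_apes, well_sampled, females_only, ",
         "extant_only"))
  d <- dataset$data
  mass <- setNames(d$mass_kg, d$species)
  drop <- character(0)

  if (variant == "small_estimates") {
    swap <- !is.na(d$mass_small_kg)
    mass[d$species[swap]] <- d$mass_small_kg[swap]
  } else if (variant == "no_eurasian_apes") {
    drop <- intersect(c("Dryopithecus_fontani", "Hispanopithecus_laietanus",
                        "Sivapithecus_indicus"), d$species)
  } else if (variant == "well_sampled") {
    bad_hominin <- d$is_hominin & d$is_fossil & (d$n <= 2L | d$probable)
    other_fossil <- d$is_fossil & !d$is_hominin
    drop <- d$species[bad_hominin | other_fossil]
  } else if (variant == "females_only") {
    drop <- d$species[is.na(d$female_mass_kg)]
    keep <- !is.na(d$female_mass_kg)
    mass[d$species[keep]] <- d$female_mass_kg[keep]
  } else if (variant == "extant_only") {
    drop <- d$species[d$is_fossil]
  }

  tree <- if (length(drop)) ape::drop.tip(dataset$tree, drop)
          else dataset$tree
  data <- d[!(d$species %in% drop), , drop = FALSE]
  traits <- log(mass[tree$tip.label])
  list(tree = tree, traits = traits, data = data, variant = variant)
}

#' Run the full model-comparison analysis on one dataset
#'
#' Fits Brownian motion, single-peak OU and the chimpanzee-sized
#' hominoid-ancestor hypothesis, runs the stepwise regime search, and
#' assembles the comparison table, the per-regime optima in kg, the
#' half-life of the best model, and the per-species deviations from their
#' regime optima (large deviations flag lineages poorly described by their
#' regime, the outlier diagnostic).
#'
#' @param tree a `phylo` chronogram.
#' @param traits named log-kg trait vector.
#' @param anchors list with `hylobatid_tips`, `hominoid_tips`, `pan_tips`,
#'   and optionally `stem_fossils`, passed to the chimpanzee-ancestor
#'   painting; `NULL` skips that hypothesis (e.g. trees without
#'   hylobatids).
#' @param control a [search_control()] list for the stepwise search.
#' @param n_outliers how many of the largest deviations to flag.
#' @return an `ou_report` list: `comparison`, `fits`, `search`,
#'   `optima_kg`, `half_life`, `deviations`.
#' @export
run_analysis <- function(tree, traits, anchors = NULL,
                         control = search_control(), n_outliers = 4L) {
  cache <- tree_cache(tree)
  fits <- list(BM = fit_bm(tree, traits, cache = cache),
               OU1 = fit_ou(tree, ou1_painting(tree), traits,
                            cache = cache))
  search <- surface_search(tree, traits, control = control, cache = cache)
  fits$Surface <- search$fit
  if (!is.null(anchors)) {
    spec <- hypothesis_spec("AncPan", base_painting = search$painting,
                            hylobatid_tips = anchors$hylobatid_tips,
                            hominoid_tips = anchors$hominoid_tips,
                            pan_tips = anchors$pan_tips,
                            stem_fossils = anchors$stem_fossils %||%
                              character())
    fits$AncPan <- fit_hypothesis(tree, traits, spec, cache = cache)
  }
  comparison <- compare_models(fits)

  best <- fits[[comparison$model[1L]]]
  painting <- best$painting %||% search$painting
  thetas <- if (length(best$params$thetas)) best$params$thetas
            else search$fit$params$thetas
  pend <- vapply(seq_len(ape::Ntip(tree)), function(i)
    painting$edge_regime[edge_below(tree, i)], character(1))
  dev <- data.frame(species = tree$tip.label,
                    trait = unname(traits[tree$tip.label]),
                    regime = pend,
                    theta = unname(thetas[pend]),
                    stringsAsFactors = FALSE)
  dev$deviation <- dev$trait - dev$theta
  dev$outlier <- rank(-abs(dev$deviation), ties.method = "first") <=
    n_outliers
  dev <- dev[order(-abs(dev$deviation)), ]
  rownames(dev) <- NULL

  structure(list(comparison = comparison, fits = fits, search = search,
                 optima_kg = sort(exp(thetas)),
                 half_life = comparison$half_life[1L],
                 deviations = dev),
            class = "ou_report")
}

#' @export
print.ou_report <- function(x, ...) {
  print(x$comparison)
  cat(sprintf("\nBest model half-life: %.3g Ma\n", x$half_life))
  cat("Regime optima (kg):",
      paste(sprintf("%s=%.2f", names(x$optima_kg), x$optima_kg),
            collapse = ", "), "\n")
  out <- x$deviations[x$deviations$outlier, ]
  cat("Largest deviations from regime optima:\n")
  for (i in seq_len(nrow(out)))
    cat(sprintf("  %-30s %+0.2f log-kg from regime %s\n",
                out$species[i], out$deviation[i], out$regime[i]))
  invisible(x)
}

#' Plot a chronogram with regime-colored branches
#'
#' Thin wrapper over [ape::plot.phylo()] coloring every edge by its regime
#' and annotating the optima (in kg) when a fit is supplied.
#'
#' @param tree a `phylo` chronogram.
#' @param painting a `regime_painting`.
#' @param fit optional `ou_fit` whose optima label the legend.
#' @param ... passed to [ape::plot.phylo()].
#' @return the regime-to-color map, invisibly.
#' @export
plot_regimes <- function(tree, painting, fit = NULL, ...) {
  labs <- regime_labels(painting)
  pal <- grDevices::hcl.colors(max(3L, length(labs)), "Dark 3")
  col <- setNames(pal[seq_along(labs)], labs)
  ape::plot.phylo(tree, edge.color = col[painting$edge_regime],
                  cex = 0.5, ...)
  legend_lab <- if (!is.null(fit) && length(fit$params$thetas))
    sprintf("%s (%.1f kg)", labs, exp(fit$params$thetas[labs]))
  else labs
  graphics::legend("topleft", legend = legend_lab, col = col, lwd = 2,
                   bty = "n", cex = 0.7)
  invisible(col)
}

#' Write the analysis outputs of one run
#'
#' Emits the comparison table (TSV), the final painting (painting text
#' format), the per-species deviations (TSV), the search trace, and a
#' machine-readable JSON manifest (inputs, seed, package version, AICc
#' table) sufficient to re-run the analysis bit-reproducibly.
#'
#' @param report an `ou_report` from [run_analysis()].
#' @param tree the analysed chronogram.
#' @param out_dir output directory (created if needed).
#' @param seed,variant metadata recorded in the manifest.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, tree, out_dir, seed = NA_integer_,
                         variant = NA_character_) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- report$comparison
  stopifnot(isTRUE(all.equal(tab$delta_aicc, tab$aicc - min(tab$aicc))))
  utils::write.table(tab, file.path(out_dir, "model_comparison.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_painting(tree, report$search$painting,
                 file.path(out_dir, "best_painting.txt"))
  utils::write.table(report$deviations,
                     file.path(out_dir, "species_deviations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(search_trace_lines(report$search),
             file.path(out_dir, "search_trace.log"))
  writeLines(write_newick(tree), file.path(out_dir, "tree.nwk"))
  manifest <- list(
    seed = seed, variant = variant,
    n_tips = ape::Ntip(tree),
    package = as.character(utils::packageVersion("oulandscape")),
    r_version = R.version.string,
    aicc = setNames(as.list(tab$aicc), tab$model),
    half_life = report$half_life,
    optima_kg = as.list(report$optima_kg))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
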
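#' Read a rooted phylogeny from Newick text
#'
#' Thin validating wrapper around [ape::read.tree()]: the tree must parse,
#' carry branch lengths, and have unique tip labels. Polytomies are
#' preserved; the tree need not be ultrametric.
#'
#' @param source a file path, or a Newick string (recognised by containing
#'   `(` and `;`).
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(source) {
  is_text <- length(source) == 1 && grepl("\\(", source) && grepl(";", source)
  tree <- tryCatch(
    if (is_text) ape::read.tree(text = source) else ape::read.tree(source),
    error = function(e) NULL, warning = function(w) NULL)
  if (inherits(tree, "multiPhylo")) tree <- tree[[1]]
  if (is.null(tree) || !inherits(tree, "phylo"))
    gs_error("parse-error", "could not parse Newick input")
  if (anyDuplicated(tree$tip.label))
    gs_error("parse-error", "duplicate tip labels")
  if (is.null(tree$edge.length))
    gs_error("missing-lengths", "tree has no branch lengths")
  if (any(tree$edge.length < 0))
    gs_error("missing-lengths", "negative branch lengths")
  tree
}

#' Normalize species names for tree/table matching
#'
#' Lower-cases, trims, and collapses spaces/underscores so that
#' `"Bryodemella_tuberculata"` and `"bryodemella tuberculata"` match.
#'
#' @param x character vector of names.
#' @return normalized character vector.
#' @export
normalize_species_names <- function(x) {
  x <- tolower(trimws(x))
  gsub("[ _]+", "_", x)
}

#' Match trait values to tree tips and prune unmatched tips
#'
#' Species with several measurements are averaged to a single tip value (the
#' species mean). Tips without a trait value are pruned; the resulting
#' degree-2 nodes are suppressed with their branch lengths summed (as done by
#' [ape::keep.tip()]).
#'
#' @param tree an [ape::phylo].
#' @param values named numeric vector (names = species) or data.frame with
#'   columns `species` and `value` (several rows per species allowed).
#' @param name_normalizer function mapping raw names to a canonical form;
#'   default [normalize_species_names()].
#' @return list with `tree` (pruned), `tip_values` (named by the pruned
#'   tree's tip labels), `matched` (data.frame tip, species, value),
#'   `unmatched_tips` and `unmatched_species`.
#' @export
match_and_prune <- function(tree, values,
                            name_normalizer = normalize_species_names) {
  stopifnot(inherits(tree, "phylo"))
  if (is.data.frame(values)) {
    stopifnot(all(c("species", "value") %in% names(values)))
    sp <- values$species; v <- values$value
  } else {
    sp <- names(values); v <- as.numeric(values)
    gs_assert(!is.null(sp), "invalid-argument", "values must be named")
  }
  key <- name_normalizer(sp)
  means <- tapply(v, key, mean)

  tipkey <- name_normalizer(tree$tip.label)
  hit <- tipkey %in% names(means)
  if (sum(hit) < 2)
    gs_error("insufficient-tips", "fewer than 2 tips have trait values")
  pruned <- ape::keep.tip(tree, tree$tip.label[hit])
  tv <- as.numeric(means[name_normalizer(pruned$tip.label)])
  names(tv) <- pruned$tip.label
  gs_assert(all(tv > 0), "invalid-argument", "trait values must be positive")
  list(tree = pruned,
       tip_values = tv,
       matched = data.frame(tip = pruned$tip.label,
                            value = unname(tv), stringsAsFactors = FALSE),
       unmatched_tips = tree$tip.label[!hit],
       unmatched_species = sp[!key %in% tipkey])
}

#' Maximum-likelihood ancestral states under Brownian motion
#'
#' Under Brownian motion the tip values are multivariate normal with
#' covariance sigma^2 C, where `C[i,j]` is the shared root-to-tip path
#' length of tips i and j. The root estimate is the generalized least squares
#' mean `(1' C^-1 1)^-1 1' C^-1 x`; each internal node's ML estimate is the
#' same GLS mean computed with the tree re-rooted at that node (the standard
#' ML identity), realised here through the path-length form of the re-rooted
#' covariance, `V_j[i,k] = (d(j,i) + d(j,k) - d(i,k)) / 2`. The Brownian rate
#' is estimated as `sigma2_hat = (x - a 1)' C^-1 (x - a 1) / N`, and 95%
#' intervals are `estimate +/- 1.96 sqrt(variance)`.
#'
#' Zero-length terminal branches would make the covariance singular; they are
#' replaced by 1e-8 times the tree height, with a warning. Polytomies are
#' handled natively by the GLS formulation.
#'
#' @param tree rooted [ape::phylo] with branch lengths.
#' @param tips named numeric vector of trait values covering every tip.
#' @param nodes `"all"` (default) estimates every internal node; `"root"`
#'   computes only the root estimate and the Brownian rate, skipping the
#'   per-node re-rooting — useful in large simulation studies.
#' @return Object of class `bm_asr`: list with `nodes` (data.frame node id,
#'   estimate, variance, ci_lower, ci_upper; root only when
#'   `nodes = "root"`), `sigma2_hat`, `root_estimate`, `n_tips`, and `tree`.
#' @export
bm_asr <- function(tree, tips, nodes = c("all", "root")) {
  nodes_mode <- match.arg(nodes)
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  gs_assert(n >= 2, "insufficient-tips", "need at least 2 tips")
  gs_assert(all(tree$tip.label %in% names(tips)), "invalid-argument",
            "every tip needs a trait value")
  x <- as.numeric(tips[tree$tip.label])
  gs_assert(all(is.finite(x)), "invalid-argument", "trait values must be finite")

  height <- max(ape::node.depth.edgelength(tree))
  if (height <= 0) gs_error("degenerate-tree", "tree has zero total depth")
  term <- tree$edge[, 2] <= n
  if (any(tree$edge.length[term] == 0)) {
    warning("zero-length terminal branches replaced by 1e-8 x tree height")
    tree$edge.length[term & tree$edge.length == 0] <- 1e-8 * height
  }

  D <- ape::dist.nodes(tree)           # all pairwise path distances
  tipsi <- seq_len(n)
  Dtt <- D[tipsi, tipsi]
  root <- n + 1L
  node_ids <- if (nodes_mode == "root") root else n + seq_len(tree$Nnode)

  node_v <- function(j) {
    # covariance of tips as seen from node j (re-rooted shared path lengths)
    (outer(D[j, tipsi], D[j, tipsi], "+") - Dtt) / 2
  }
  gls_mean <- function(V) {
    Vi <- tryCatch(solve(V), error = function(e)
      gs_error("degenerate-tree", "singular tip covariance"))
    w <- colSums(Vi)
    c(est = sum(w * x) / sum(w), vfac = 1 / sum(w))
  }

  C <- node_v(root)
  gr <- gls_mean(C)
  a_root <- gr[["est"]]
  r <- x - a_root
  Ci <- solve(C)
  sigma2 <- as.numeric(t(r) %*% Ci %*% r) / n

  est <- vfac <- numeric(length(node_ids))
  for (k in seq_along(node_ids)) {
    g <- if (node_ids[k] == root) gr else gls_mean(node_v(node_ids[k]))
    est[k] <- g[["est"]]
    vfac[k] <- g[["vfac"]]
  }
  variance <- sigma2 * vfac
  half <- 1.96 * sqrt(variance)
  structure(list(nodes = data.frame(node = node_ids, estimate = est,
                                    variance = variance,
                                    ci_lower = est - half,
                                    ci_upper = est + half),
                 sigma2_hat = sigma2,
                 root_estimate = a_root,
                 n_tips = n, tree = tree),
            class = "bm_asr")
}

#' @export
print.bm_asr <- function(x, ...) {
  cat(sprintf("Brownian-motion ASR: %d tips, %d internal nodes\n",
              x$n_tips, nrow(x$nodes)))
  cat(sprintf("  root estimate %.4g (95%% CI %.4g..%.4g), sigma2_hat %.4g\n",
              x$root_estimate, x$nodes$ci_lower[1], x$nodes$ci_upper[1],
              x$sigma2_hat))
  invisible(x)
}

#' Annotate a tree with ancestral estimates
#'
#' Writes the per-node estimates as internal node labels (`"id|estimate"`)
#' and returns the labelled Newick string alongside a node table suitable
#' for CSV export.
#'
#' @param tree the tree the reconstruction was computed on.
#' @param result a [bm_asr()] result for `tree`.
#' @param digits significant digits for node-label estimates.
#' @return list with `newick` (character), `tree` (labelled phylo) and
#'   `node_table` (data.frame node, estimate, variance, ci_lower, ci_upper).
#' @export
annotate_tree <- function(tree, result, digits = 6) {
  stopifnot(inherits(tree, "phylo"), inherits(result, "bm_asr"))
  if (length(tree$tip.label) != result$n_tips ||
      nrow(result$nodes) != tree$Nnode)
    gs_error("inconsistent-input", "tree does not match the ASR result")
  lab <- sprintf("%d|%s", result$nodes$node,
                 formatC(result$nodes$estimate, digits = digits, format = "g"))
  tree$node.label <- lab
  list(newick = ape::write.tree(tree), tree = tree,
       node_table = result$nodes)
}
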
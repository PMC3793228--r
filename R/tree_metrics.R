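#' Read and validate an ultrametric chronogram
#'
#' Reads a rooted tree with branch lengths in Myr from a Newick or NEXUS file
#' and validates it for age-based analysis: at least two uniquely labelled
#' tips, branch lengths present and non-negative, rooted. Polytomies are
#' preserved. Ultrametricity is *not* enforced here; age-based operations
#' ([node_ages()], [crown_age()], [count_pleistocene_tips()]) check it
#' themselves via [check_ultrametric()].
#'
#' @param path path to the tree file.
#' @param format `"auto"` (sniff `#NEXUS` magic), `"newick"` or `"nexus"`.
#'   NEXUS files holding several trees yield an error; extract one first.
#' @return An object of class `"phylo"` (see [ape::read.tree()]).
#' @examples
#' tf <- tempfile(fileext = ".nwk")
#' writeLines("((A:1.0,B:1.0):3.0,C:4.0);", tf)
#' tr <- read_chronogram(tf)
#' crown_age(tr)
#' @export
read_chronogram <- function(path, format = c("auto", "newick", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_arg("tree file not found: %s", path)
  if (format == "auto") {
    first <- toupper(trimws(readLines(path, n = 1L, warn = FALSE)))
    format <- if (startsWith(first, "#NEXUS")) "nexus" else "newick"
  }
  tree <- tryCatch(
    if (format == "nexus") ape::read.nexus(path) else ape::read.tree(path),
    error = function(e) stop_arg("failed to parse %s as %s: %s",
                                 path, format, conditionMessage(e)))
  if (inherits(tree, "multiPhylo")) {
    if (length(tree) != 1L)
      stop_arg("%s contains %d trees; a chronogram file must hold exactly one",
               path, length(tree))
    tree <- tree[[1L]]
  }
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop_arg("failed to parse %s: no tree found", path)
  validate_chronogram(tree)
  tree
}

validate_chronogram <- function(tree) {
  if (ape::Ntip(tree) < 2L)
    stop_arg("chronogram must have at least 2 tips, found %d", ape::Ntip(tree))
  labs <- tree$tip.label
  if (any(is.na(labs) | labs == ""))
    stop_arg("all tip labels must be non-empty")
  if (anyDuplicated(labs))
    stop_arg("duplicate tip label(s): %s",
             paste(unique(labs[duplicated(labs)]), collapse = ", "))
  if (is.null(tree$edge.length))
    stop_arg("chronogram has no branch lengths")
  if (length(tree$edge.length) != nrow(tree$edge) || anyNA(tree$edge.length)) {
    bad <- which(is.na(tree$edge.length))[1L]
    stop_arg("missing branch length on edge %s",
             if (length(bad)) paste(tree$edge[bad, ], collapse = "->") else "(count mismatch)")
  }
  if (any(tree$edge.length < 0))
    stop_arg("negative branch length on edge %s",
             paste(tree$edge[which(tree$edge.length < 0)[1L], ], collapse = "->"))
  if (!ape::is.rooted(tree)) stop_arg("chronogram must be rooted")
  invisible(tree)
}

#' Write a chronogram to Newick
#'
#' @param tree a `"phylo"` object.
#' @param path output file path.
#' @param digits decimal places for branch lengths.
#' @return `path`, invisibly.
#' @export
write_chronogram <- function(tree, path, digits = 6) {
  ape::write.tree(tree, file = path, digits = digits)
  invisible(path)
}

#' Test whether a tree is ultrametric
#'
#' A chronogram is usable for age-based operations only if all root-to-tip
#' path lengths agree. Dating software emits rounding noise, so agreement is
#' judged against a tolerance expressed relative to the tree depth.
#'
#' @param tree a `"phylo"` object.
#' @param tol tolerance on the spread of root-to-tip depths, relative to the
#'   maximum depth (absolute when the tree has zero depth).
#' @return List with `ok` (logical) and `deviation`, the absolute spread
#'   (max minus min root-to-tip depth) in Myr.
#' @export
check_ultrametric <- function(tree, tol = 1e-5) {
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  dev <- max(depths) - min(depths)
  scale <- max(depths)
  list(ok = dev <= tol * (if (scale > 0) scale else 1), deviation = dev)
}

#' Node ages of an ultrametric chronogram
#'
#' Ages in Ma before present for every node: tips at 0 (exactly; sub-tolerance
#' rounding noise is absorbed), the root at the crown age, each internal node
#' at its distance to any descendant tip.
#'
#' @param tree a `"phylo"` object passing [check_ultrametric()].
#' @param tol ultrametricity tolerance, relative to tree depth.
#' @return Named numeric vector indexed by node number (1..Ntip are tips,
#'   named by tip label; internal nodes named `"node<N>"`).
#' @export
node_ages <- function(tree, tol = 1e-5) {
  validate_chronogram(tree)
  chk <- check_ultrametric(tree, tol)
  if (!chk$ok)
    stop_arg("tree is not ultrametric: root-to-tip depth spread %.3g exceeds tolerance",
             chk$deviation)
  depths <- ape::node.depth.edgelength(tree)
  ntip <- ape::Ntip(tree)
  ages <- max(depths[seq_len(ntip)]) - depths
  ages[seq_len(ntip)] <- 0 # tips are extant by construction
  names(ages) <- c(tree$tip.label,
                   paste0("node", (ntip + 1L):(ntip + tree$Nnode)))
  ages
}

#' Crown age of a chronogram
#'
#' Age of the root node (the crown node of the sampled clade) in Ma.
#'
#' @inheritParams node_ages
#' @return Crown age in Ma.
#' @examples
#' tr <- ape::read.tree(text = "((A:1.0,B:1.0):3.0,C:4.0);")
#' crown_age(tr) # 4
#' @export
crown_age <- function(tree, tol = 1e-5) {
  ages <- node_ages(tree, tol)
  unname(ages[ape::Ntip(tree) + 1L])
}

#' Count tips that diverged during the Pleistocene
#'
#' Counts the tips of a chronogram whose divergence from their most recent
#' ancestor node is younger than a threshold age, by default the base of the
#' Pleistocene at 2.58 Ma. A tip's divergence age is its parent-node age; for
#' a polytomy every child uses the polytomy's age.
#'
#' @param tree a `"phylo"` object passing [check_ultrametric()].
#' @param threshold age cutoff in Ma, > 0.
#' @param rule boundary handling: `"strict"` counts a tip iff its parent age
#'   is strictly below the threshold ("within the last 2.58 Myr");
#'   `"inclusive"` also counts exact ties.
#' @param tol ultrametricity tolerance.
#' @return List with `k` (tips younger than the cutoff), `n` (total tips) and
#'   `parent_ages` (named vector of per-tip divergence ages, Ma).
#' @examples
#' tr <- ape::read.tree(text = "((A:1.0,B:1.0):3.0,C:4.0);")
#' count_pleistocene_tips(tr)[c("k", "n")] # A and B split at 1.0 Ma: k = 2
#' @export
count_pleistocene_tips <- function(tree, threshold = 2.58,
                                   rule = c("strict", "inclusive"),
                                   tol = 1e-5) {
  rule <- match.arg(rule)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop_arg("'threshold' must be a single positive age in Ma")
  ages <- node_ages(tree, tol)
  ntip <- ape::Ntip(tree)
  tip_edges <- tree$edge[, 2] <= ntip
  parent_ages <- ages[tree$edge[tip_edges, 1]]
  names(parent_ages) <- tree$tip.label[tree$edge[tip_edges, 2]]
  parent_ages <- parent_ages[tree$tip.label]
  k <- if (rule == "strict") sum(parent_ages < threshold)
       else sum(parent_ages <= threshold)
  list(k = as.integer(k), n = ntip, parent_ages = parent_ages)
}
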
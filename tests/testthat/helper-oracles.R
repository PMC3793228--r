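# Independent oracles used across the suite. These re-derive quantities by a
# different route than the package code they check.

# Forward moment equation of the constant-rate birth-death process, written
# from first principles: expected extant diversity at time t conditional on
# clade survival. Stem: one founding lineage with extant descendants.
# Crown: at least one of the two crown lineages with extant descendants.
oracle_expected_n <- function(r, t, eps, mode) {
  if (eps == 0) return(if (mode == "crown") 2 * exp(r * t) else exp(r * t))
  if (mode == "stem") {
    (exp(r * t) - eps) / (1 - eps)
  } else {
    p_ext <- eps * (1 - exp(-r * t)) / (1 - eps * exp(-r * t))
    2 * exp(r * t) / (1 - p_ext^2)
  }
}

# Invert the moment equation for r by bisection (uniroot on log scale bounds).
oracle_rate_by_bisection <- function(n, t, eps, mode, tol = 1e-12) {
  f <- function(r) oracle_expected_n(r, t, eps, mode) - n
  stats::uniroot(f, lower = 1e-12, upper = log(n) / t + 10,
                 tol = tol)$root
}

# Per-tip divergence ages read straight off the pendant edges: for an
# ultrametric tree a tip's parent age equals its pendant branch length.
oracle_tip_parent_ages <- function(tree) {
  ntip <- ape::Ntip(tree)
  pend <- tree$edge[, 2] <= ntip
  ages <- tree$edge.length[pend]
  names(ages) <- tree$tip.label[tree$edge[pend, 2]]
  ages[tree$tip.label]
}

toy_tree <- function(txt) ape::read.tree(text = txt)

two_hotspot_table <- function() {
  data.frame(lineage_id = c("x1", "x2", "y1", "y2"),
             hotspot = c("X", "X", "Y", "Y"),
             rate = c(3, 1, 2, 0))
}
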
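# branching times of a Yule (pure-birth) clade, sampled directly: the
# internode with k lineages lasts Exp(k * lambda), final interval included
sim_yule_bt <- function(n, lambda = 1) {
  g <- stats::rexp(n - 1, rate = lambda * (2:n))
  new_branching_times(rev(cumsum(rev(g)))[seq_len(n - 1)])
}

# Yule with a rate shift once m lineages have accumulated
sim_shift_bt <- function(n, m, l1 = 1, l2 = 0.1) {
  k <- 2:n
  g <- stats::rexp(n - 1, rate = ifelse(k < m, l1, l2) * k)
  new_branching_times(rev(cumsum(rev(g)))[seq_len(n - 1)])
}

unit_depth <- function(tree) {
  tree$edge.length <- tree$edge.length / tree_depth(tree)
  tree
}

# compact occurrence table builder
occ_df <- function(species, lon, lat, ...) {
  data.frame(species = species, lon = lon, lat = lat, ...)
}
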
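# Independent oracles and small fixture builders. Each oracle deliberately
# avoids the code path it checks: brute-force scans, exhaustive
# enumerations, and closed forms only.

# pI by exhaustive scan of the charge curve on a 0.001-pH grid; the
# Henderson-Hasselbalch terms are evaluated directly, not via net_charge().
grid_pi <- function(groups, lo = -2, hi = 16, step = 0.001) {
  grid <- seq(lo, hi, by = step)
  base <- groups$polarity == "base"
  pos <- colSums(groups$count[base] /
                   (1 + 10^outer(-groups$pka[base], grid, "+")))
  neg <- colSums(groups$count[!base] /
                   (1 + 10^outer(groups$pka[!base], grid, "-")))
  grid[which.min(abs(pos - neg))]
}

# Minimum state changes by enumerating every internal-node assignment.
brute_force_parsimony <- function(tree, states) {
  states <- states[tree$tip.label]
  alphabet <- unique(unname(states))
  n_tip <- length(tree$tip.label)
  internal <- sort(unique(tree$edge[, 1]))
  grids <- rep(list(alphabet), length(internal))
  combos <- do.call(expand.grid, c(grids, stringsAsFactors = FALSE))
  best <- Inf
  node_state <- character(n_tip + tree$Nnode)
  node_state[seq_len(n_tip)] <- states
  for (i in seq_len(nrow(combos))) {
    node_state[internal] <- as.character(combos[i, ])
    changes <- sum(node_state[tree$edge[, 1]] != node_state[tree$edge[, 2]])
    if (changes < best) best <- changes
  }
  best
}

# One-sided hypergeometric tail by explicit enumeration over all tables
# with the observed margins, probabilities from binomial coefficients.
hypergeom_tail <- function(a, b, c, d) {
  n <- a + b + c + d
  k_charged <- a + b    # margin: charged sites
  n_sel <- a + c        # margin: selected sites
  denom <- choose(n, n_sel)
  xs <- max(0, n_sel - (n - k_charged)):min(k_charged, n_sel)
  probs <- choose(k_charged, xs) * choose(n - k_charged, n_sel - xs) / denom
  sum(probs[xs >= a])
}

# Toy ortholog pI set from a long data frame literal.
toy_piset <- function(...) {
  ortholog_pi_set(data.frame(...))
}

write_temp_fasta <- function(entries, dir = tempdir()) {
  path <- tempfile("seqs", fileext = ".fasta", tmpdir = dir)
  writeLines(unlist(lapply(names(entries), function(h) {
    c(paste0(">", h), entries[[h]])
  })), path)
  path
}

write_temp_tsv <- function(df, name = "tab") {
  path <- tempfile(name, fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Random trees for parsimony property tests: random topology via ape.
random_leaf_tree <- function(n_leaves) {
  ape::rtree(n_leaves, rooted = TRUE, br = NULL)
}

# keep test output clean; WARN and ERROR still surface
options(pishift.log_level = "WARN")
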
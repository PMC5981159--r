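# Independent brute-force oracle for Brownian-motion ancestral states,
# plus small fixture builders shared across test files.

# GLS estimate of every internal node's state from the explicit BM
# covariance structure. For node v and sequenced tips i, j the covariance
# (up to sigma^2) of tip states, measured from v as the root, is the
# shared path length V_ij = (d(v,i) + d(v,j) - d(i,j)) / 2; the marginal
# estimate is (1' V^-1 x) / (1' V^-1 1). Entirely independent of the
# message-passing engine: only patristic distances are used.
gls_node_states <- function(tree, traits, eps = 1e-6) {
  tree$edge.length[tree$edge.length == 0] <- eps
  D <- ape::dist.nodes(tree)
  ntip <- length(tree$tip.label)
  tips <- match(rownames(traits), tree$tip.label)
  nodes <- (ntip + 1L):(ntip + tree$Nnode)
  est <- matrix(NA_real_, length(nodes), ncol(traits),
                dimnames = list(as.character(nodes), colnames(traits)))
  for (v in nodes) {
    dv <- D[v, tips]
    V <- (outer(dv, dv, "+") - D[tips, tips]) / 2
    diag(V) <- dv
    Vi <- solve(V)
    w <- colSums(Vi) / sum(Vi)
    est[as.character(v), ] <- as.numeric(t(w) %*% as.matrix(traits))
  }
  est
}

# Random tree with strictly positive branch lengths and a random sequenced
# subset of >= 2 tips; trait values drawn uniformly.
random_asr_case <- function(n_tips, n_traits = 2L) {
  tree <- ape::rtree(n_tips)
  tree$edge.length <- stats::runif(nrow(tree$edge), 0.05, 2)
  n_seq <- sample(2:n_tips, 1L)
  seq_tips <- sample(tree$tip.label, n_seq)
  traits <- matrix(stats::runif(n_seq * n_traits, 0, 10), n_seq, n_traits,
                   dimnames = list(seq_tips, paste0("K", seq_len(n_traits))))
  list(tree = tree, traits = traits)
}

# Minimal 5-tip reference bundle with hand-set values.
tiny_bundle <- function() {
  tree <- ape::read.tree(text = "((g1:1,g2:1):1,(g3:1,g4:2):1,g5:3);")
  traits <- matrix(c(1, 0, 2,
                     0, 1, 1,
                     3, 2, 0), nrow = 3, byrow = TRUE,
                   dimnames = list(c("g1", "g2", "g3"),
                                   c("K00001", "K00002", "K00003")))
  copies <- c(g1 = 1, g2 = 2, g3 = 4)
  seqs <- c(g1 = "ACGTACGTACGTACGTACGT", g2 = "ACGTACGAACGTACGTACGT",
            g3 = "TTGTACGTACGTACGTACCT", g4 = "TTGTACGTACGAACGTACCT",
            g5 = "GGGTACGTACGTACGTACCC")
  brite <- data.frame(
    ko = c("K00001", "K00002", "K00002"),
    level1 = "Metabolism",
    level2 = c("Carbohydrate metabolism", "Energy metabolism",
               "Amino acid metabolism"),
    level3 = c("Glycolysis", "Methane metabolism", "Lysine biosynthesis"),
    stringsAsFactors = FALSE)
  suppressWarnings(
    format_tree_and_traits(tree, traits, copies, seqs = seqs, brite = brite))
}

# Random bundle via the synthetic generators, small enough for fast tests.
random_bundle <- function(seed, n_tips = 12L, f = 0.75) {
  cfg <- sim_config(n_tips = n_tips, f = f, seq_length = 120L,
                    samples = 2L, depth = 200L,
                    root_traits = stats::setNames(rep(8, 5L),
                                                  sprintf("K%05d", 1:5)),
                    seed = seed)
  simulate_fixture(cfg)
}
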
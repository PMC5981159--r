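# Seeded synthetic-data generators: Yule trees, Brownian-motion trait
# counts, Jukes-Cantor 16S sequences, Dirichlet-multinomial OTU sampling,
# and hold-out benchmarks. These emulate the structure the inference
# assumes — a modest set of sequenced genomes embedded in a larger 16S
# phylogeny — with models simple enough to admit closed-form checks.
#
# Every generator derives its RNG state from the config seed plus a fixed
# per-operation offset, so each is deterministic standalone and composed
# runs are reproducible end to end.
.SIM_OFFSETS <- c(tree = 0L, traits = 1L, seqs = 2L, copies = 3L,
                  otus = 4L, brite = 5L)

.sim_seed <- function(config, op) {
  set.seed((config$seed + .SIM_OFFSETS[[op]]) %% .Machine$integer.max)
}

#' Simulation configuration
#'
#' Bundles the parameters of the synthetic generators. The seed is
#' mandatory: there is no implicit entropy.
#'
#' @param n_tips Number of tree tips (organisms), `>= 2`.
#' @param birth Yule birth rate per unit time (default 1; with `n_tips`
#'   around 100 this gives root-to-tip depths near `log(n_tips)`).
#' @param sigma2 Brownian-motion trait variance per unit branch length.
#' @param root_traits Named numeric vector of root trait values; names are
#'   KO IDs. Default: 20 KO families at value 10 (large enough that the
#'   non-negativity clamp on simulated counts rarely binds).
#' @param seq_length 16S sequence length in bases.
#' @param mu Per-site Jukes-Cantor substitution rate.
#' @param f Fraction of tips flagged as sequenced genomes, in `(0, 1]`.
#' @param samples Number of community samples.
#' @param depth Sequencing depth (reads per sample).
#' @param alpha Symmetric Dirichlet concentration for per-sample tip
#'   proportions (default 0.5: uneven communities).
#' @param copy_root,copy_sigma2 Root value and BM rate for the 16S
#'   copy-number trait (counts clamped to `>= 1`).
#' @param query_mutations Extra point mutations applied to each OTU
#'   representative sequence (0 = identical to the tip sequence).
#' @param seed Integer random seed (mandatory).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_tips = 100L, birth = 1, sigma2 = 1,
                       root_traits = stats::setNames(
                         rep(10, 20L), sprintf("K%05d", 1:20)),
                       seq_length = 250L, mu = 0.5, f = 0.8,
                       samples = 3L, depth = 1000L, alpha = 0.5,
                       copy_root = 3, copy_sigma2 = 0.2,
                       query_mutations = 0L, seed) {
  if (missing(seed)) stop("sim_config: seed is mandatory")
  cfg <- list(n_tips = as.integer(n_tips), birth = birth, sigma2 = sigma2,
              root_traits = root_traits, seq_length = as.integer(seq_length),
              mu = mu, f = f, samples = as.integer(samples),
              depth = as.integer(depth), alpha = alpha,
              copy_root = copy_root, copy_sigma2 = copy_sigma2,
              query_mutations = as.integer(query_mutations),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_tips >= 2L, birth > 0, sigma2 >= 0, mu >= 0,
              seq_length >= 1L, f > 0, f <= 1, samples >= 1L, depth >= 1L,
              alpha > 0, f * n_tips >= 2)
  })
  if (is.null(names(cfg$root_traits)))
    stop("root_traits must be named by KO ID")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a Yule reference tree
#'
#' Pure-birth tree with exponential waiting times, tips labeled
#' `g1..gN` in tip order, and a uniformly random `f`-fraction flagged as
#' sequenced (attribute `sequenced`, a named logical).
#'
#' @param config A [sim_config()].
#' @return An [ape::phylo] with attribute `sequenced`.
#' @export
simulate_tree <- function(config) {
  .sim_seed(config, "tree")
  tree <- phytools::pbtree(b = config$birth, n = config$n_tips, quiet = TRUE)
  tree$tip.label <- paste0("g", seq_len(config$n_tips))
  n_seq <- max(2L, round(config$f * config$n_tips))
  seq_tips <- sample(tree$tip.label, n_seq)
  attr(tree, "sequenced") <- stats::setNames(
    tree$tip.label %in% seq_tips, tree$tip.label)
  tree
}

#' Evolve trait counts along a tree under Brownian motion
#'
#' Each trait starts at its root value and evolves with variance
#' `sigma2` per unit branch length. Tip values are turned into counts by
#' `round(max(0, x))`. The observed table exposes only sequenced tips; the
#' pre-rounding truth for all tips is returned alongside for recovery
#' benchmarks.
#'
#' @param tree Tree from [simulate_tree()] (attribute `sequenced` required
#'   unless `sequenced` is given).
#' @param config A [sim_config()].
#' @param sequenced Optional named logical overriding the tree attribute.
#' @return List with `observed` (sequenced-tip count matrix), `truth`
#'   (all-tip pre-rounding matrix) and `truth_counts` (all-tip counts).
#' @export
evolve_traits <- function(tree, config, sequenced = NULL) {
  if (is.null(sequenced)) sequenced <- attr(tree, "sequenced")
  stopifnot(!is.null(sequenced))
  .sim_seed(config, "traits")
  K <- length(config$root_traits)
  truth <- matrix(NA_real_, length(tree$tip.label), K,
                  dimnames = list(tree$tip.label, names(config$root_traits)))
  for (k in seq_len(K)) {
    x <- phytools::fastBM(tree, a = config$root_traits[[k]],
                          sig2 = config$sigma2)
    truth[, k] <- x[tree$tip.label]
  }
  counts <- round(pmax(truth, 0))
  list(observed = counts[names(sequenced)[sequenced], , drop = FALSE],
       truth = truth, truth_counts = counts)
}

#' Evolve 16S copy numbers along a tree
#'
#' One-trait Brownian motion from `copy_root` at rate `copy_sigma2`,
#' rounded and clamped to `>= 1`, giving phylogenetically autocorrelated
#' integer copy numbers. Returns all-tip truth; the bundle exposes only the
#' sequenced entries.
#'
#' @inheritParams evolve_traits
#' @return Named numeric vector over all tips.
#' @export
evolve_copy_numbers <- function(tree, config) {
  .sim_seed(config, "copies")
  x <- phytools::fastBM(tree, a = config$copy_root, sig2 = config$copy_sigma2)
  pmax(round(x[tree$tip.label]), 1)
}

#' Evolve 16S sequences along a tree under Jukes-Cantor
#'
#' The root sequence is uniform over `{A,C,G,T}`; substitutions accrue at
#' rate `mu` per site per unit branch length.
#'
#' @inheritParams evolve_traits
#' @return Named character vector of tip sequences.
#' @export
evolve_sequences <- function(tree, config) {
  .sim_seed(config, "seqs")
  sim <- phangorn::simSeq(tree, l = config$seq_length, rate = config$mu,
                          type = "DNA")
  m <- toupper(as.character(sim))
  stats::setNames(apply(m, 1L, paste, collapse = ""), rownames(m))[
    tree$tip.label]
}

#' Sample an OTU table from a tree's community
#'
#' Per-sample tip proportions are drawn from a symmetric Dirichlet
#' (concentration `alpha`) and reads multinomially at depth `depth`. One
#' OTU per tip; representative sequences are the tip sequences, optionally
#' with `query_mutations` extra point mutations each.
#'
#' @inheritParams evolve_traits
#' @param seqs Tip sequences from [evolve_sequences()].
#' @return List with `table` (OTU x sample counts), `seqs` (representative
#'   sequences named by OTU ID) and `origin` (OTU ID -> tip label).
#' @export
sample_otu_table <- function(tree, config, seqs = NULL) {
  .sim_seed(config, "otus")
  n <- length(tree$tip.label)
  otu_ids <- paste0("otu", seq_len(n))
  tab <- matrix(0L, n, config$samples,
                dimnames = list(otu_ids, paste0("s", seq_len(config$samples))))
  for (s in seq_len(config$samples)) {
    g <- stats::rgamma(n, shape = config$alpha)   # symmetric Dirichlet
    tab[, s] <- stats::rmultinom(1L, config$depth, prob = g / sum(g))
  }
  rep_seqs <- NULL
  if (!is.null(seqs)) {
    rep_seqs <- stats::setNames(seqs[tree$tip.label], otu_ids)
    if (config$query_mutations > 0L) {
      for (i in seq_len(n)) {
        chars <- strsplit(rep_seqs[[i]], "", fixed = TRUE)[[1L]]
        pos <- sample(length(chars), min(config$query_mutations, length(chars)))
        for (p in pos)
          chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
        rep_seqs[[i]] <- paste(chars, collapse = "")
      }
    }
  }
  list(table = tab, seqs = rep_seqs,
       origin = stats::setNames(tree$tip.label, otu_ids))
}

#' Generate a synthetic KO-to-BRITE membership map
#'
#' Assigns each KO 1-3 level-3 pathway memberships drawn from a small
#' synthetic hierarchy, so both collapse modes are exercised.
#'
#' @param kos Character vector of KO IDs.
#' @param config A [sim_config()].
#' @return A BRITE map `data.frame`.
#' @export
simulate_brite <- function(kos, config) {
  .sim_seed(config, "brite")
  l1 <- c("Metabolism", "Genetic Information Processing",
          "Environmental Information Processing")
  rows <- lapply(kos, function(k) {
    n_memb <- sample(1:3, 1L)
    top <- sample(l1, n_memb, replace = TRUE)
    data.frame(ko = k, level1 = top,
               level2 = paste(top, "group", sample(1:4, n_memb, replace = TRUE)),
               level3 = paste0("Pathway ", sample(LETTERS[1:12], n_memb)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[!duplicated(paste(out$ko, out$level1, out$level2, out$level3)), ]
}

#' Generate a complete synthetic fixture
#'
#' A reference bundle plus a query dataset and the hidden truth, all from
#' one config: tree, trait counts, copy numbers, 16S sequences, BRITE map,
#' OTU table and representative sequences.
#'
#' @param config A [sim_config()].
#' @return List with `bundle` (a `ref_bundle`), `query` (list `table`,
#'   `seqs`, `origin`) and `truth` (list `traits` pre-rounding for all
#'   tips, `trait_counts`, `copy_numbers`).
#' @export
simulate_fixture <- function(config) {
  tree <- simulate_tree(config)
  sequenced <- attr(tree, "sequenced")
  tr <- evolve_traits(tree, config)
  cn_all <- evolve_copy_numbers(tree, config)
  seqs <- evolve_sequences(tree, config)
  brite <- simulate_brite(names(config$root_traits), config)
  bundle <- format_tree_and_traits(tree, tr$observed,
                                   cn_all[names(sequenced)[sequenced]],
                                   seqs = seqs, brite = brite)
  query <- sample_otu_table(tree, config, seqs)
  list(bundle = bundle, query = query,
       truth = list(traits = tr$truth, trait_counts = tr$truth_counts,
                    copy_numbers = cn_all))
}

#' Build a hold-out benchmark
#'
#' Returns the fixture exactly as the pipeline sees it (held-out tips are
#' unsequenced in the bundle) together with the hidden truth needed to
#' score recovery: pre-rounding trait values for every tip and the true
#' tip of origin of every OTU.
#'
#' @param config A [sim_config()] with `f < 1`.
#' @return List with `bundle`, `query`, `truth` and `holdout` (character
#'   vector of held-out tip labels).
#' @export
make_holdout_benchmark <- function(config) {
  if (config$f >= 1) stop("hold-out benchmark requires f < 1")
  fx <- simulate_fixture(config)
  seqd <- fx$bundle$sequenced
  fx$holdout <- names(seqd)[!seqd]
  fx
}
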
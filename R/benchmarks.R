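# Seeded benchmark replicates used to characterize prediction quality on
# synthetic communities: hold-out trait recovery, and the focused-versus-
# distant reference contrast.

#' One hold-out trait-recovery replicate
#'
#' Simulates a Yule tree community, hides a fraction of tips from the
#' reference, predicts their KO trait values from the sequenced remainder,
#' and scores recovery against the hidden pre-rounding truth: the pooled
#' Pearson correlation over (held-out tip, trait) pairs, and per-NSTI-
#' tercile mean absolute errors (prediction error is expected to grow with
#' distance from the nearest sequenced taxon).
#'
#' @param seed Integer seed for this replicate.
#' @param n_tips,f,sigma2 Simulation conditions (defaults: 100 tips, 80%
#'   sequenced, unit BM rate).
#' @return List with `r` (pooled Pearson r), `tercile_mae` (length-3
#'   vector, NSTI terciles low to high) and `monotone` (logical: MAE
#'   non-decreasing across terciles).
#' @export
benchmark_trait_recovery <- function(seed, n_tips = 100L, f = 0.8,
                                     sigma2 = 1) {
  cfg <- sim_config(n_tips = n_tips, f = f, sigma2 = sigma2, seed = seed)
  tree <- simulate_tree(cfg)
  seqd <- attr(tree, "sequenced")
  tr <- evolve_traits(tree, cfg)
  bundle <- format_tree_and_traits(
    tree, tr$observed,
    stats::setNames(rep(1, sum(seqd)), names(seqd)[seqd]))
  pred <- predict_tip_traits(bundle)
  hold <- names(seqd)[!seqd]
  r <- pearson_r2(as.vector(pred$traits[hold, , drop = FALSE]),
                  as.vector(tr$truth[hold, , drop = FALSE]))$r
  mae <- rowMeans(abs(pred$traits[hold, , drop = FALSE] -
                        tr$truth[hold, , drop = FALSE]))
  terc <- cut(rank(pred$nsti[hold], ties.method = "first"), 3L,
              labels = FALSE)
  tm <- as.numeric(tapply(mae, terc, mean))
  list(r = r, tercile_mae = tm,
       monotone = tm[1] <= tm[2] && tm[2] <= tm[3])
}

#' One focused-versus-distant reference contrast replicate
#'
#' Simulates one community and compares trait prediction accuracy under
#' two references of equal size: a "focused" reference whose sequenced
#' tips are spread across the tree (low mean NSTI, the matched-reference
#' setting) and a "distant" reference whose sequenced tips all come from a
#' single clade (high mean NSTI, the mismatched-database setting).
#' Accuracy is the squared pooled Pearson correlation between predicted
#' and true (pre-rounding) trait values over the tips outside each
#' reference.
#'
#' @param seed Integer seed for this replicate.
#' @param n_tips,sigma2 Simulation conditions.
#' @param ref_size Number of sequenced reference tips in each variant.
#' @return List with `focused_r2`, `distant_r2`, `focused_nsti`,
#'   `distant_nsti` (mean NSTI over non-reference tips).
#' @export
benchmark_reference_contrast <- function(seed, n_tips = 100L, sigma2 = 1,
                                         ref_size = 20L) {
  cfg <- sim_config(n_tips = n_tips, f = ref_size / n_tips,
                    sigma2 = sigma2, seed = seed)
  tree <- simulate_tree(cfg)
  all_seq <- stats::setNames(rep(TRUE, n_tips), tree$tip.label)
  tr <- evolve_traits(tree, cfg, sequenced = all_seq)

  score <- function(ref_tips) {
    bundle <- format_tree_and_traits(
      tree, tr$truth_counts[ref_tips, , drop = FALSE],
      stats::setNames(rep(1, length(ref_tips)), ref_tips))
    pred <- predict_tip_traits(bundle)
    other <- setdiff(tree$tip.label, ref_tips)
    list(r2 = pearson_r2(as.vector(pred$traits[other, , drop = FALSE]),
                         as.vector(tr$truth[other, , drop = FALSE]))$r_squared,
         nsti = mean(pred$nsti[other]))
  }

  set.seed(2L * seed + 1L)
  focused <- sample(tree$tip.label, ref_size)   # clade-proportional spread
  nodes <- (n_tips + 1L):(n_tips + tree$Nnode)
  clades <- phangorn::Descendants(tree, nodes, "tips")
  sizes <- lengths(clades)
  pick <- which.min(abs(sizes - ref_size))      # one concentrated clade
  distant <- tree$tip.label[clades[[pick]]]

  sf <- score(focused)
  sd_ <- score(distant)
  list(focused_r2 = sf$r2, distant_r2 = sd_$r2,
       focused_nsti = sf$nsti, distant_nsti = sd_$nsti)
}
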
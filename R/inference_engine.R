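# Brownian-motion ancestral state reconstruction by Gaussian message
# passing (Felsenstein pruning with the rerooting convention), trait
# prediction for unsequenced tips, and nearest-sequenced-taxon distances.
#
# Under BM the ML estimate of a node's state is an inverse-branch-length
# weighted average of the messages arriving along its incident edges. A
# message summarizes a subtree as (mean, effective length): a sequenced tip
# at the far end of an edge of length t contributes (x, t); combining k
# messages at a node gives mean sum(x_i/t_i)/sum(1/t_i) and effective
# length 1/sum(1/t_i); passing through an edge adds its length. Treating
# each internal node in turn as the root (all sequenced tips contributing
# through effective lengths) yields the marginal estimates; for two child
# subtrees this is the classic "prune and add t_parent + t_a*t_b/(t_a+t_b)"
# recursion. Multifurcations are handled natively. Unsequenced tips send no
# message, so they never influence the reconstruction.

# Branch lengths of exactly 0 are replaced by this epsilon inside the
# engine only (never in user data) to avoid division by zero in the
# inverse-length weights.
.BL_EPSILON <- 1e-6

#' Reconstruct ancestral trait states under Brownian motion
#'
#' Computes, for every internal node and every trait column, the
#' maximum-likelihood Brownian-motion state estimate given the sequenced
#' tips, using the rerooted weighted-average (pruning) scheme. Unsequenced
#' tips (tips without a trait row) are excluded from the computation.
#'
#' @param tree An [ape::phylo] tree. Zero-length branches are clamped to
#'   `1e-6` internally.
#' @param traits Numeric matrix, rows = sequenced tip labels, columns =
#'   traits. At least 2 rows must match tips.
#' @return Numeric matrix (internal node x trait). Row names are ape node
#'   numbers, `as.character((Ntip+1):(Ntip+Nnode))`.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' x <- matrix(c(0, 2, 6), dimnames = list(c("A", "B", "C"), "K00001"))
#' reconstruct_ancestral_states(tr, x)  # root 22/7, node AB 12/7
#' @export
reconstruct_ancestral_states <- function(tree, traits) {
  stopifnot(inherits(tree, "phylo"))
  traits <- as.matrix(traits)
  if (ncol(traits) < 1L) stop("trait table has no columns")
  if (any(is.na(traits))) {
    all_missing <- colnames(traits)[colSums(is.na(traits)) == nrow(traits)]
    if (length(all_missing) > 0L)
      stop("trait column(s) entirely missing: ",
           paste(all_missing, collapse = ", "))
    stop("missing values in trait table")
  }
  seq_tips <- intersect(tree$tip.label, rownames(traits))
  if (length(seq_tips) < 2L)
    stop("ancestral state reconstruction requires >= 2 sequenced tips")
  msg <- .bm_messages(tree, traits[seq_tips, , drop = FALSE])
  ntip <- length(tree$tip.label)
  nodes <- (ntip + 1L):(ntip + tree$Nnode)
  prec <- msg$dn_prec[nodes] + msg$up_prec[nodes]
  est <- (msg$dn_wsum[nodes, , drop = FALSE] +
            msg$up_wsum[nodes, , drop = FALSE]) / prec
  dimnames(est) <- list(as.character(nodes), colnames(traits))
  est
}

# Gaussian message passing over the tree. Returns, for every node, the
# precision (1/effective length) and precision-weighted mean sum of
#  - dn: the combined, edge-extended messages from the node's children;
#  - up: the message arriving from the rest of the tree through the parent
#        edge (already extended by that edge).
# A precision of 0 marks an absent message (no sequenced tips in that
# direction).
.bm_messages <- function(tree, x) {
  ntip <- length(tree$tip.label)
  ntot <- ntip + tree$Nnode
  K <- ncol(x)
  po <- ape::reorder.phylo(tree, "postorder")
  elen <- po$edge.length
  elen[elen == 0] <- .BL_EPSILON
  parent <- po$edge[, 1L]
  child <- po$edge[, 2L]
  nedge <- nrow(po$edge)

  tip_state <- matrix(NA_real_, ntip, K)
  idx <- match(rownames(x), tree$tip.label)
  tip_state[idx, ] <- x
  is_seq_tip <- logical(ntot)
  is_seq_tip[idx] <- TRUE

  dn_prec <- numeric(ntot)
  dn_wsum <- matrix(0, ntot, K)
  edge_w <- numeric(nedge)          # weight of the message along each edge
  edge_mean <- matrix(0, nedge, K)  # its mean (valid only when edge_w > 0)

  for (e in seq_len(nedge)) {       # postorder: subtrees before their root
    ch <- child[e]
    if (ch <= ntip) {
      if (!is_seq_tip[ch]) next
      w <- 1 / elen[e]
      m <- tip_state[ch, ]
    } else {
      if (dn_prec[ch] == 0) next
      w <- 1 / (1 / dn_prec[ch] + elen[e])
      m <- dn_wsum[ch, ] / dn_prec[ch]
    }
    edge_w[e] <- w
    edge_mean[e, ] <- m
    dn_prec[parent[e]] <- dn_prec[parent[e]] + w
    dn_wsum[parent[e], ] <- dn_wsum[parent[e], ] + w * m
  }

  up_prec <- numeric(ntot)
  up_wsum <- matrix(0, ntot, K)
  for (e in rev(seq_len(nedge))) {  # preorder: parents before children
    pa <- parent[e]
    ch <- child[e]
    # everything at pa except the message that came up through this edge
    p_other <- dn_prec[pa] - edge_w[e] + up_prec[pa]
    if (p_other <= 0) next
    ws_other <- dn_wsum[pa, ] - edge_w[e] * edge_mean[e, ] + up_wsum[pa, ]
    w <- 1 / (1 / p_other + elen[e])
    up_prec[ch] <- w
    up_wsum[ch, ] <- w * (ws_other / p_other)
  }

  list(dn_prec = dn_prec, dn_wsum = dn_wsum,
       up_prec = up_prec, up_wsum = up_wsum)
}

#' Nearest-sequenced-taxon distances
#'
#' For every tip, the minimum patristic distance (sum of branch lengths) to
#' any sequenced tip: the NSTI reliability proxy. Sequenced tips score 0.
#'
#' @param tree An [ape::phylo] tree.
#' @param sequenced Character vector of sequenced tip labels, or a named
#'   logical over tips.
#' @return Named numeric vector over all tips.
#' @export
compute_nsti <- function(tree, sequenced) {
  if (is.logical(sequenced)) sequenced <- names(sequenced)[sequenced]
  sequenced <- intersect(tree$tip.label, sequenced)
  if (length(sequenced) < 1L) stop("no sequenced tips")
  D <- stats::cophenetic(tree)
  d <- apply(D[, sequenced, drop = FALSE], 1L, min)
  d[sequenced] <- 0
  d[tree$tip.label]
}

#' Predict tip trait values from reconstructed ancestral states
#'
#' Sequenced tips copy their observed trait rows exactly (and get NSTI 0);
#' each unsequenced tip receives the reconstructed state of its most
#' proximal ancestor whose state is defined. All predictions are clamped to
#' be non-negative.
#'
#' @param bundle A `ref_bundle` (see [format_tree_and_traits()]).
#' @param states Node-state matrix from [reconstruct_ancestral_states()],
#'   computed on the same tree. Computed on the fly when `NULL`.
#' @param traits Trait matrix matching `states`; defaults to
#'   `bundle$traits`.
#' @return Object of class `predicted_traits`: list with `traits` (tip x
#'   trait matrix over all tips) and `nsti` (named vector).
#' @export
predict_tip_traits <- function(bundle, states = NULL, traits = NULL) {
  stopifnot(inherits(bundle, "ref_bundle"))
  if (sum(bundle$sequenced) < 1L) stop("no sequenced tips")
  tree <- bundle$tree
  if (is.null(traits)) traits <- bundle$traits
  if (is.null(states)) states <- reconstruct_ancestral_states(tree, traits)
  ntip <- length(tree$tip.label)
  out <- matrix(NA_real_, ntip, ncol(traits),
                dimnames = list(tree$tip.label, colnames(traits)))
  out[rownames(traits), ] <- as.matrix(traits)

  parent_of <- integer(ntip + tree$Nnode)
  parent_of[tree$edge[, 2L]] <- tree$edge[, 1L]
  root <- ntip + 1L
  for (i in seq_len(ntip)) {
    if (!is.na(out[i, 1L])) next
    node <- parent_of[i]
    repeat {   # most proximal ancestor with a defined state
      st <- states[as.character(node), ]
      if (!any(is.na(st))) break
      if (node == root) stop("no defined ancestral state for tip ",
                             tree$tip.label[i])
      node <- parent_of[node]
    }
    out[i, ] <- st
  }
  out[out < 0] <- 0
  structure(list(traits = out,
                 nsti = compute_nsti(tree, bundle$sequenced)),
            class = "predicted_traits")
}

#' @export
print.predicted_traits <- function(x, ...) {
  cat("Predicted traits: ", nrow(x$traits), " tips x ", ncol(x$traits),
      " traits; mean NSTI ", signif(mean(x$nsti), 4L), "\n", sep = "")
  invisible(x)
}

#' Predict KO traits and 16S copy numbers for a reference bundle
#'
#' Convenience wrapper: runs ancestral state reconstruction and tip
#' prediction for the KO trait table and, as a one-column trait, the 16S
#' copy-number table. Predicted copy numbers below 1 are clamped to 1
#' (a genome carries at least one rRNA operon), so they are safe divisors
#' for abundance normalization.
#'
#' @param bundle A `ref_bundle`.
#' @return A `predicted_traits` object with an extra element
#'   `copy_number`: named vector of predicted 16S copy numbers per tip.
#' @export
predict_traits <- function(bundle) {
  validate_bundle(bundle)
  pred <- predict_tip_traits(bundle)
  cn_tab <- matrix(bundle$copies, ncol = 1L,
                   dimnames = list(names(bundle$copies), "16S"))
  cn <- predict_tip_traits(bundle, traits = cn_tab)$traits[, 1L]
  pred$copy_number <- pmax(cn, 1)
  pred
}

#' Write a predicted trait table as TSV
#'
#' Tip x trait table with a trailing `NSTI` column.
#'
#' @param pred A `predicted_traits` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predicted_traits <- function(pred, path) {
  m <- cbind(pred$traits, NSTI = pred$nsti[rownames(pred$traits)])
  write_tsv_matrix(m, path, id_header = "#OTU ID")
}
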
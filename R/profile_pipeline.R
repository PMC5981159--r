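# The query path: classify OTU representative 16S sequences against the
# reference sequences, sum abundances by classification, divide by
# predicted 16S copy number, multiply by the predicted trait table, and
# collapse the resulting KO profile onto BRITE pathways.

#' Classify OTU sequences against reference 16S sequences
#'
#' Each query is assigned to the reference sequence with maximal global
#' alignment identity, if that identity reaches the threshold (inclusive);
#' otherwise it is `UNASSIGNED`. Identity is matches / aligned columns with
#' terminal gaps excluded and internal gaps counted as mismatch columns.
#' The alignment is global (Needleman-Wunsch); terminal gap columns are
#' excluded only from the identity count, not from the alignment search,
#' so unrelated sequences cannot score high over a short overhang.
#' The search is exhaustive over the reference, and ties in
#' best identity are broken by the lexicographically smallest reference ID
#' (C collation), so repeated runs are bit-identical.
#'
#' @param query Named character vector or `DNAStringSet` of OTU
#'   representative sequences (alphabet `A,C,G,T,N`; `N` never matches).
#' @param reference Named character vector or `DNAStringSet` of reference
#'   16S sequences.
#' @param threshold Percent identity cutoff in `(0, 100]`; default 97,
#'   mirroring the 97% similarity grain of OTU clustering.
#' @return `data.frame` with columns `otu_id`, `reference_id` (`NA` for
#'   unassigned) and `identity` (percent; `NA` for unassigned).
#' @export
classify_otus <- function(query, reference, threshold = 97) {
  if (is.character(query)) query <- Biostrings::DNAStringSet(query)
  if (is.character(reference)) reference <- Biostrings::DNAStringSet(reference)
  if (length(reference) < 1L) stop("empty reference sequence set")
  if (is.null(names(query)) || is.null(names(reference)))
    stop("query and reference sequences must be named")
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 100)
    stop("threshold must be in (0, 100]")

  ref_order <- order(names(reference), method = "radix")
  reference <- reference[ref_order]

  res <- data.frame(otu_id = names(query),
                    reference_id = NA_character_,
                    identity = NA_real_,
                    stringsAsFactors = FALSE)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  for (i in seq_along(query)) {
    qs <- query[[i]]
    if (sum(Biostrings::alphabetFrequency(qs)[c("A", "C", "G", "T")]) == 0L) {
      warning("query '", names(query)[i],
              "' contains no unambiguous bases; UNASSIGNED")
      next
    }
    aln <- Biostrings::pairwiseAlignment(reference, qs, type = "global",
                                         substitutionMatrix = mat,
                                         gapOpening = 5, gapExtension = 2)
    ids <- .alignment_identity(Biostrings::compareStrings(aln))
    best <- which.max(ids)   # ties: first index = smallest ID (sorted above)
    if (ids[best] >= threshold) {
      res$reference_id[i] <- names(reference)[best]
      res$identity[i] <- ids[best]
    }
  }
  res
}

# Percent identity from alignment comparison strings (one character per
# column: the base where both agree, "?" at mismatches, "+"/"-" at gaps).
# Terminal gap runs are excluded; internal gaps count as mismatch columns;
# ambiguous bases never match. Vectorized over alignments.
.alignment_identity <- function(comparison) {
  core <- sub("[+-]+$", "", sub("^[+-]+", "", comparison))
  span <- nchar(core)
  matches <- nchar(gsub("[^ACGT]", "", core))
  ifelse(span == 0L, 0, 100 * matches / span)
}

#' Sum OTU abundances by reference classification
#'
#' Implements the closed-reference aggregation step: abundances of all OTUs
#' assigned to the same reference organism are summed; unassigned OTUs are
#' dropped (their count and total abundance are reported to the message
#' stream, so coverage loss is visible).
#'
#' @param assignments Output of [classify_otus()], covering every OTU in
#'   the table.
#' @param otu_table Numeric matrix, OTU x sample abundances.
#' @return Numeric matrix, reference ID x sample.
#' @export
aggregate_by_reference <- function(assignments, otu_table) {
  stopifnot(is.matrix(otu_table))
  missing <- setdiff(rownames(otu_table), assignments$otu_id)
  if (length(missing) > 0L)
    stop("OTU(s) without a classification record: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  a <- assignments[match(rownames(otu_table), assignments$otu_id), ]
  keep <- !is.na(a$reference_id)
  if (!any(keep)) stop("no classifiable OTUs")
  n_drop <- sum(!keep)
  if (n_drop > 0L)
    message(n_drop, " unassigned OTU(s) dropped (total abundance ",
            sum(otu_table[!keep, , drop = FALSE]), ")")
  kept <- otu_table[keep, , drop = FALSE]
  out <- rowsum(kept, group = a$reference_id[keep])
  out[order(rownames(out), method = "radix"), , drop = FALSE]
}

#' Normalize classified abundances by predicted 16S copy number
#'
#' Divides each organism's abundances by its predicted 16S gene copy
#' number, so abundances approximate organism counts rather than amplicon
#' counts. Divisors below 1 are clamped to 1.
#'
#' @param classified Reference x sample abundance matrix (see
#'   [aggregate_by_reference()]).
#' @param predicted A `predicted_traits` object carrying `copy_number`, or
#'   a named numeric vector of copy numbers.
#' @return Real-valued matrix of the same shape.
#' @export
normalize_by_copy_number <- function(classified, predicted) {
  cn <- if (inherits(predicted, "predicted_traits")) predicted$copy_number
        else predicted
  missing <- setdiff(rownames(classified), names(cn))
  if (length(missing) > 0L)
    stop("no predicted 16S copy number for: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  classified / pmax(cn[rownames(classified)], 1)
}

#' Predict the KO metagenome from normalized abundances
#'
#' The metagenome prediction step: `M[k,s] = sum_g normalized[g,s] *
#' traits[g,k]` — expected KO counts per sample given organism abundances
#' and per-organism gene copy counts.
#'
#' @param normalized Reference x sample matrix of copy-number-normalized
#'   abundances.
#' @param predicted A `predicted_traits` object (or a tip x KO trait
#'   matrix) covering every reference ID in `normalized`.
#' @return `FunctionalProfile`: KO x sample numeric matrix.
#' @export
predict_metagenome <- function(normalized, predicted) {
  traits <- if (inherits(predicted, "predicted_traits")) predicted$traits
            else predicted
  missing <- setdiff(rownames(normalized), rownames(traits))
  if (length(missing) > 0L)
    stop("reference ID(s) missing from predicted traits: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  t(traits[rownames(normalized), , drop = FALSE]) %*% normalized
}

#' Collapse a KO profile onto BRITE level-3 pathways
#'
#' In `duplicated` mode a KO's counts are added to every pathway it belongs
#' to (so multi-pathway gene families are fully represented, and column
#' totals may grow); in `deduplicated` mode only to its first-listed
#' membership (column totals are conserved). KOs absent from the map pool
#' into `"Unclassified"`.
#'
#' @param profile KO x sample matrix.
#' @param brite BRITE map `data.frame` (see [read_brite_map()]).
#' @param mode `"deduplicated"` or `"duplicated"`.
#' @return Pathway x sample matrix, rows keyed by the level-3 label, with a
#'   `hierarchy` attribute (data.frame of level1/level2/level3 per row) and
#'   a `mode` attribute.
#' @export
collapse_to_pathways <- function(profile, brite,
                                 mode = c("deduplicated", "duplicated")) {
  mode <- match.arg(mode)
  brite <- as_brite_map(brite)
  kos <- rownames(profile)
  rows <- integer(0)     # profile row index, fanned out per membership
  path <- character(0)
  l1 <- character(0); l2 <- character(0)
  for (i in seq_along(kos)) {
    b <- brite[brite$ko == kos[i], , drop = FALSE]
    if (nrow(b) == 0L) {
      rows <- c(rows, i); path <- c(path, "Unclassified")
      l1 <- c(l1, "Unclassified"); l2 <- c(l2, "Unclassified")
    } else {
      if (mode == "deduplicated") b <- b[1L, , drop = FALSE]
      rows <- c(rows, rep(i, nrow(b))); path <- c(path, b$level3)
      l1 <- c(l1, b$level1); l2 <- c(l2, b$level2)
    }
  }
  fan <- profile[rows, , drop = FALSE]
  out <- rowsum(fan, group = path)
  hier <- unique(data.frame(level1 = l1, level2 = l2, level3 = path,
                            stringsAsFactors = FALSE))
  hier <- hier[match(rownames(out), hier$level3), ]
  rownames(hier) <- NULL
  attr(out, "hierarchy") <- hier
  attr(out, "mode") <- mode
  out
}

#' Run the full query pipeline against a reference bundle
#'
#' Convenience composition: classify, aggregate, normalize, predict — from
#' an OTU table plus representative sequences to a KO functional profile.
#'
#' @param otu_table OTU x sample abundance matrix.
#' @param otu_seqs Representative sequences named by OTU ID.
#' @param bundle A `ref_bundle` carrying reference sequences.
#' @param threshold Percent identity cutoff for classification.
#' @param predicted Optional precomputed [predict_traits()] result.
#' @return List with `assignments`, `classified`, `normalized`, `profile`.
#' @export
run_profile_pipeline <- function(otu_table, otu_seqs, bundle,
                                 threshold = 97, predicted = NULL) {
  validate_bundle(bundle)
  if (is.null(bundle$seqs)) stop("bundle has no reference sequences")
  nonzero <- rownames(otu_table)[rowSums(otu_table) > 0]
  if (!all(nonzero %in% names(otu_seqs)))
    stop("OTU(s) with abundance but no representative sequence")
  if (is.null(predicted)) predicted <- predict_traits(bundle)
  assignments <- classify_otus(otu_seqs, bundle$seqs, threshold)
  classified <- aggregate_by_reference(assignments, otu_table)
  normalized <- normalize_by_copy_number(classified, predicted)
  profile <- predict_metagenome(normalized, predicted)
  list(assignments = assignments, classified = classified,
       normalized = normalized, profile = profile)
}
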
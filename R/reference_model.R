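# The three-file reference model: a 16S phylogeny whose tips are organisms
# (some with sequenced genomes), a KO gene-copy trait table for the
# sequenced tips, and a 16S copy-number table. A reference bundle
# additionally carries the reference 16S sequences and a KO-to-BRITE
# pathway membership map.

#' Reconcile a reference tree with trait and copy-number tables
#'
#' Builds a validated reference bundle from a phylogeny and per-genome
#' tables. Trait rows whose IDs are not tree tips are dropped with a
#' warning; tips without a trait row are flagged as unsequenced genomes.
#' Trait rows are reordered to match tip traversal order. Organism IDs are
#' case-sensitive exact strings; no normalization beyond leading/trailing
#' whitespace is applied by the readers.
#'
#' @param tree An [ape::phylo] reference tree. Tip labels are organism IDs;
#'   branch lengths are substitutions/site and must be finite and
#'   non-negative. Multifurcations are permitted.
#' @param traits Numeric matrix of gene-family (KO) copy counts, rows =
#'   organism IDs, columns = KO identifiers. Counts are non-negative reals.
#' @param copies Named numeric vector (or 1-column matrix) of 16S gene copy
#'   numbers, `>= 1`, covering every trait-table row.
#' @param seqs Optional reference 16S sequences (named character vector or
#'   `DNAStringSet`); names must be a subset of tip labels.
#' @param brite Optional KO-to-BRITE membership map (see [read_brite_map()]).
#' @return An object of class `ref_bundle`: a list with elements `tree`,
#'   `sequenced` (named logical over tips), `traits`, `copies`, `seqs`,
#'   `brite`.
#' @examples
#' tr <- ape::read.tree(text = "((g1:1,g2:1):1,(g3:1,g4:1):1,g5:2);")
#' tt <- matrix(c(1, 0, 2, 1, 0, 3), nrow = 3, byrow = TRUE,
#'              dimnames = list(c("g1", "g2", "g3"), c("K00001", "K00002")))
#' cn <- c(g1 = 1, g2 = 2, g3 = 4)
#' b <- format_tree_and_traits(tr, tt, cn)
#' sum(b$sequenced)   # 3 sequenced, 2 unsequenced tips
#' @export
format_tree_and_traits <- function(tree, traits, copies, seqs = NULL,
                                   brite = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 1L) stop("empty tree")
  if (is.null(dim(traits)) || nrow(traits) < 1L) stop("empty trait table")
  if (anyDuplicated(rownames(traits)))
    stop("duplicate organism IDs in trait table: ",
         paste(unique(rownames(traits)[duplicated(rownames(traits))]),
               collapse = ", "))
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels in tree")
  if (is.null(tree$edge.length) || any(!is.finite(tree$edge.length)) ||
      any(tree$edge.length < 0))
    stop("tree branch lengths must be finite and >= 0")
  if (any(traits < 0)) stop("trait table contains negative counts")

  if (is.matrix(copies)) copies <- stats::setNames(copies[, 1L], rownames(copies))
  tips <- tree$tip.label
  keep <- rownames(traits) %in% tips
  if (!any(keep))
    stop("no trait-table row ID matches a tree tip label")
  if (any(!keep)) {
    warning(sum(!keep), " trait row(s) not present in the tree dropped: ",
            paste(rownames(traits)[!keep], collapse = ", "))
    traits <- traits[keep, , drop = FALSE]
  }
  sequenced <- stats::setNames(tips %in% rownames(traits), tips)
  missing_cn <- setdiff(rownames(traits), names(copies))
  if (length(missing_cn) > 0L)
    stop("sequenced genome(s) missing a 16S copy number: ",
         paste(missing_cn, collapse = ", "))
  # row order follows tip traversal order
  ord <- tips[sequenced]
  traits <- traits[ord, , drop = FALSE]
  copies <- copies[ord]
  if (any(copies < 1))
    stop("16S copy numbers must be >= 1 for observed genomes")

  if (!is.null(seqs)) {
    if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
    extra <- setdiff(names(seqs), tips)
    if (length(extra) > 0L)
      stop("reference sequence ID(s) not in the tree: ",
           paste(extra, collapse = ", "))
  }
  if (!is.null(brite)) brite <- as_brite_map(brite)

  structure(list(tree = tree, sequenced = sequenced, traits = traits,
                 copies = copies, seqs = seqs, brite = brite),
            class = "ref_bundle")
}

#' Validate reference-bundle invariants
#'
#' Checks that every trait row is a tree tip, every sequenced tip has a
#' trait row and a copy-number entry, sequence IDs are a subset of tip
#' labels, branch lengths are finite and non-negative, and at least one tip
#' is sequenced.
#'
#' @param bundle A `ref_bundle`.
#' @return `TRUE` invisibly; otherwise an error.
#' @export
validate_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "ref_bundle"))
  tips <- bundle$tree$tip.label
  if (anyDuplicated(tips)) stop("tip labels not unique")
  if (any(!is.finite(bundle$tree$edge.length)) ||
      any(bundle$tree$edge.length < 0))
    stop("branch lengths must be finite and >= 0")
  if (!setequal(names(bundle$sequenced), tips))
    stop("sequenced flags do not cover the tips")
  seq_tips <- names(bundle$sequenced)[bundle$sequenced]
  if (length(seq_tips) < 1L) stop("no sequenced tips")
  if (!setequal(rownames(bundle$traits), seq_tips))
    stop("trait rows do not match sequenced tips")
  if (!all(seq_tips %in% names(bundle$copies)))
    stop("copy-number table does not cover sequenced tips")
  if (any(bundle$traits < 0)) stop("negative trait counts")
  if (any(bundle$copies < 1)) stop("copy numbers must be >= 1")
  if (!is.null(bundle$seqs) && !all(names(bundle$seqs) %in% tips))
    stop("sequence IDs must be a subset of tip labels")
  invisible(TRUE)
}

#' @export
print.ref_bundle <- function(x, ...) {
  cat("Reference bundle\n")
  cat("  tips:      ", length(x$tree$tip.label),
      " (", sum(x$sequenced), " sequenced)\n", sep = "")
  cat("  KO traits: ", ncol(x$traits), "\n", sep = "")
  cat("  sequences: ", if (is.null(x$seqs)) 0L else length(x$seqs), "\n",
      sep = "")
  cat("  BRITE map: ", if (is.null(x$brite)) "absent"
      else paste0(nrow(x$brite), " memberships"), "\n", sep = "")
  invisible(x)
}

#' Write a reference bundle to a directory
#'
#' Emits `tree.nwk` (Newick), `traits.tsv`, `copy_number.tsv`,
#' `sequences.fasta` and `brite.tsv` (the last two only when present).
#'
#' @param bundle A `ref_bundle`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the file paths written.
#' @export
write_bundle <- function(bundle, dir) {
  validate_bundle(bundle)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(tree = file.path(dir, "tree.nwk"),
             traits = file.path(dir, "traits.tsv"),
             copies = file.path(dir, "copy_number.tsv"))
  ape::write.tree(bundle$tree, paths[["tree"]], digits = 10L)
  write_tsv_matrix(bundle$traits, paths[["traits"]], id_header = "#OTU ID")
  cn <- matrix(bundle$copies, ncol = 1L,
               dimnames = list(names(bundle$copies), "16S_rRNA_Count"))
  write_tsv_matrix(cn, paths[["copies"]], id_header = "#OTU ID")
  if (!is.null(bundle$seqs)) {
    paths[["seqs"]] <- file.path(dir, "sequences.fasta")
    write_fasta(bundle$seqs, paths[["seqs"]])
  }
  if (!is.null(bundle$brite)) {
    paths[["brite"]] <- file.path(dir, "brite.tsv")
    write_brite_map(bundle$brite, paths[["brite"]])
  }
  paths
}

#' Read a reference bundle from a directory
#'
#' Counterpart of [write_bundle()]; `read_bundle(write_bundle(b))`
#' reproduces `b` (labels and counts exactly, branch lengths to 10
#' significant digits).
#'
#' @param dir Directory holding the bundle files.
#' @return A `ref_bundle`.
#' @export
read_bundle <- function(dir) {
  tree_path <- file.path(dir, "tree.nwk")
  if (!file.exists(tree_path)) stop("missing tree file: ", tree_path)
  tree <- tryCatch(ape::read.tree(tree_path), error = function(e)
    stop(tree_path, ": malformed Newick: ", conditionMessage(e)))
  if (is.null(tree)) stop(tree_path, ": malformed Newick")
  traits <- read_tsv_matrix(file.path(dir, "traits.tsv"))
  cn <- read_tsv_matrix(file.path(dir, "copy_number.tsv"))
  seqs_path <- file.path(dir, "sequences.fasta")
  seqs <- if (file.exists(seqs_path)) read_fasta(seqs_path) else NULL
  brite_path <- file.path(dir, "brite.tsv")
  brite <- if (file.exists(brite_path)) read_brite_map(brite_path) else NULL
  format_tree_and_traits(tree, traits, stats::setNames(cn[, 1L], rownames(cn)),
                         seqs = seqs, brite = brite)
}

#' Build KO trait tables from per-genome annotations
#'
#' Turns a flat list of gene-to-KO assignments into the two count-table
#' variants used by the workflow: a deduplicated table with one column per
#' distinct KO, and a duplicated table in which a KO column is repeated once
#' per BRITE pathway membership (identical counts in each repeat), so that
#' multi-pathway gene families are not under-counted at the pathway level.
#'
#' @param annotations `data.frame` with columns `genome`, `gene`, `ko`; one
#'   row per annotated gene copy. Genomes with zero annotated KOs yield
#'   all-zero rows (and are reported with a message).
#' @param brite Optional BRITE map used to expand the duplicated variant;
#'   KOs absent from the map contribute a single column in both variants.
#' @param genomes Optional character vector fixing the full genome set (and
#'   row order); defaults to the genomes observed in `annotations`.
#' @return List with elements `deduplicated` and `duplicated`, both numeric
#'   matrices (genome x KO). The duplicated matrix carries an attribute
#'   `membership`, a data.frame aligning its columns with BRITE memberships.
#' @examples
#' ann <- data.frame(genome = "g1", gene = c("a", "b", "c"),
#'                   ko = c("K00001", "K00001", "K00002"))
#' br <- data.frame(ko = "K00002",
#'                  level1 = "Metabolism", level2 = c("X", "Y"),
#'                  level3 = c("P1", "P2"))
#' tabs <- build_trait_tables(ann, br)
#' tabs$deduplicated   # counts 2, 1
#' tabs$duplicated     # counts 2, 1, 1
#' @export
build_trait_tables <- function(annotations, brite = NULL, genomes = NULL) {
  stopifnot(is.data.frame(annotations),
            all(c("genome", "ko") %in% names(annotations)))
  if (nrow(annotations) > 0L &&
      !all(grepl("^K[0-9]{5}$", annotations$ko)))
    stop("invalid KO identifier(s): ",
         paste(utils::head(unique(
           annotations$ko[!grepl("^K[0-9]{5}$", annotations$ko)]), 5L),
           collapse = ", "))
  if (is.null(genomes)) genomes <- sort(unique(as.character(annotations$genome)))
  kos <- sort(unique(as.character(annotations$ko)))
  dedup <- matrix(0, length(genomes), length(kos),
                  dimnames = list(genomes, kos))
  if (nrow(annotations) > 0L) {
    counts <- table(factor(annotations$genome, levels = genomes),
                    factor(annotations$ko, levels = kos))
    dedup[] <- as.numeric(counts)
  }
  empty <- rownames(dedup)[rowSums(dedup) == 0]
  if (length(empty) > 0L)
    message("genome(s) with zero annotated KOs (all-zero rows): ",
            paste(empty, collapse = ", "))

  if (!is.null(brite)) brite <- as_brite_map(brite)
  cols <- integer(0)      # index into kos, repeated per membership
  memb <- list()
  for (j in seq_along(kos)) {
    b <- if (is.null(brite)) NULL else brite[brite$ko == kos[j], , drop = FALSE]
    reps <- if (is.null(b) || nrow(b) == 0L) 1L else nrow(b)
    cols <- c(cols, rep(j, reps))
    memb[[j]] <- if (is.null(b) || nrow(b) == 0L)
      data.frame(ko = kos[j], level1 = NA_character_,
                 level2 = NA_character_, level3 = NA_character_)
    else b
  }
  dup <- dedup[, cols, drop = FALSE]
  colnames(dup) <- kos[cols]
  attr(dup, "membership") <- do.call(rbind, memb)
  list(deduplicated = dedup, duplicated = dup)
}
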
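# Predicted-versus-observed evaluation: restrict profiles to the KOs
# present in every dataset, convert to relative abundance, and compute the
# Pearson correlation between profiles.

#' Restrict functional profiles to their shared features
#'
#' Given two or more KO x sample profiles, keeps only the KOs present in
#' all of them, in a common row order. By default "present" means the KO
#' row exists and has a nonzero total count; `presence = "exists"` relaxes
#' this to row existence.
#'
#' @param profiles List of KO x sample numeric matrices.
#' @param presence `"nonzero"` (default) or `"exists"`.
#' @return List of matrices restricted to the shared KOs, identical row
#'   order (sorted KO IDs).
#' @export
shared_feature_subset <- function(profiles, presence = c("nonzero", "exists")) {
  presence <- match.arg(presence)
  stopifnot(is.list(profiles), length(profiles) >= 2L)
  feat <- lapply(profiles, function(p) {
    if (presence == "nonzero") rownames(p)[rowSums(p) > 0] else rownames(p)
  })
  shared <- Reduce(intersect, feat)
  if (length(shared) == 0L) stop("no features shared by all profiles")
  shared <- sort(shared, method = "radix")
  lapply(profiles, function(p) p[shared, , drop = FALSE])
}

#' Convert a profile to relative abundance
#'
#' Divides each value by its normalization unit's total. By default the
#' unit is the whole profile pooled over samples (one total per dataset, as
#' used when comparing one predicted metagenome against one observed
#' metagenome); with `per_sample = TRUE` each sample column is normalized
#' separately.
#'
#' @param profile KO x sample numeric matrix (a vector is treated as a
#'   one-sample profile).
#' @param per_sample Normalize each sample column to 1 instead of the
#'   pooled profile.
#' @return Matrix of proportions; unit totals equal 1 to within 1e-12.
#' @export
relative_abundance <- function(profile, per_sample = FALSE) {
  if (is.null(dim(profile))) profile <- as.matrix(profile)
  if (per_sample) {
    tot <- colSums(profile)
    if (any(tot == 0)) stop("all-zero sample column; relative abundance undefined")
    sweep(profile, 2L, tot, "/")
  } else {
    tot <- sum(profile)
    if (tot == 0) stop("all-zero profile; relative abundance undefined")
    profile / tot
  }
}

#' Pearson correlation and its square
#'
#' Standard product-moment correlation between two equal-length vectors,
#' with the squared correlation and a t-transform p-value (n - 2 degrees of
#' freedom). The p-value is descriptive; nothing in the package gates on
#' it.
#'
#' @param x,y Numeric vectors of equal length `>= 3` with nonzero variance.
#' @return List with `r`, `r_squared`, `p`, `n`.
#' @export
pearson_r2 <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance")
  r <- stats::cor(x, y)
  tval <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  list(r = r, r_squared = r^2, p = p, n = n)
}

#' Compare a predicted profile against an observed profile
#'
#' The validation-study comparison: restrict both profiles to shared KOs,
#' convert to relative abundance (pooled per dataset by default), and
#' report the Pearson correlation between the paired KO relative
#' abundances.
#'
#' @param predicted,observed KO x sample numeric matrices.
#' @param presence Shared-feature rule, see [shared_feature_subset()].
#' @param per_sample Per-sample instead of pooled normalization.
#' @return Object of class `comparison_report`: list with `n_shared`, `r`,
#'   `r_squared`, `p` and `pairs` (data.frame of KO, predicted and observed
#'   relative abundance, for scatter plotting).
#' @export
compare_profiles <- function(predicted, observed,
                             presence = c("nonzero", "exists"),
                             per_sample = FALSE) {
  sub <- shared_feature_subset(list(predicted = predicted,
                                    observed = observed),
                               presence = match.arg(presence))
  ra_p <- relative_abundance(sub$predicted, per_sample = per_sample)
  ra_o <- relative_abundance(sub$observed, per_sample = per_sample)
  x <- rowSums(ra_p)
  y <- rowSums(ra_o)
  stat <- pearson_r2(x, y)
  structure(list(n_shared = nrow(sub$predicted),
                 r = stat$r, r_squared = stat$r_squared, p = stat$p,
                 pairs = data.frame(ko = rownames(sub$predicted),
                                    predicted = x, observed = y,
                                    row.names = NULL)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Predicted vs observed profile comparison\n")
  cat("  shared KOs: ", x$n_shared, "\n", sep = "")
  cat("  Pearson r = ", signif(x$r, 6L), "  R^2 = ", signif(x$r_squared, 6L),
      "  p = ", format(x$p, digits = 3L), "\n", sep = "")
  invisible(x)
}
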
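# Allele reconciliation between variant panels genotyped on different arrays.
#
# Panels are matched on variant id alone (the HapMap3-intersection workflow);
# position disagreements are logged, not fatal. Strand-ambiguous pairs
# (A/T and C/G) can never be oriented from allele labels and are dropped.

.complement <- c(A = "T", C = "G", G = "C", T = "A")

.is_ambiguous <- function(a1, a2) .complement[a1] == a2

#' Align the alleles of one variant panel to another
#'
#' For every variant id shared by panels \code{a} and \code{b}, decides how
#' \code{b}'s dosages must be transformed so that both panels count the same
#' allele: \code{keep} (same orientation), \code{swap} (alleles exchanged,
#' dosage becomes \code{2 - x}), \code{strand_flip} (labels on the opposite
#' strand, dosage unchanged), \code{swap_and_flip}, \code{drop_ambiguous}
#' (A/T or C/G pairs, unresolvable), or \code{drop_mismatch} (incompatible
#' alleles even after flipping).
#'
#' @param a,b data.frames of variant records (columns \code{id},
#'   \code{allele1}, \code{allele2}, optionally \code{pos}), or
#'   \code{genotype_dataset} objects.
#' @return data.frame of class \code{allele_alignment} with columns
#'   \code{id} and \code{action}, one row per shared id.
#' @export
align_alleles <- function(a, b) {
  if (inherits(a, "genotype_dataset")) a <- a$variants
  if (inherits(b, "genotype_dataset")) b <- b$variants
  a <- a[!duplicated(a$id), , drop = FALSE]
  b <- b[!duplicated(b$id), , drop = FALSE]
  shared <- intersect(a$id, b$id)
  ia <- match(shared, a$id)
  ib <- match(shared, b$id)

  a1 <- a$allele1[ia]; a2 <- a$allele2[ia]
  b1 <- b$allele1[ib]; b2 <- b$allele2[ib]
  fb1 <- unname(.complement[b1]); fb2 <- unname(.complement[b2])

  action <- rep("drop_mismatch", length(shared))
  action[b1 == a1 & b2 == a2] <- "keep"
  action[b1 == a2 & b2 == a1] <- "swap"
  action[fb1 == a1 & fb2 == a2] <- "strand_flip"
  action[fb1 == a2 & fb2 == a1] <- "swap_and_flip"
  # ambiguity dominates: an A/T or C/G pair matches both "keep" and
  # "swap_and_flip" patterns, so orientation is undecidable
  ambiguous <- .is_ambiguous(a1, a2) | .is_ambiguous(b1, b2)
  action[ambiguous] <- "drop_ambiguous"

  if (!is.null(a$pos) && !is.null(b$pos)) {
    pos_conflict <- sum(a$pos[ia] != b$pos[ib], na.rm = TRUE)
    if (pos_conflict > 0)
      message(pos_conflict,
              " shared id(s) disagree on position; matched on id anyway")
  }
  structure(
    data.frame(id = shared, action = action, stringsAsFactors = FALSE),
    class = c("allele_alignment", "data.frame")
  )
}

#' Merge two genotype datasets into one cohort-labelled dataset
#'
#' Keeps the variants shared by both datasets that survive allele alignment,
#' transforms \code{b}'s dosages according to the alignment action
#' (\code{swap}/\code{swap_and_flip} recode dosage as \code{2 - x}), and
#' column-binds samples (\code{a}'s first). Sample id sets must be disjoint:
#' the downstream multi-trait model assumes independent cohorts.
#'
#' @param a,b \code{genotype_dataset} objects.
#' @param alignment Optional \code{allele_alignment}; computed from the two
#'   variant tables when omitted.
#' @return A merged \code{genotype_dataset} whose variant metadata (alleles,
#'   positions) is taken from \code{a}.
#' @export
merge_datasets <- function(a, b, alignment = NULL) {
  stopifnot(inherits(a, "genotype_dataset"), inherits(b, "genotype_dataset"))
  if (length(intersect(sample_ids(a), sample_ids(b))) > 0)
    stop("sample ids overlap between datasets; cohorts must be disjoint")
  if (is.null(alignment)) alignment <- align_alleles(a, b)

  keepable <- c("keep", "swap", "strand_flip", "swap_and_flip")
  kept <- alignment[alignment$action %in% keepable, , drop = FALSE]
  dropped <- nrow(alignment) - nrow(kept)
  if (dropped > 0)
    message("merge: dropped ", dropped,
            " shared variant(s) (ambiguous or mismatched alleles)")
  # preserve a's variant order
  kept <- kept[order(match(kept$id, a$variants$id)), , drop = FALSE]

  ia <- match(kept$id, a$variants$id)
  ib <- match(kept$id, b$variants$id)
  calls_b <- b$calls[ib, , drop = FALSE]
  recode <- kept$action %in% c("swap", "swap_and_flip")
  if (any(recode))
    calls_b[recode, ] <- 2L - calls_b[recode, , drop = FALSE]

  samples <- rbind(
    a$samples[, c("fid", "iid", "sex", "cohort"), drop = FALSE],
    b$samples[, c("fid", "iid", "sex", "cohort"), drop = FALSE]
  )
  genotype_dataset(a$variants[ia, , drop = FALSE], samples,
                   cbind(a$calls[ia, , drop = FALSE], calls_b))
}
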
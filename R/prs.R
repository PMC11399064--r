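# PRS engine: harmonize GWAS weights against genotype data, score, and
# standardize against a reference (control) distribution.

#' Harmonize a weights panel against genotyped variants
#'
#' Matches panel variants to genotype data by chromosome and position, then
#' classifies each: `matched` when the effect allele is the counted (ALT)
#' allele; `flipped` when the effect allele is the reference allele, so the
#' counted dosage must be reversed (`2 - x`); `strand_ambiguous_dropped` for
#' palindromic A/T or C/G pairs, whose strand cannot be resolved without
#' frequency matching; `allele_mismatch_dropped` when the allele sets
#' disagree; `absent_dropped` when the position is not genotyped.
#'
#' @param panel A `variant_panel` (see [generate_variant_panel()] or
#'   [read_weights()]).
#' @param G Samples x variants dosage matrix whose column names are
#'   canonical `chrom:pos:ref:alt` ids.
#' @param variant_meta `data.frame` with `variant_id`, `chrom`, `pos`,
#'   `ref`, `alt` covering the genotyped variants (`alt` is the counted
#'   allele).
#' @return A list with `panel` (the aligned panel: retained rows plus
#'   `g_variant_id` and logical `flip`) and `log`, a `data.frame`
#'   (`variant_id`, `action`) covering every input panel variant.
#' @export
harmonize <- function(panel, G, variant_meta) {
  need <- c("variant_id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(variant_meta)))
    stop("variant_meta must have columns ", paste(need, collapse = ", "))
  key_p <- paste(panel$chrom, panel$pos, sep = ":")
  key_m <- paste(variant_meta$chrom, variant_meta$pos, sep = ":")
  idx <- match(key_p, key_m)
  present <- !is.na(idx) & variant_meta$variant_id[ifelse(is.na(idx), 1L, idx)] %in% colnames(G)
  complement <- c(A = "T", C = "G", G = "C", T = "A")
  palindromic <- panel$other_allele ==
    unname(complement[panel$effect_allele])
  ref <- variant_meta$ref[idx]; alt <- variant_meta$alt[idx]
  matched <- present & panel$effect_allele == alt & panel$other_allele == ref
  flipped <- present & panel$effect_allele == ref & panel$other_allele == alt

  action <- rep("allele_mismatch_dropped", nrow(panel))
  action[!present] <- "absent_dropped"
  action[present & palindromic] <- "strand_ambiguous_dropped"
  action[matched & !palindromic] <- "matched"
  action[flipped & !palindromic] <- "flipped"

  keep <- action %in% c("matched", "flipped")
  if (!any(keep))
    stop("no overlap between weights panel and genotyped variants")
  aligned <- panel[keep, , drop = FALSE]
  aligned$g_variant_id <- variant_meta$variant_id[idx[keep]]
  aligned$flip <- action[keep] == "flipped"
  rownames(aligned) <- NULL
  list(panel = aligned,
       log = data.frame(variant_id = panel$variant_id, action = action,
                        stringsAsFactors = FALSE))
}

#' Compute raw polygenic risk scores
#'
#' `PRS_i = sum_j w_j x'_ij`, where `x'` is the flip-adjusted effect-allele
#' dosage. Missing dosages are imputed, under the default policy, as twice
#' the effect-allele frequency estimated in the reference (control) samples
#' — the population-mean contribution, which leaves the score expectation
#' unbiased. The `"zero"` policy instead drops missing terms from the sum.
#'
#' @param G Samples x variants dosage matrix.
#' @param aligned The `panel` element returned by [harmonize()].
#' @param reference_ids Sample ids defining the reference set for frequency
#'   estimation (typically the controls); defaults to all samples.
#' @param missing_policy `"reference_mean"` (default) or `"zero"`.
#' @return A `data.frame` with `participant_id`, `raw_score`, and a
#'   `z_score` column of `NA` to be filled by [standardize_prs()].
#' @export
compute_prs <- function(G, aligned, reference_ids = NULL,
                        missing_policy = c("reference_mean", "zero")) {
  missing_policy <- match.arg(missing_policy)
  if (is.null(aligned$g_variant_id) || is.null(aligned$flip))
    stop("contract violation: panel must be harmonized first (run harmonize())")
  if (!all(aligned$g_variant_id %in% colnames(G)))
    stop("contract violation: harmonized variant absent from genotype matrix")
  if (any(!is.finite(aligned$weight)))
    stop("weights must be finite")
  X <- G[, aligned$g_variant_id, drop = FALSE]
  if (any(aligned$flip))
    X[, aligned$flip] <- 2 - X[, aligned$flip, drop = FALSE]
  if (anyNA(X)) {
    fill <- if (missing_policy == "reference_mean") {
      ref <- if (is.null(reference_ids)) rownames(X) else
        intersect(reference_ids, rownames(X))
      if (!length(ref)) stop("no reference samples available for imputation")
      fhat <- colMeans(X[ref, , drop = FALSE], na.rm = TRUE) / 2
      # a variant missing in every reference sample: fall back to all samples
      bad <- !is.finite(fhat)
      if (any(bad)) fhat[bad] <- colMeans(X[, bad, drop = FALSE],
                                          na.rm = TRUE)[bad] / 2
      2 * fhat
    } else {
      rep(0, ncol(X))
    }
    miss <- which(is.na(X), arr.ind = TRUE)
    X[miss] <- fill[miss[, 2L]]
  }
  raw <- as.vector(X %*% aligned$weight)
  ids <- rownames(G)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(G)))
  data.frame(participant_id = ids, raw_score = raw, z_score = NA_real_,
             stringsAsFactors = FALSE)
}

#' Z-score standardization against a reference set
#'
#' `z_i = (raw_i - mean_ref) / sd_ref`, with the reference mean and SD
#' (n - 1 denominator) computed over `reference_ids`. Standardizing against
#' the controls keeps the scores on the same scale as the control-based
#' decile boundaries.
#'
#' @param scores Output of [compute_prs()].
#' @param reference_ids Sample ids of the reference set (>= 2 distinct raw
#'   scores required).
#' @return `scores` with the `z_score` column filled.
#' @export
standardize_prs <- function(scores, reference_ids) {
  ref <- scores$raw_score[scores$participant_id %in% reference_ids]
  if (length(ref) < 2L)
    stop("degenerate reference: need at least 2 reference scores")
  s <- stats::sd(ref)
  if (!is.finite(s) || s == 0)
    stop("degenerate reference: zero variance in reference scores")
  scores$z_score <- (scores$raw_score - mean(ref)) / s
  scores
}
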
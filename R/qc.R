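# Genotype quality control: call rates, exact Hardy-Weinberg test,
# method-of-moments identity-by-descent, and the composite filter.

#' Per-sample and per-variant call rates
#'
#' @param G Samples x variants dosage matrix (missing entries `NA`).
#' @return A list with numeric vectors `sample` and `variant`, each the
#'   fraction of non-missing entries, named by id.
#' @export
call_rates <- function(G) {
  if (!is.matrix(G) || nrow(G) == 0L || ncol(G) == 0L)
    stop("invalid input: empty genotype matrix")
  obs <- !is.na(G)
  list(sample = rowMeans(obs), variant = colMeans(obs))
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test of the heterozygote count conditional on the allele
#' counts: the p-value is the summed probability of all heterozygote
#' configurations no more probable than the observed one. Probabilities are
#' computed by the standard recurrence over heterozygote counts of matching
#' parity (the SNP-HWE algorithm), so the test is exact for any sample size.
#'
#' @param n_hom_effect Count of effect-allele homozygotes.
#' @param n_het Count of heterozygotes.
#' @param n_hom_other Count of other-allele homozygotes.
#' @return The exact two-sided p-value, in (0, 1]. Monomorphic input gives 1.
#' @examples
#' hwe_exact_test(25, 50, 25)  # perfect HWE: p = 1
#' hwe_exact_test(50, 0, 50)   # extreme heterozygote deficit: p << 1e-6
#' @export
hwe_exact_test <- function(n_hom_effect, n_het, n_hom_other) {
  counts <- c(n_hom_effect, n_het, n_hom_other)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("invalid input: genotype counts must be nonnegative integers")
  n <- sum(counts)
  if (n < 1L) stop("invalid input: at least one genotype required")
  rare <- min(2 * n_hom_effect + n_het, 2 * n_hom_other + n_het)
  if (rare == 0L) return(1)

  hets <- seq(rare %% 2L, rare, by = 2L)
  probs <- numeric(length(hets))
  # start near the mode and fill both directions by the probability ratio
  mid <- floor(rare * (2 * n - rare) / (2 * n))
  if (mid %% 2L != rare %% 2L) mid <- mid + 1L
  i_mid <- match(mid, hets)
  probs[i_mid] <- 1
  homr <- function(h) (rare - h) / 2          # rare-allele homozygotes
  homc <- function(h) n - h - homr(h)         # common-allele homozygotes
  h <- mid
  while (h >= 2L) {  # downward: p(h-2) = p(h) * h(h-1) / (4 (homr+1)(homc+1))
    i <- match(h, hets)
    probs[i - 1L] <- probs[i] * h * (h - 1) /
      (4 * (homr(h) + 1) * (homc(h) + 1))
    h <- h - 2L
  }
  h <- mid
  while (h + 2L <= rare) {  # upward: p(h+2) = p(h) * 4 homr homc / ((h+2)(h+1))
    i <- match(h, hets)
    probs[i + 1L] <- probs[i] * 4 * homr(h) * homc(h) / ((h + 2) * (h + 1))
    h <- h + 2L
  }
  probs <- probs / sum(probs)
  obs <- match(n_het, hets)
  if (is.na(obs))
    stop("invalid input: heterozygote count inconsistent with allele counts")
  min(1, sum(probs[probs <= probs[obs] * (1 + 1e-12)]))
}

#' Method-of-moments identity-by-descent estimates for all sample pairs
#'
#' Estimates the proportion of the genome shared identical by descent,
#' `pi_hat = P(IBD = 2) + P(IBD = 1) / 2`, for every unordered sample pair
#' from identity-by-state counts and the expected IBS distribution given the
#' supplied allele frequencies (the PLINK moments estimator). Requires hard
#' genotype calls; pairs are evaluated over their jointly non-missing
#' variants.
#'
#' @param G Samples x variants matrix of hard-call dosages in \{0, 1, 2\}.
#' @param allele_freqs Per-variant effect-allele frequencies in (0, 1),
#'   aligned with the columns of `G`.
#' @return A `data.frame` with `id1`, `id2` and `pi_hat` (truncated into
#'   \[0, 1\]) for each unordered pair.
#' @export
estimate_ibd <- function(G, allele_freqs) {
  if (!is.matrix(G) || nrow(G) < 2L)
    stop("invalid input: need at least 2 samples")
  vals <- G[!is.na(G)]
  if (any(vals != round(vals)) || any(vals < 0 | vals > 2))
    stop("invalid input: IBD estimation requires hard genotype calls in {0,1,2}")
  p <- allele_freqs
  if (length(p) != ncol(G) || any(!is.finite(p)) || any(p <= 0 | p >= 1))
    stop("invalid input: allele frequencies must lie in (0, 1), one per variant")
  q <- 1 - p
  # expected P(IBS = s | IBD = k) per variant
  e0_ibd0 <- 2 * p^2 * q^2
  e1_ibd0 <- 4 * p^3 * q + 4 * p * q^3
  e2_ibd0 <- p^4 + q^4 + 4 * p^2 * q^2
  e1_ibd1 <- 2 * p^2 * q + 2 * p * q^2
  e2_ibd1 <- p^3 + q^3 + p^2 * q + p * q^2

  obs <- !is.na(G)
  M <- obs * 1
  I0 <- (obs & G == 0) * 1
  I1 <- (obs & G == 1) * 1
  I2 <- (obs & G == 2) * 1
  n_pairs_obs <- M %*% t(M)                       # jointly observed variants
  N2 <- I0 %*% t(I0) + I1 %*% t(I1) + I2 %*% t(I2)  # IBS2 counts
  N0 <- I0 %*% t(I2) + I2 %*% t(I0)                 # IBS0 counts
  N1 <- n_pairs_obs - N0 - N2
  wsum <- function(e) (M * rep(e, each = nrow(M))) %*% t(M)
  E0_0 <- wsum(e0_ibd0); E1_0 <- wsum(e1_ibd0); E2_0 <- wsum(e2_ibd0)
  E1_1 <- wsum(e1_ibd1); E2_1 <- wsum(e2_ibd1)

  p0 <- N0 / E0_0
  p1 <- (N1 - p0 * E1_0) / E1_1
  p2 <- (N2 - p0 * E2_0 - p1 * E2_1) / n_pairs_obs
  pihat <- p2 + p1 / 2
  pihat <- pmin(pmax(pihat, 0), 1)  # matrix first: keep the dim attribute

  idx <- which(upper.tri(pihat), arr.ind = TRUE)
  ids <- rownames(G)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(G)))
  data.frame(id1 = ids[idx[, 1L]], id2 = ids[idx[, 2L]],
             pi_hat = pihat[idx], stringsAsFactors = FALSE)
}

# Genotype counts (hom effect, het, hom other) from rounded dosages.
genotype_counts <- function(x) {
  x <- round(x[!is.na(x)])
  c(sum(x == 2), sum(x == 1), sum(x == 0))
}

#' Apply the genotype quality-control filter chain
#'
#' Filters in a fixed order: (1) variants with call rate at or below
#' `variant_thresh`; (2) samples with call rate at or below `sample_thresh`;
#' (3) variants failing the exact Hardy-Weinberg test at `hwe_alpha`,
#' computed on retained control samples only (case enrichment distorts
#' genotype frequencies at true risk loci); (4) relatedness: for each pair
#' with `pi_hat >= ibd_thresh`, the member with the lower call rate is
#' removed (ties: the lexicographically later id). Imputed real-valued
#' dosages are rounded to hard calls for the HWE and IBD steps only.
#'
#' @param G Samples x variants dosage matrix with dimnames.
#' @param sample_thresh,variant_thresh Call-rate thresholds; entities with
#'   rate strictly above the threshold are kept (">99%" convention).
#' @param hwe_alpha Exclusion threshold: variants with exact-test p-value
#'   strictly below it are removed.
#' @param ibd_thresh Pairs at or above this `pi_hat` are treated as related.
#' @param ibd_min_variants Minimum number of polymorphic variants required
#'   to run the relatedness step. Moments-based `pi_hat` has a per-pair
#'   sampling SD of roughly `1 / sqrt(m)` over `m` variants; below a few
#'   hundred variants a 0.2 threshold flags large numbers of unrelated
#'   pairs, so the step is skipped (with a warning, recorded in the report)
#'   rather than producing spurious exclusions.
#' @param control_ids Participant ids of controls, used for the HWE test and
#'   allele-frequency estimation; defaults to all samples.
#' @return A list of class `qc_result`: `genotypes` (the filtered matrix)
#'   and `report`, which records `excluded_samples` and `excluded_variants`
#'   (`data.frame`s of id + reason), the thresholds used, and the `pi_hat`
#'   table computed at step 4.
#' @export
apply_qc <- function(G, sample_thresh = 0.99, variant_thresh = 0.99,
                     hwe_alpha = 1e-6, ibd_thresh = 0.2,
                     ibd_min_variants = 500L, control_ids = NULL) {
  if (!is.matrix(G) || nrow(G) == 0L || ncol(G) == 0L)
    stop("invalid input: empty genotype matrix")
  thr <- c(sample_thresh, variant_thresh, hwe_alpha)
  if (any(!is.finite(thr)) || any(thr < 0 | thr > 1))
    stop("invalid input: thresholds must lie in [0, 1]")
  excl_s <- data.frame(id = character(0), reason = character(0),
                       stringsAsFactors = FALSE)
  excl_v <- excl_s

  # 1. variant call rate
  vr <- colMeans(!is.na(G))
  drop_v <- names(vr)[vr <= variant_thresh]
  if (length(drop_v))
    excl_v <- rbind(excl_v, data.frame(id = drop_v, reason = "low_call_rate",
                                       stringsAsFactors = FALSE))
  G <- G[, setdiff(colnames(G), drop_v), drop = FALSE]

  # 2. sample call rate (on retained variants)
  sr <- rowMeans(!is.na(G))
  drop_s <- names(sr)[sr <= sample_thresh]
  if (length(drop_s))
    excl_s <- rbind(excl_s, data.frame(id = drop_s, reason = "low_call_rate",
                                       stringsAsFactors = FALSE))
  G <- G[setdiff(rownames(G), drop_s), , drop = FALSE]
  if (nrow(G) == 0L) {
    report <- list(excluded_samples = excl_s, excluded_variants = excl_v,
                   thresholds = list(sample = sample_thresh,
                                     variant = variant_thresh,
                                     hwe = hwe_alpha, ibd = ibd_thresh),
                   pi_hat = NULL)
    stop(structure(class = c("msprisk_empty_result", "error", "condition"),
                   list(message = "all samples excluded by call-rate filters",
                        call = sys.call(-1), report = report)))
  }

  # 3. Hardy-Weinberg on retained controls
  ctrl <- if (is.null(control_ids)) rownames(G) else
    intersect(control_ids, rownames(G))
  if (length(ctrl) >= 1L && ncol(G) > 0L) {
    hwe_p <- apply(G[ctrl, , drop = FALSE], 2L, function(x) {
      cts <- genotype_counts(x)
      if (sum(cts) == 0L) return(1)
      hwe_exact_test(cts[1L], cts[2L], cts[3L])
    })
    drop_h <- names(hwe_p)[hwe_p < hwe_alpha]
    if (length(drop_h))
      excl_v <- rbind(excl_v, data.frame(id = drop_h, reason = "hwe_failure",
                                         stringsAsFactors = FALSE))
    G <- G[, setdiff(colnames(G), drop_h), drop = FALSE]
  }

  # 4. relatedness on rounded calls, frequencies from retained samples
  pihat_tab <- NULL
  ibd_skipped <- FALSE
  if (nrow(G) >= 2L && ncol(G) > 0L && ibd_thresh <= 1) {
    Gr <- round(G)
    f <- colMeans(Gr, na.rm = TRUE) / 2
    poly <- f > 0 & f < 1 & is.finite(f)
    if (sum(poly) < ibd_min_variants) {
      warning(sprintf(paste("relatedness step skipped: only %d polymorphic",
                            "variants (< %d); pi_hat would be too noisy at",
                            "this marker count"),
                      sum(poly), ibd_min_variants))
      ibd_skipped <- TRUE
      poly[] <- FALSE
    }
    if (any(poly)) {
      pihat_tab <- estimate_ibd(Gr[, poly, drop = FALSE], f[poly])
      flagged <- pihat_tab[pihat_tab$pi_hat >= ibd_thresh, , drop = FALSE]
      cr <- rowMeans(!is.na(G))
      removed <- character(0)
      # greedy: resolve pairs one at a time, skipping already-removed members
      while (nrow(flagged)) {
        pair <- flagged[1L, ]
        a <- pair$id1; b <- pair$id2
        victim <- if (cr[a] < cr[b]) a
                  else if (cr[b] < cr[a]) b
                  else max(a, b)
        removed <- c(removed, victim)
        flagged <- flagged[flagged$id1 != victim & flagged$id2 != victim, ,
                           drop = FALSE]
      }
      if (length(removed)) {
        excl_s <- rbind(excl_s,
                        data.frame(id = removed, reason = "relatedness",
                                   stringsAsFactors = FALSE))
        G <- G[setdiff(rownames(G), removed), , drop = FALSE]
      }
    }
  }
  if (nrow(G) == 0L)
    stop("all samples excluded by quality control")

  report <- list(excluded_samples = excl_s, excluded_variants = excl_v,
                 thresholds = list(sample = sample_thresh,
                                   variant = variant_thresh,
                                   hwe = hwe_alpha, ibd = ibd_thresh),
                 pi_hat = pihat_tab, ibd_skipped = ibd_skipped)
  structure(list(genotypes = G, report = report), class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  r <- x$report
  cat("Genotype QC result\n")
  cat(sprintf("  retained: %d samples x %d variants\n",
              nrow(x$genotypes), ncol(x$genotypes)))
  cat(sprintf("  excluded samples: %d (%s)\n", nrow(r$excluded_samples),
              if (nrow(r$excluded_samples))
                paste(r$excluded_samples$reason, collapse = ", ")
              else "none"))
  cat(sprintf("  excluded variants: %d (%s)\n", nrow(r$excluded_variants),
              if (nrow(r$excluded_variants))
                paste(r$excluded_variants$reason, collapse = ", ")
              else "none"))
  invisible(x)
}
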
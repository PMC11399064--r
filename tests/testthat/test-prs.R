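make_panel <- function(...) {
  rows <- list(...)
  p <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  p$variant_id <- paste(p$chrom, p$pos, p$other_allele, p$effect_allele,
                        sep = ":")
  p$weight <- log(p$odds_ratio)
  p$eaf <- 0.5
  class(p) <- c("variant_panel", "data.frame")
  p
}

test_that("harmonization classifies matched, flipped, ambiguous, mismatched and absent variants", {
  panel <- make_panel(
    list(chrom = 1, pos = 100, effect_allele = "A", other_allele = "G",
         odds_ratio = 1.5),   # matched (effect = alt)
    list(chrom = 1, pos = 200, effect_allele = "C", other_allele = "T",
         odds_ratio = 0.8),   # flipped (effect = ref)
    list(chrom = 2, pos = 300, effect_allele = "A", other_allele = "T",
         odds_ratio = 2.0),   # palindromic
    list(chrom = 2, pos = 400, effect_allele = "A", other_allele = "C",
         odds_ratio = 1.2),   # allele mismatch
    list(chrom = 3, pos = 500, effect_allele = "G", other_allele = "T",
         odds_ratio = 1.1))   # absent
  meta <- data.frame(
    variant_id = c("1:100:G:A", "1:200:C:T", "2:300:T:A", "2:400:G:T"),
    chrom = c(1, 1, 2, 2), pos = c(100, 200, 300, 400),
    ref = c("G", "C", "T", "G"), alt = c("A", "T", "A", "T"),
    stringsAsFactors = FALSE)
  G <- matrix(1, nrow = 2, ncol = 4,
              dimnames = list(c("s1", "s2"), meta$variant_id))
  h <- harmonize(panel, G, meta)
  expect_equal(h$log$action,
               c("matched", "flipped", "strand_ambiguous_dropped",
                 "allele_mismatch_dropped", "absent_dropped"))
  expect_equal(nrow(h$panel), 2L)
  expect_equal(h$panel$flip, c(FALSE, TRUE))
  expect_equal(nrow(h$log), nrow(panel))  # every panel variant logged once

  far_panel <- panel[5, , drop = FALSE]
  expect_error(harmonize(far_panel, G, meta), "no overlap")
})

test_that("raw PRS matches hand arithmetic and flip/missing conventions", {
  panel <- make_panel(
    list(chrom = 1, pos = 1, effect_allele = "A", other_allele = "G",
         odds_ratio = 1.5),
    list(chrom = 1, pos = 2, effect_allele = "C", other_allele = "T",
         odds_ratio = 0.8),
    list(chrom = 1, pos = 3, effect_allele = "G", other_allele = "A",
         odds_ratio = 2.0))
  meta <- data.frame(variant_id = panel$variant_id, chrom = panel$chrom,
                     pos = panel$pos, ref = panel$other_allele,
                     alt = panel$effect_allele, stringsAsFactors = FALSE)
  G <- matrix(c(2, 1, 0), nrow = 1,
              dimnames = list("s1", panel$variant_id))
  h <- harmonize(panel, G, meta)
  prs <- compute_prs(G, h$panel)
  expect_equal(prs$raw_score, 2 * log(1.5) + log(0.8), tolerance = 1e-5)
  expect_equal(prs$raw_score, 0.58779, tolerance = 1e-4)

  # flipped variant with dosage 2 contributes 2 - 2 = 0
  meta_f <- meta
  meta_f$ref <- panel$effect_allele
  meta_f$alt <- panel$other_allele
  meta_f$variant_id <- paste(meta_f$chrom, meta_f$pos, meta_f$ref,
                             meta_f$alt, sep = ":")
  meta_f <- meta_f[1, , drop = FALSE]
  G_f <- matrix(2, nrow = 1, dimnames = list("s1", meta_f$variant_id))
  h_f <- harmonize(panel[1, , drop = FALSE], G_f, meta_f)
  expect_true(h_f$panel$flip)
  expect_equal(compute_prs(G_f, h_f$panel)$raw_score, 0)

  # all dosages zero, no flips -> empty sum
  G0 <- matrix(0, nrow = 1, ncol = 3,
               dimnames = list("s1", panel$variant_id))
  expect_equal(compute_prs(G0, h$panel)$raw_score, 0)

  # a fully missing participant scores at the reference-mean contribution
  G2 <- rbind(G, s2 = NA, s3 = c(2, 2, 2))
  rownames(G2) <- c("s1", "s2", "s3")
  prs2 <- compute_prs(G2, h$panel, reference_ids = c("s1", "s3"))
  fhat <- colMeans(G2[c("s1", "s3"), ]) / 2
  expect_equal(prs2$raw_score[2], sum(h$panel$weight * 2 * fhat),
               tolerance = 1e-12)

  expect_error(compute_prs(G, panel), "harmonize")
})

test_that("z-score standardization uses the reference mean and n-1 SD", {
  scores <- data.frame(participant_id = c("a", "b", "c", "t"),
                       raw_score = c(1, 2, 3, 3), z_score = NA_real_)
  z <- standardize_prs(scores, reference_ids = c("a", "b", "c"))
  expect_equal(z$z_score[4], 1)  # sd(1,2,3) = 1 with n-1
  expect_equal(z$z_score[2], 0)
  expect_equal(mean(z$z_score[1:3]), 0, tolerance = 1e-12)
  expect_equal(sd(z$z_score[1:3]), 1, tolerance = 1e-12)

  degenerate <- data.frame(participant_id = c("a", "b"),
                           raw_score = c(2, 2), z_score = NA_real_)
  expect_error(standardize_prs(degenerate, c("a", "b")), "degenerate")
})

test_that("recoding variants to the opposite counted allele leaves z-scores unchanged", {
  sc <- small_cohort(seed = 59)
  panel <- sc$panel; G <- sc$genotypes
  prs1 <- score_cohort(panel, G, sc$pheno)

  # recode a third of the variants: dosage -> 2 - x, ref/alt swapped
  set.seed(9)
  swap <- sample(ncol(G), 20)
  G2 <- G
  G2[, swap] <- 2 - G2[, swap]
  meta2 <- data.frame(variant_id = panel$variant_id, chrom = panel$chrom,
                      pos = panel$pos, ref = panel$other_allele,
                      alt = panel$effect_allele, stringsAsFactors = FALSE)
  meta2$ref[swap] <- panel$effect_allele[swap]
  meta2$alt[swap] <- panel$other_allele[swap]
  meta2$variant_id <- paste(meta2$chrom, meta2$pos, meta2$ref, meta2$alt,
                            sep = ":")
  colnames(G2) <- meta2$variant_id
  ctrl <- sc$pheno$participant_id[sc$pheno$status == "control"]
  h2 <- harmonize(panel, G2, meta2)
  expect_equal(sum(h2$panel$flip), 20L)
  prs2 <- standardize_prs(compute_prs(G2, h2$panel, reference_ids = ctrl),
                          ctrl)
  expect_equal(prs2$z_score, prs1$z_score, tolerance = 1e-9)
})

test_that("zero-weight variants do not affect scores", {
  sc <- small_cohort(seed = 61)
  panel0 <- sc$panel
  panel0$weight[5] <- 0
  panel0$odds_ratio[5] <- 1
  prs_with <- score_cohort(panel0, sc$genotypes, sc$pheno)
  prs_without <- score_cohort(panel0[-5, , drop = FALSE],
                              sc$genotypes, sc$pheno)
  expect_equal(prs_with$raw_score, prs_without$raw_score,
               tolerance = 1e-12)
})

test_that("cases score higher than controls on average in a simulated cohort", {
  sc <- small_cohort(seed = 67)
  prs <- score_cohort(sc$panel, sc$genotypes, sc$pheno)
  case <- sc$pheno$status == "MS"
  expect_gt(mean(prs$z_score[case]), mean(prs$z_score[!case]))
})
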
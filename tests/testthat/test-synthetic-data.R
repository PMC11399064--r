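test_that("variant panel has the configured size, seeded determinism, and consistent weights", {
  cfg <- sim_config(seed = 11)
  p1 <- generate_variant_panel(cfg)
  expect_equal(nrow(p1), 215L)
  expect_identical(p1, generate_variant_panel(cfg))
  expect_true(all(abs(p1$weight - log(p1$odds_ratio)) < 1e-12))
  expect_true(all(p1$eaf > 0.05 & p1$eaf < 0.95))
  expect_true(all(p1$effect_allele != p1$other_allele))
  expect_true(all(p1$chrom %in% 1:22))
  expect_false(any(duplicated(p1$variant_id)))
  expect_equal(sum(p1$odds_ratio >= 2), 1L)

  p0 <- generate_variant_panel(small_config(seed = 2, n_large_effect = 0L))
  expect_true(all(p0$odds_ratio < 2))
})

test_that("allele pairs are never palindromic, so a synthetic panel survives harmonization", {
  p <- generate_variant_panel(small_config(seed = 3, n_variants = 200L))
  complement <- c(A = "T", C = "G", G = "C", T = "A")
  expect_false(any(p$other_allele == complement[p$effect_allele]))
})

test_that("invalid simulation configurations are rejected", {
  expect_error(sim_config(n_variants = 0), "n_variants")
  expect_error(sim_config(onset_sd = 0), "onset_sd")
  expect_error(sim_config(n_cases_f = -1), "counts")
  expect_error(sim_config(subtype_props = c(RRMS = 0.5, SPMS = 0.5,
                                            PPMS = 0.2)), "summing to 1")
  expect_error(simulate_cohort(sim_config(lifetime_risk_f = 0),
                               generate_variant_panel(small_config())),
               "calibration")
})

test_that("simulated cohort meets the configured case/control quotas and phenotype invariants", {
  sc <- small_cohort(seed = 5)
  ph <- sc$pheno
  expect_equal(sum(ph$sex == "F" & ph$status == "MS"), 40L)
  expect_equal(sum(ph$sex == "M" & ph$status == "MS"), 20L)
  expect_equal(sum(ph$status == "control"), 80L)
  expect_equal(dim(sc$genotypes), c(140L, 60L))
  expect_true(all(sc$genotypes %in% 0:2))

  ctrl <- ph$status == "control"
  expect_true(all(ph$subtype[ctrl] == "none"))
  expect_true(all(is.na(ph$age_onset[ctrl])))
  cases <- !ctrl
  expect_true(all(ph$age_onset[cases] > 5 &
                    ph$age_onset[cases] < ph$age_visit[cases]))
  spms <- ph$subtype == "SPMS"
  expect_true(all(!is.na(ph$age_progression[spms])))
  expect_true(all(ph$age_progression[spms] > ph$age_onset[spms]))
  expect_true(all(is.na(ph$age_progression[!spms])))
  expect_true(all(ph$age_visit > 0 & ph$age_visit < 120))

  sc2 <- small_cohort(seed = 5)
  expect_identical(sc$genotypes, sc2$genotypes)
  expect_identical(sc$pheno, sc2$pheno)
})

test_that("intercept calibration reproduces the target population risk in a large unselected sample", {
  cfg <- small_config(seed = 17, n_variants = 50L,
                      lifetime_risk_f = 282)
  panel <- generate_variant_panel(cfg)
  target <- 282 / 1e5
  set.seed(401)
  s_cal <- msprisk:::draw_centered_scores(50000L, panel$eaf, panel$weight)
  alpha <- msprisk:::calibrate_alpha(s_cal, target)
  n <- 4e5
  s <- msprisk:::draw_centered_scores(n, panel$eaf, panel$weight)
  y <- stats::rbinom(n, 1L, stats::plogis(alpha + s))
  se <- sqrt(target * (1 - target) / n)
  expect_lt(abs(mean(y) - target), 3 * se + 0.01 * target)
})

test_that("zero-weight disease model yields no case-control score separation", {
  cfg <- small_config(seed = 23)
  panel <- generate_variant_panel(cfg)
  null_panel <- panel
  null_panel$weight <- 0
  null_panel$odds_ratio <- 1
  coh <- simulate_cohort(cfg, null_panel)
  # score the genotypes with the original (nonzero) weights: under the null
  # disease model cases and controls have the same genotype distribution
  prs <- score_cohort(panel, coh$genotypes, coh$pheno)
  case <- coh$pheno$status == "MS"
  d <- mean(prs$raw_score[case]) - mean(prs$raw_score[!case])
  se <- sqrt(stats::var(prs$raw_score[case]) / sum(case) +
               stats::var(prs$raw_score[!case]) / sum(!case))
  expect_lt(abs(d), 3 * se)
})

test_that("control genotype frequencies follow Binomial(2, eaf) by chi-square goodness of fit", {
  cfg <- small_config(seed = 29, n_variants = 20L, n_cases_f = 0L,
                      n_cases_m = 0L, n_controls_f = 5000L,
                      n_controls_m = 5000L)
  panel <- generate_variant_panel(cfg)
  coh <- simulate_cohort(cfg, panel)
  G <- coh$genotypes
  pvals <- vapply(seq_len(ncol(G)), function(j) {
    f <- panel$eaf[j]
    expected <- c((1 - f)^2, 2 * f * (1 - f), f^2)
    obs <- c(sum(G[, j] == 0), sum(G[, j] == 1), sum(G[, j] == 2))
    suppressWarnings(stats::chisq.test(obs, p = expected)$p.value)
  }, numeric(1))
  expect_true(all(pvals > 0.001))
})

test_that("cases are enriched in the top control-based decile across a 10-seed suite", {
  for (seed in 1:10) {
    sc <- small_cohort(seed = seed)
    prs <- score_cohort(sc$panel, sc$genotypes, sc$pheno)
    ctrl <- sc$pheno$status == "control"
    dec <- assign_deciles(prs$z_score,
                          decile_boundaries(prs$z_score[ctrl]))
    case_dec <- dec[!ctrl]
    expect_gt(mean(case_dec == 10), mean(case_dec == 1))
  }
})

test_that("doubling every weight widens the case-control raw score gap", {
  cfg <- small_config(seed = 31)
  panel <- generate_variant_panel(cfg)
  gap <- function(p) {
    coh <- simulate_cohort(cfg, p)
    prs <- score_cohort(panel, coh$genotypes, coh$pheno)
    case <- coh$pheno$status == "MS"
    mean(prs$raw_score[case]) - mean(prs$raw_score[!case])
  }
  doubled <- panel
  doubled$weight <- 2 * panel$weight
  doubled$odds_ratio <- exp(doubled$weight)
  expect_gt(gap(doubled), gap(panel))
})

test_that("QC artifact injection is seeded, complete, and guarded", {
  sc <- small_cohort(seed = 37)
  inj <- inject_qc_artifacts(sc$genotypes, sc$pheno, seed = 7)
  expect_equal(nrow(inj$genotypes), nrow(sc$genotypes) + 1L)
  expect_equal(nrow(inj$pheno), nrow(sc$pheno) + 1L)
  exp <- inj$expected_exclusions
  expect_equal(sort(exp$reason),
               sort(c("low_call_rate", "relatedness", "low_call_rate",
                      "hwe_failure")))
  expect_equal(sum(exp$type == "sample"), 2L)
  expect_equal(sum(exp$type == "variant"), 2L)

  inj2 <- inject_qc_artifacts(sc$genotypes, sc$pheno, seed = 7)
  expect_identical(inj$genotypes, inj2$genotypes)
  expect_identical(inj$expected_exclusions, inj2$expected_exclusions)

  expect_error(inject_qc_artifacts(sc$genotypes[1:2, ], sc$pheno[1:2, ]),
               "invalid input")
  expect_error(inject_qc_artifacts(sc$genotypes[, 1:5], sc$pheno),
               "invalid input")
})
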
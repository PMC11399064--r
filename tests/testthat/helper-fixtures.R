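# Shared fixtures: scaled-down cohorts (generous base risks keep rejection
# sampling cheap), Table-3-analogue count vectors, and independent oracles.

small_config <- function(seed = 1L, ...) {
  args <- list(seed = seed, n_variants = 60L, n_large_effect = 1L,
               n_cases_f = 40L, n_cases_m = 20L,
               n_controls_f = 45L, n_controls_m = 35L,
               lifetime_risk_f = 2000, lifetime_risk_m = 800)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

small_cohort <- function(seed = 1L, ...) {
  cfg <- small_config(seed = seed, ...)
  panel <- generate_variant_panel(cfg)
  coh <- simulate_cohort(cfg, panel)
  list(config = cfg, panel = panel, genotypes = coh$genotypes,
       pheno = coh$pheno)
}

# female / male case counts per decile of the published study cohort
table3_counts_f <- c(3, 3, 2, 8, 15, 25, 22, 30, 19, 79)
table3_counts_m <- c(0, 2, 1, 2, 5, 11, 10, 8, 13, 27)

# Exact HWE test by direct enumeration: conditional probability of each
# heterozygote configuration given the allele counts, via log-factorials.
# Independent of the recurrence-based implementation.
hwe_oracle <- function(n_hom_effect, n_het, n_hom_other) {
  n <- n_hom_effect + n_het + n_hom_other
  n_eff <- 2 * n_hom_effect + n_het
  r <- min(n_eff, 2 * n - n_eff)
  if (r == 0) return(1)
  hs <- seq(r %% 2, r, by = 2)
  hom_r <- (r - hs) / 2
  hom_c <- n - hs - hom_r
  logp <- lfactorial(n) - lfactorial(hom_r) - lfactorial(hs) -
    lfactorial(hom_c) + hs * log(2) - lchoose(2 * n, r)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- match(n_het, hs)
  sum(p[p <= p[obs] * (1 + 1e-12)])
}

# Cox partial log-likelihood for a single covariate with untied event
# times, maximized numerically; oracle for fit_cox.
cox_loglik_oracle <- function(beta, time, event, x) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# score a cohort end to end: harmonize, raw PRS, control-standardized z
score_cohort <- function(panel, G, pheno) {
  meta <- data.frame(variant_id = panel$variant_id, chrom = panel$chrom,
                     pos = panel$pos, ref = panel$other_allele,
                     alt = panel$effect_allele, stringsAsFactors = FALSE)
  ctrl <- pheno$participant_id[pheno$status == "control"]
  h <- harmonize(panel, G, meta)
  standardize_prs(compute_prs(G, h$panel, reference_ids = ctrl), ctrl)
}
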
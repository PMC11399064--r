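# Seeded synthetic MS birth-year cohorts: variant panel, genotypes under
# Hardy-Weinberg, disease status from a calibrated logistic liability on the
# weighted score, and phenotype tables with onset / progression / visit ages.

#' Configuration for the synthetic cohort generator
#'
#' Bundles every tunable of the generator with defaults matching the study
#' conditions the package emulates: a 215-variant autosomal susceptibility
#' panel, 206 female and 79 male cases, 154 female and 113 male controls,
#' sex-specific lifetime risks of 282 (women) and 100 (men) per 100,000
#' births, onset ages Normal(36.6, 9.30), a 59.3/27.7/13.0 percent
#' RRMS/SPMS/PPMS subtype mix, and visit ages of 53.0 +/- 0.9 years for cases
#' and 51.8 +/- 3.2 for controls.
#'
#' @param seed Integer root seed; every generator stage derives its stream
#'   from it, so identical configurations reproduce identical cohorts.
#' @param n_variants Number of susceptibility variants in the panel.
#' @param n_large_effect Number of variants given odds ratios in \[2, 3.5\],
#'   emulating major MHC signals.
#' @param n_cases_f,n_cases_m Target case counts per sex.
#' @param n_controls_f,n_controls_m Target control counts per sex.
#' @param lifetime_risk_f,lifetime_risk_m Population lifetime risk per
#'   100,000, used to calibrate the disease model intercept per sex.
#' @param onset_mean,onset_sd Mean and SD (years) of the onset-age
#'   distribution before truncation to (5, age at visit).
#' @param subtype_props Named proportions for RRMS, SPMS and PPMS; must sum
#'   to 1.
#' @param visit_mean_case,visit_sd_case,visit_mean_control,visit_sd_control
#'   Mean and SD (years) of study-visit age for cases and controls.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 42, n_variants = 20, n_cases_f = 10,
#'                   n_cases_m = 5, n_controls_f = 10, n_controls_m = 5,
#'                   lifetime_risk_f = 2000, lifetime_risk_m = 1000)
#' @export
sim_config <- function(seed = 1L,
                       n_variants = 215L,
                       n_large_effect = 1L,
                       n_cases_f = 206L, n_cases_m = 79L,
                       n_controls_f = 154L, n_controls_m = 113L,
                       lifetime_risk_f = 282, lifetime_risk_m = 100,
                       onset_mean = 36.6, onset_sd = 9.30,
                       subtype_props = c(RRMS = 0.593, SPMS = 0.277,
                                         PPMS = 0.130),
                       visit_mean_case = 53.0, visit_sd_case = 0.9,
                       visit_mean_control = 51.8, visit_sd_control = 3.2) {
  cfg <- list(seed = as.integer(seed), n_variants = as.integer(n_variants),
              n_large_effect = as.integer(n_large_effect),
              n_cases_f = as.integer(n_cases_f),
              n_cases_m = as.integer(n_cases_m),
              n_controls_f = as.integer(n_controls_f),
              n_controls_m = as.integer(n_controls_m),
              lifetime_risk_f = lifetime_risk_f,
              lifetime_risk_m = lifetime_risk_m,
              onset_mean = onset_mean, onset_sd = onset_sd,
              subtype_props = subtype_props,
              visit_mean_case = visit_mean_case,
              visit_sd_case = visit_sd_case,
              visit_mean_control = visit_mean_control,
              visit_sd_control = visit_sd_control)
  if (is.na(cfg$seed)) stop("invalid configuration: seed must be an integer")
  if (cfg$n_variants < 1L)
    stop("invalid configuration: n_variants must be >= 1")
  if (cfg$n_large_effect < 0L || cfg$n_large_effect > cfg$n_variants)
    stop("invalid configuration: n_large_effect must be in [0, n_variants]")
  counts <- c(cfg$n_cases_f, cfg$n_cases_m, cfg$n_controls_f,
              cfg$n_controls_m)
  if (any(counts < 0L))
    stop("invalid configuration: counts must be >= 0")
  if (cfg$onset_sd <= 0)
    stop("invalid configuration: onset_sd must be > 0")
  if (length(cfg$subtype_props) != 3L ||
      abs(sum(cfg$subtype_props) - 1) > 1e-9)
    stop("invalid configuration: subtype_props must be 3 proportions summing to 1")
  if (!all(c("RRMS", "SPMS", "PPMS") %in% names(cfg$subtype_props)))
    stop("invalid configuration: subtype_props must be named RRMS, SPMS, PPMS")
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic GWAS susceptibility-variant panel
#'
#' Draws `n_variants` autosomal biallelic variants with effect-allele
#' frequencies Uniform(0.05, 0.95) and log odds ratios Normal(0.06, 0.04);
#' `n_large_effect` of them instead receive odds ratios Uniform(2, 3.5),
#' standing in for major MHC signals. Allele pairs are drawn non-palindromic
#' (never A/T or C/G) so a synthetic panel is never lost to strand-ambiguity
#' filtering. The panel is sorted by chromosome and position, and the weight
#' column always equals `log(odds_ratio)`.
#'
#' @param config A [sim_config()] object.
#' @return A `data.frame` of class `variant_panel` with columns
#'   `variant_id` (`chrom:pos:ref:alt`, ref = other allele, alt = effect
#'   allele), `chrom`, `pos`, `effect_allele`, `other_allele`, `odds_ratio`,
#'   `weight`, `eaf`.
#' @export
generate_variant_panel <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("config must be a sim_config object")
  m <- config$n_variants
  set.seed(config$seed)
  chrom <- sample(1:22, m, replace = TRUE)
  pos <- sample.int(2e8L, m)
  repeat {
    dup <- duplicated(paste(chrom, pos))
    if (!any(dup)) break
    pos[dup] <- sample.int(2e8L, sum(dup))
  }
  bases <- c("A", "C", "G", "T")
  complement <- c(A = "T", C = "G", G = "C", T = "A")
  effect <- sample(bases, m, replace = TRUE)
  # exclude the same base and its complement: pairs stay strand-unambiguous
  other <- vapply(effect, function(b) {
    sample(setdiff(bases, c(b, complement[[b]])), 1L)
  }, character(1L), USE.NAMES = FALSE)
  weight <- stats::rnorm(m, mean = 0.06, sd = 0.04)
  if (config$n_large_effect > 0L) {
    large <- sample.int(m, config$n_large_effect)
    weight[large] <- log(stats::runif(config$n_large_effect, 2, 3.5))
  }
  eaf <- stats::runif(m, 0.05, 0.95)
  panel <- data.frame(
    variant_id = paste(chrom, pos, other, effect, sep = ":"),
    chrom = chrom, pos = pos,
    effect_allele = effect, other_allele = other,
    odds_ratio = exp(weight), weight = weight, eaf = eaf,
    stringsAsFactors = FALSE)
  panel <- panel[order(panel$chrom, panel$pos), , drop = FALSE]
  rownames(panel) <- NULL
  class(panel) <- c("variant_panel", "data.frame")
  panel
}

# Centered weighted scores s_i = sum_j w_j (x_ij - 2 f_j) for n individuals
# drawn genotype-wise Binomial(2, f_j); chunked to bound memory.
draw_centered_scores <- function(n, eaf, weight, chunk = 10000L) {
  offset <- sum(2 * eaf * weight)
  out <- numeric(0)
  left <- n
  while (left > 0L) {
    nb <- min(chunk, left)
    g <- matrix(stats::rbinom(nb * length(eaf), 2L, rep(eaf, each = nb)),
                nrow = nb)
    out <- c(out, as.vector(g %*% weight) - offset)
    left <- left - nb
  }
  out
}

# Bisection on the intercept alpha so that mean plogis(alpha + s) over a
# Monte-Carlo sample of centered scores hits the target population risk.
calibrate_alpha <- function(scores, target, rel_tol = 1e-3,
                            max_iter = 200L) {
  if (target <= 0 || target >= 1)
    stop("calibration error: target risk must lie in (0, 1)")
  risk_at <- function(a) mean(stats::plogis(a + scores))
  lo <- -40; hi <- 10
  if (risk_at(lo) > target || risk_at(hi) < target)
    stop("calibration error: target risk outside attainable range")
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    r <- risk_at(mid)
    if (abs(r - target) <= rel_tol * target) return(mid)
    if (r < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Rejection-sample one sex stratum until case/control quotas are met.
# Returns genotype matrices for accepted cases and controls.
sample_stratum <- function(n_case, n_control, alpha, eaf, weight,
                           batch = 20000L, max_batches = 5000L) {
  m <- length(eaf)
  offset <- sum(2 * eaf * weight)
  cases <- vector("list", 0L); ctrls <- vector("list", 0L)
  n_ca <- 0L; n_co <- 0L
  for (b in seq_len(max_batches)) {
    if (n_ca >= n_case && n_co >= n_control) break
    g <- matrix(stats::rbinom(batch * m, 2L, rep(eaf, each = batch)),
                nrow = batch)
    p <- stats::plogis(alpha + as.vector(g %*% weight) - offset)
    y <- stats::rbinom(batch, 1L, p)
    if (n_ca < n_case) {
      take <- which(y == 1L)
      take <- take[seq_len(min(length(take), n_case - n_ca))]
      if (length(take)) {
        cases[[length(cases) + 1L]] <- g[take, , drop = FALSE]
        n_ca <- n_ca + length(take)
      }
    }
    if (n_co < n_control) {
      take <- which(y == 0L)
      take <- take[seq_len(min(length(take), n_control - n_co))]
      if (length(take)) {
        ctrls[[length(ctrls) + 1L]] <- g[take, , drop = FALSE]
        n_co <- n_co + length(take)
      }
    }
  }
  if (n_ca < n_case || n_co < n_control)
    stop("calibration error: case/control quotas not reached by rejection sampling")
  list(cases = do.call(rbind, c(cases, list(matrix(0L, 0L, m)))),
       controls = do.call(rbind, c(ctrls, list(matrix(0L, 0L, m)))))
}

# Normal(mean, sd) truncated to (lo, hi), elementwise bounds, by rejection.
rtruncnorm_vec <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lo | x >= hi)
  guard <- 0L
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lo[bad] | x[bad] >= hi[bad]]
    guard <- guard + 1L
    if (guard > 10000L) { # pathological bounds: fall back to uniform
      x[bad] <- stats::runif(length(bad), lo[bad], hi[bad])
      break
    }
  }
  x
}

#' Simulate a case-control cohort from a variant panel
#'
#' Genotypes are drawn per variant as Binomial(2, eaf) (Hardy-Weinberg,
#' no linkage disequilibrium). Disease status follows a logistic model on the
#' centered weighted score, `P(MS | x, sex) = plogis(alpha_sex +
#' sum_j w_j (x_j - 2 f_j))`, with `alpha_sex` calibrated by bisection so the
#' unselected population risk matches the configured lifetime risk per
#' 100,000 for that sex. Individuals are then rejection-sampled until the
#' configured case and control quotas per sex are met. Cases receive onset
#' ages from a truncated normal on (5, age at visit), a subtype draw, and —
#' for secondary-progressive cases — a progression age between onset and
#' visit.
#'
#' @param config A [sim_config()] object.
#' @param panel A `variant_panel` from [generate_variant_panel()].
#' @return A list of class `ms_cohort` with elements `genotypes` (samples x
#'   variants integer dosage matrix of the effect allele, dimnames set) and
#'   `pheno` (a `data.frame` with `participant_id`, `sex`, `status`,
#'   `subtype`, `age_onset`, `age_progression`, `age_visit`). The root seed
#'   is kept in attribute `seed`.
#' @export
simulate_cohort <- function(config, panel) {
  if (!inherits(config, "sim_config"))
    stop("config must be a sim_config object")
  if (!is.data.frame(panel) || nrow(panel) == 0L)
    stop("panel must be a nonempty variant panel")
  eaf <- panel$eaf; weight <- panel$weight
  target_f <- config$lifetime_risk_f / 1e5
  target_m <- config$lifetime_risk_m / 1e5
  set.seed(config$seed + 1L)
  s_cal <- draw_centered_scores(50000L, eaf, weight)
  alpha_f <- calibrate_alpha(s_cal, target_f)
  alpha_m <- calibrate_alpha(s_cal, target_m)
  fem <- sample_stratum(config$n_cases_f, config$n_controls_f, alpha_f,
                        eaf, weight)
  mal <- sample_stratum(config$n_cases_m, config$n_controls_m, alpha_m,
                        eaf, weight)

  g <- rbind(fem$cases, mal$cases, fem$controls, mal$controls)
  n_case <- config$n_cases_f + config$n_cases_m
  n_ctrl <- config$n_controls_f + config$n_controls_m
  n <- n_case + n_ctrl
  ids <- sprintf("S%04d", seq_len(n))
  dimnames(g) <- list(ids, panel$variant_id)
  sex <- c(rep("F", config$n_cases_f), rep("M", config$n_cases_m),
           rep("F", config$n_controls_f), rep("M", config$n_controls_m))
  status <- c(rep("MS", n_case), rep("control", n_ctrl))

  visit <- c(stats::rnorm(n_case, config$visit_mean_case,
                          config$visit_sd_case),
             stats::rnorm(n_ctrl, config$visit_mean_control,
                          config$visit_sd_control))
  visit <- pmax(visit, 6)  # keep ages positive and onsets placeable
  onset <- rep(NA_real_, n)
  progression <- rep(NA_real_, n)
  subtype <- rep("none", n)
  if (n_case > 0L) {
    ci <- seq_len(n_case)
    onset[ci] <- rtruncnorm_vec(n_case, config$onset_mean, config$onset_sd,
                                lo = rep(5, n_case), hi = visit[ci])
    subtype[ci] <- sample(names(config$subtype_props), n_case,
                          replace = TRUE, prob = config$subtype_props)
    sp <- ci[subtype[ci] == "SPMS"]
    if (length(sp)) {
      lo <- onset[sp] + pmin(1, (visit[sp] - onset[sp]) / 2)
      progression[sp] <- stats::runif(length(sp), lo, visit[sp])
    }
  }
  pheno <- data.frame(participant_id = ids, sex = sex, status = status,
                      subtype = subtype, age_onset = onset,
                      age_progression = progression, age_visit = visit,
                      stringsAsFactors = FALSE)
  structure(list(genotypes = g, pheno = pheno),
            class = "ms_cohort", seed = config$seed,
            alpha = c(F = alpha_f, M = alpha_m))
}

#' Inject quality-control artifacts into a clean cohort
#'
#' Plants exactly the defects the QC stage is designed to catch: one
#' near-duplicate participant (a genotype copy with 1% of entries
#' resampled), one participant and one variant with call rate below 0.99,
#' and one variant replaced by an extreme heterozygote-deficit
#' configuration (every genotype homozygous). Artifact targets are chosen
#' among controls where possible so case quotas survive QC.
#'
#' @param G Samples x variants dosage matrix with dimnames.
#' @param pheno Matching phenotype table.
#' @param seed Integer seed for artifact placement.
#' @return A list with the modified `genotypes` and `pheno` plus
#'   `expected_exclusions`, a `data.frame` (`id`, `type`, `reason`) listing
#'   what a downstream [apply_qc()] run must remove.
#' @export
inject_qc_artifacts <- function(G, pheno, seed = 1L) {
  n <- nrow(G); m <- ncol(G)
  if (n < 3L || m < 10L)
    stop("invalid input: need at least 3 participants and 10 variants")
  set.seed(seed)
  ctrl <- pheno$participant_id[pheno$status == "control"]
  pool <- if (length(ctrl) >= 2L) ctrl else rownames(G)
  picks <- sample(pool, 2L)
  dup_src <- picks[1L]; low_sample <- picks[2L]
  freq <- colMeans(G, na.rm = TRUE) / 2
  vpool <- which(freq > 0.2 & freq < 0.8)
  if (length(vpool) < 2L) vpool <- which(freq > 0 & freq < 1)
  if (length(vpool) < 2L)
    stop("invalid input: need at least 2 polymorphic variants")
  vpicks <- sample(vpool, 2L)
  hwe_var <- colnames(G)[vpicks[1L]]
  low_var <- colnames(G)[vpicks[2L]]

  # near-duplicate of dup_src; its id sorts after the source, so the
  # lexicographic tie-break in apply_qc removes the copy, not the original
  dup_id <- paste0(dup_src, "D")
  g_dup <- G[dup_src, ]
  k <- max(1L, round(0.01 * m))
  sel <- sample.int(m, k)
  g_dup[sel] <- stats::rbinom(k, 2L, freq[sel])
  G2 <- rbind(G, g_dup)
  rownames(G2)[n + 1L] <- dup_id
  dup_row <- pheno[pheno$participant_id == dup_src, , drop = FALSE]
  dup_row$participant_id <- dup_id
  pheno2 <- rbind(pheno, dup_row)
  rownames(pheno2) <- NULL

  # heterozygote deficit: all-homozygous genotypes at the original frequency
  G2[, hwe_var] <- 2L * stats::rbinom(nrow(G2), 1L, freq[hwe_var])

  # low-call-rate variant: >1% of entries missing
  kv <- max(ceiling(0.02 * nrow(G2)), floor(0.01 * nrow(G2)) + 1L)
  G2[sample.int(nrow(G2), kv), low_var] <- NA

  # low-call-rate sample: missing entries placed on variants that survive
  # the variant filter, so the sample's post-filter call rate stays low
  ks <- max(3L, ceiling(0.02 * m))
  scols <- sample(setdiff(colnames(G2), c(low_var, hwe_var)), ks)
  G2[low_sample, scols] <- NA

  expected <- data.frame(
    id = c(low_sample, dup_id, low_var, hwe_var),
    type = c("sample", "sample", "variant", "variant"),
    reason = c("low_call_rate", "relatedness", "low_call_rate",
               "hwe_failure"),
    stringsAsFactors = FALSE)
  list(genotypes = G2, pheno = pheno2, expected_exclusions = expected)
}
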
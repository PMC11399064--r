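test_that("principal components are orthogonal, sign-fixed, and reduce to the rank-1 case", {
  set.seed(97)
  G <- matrix(rbinom(40 * 30, 2, 0.4), nrow = 40,
              dimnames = list(sprintf("s%02d", 1:40), paste0("v", 1:30)))
  pcs <- compute_pcs(G, k = 5)
  expect_equal(colnames(pcs), paste0("pc", 1:5))
  cross <- crossprod(pcs)
  expect_lt(max(abs(cross[upper.tri(cross)])), 1e-8)

  # one informative variant among constants: PC1 proportional to its
  # standardized dosage
  G1 <- cbind(v1 = rbinom(30, 2, 0.5), v2 = rep(1, 30), v3 = rep(2, 30))
  rownames(G1) <- sprintf("r%02d", 1:30)
  expect_warning(p1 <- compute_pcs(G1, k = 1), "zero-variance")
  x <- G1[, 1] - mean(G1[, 1])
  expect_equal(abs(cor(p1[, 1], x)), 1, tolerance = 1e-12)

  expect_error(compute_pcs(G, k = 30), "smaller")
})

test_that("PC1 separates two simulated subpopulations with divergent frequencies", {
  set.seed(101)
  n <- 60; m <- 400
  f1 <- runif(m, 0.1, 0.9)
  shift <- sample(c(-0.25, 0.25), m, replace = TRUE)
  f2 <- pmin(0.95, pmax(0.05, f1 + shift))
  G <- rbind(
    matrix(rbinom(n * m, 2, rep(f1, each = n)), nrow = n),
    matrix(rbinom(n * m, 2, rep(f2, each = n)), nrow = n))
  dimnames(G) <- list(sprintf("s%03d", 1:(2 * n)), paste0("v", 1:m))
  pcs <- compute_pcs(G, k = 2)
  grp <- rep(c(1, 2), each = n)
  gap <- abs(mean(pcs[grp == 1, 1]) - mean(pcs[grp == 2, 1]))
  pooled_sd <- sqrt((var(pcs[grp == 1, 1]) + var(pcs[grp == 2, 1])) / 2)
  expect_gt(gap, 2 * pooled_sd)
})

test_that("survival records implement the outcome and censoring rules", {
  pheno <- data.frame(
    participant_id = c("a", "b", "c"),
    sex = c("F", "M", "F"),
    status = c("MS", "MS", "control"),
    subtype = c("SPMS", "RRMS", "none"),
    age_onset = c(30, 30, NA), age_progression = c(40, NA, NA),
    age_visit = c(53, 53, 52), stringsAsFactors = FALSE)
  prs <- data.frame(participant_id = c("a", "b", "c"),
                    raw_score = 0, z_score = c(1, -1, 0))

  on <- build_survival_records(pheno, prs, outcome = "onset_age")
  expect_equal(on$time, c(30, 30))
  expect_equal(on$event, c(1L, 1L))

  pa <- build_survival_records(pheno, prs, outcome = "progression_age")
  expect_equal(pa$time, c(40, 53))
  expect_equal(pa$event, c(1L, 0L))

  tp <- build_survival_records(pheno, prs, outcome = "time_to_progression")
  expect_equal(tp$time, c(10, 23))
  expect_equal(tp$event, c(1L, 0L))

  bad <- pheno
  bad$age_onset[2] <- 60  # visit before onset: nonpositive time
  expect_warning(tp2 <- build_survival_records(bad, prs,
                                               outcome = "time_to_progression"),
                 "nonpositive")
  expect_equal(nrow(tp2), 1L)
})

test_that("fit_cox matches a brute-force partial-likelihood maximizer", {
  set.seed(103)
  n <- 12
  x <- sample(rep(c(0, 1), each = n / 2))
  time <- rexp(n, rate = exp(0.5 * x)) + (1:n) * 1e-4  # distinct times
  rec <- data.frame(time = time, event = 1L, z = x)
  fit <- fit_cox(rec, covariates = "z")
  opt <- optimize(function(b) -cox_loglik_oracle(b, rec$time, rec$event,
                                                 rec$z),
                  interval = c(-5, 5), tol = 1e-9)
  expect_equal(unname(log(fit$hr)), opt$minimum, tolerance = 1e-6)

  expect_error(fit_cox(transform(rec, event = 0L), "z"), "no events")
  rec$z2 <- rec$z
  expect_error(fit_cox(rec, covariates = c("z", "z2")), "collinear")
})

test_that("duplicated covariates are flagged by an unbounded VIF", {
  set.seed(104)
  X <- cbind(a = rnorm(50), b = rnorm(50))
  X <- cbind(X, c = X[, "a"])
  v <- compute_vif(X)
  expect_true(is.infinite(v["a"]) && is.infinite(v["c"]))
  expect_lt(compute_vif(X[, 1:2])["a"], 1.5)  # orthogonal covariates
})

test_that("the association suite returns the 9 primary fits with BH-corrected p-values", {
  sc <- small_cohort(seed = 107, n_cases_f = 70L, n_cases_m = 40L,
                     n_controls_f = 60L, n_controls_m = 50L)
  prs <- score_cohort(sc$panel, sc$genotypes, sc$pheno)
  qG <- sc$genotypes
  pcs <- compute_pcs(qG, k = 5)
  suite <- suppressWarnings(run_association_suite(sc$pheno, prs, pcs))
  expect_equal(nrow(suite), 9L)
  expect_equal(suite$outcome,
               rep(c("onset_age", "progression_age", "time_to_progression"),
                   each = 3))
  expect_equal(suite$stratum, rep(c("all", "F", "M"), times = 3))
  ok <- !is.na(suite$p)
  expect_true(all(suite$p_adj[ok] >= suite$p[ok]))
  expect_true(all(suite$p_adj[ok] <= 1))
  # BH preserves the ordering of raw p-values
  expect_false(is.unsorted(suite$p_adj[ok][order(suite$p[ok])]))
  expect_true(all(suite$ci_low[ok] <= suite$hr[ok] &
                    suite$hr[ok] <= suite$ci_high[ok]))
  expect_true(all(suite$n[suite$stratum == "all"] ==
                    sum(sc$pheno$status == "MS")))
})

test_that("decile tests are restricted to deciles 5-10 and skip empty deciles", {
  sc <- small_cohort(seed = 109, n_cases_f = 70L, n_cases_m = 40L,
                     n_controls_f = 60L, n_controls_m = 50L)
  prs <- score_cohort(sc$panel, sc$genotypes, sc$pheno)
  ctrl <- sc$pheno$status == "control"
  dec <- assign_deciles(prs$z_score, decile_boundaries(prs$z_score[ctrl]))
  pcs <- compute_pcs(sc$genotypes, k = 5)
  expect_error(run_decile_tests(sc$pheno, prs, dec, pcs, deciles = 3:10),
               "deciles 5-10")
  res <- suppressWarnings(run_decile_tests(sc$pheno, prs, dec, pcs))
  expect_lte(nrow(res), 18L)
  expect_true(all(grepl("^decile (5|6|7|8|9|10)$", res$stratum)))
})

test_that("model diagnostics report PH tests, VIFs and linearity checks", {
  set.seed(113)
  n <- 200
  rec <- data.frame(z = rnorm(n), x2 = rnorm(n))
  rec$time <- rexp(n, exp(0.3 * rec$z))
  rec$event <- 1L
  fit <- fit_cox(rec, covariates = c("z", "x2"))
  d <- check_model_assumptions(fit)
  expect_true(d$available)
  expect_setequal(d$ph$covariate, c("z", "x2"))
  expect_true(all(d$vif < 1.5))
  expect_equal(nrow(d$linearity), 2L)
  # proportional hazards holds in this generating model
  expect_true(all(d$ph$p > 0.01))

  tiny <- data.frame(time = c(1, 2, 3), event = c(1L, 1L, 0L),
                     z = c(0.3, -1, 2))
  d2 <- check_model_assumptions(fit_cox(tiny, "z"))
  expect_false(d2$available)
})

test_that("permuting the covariate yields uniform p-values (null calibration)", {
  set.seed(127)
  n <- 120
  base <- data.frame(time = rexp(n), event = rbinom(n, 1, 0.8),
                     z = rnorm(n))
  pvals <- replicate(200, {
    r <- base
    r$z <- sample(r$z)
    fit_cox(r, "z")$p
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})
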
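# Cox proportional-hazards associations between the PRS and disease-course
# outcomes: principal components, survival-record construction, model fits
# (survival::coxph, Efron ties), the 9-fit suite with Benjamini-Hochberg
# correction, per-decile tests, and model diagnostics.

#' Genetic principal components of a dosage matrix
#'
#' Columns are centered by twice the estimated effect-allele frequency and
#' scaled by `sqrt(2 f (1 - f))` (the binomial SD), missing entries set to
#' the column mean after centering, and the top `k` principal components
#' extracted. Zero-variance variants are dropped with a warning. Each
#' component's sign is fixed by making its largest-magnitude loading
#' positive.
#'
#' @param G Post-QC samples x variants dosage matrix.
#' @param k Number of components (default 5); must be smaller than both
#'   dimensions.
#' @return Samples x k matrix with columns `pc1..pck`.
#' @export
compute_pcs <- function(G, k = 5L) {
  if (!is.matrix(G)) stop("G must be a matrix")
  if (k >= min(dim(G))) stop("k must be smaller than both matrix dimensions")
  f <- colMeans(G, na.rm = TRUE) / 2
  v <- apply(G, 2L, stats::var, na.rm = TRUE)
  keep <- is.finite(f) & f > 0 & f < 1 & is.finite(v) & v > 0
  if (!all(keep)) {
    warning(sprintf("dropping %d zero-variance variant(s) before PCA",
                    sum(!keep)))
    G <- G[, keep, drop = FALSE]
    f <- f[keep]
  }
  if (k > min(dim(G))) stop("too few informative variants for k components")
  X <- sweep(G, 2L, 2 * f, "-")
  X <- sweep(X, 2L, sqrt(2 * f * (1 - f)), "/")
  X[is.na(X)] <- 0
  pc <- stats::prcomp(X, center = FALSE, scale. = FALSE, rank. = k)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (i in seq_len(k)) {
    j <- which.max(abs(pc$rotation[, i]))
    if (pc$rotation[j, i] < 0) scores[, i] <- -scores[, i]
  }
  colnames(scores) <- paste0("pc", seq_len(k))
  rownames(scores) <- rownames(G)
  scores
}

#' Build survival records for one disease-course outcome
#'
#' Cases only. For `onset_age` every case contributes an event at its onset
#' age. For `progression_age`, secondary-progressive (SPMS) cases contribute
#' an event at their progression age and all other cases are censored at
#' their visit age. For `time_to_progression` the same events and censoring
#' are measured from onset instead of birth. Records with nonpositive or
#' missing times are dropped with a warning.
#'
#' @param pheno Phenotype table (`participant_id`, `sex`, `status`,
#'   `subtype`, `age_onset`, `age_progression`, `age_visit`).
#' @param prs PRS table with `participant_id` and `z_score`.
#' @param pcs Optional samples x k principal-component matrix (rownames =
#'   participant ids).
#' @param outcome One of `"onset_age"`, `"progression_age"`,
#'   `"time_to_progression"`.
#' @return A `data.frame` with `participant_id`, `time`, `event`, `z`,
#'   `sex`, and any PC columns.
#' @export
build_survival_records <- function(pheno, prs, pcs = NULL,
                                   outcome = c("onset_age",
                                               "progression_age",
                                               "time_to_progression")) {
  outcome <- match.arg(outcome)
  cases <- pheno[pheno$status == "MS", , drop = FALSE]
  z <- prs$z_score[match(cases$participant_id, prs$participant_id)]
  spms <- cases$subtype == "SPMS" & !is.na(cases$age_progression)
  if (outcome == "onset_age") {
    time <- cases$age_onset
    event <- rep(1L, nrow(cases))
  } else if (outcome == "progression_age") {
    time <- ifelse(spms, cases$age_progression, cases$age_visit)
    event <- as.integer(spms)
  } else {
    time <- ifelse(spms, cases$age_progression, cases$age_visit) -
      cases$age_onset
    event <- as.integer(spms)
  }
  rec <- data.frame(participant_id = cases$participant_id, time = time,
                    event = event, z = z, sex = cases$sex,
                    stringsAsFactors = FALSE)
  if (!is.null(pcs)) {
    idx <- match(rec$participant_id, rownames(pcs))
    rec <- cbind(rec, as.data.frame(pcs[idx, , drop = FALSE],
                                    row.names = NULL))
  }
  bad <- is.na(rec$time) | rec$time <= 0 | is.na(rec$z)
  if (any(bad)) {
    warning(sprintf("dropping %d record(s) with missing or nonpositive time",
                    sum(bad)))
    rec <- rec[!bad, , drop = FALSE]
  }
  rownames(rec) <- NULL
  rec
}

#' Fit one Cox proportional-hazards association
#'
#' Maximizes the Cox partial likelihood with the Efron tie correction
#' (via [survival::coxph()]) and reports the hazard ratio for `term` with
#' its Wald 95% CI, the standard error of the log-HR, and the Wald p-value.
#'
#' @param records Output of [build_survival_records()] (or any data frame
#'   with `time`, `event` and the covariates).
#' @param covariates Covariate column names to adjust for; the first is the
#'   reported term unless `term` says otherwise.
#' @param term The covariate whose hazard ratio is reported.
#' @return An object of class `cox_result`: `term`, `hr`, `ci_low`,
#'   `ci_high`, `se` (of the log-HR), `p`, `n`, `n_events`, and the
#'   underlying `fit`.
#' @export
fit_cox <- function(records, covariates = "z", term = covariates[1L]) {
  if (!all(c("time", "event") %in% names(records)))
    stop("records must have 'time' and 'event' columns")
  if (!all(covariates %in% names(records)))
    stop("missing covariate column(s): ",
         paste(setdiff(covariates, names(records)), collapse = ", "))
  if (sum(records$event) < 1L)
    stop("no events: cannot fit a Cox model")
  mm <- stats::model.matrix(
    stats::reformulate(covariates),
    data = records)[, -1L, drop = FALSE]
  if (qr(cbind(1, mm))$rank < ncol(mm) + 1L)
    stop("collinear covariates detected; drop or combine them")
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = records, ties = "efron", x = TRUE)
  if (any(!is.finite(stats::coef(fit))))
    stop("Cox model did not converge: non-finite coefficient")
  cf <- summary(fit)$coefficients
  rn <- rownames(cf)
  i <- if (term %in% rn) term else grep(paste0("^", term), rn, value = TRUE)[1L]
  if (is.na(i)) stop("term '", term, "' not found in the fitted model")
  b <- cf[i, "coef"]; se <- cf[i, "se(coef)"]
  structure(list(term = term, hr = exp(b),
                 ci_low = exp(b - 1.96 * se), ci_high = exp(b + 1.96 * se),
                 se = se, p = cf[i, "Pr(>|z|)"],
                 n = nrow(records), n_events = sum(records$event),
                 fit = fit),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox PH fit (Efron ties): HR[%s] = %.3f (95%% CI %.3f-%.3f), SE(log HR) = %.3f, p = %.3g, n = %d (%d events)\n",
              x$term, x$hr, x$ci_low, x$ci_high, x$se, x$p, x$n,
              x$n_events))
  invisible(x)
}

cox_row <- function(res, outcome, stratum) {
  if (is.null(res))
    return(data.frame(outcome = outcome, stratum = stratum, hr = NA_real_,
                      ci_low = NA_real_, ci_high = NA_real_, se = NA_real_,
                      p = NA_real_, p_adj = NA_real_, n = NA_integer_,
                      stringsAsFactors = FALSE))
  data.frame(outcome = outcome, stratum = stratum, hr = res$hr,
             ci_low = res$ci_low, ci_high = res$ci_high, se = res$se,
             p = res$p, p_adj = NA_real_, n = res$n,
             stringsAsFactors = FALSE)
}

#' Run the primary association suite
#'
#' Nine fits — the three disease-course outcomes (age at onset, age at
#' progression, time to progression) by three strata (all, women, men).
#' Pooled fits adjust for sex and the principal components; sex-stratified
#' fits adjust for the components only. Benjamini-Hochberg correction is
#' applied across the 9 raw p-values. A failing stratum yields an NA row
#' and the suite continues.
#'
#' @param pheno,prs,pcs As in [build_survival_records()].
#' @return A `data.frame` of class `cox_suite` with columns `outcome`,
#'   `stratum`, `hr`, `ci_low`, `ci_high`, `se`, `p`, `p_adj`, `n`.
#' @export
run_association_suite <- function(pheno, prs, pcs = NULL) {
  outcomes <- c("onset_age", "progression_age", "time_to_progression")
  pc_names <- if (is.null(pcs)) character(0) else colnames(pcs)
  rows <- list()
  for (oc in outcomes) {
    rec <- build_survival_records(pheno, prs, pcs, outcome = oc)
    for (st in c("all", "F", "M")) {
      r <- if (st == "all") rec else rec[rec$sex == st, , drop = FALSE]
      covs <- if (st == "all") c("z", "sex", pc_names) else c("z", pc_names)
      covs <- intersect(covs, names(r))
      if (st == "all" && length(unique(r$sex)) < 2L)
        covs <- setdiff(covs, "sex")
      res <- tryCatch(fit_cox(r, covariates = covs, term = "z"),
                      error = function(e) {
                        warning(sprintf("suite fit %s/%s failed: %s", oc, st,
                                        conditionMessage(e)))
                        NULL
                      })
      rows[[length(rows) + 1L]] <- cox_row(res, oc, st)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  class(out) <- c("cox_suite", "data.frame")
  out
}

#' Per-decile membership association tests
#'
#' For each tested decile (restricted to 5-10: lower deciles hold too few
#' cases) and each outcome, fits a Cox model on a decile-membership
#' indicator, adjusting for sex and the principal components.
#' Benjamini-Hochberg correction is applied within this family. Deciles
#' with no cases are skipped.
#'
#' @param pheno,prs,pcs As in [build_survival_records()].
#' @param decile Integer decile per participant, aligned with `prs`
#'   (e.g. from [assign_deciles()] on the z-scores).
#' @param deciles Deciles to test; must lie within 5..10.
#' @return A `cox_suite` data frame with `stratum` = `"decile <d>"`.
#' @export
run_decile_tests <- function(pheno, prs, decile, pcs = NULL,
                             deciles = 5:10) {
  if (any(!deciles %in% 5:10))
    stop("invalid input: only deciles 5-10 are tested")
  if (length(decile) != nrow(prs))
    stop("decile must align with the prs table")
  outcomes <- c("onset_age", "progression_age", "time_to_progression")
  pc_names <- if (is.null(pcs)) character(0) else colnames(pcs)
  rows <- list()
  for (oc in outcomes) {
    rec <- build_survival_records(pheno, prs, pcs, outcome = oc)
    d_rec <- decile[match(rec$participant_id, prs$participant_id)]
    for (dd in deciles) {
      if (!any(d_rec == dd)) next  # no cases in this decile
      r <- rec
      r$in_decile <- as.integer(d_rec == dd)
      covs <- c("in_decile", if (length(unique(r$sex)) > 1L) "sex", pc_names)
      res <- tryCatch(fit_cox(r, covariates = covs, term = "in_decile"),
                      error = function(e) NULL)
      rows[[length(rows) + 1L]] <- cox_row(res, oc,
                                           paste("decile", dd))
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- cox_row(NULL, character(0), character(0))[0L, ]
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  class(out) <- c("cox_suite", "data.frame")
  out
}

#' Variance inflation factors of a covariate matrix
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing each column on the others;
#' `Inf` flags perfect collinearity.
#'
#' @param X Numeric matrix (columns = covariates, >= 2 columns).
#' @return Named numeric vector of VIFs.
#' @export
compute_vif <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) return(stats::setNames(rep(1, ncol(X)), colnames(X)))
  v <- vapply(seq_len(ncol(X)), function(j) {
    r2 <- suppressWarnings(
      summary(stats::lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1L))
  stats::setNames(v, colnames(X))
}

#' Diagnostics for a fitted Cox association
#'
#' Proportional-hazards check via the scaled-Schoenfeld-residual trend test
#' ([survival::cox.zph()]), variance inflation factors of the covariates,
#' and a linearity check regressing martingale residuals on each continuous
#' covariate. Unavailable (flagged) with fewer than 3 events.
#'
#' @param result A `cox_result` from [fit_cox()].
#' @return A list of class `cox_diagnostics`: `available`, `ph`
#'   (`data.frame` covariate/p), `vif`, `linearity` (`data.frame`
#'   covariate/slope/p).
#' @export
check_model_assumptions <- function(result) {
  if (!inherits(result, "cox_result")) stop("result must be a cox_result")
  fit <- result$fit
  if (result$n_events < 3L)
    return(structure(list(available = FALSE,
                          reason = "fewer than 3 events"),
                     class = "cox_diagnostics"))
  zp <- survival::cox.zph(fit)
  tab <- zp$table
  ph <- data.frame(covariate = rownames(tab)[rownames(tab) != "GLOBAL"],
                   p = tab[rownames(tab) != "GLOBAL", "p"],
                   stringsAsFactors = FALSE)
  rownames(ph) <- NULL
  X <- fit$x
  vif <- compute_vif(X)
  mr <- stats::residuals(fit, type = "martingale")
  cont <- colnames(X)[apply(X, 2L, function(x) length(unique(x)) > 2L)]
  lin <- do.call(rbind, lapply(cont, function(cv) {
    sm <- summary(stats::lm(mr ~ X[, cv]))$coefficients
    data.frame(covariate = cv, slope = sm[2L, 1L], p = sm[2L, 4L],
               stringsAsFactors = FALSE)
  }))
  structure(list(available = TRUE, ph = ph, vif = vif,
                 linearity = if (is.null(lin))
                   data.frame(covariate = character(0), slope = numeric(0),
                              p = numeric(0))
                 else lin),
            class = "cox_diagnostics")
}

#' @export
print.cox_diagnostics <- function(x, ...) {
  if (!x$available) {
    cat("Cox diagnostics unavailable:", x$reason, "\n")
    return(invisible(x))
  }
  cat("Proportional-hazards (scaled Schoenfeld) p-values:\n")
  print(x$ph, row.names = FALSE)
  cat("Variance inflation factors:\n")
  print(round(x$vif, 2))
  invisible(x)
}
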
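# Pipeline driver: simulate (optional) -> QC -> PRS -> lifetime risk ->
# associations, with every stage writing its artifact plus a JSON
# provenance record. Reruns with an identical configuration are
# reproducible: all randomness derives from the configured seed.

#' Pipeline configuration
#'
#' Validates and bundles the settings of [run_pipeline()]. When
#' `genotypes_path` is `NULL` the pipeline simulates its inputs from `sim`
#' (a [sim_config()], defaulting to the study conditions with this
#' configuration's seed); otherwise the weights/genotypes/phenotypes paths
#' must all exist.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer root seed for all pipeline randomness.
#' @param weights_path,genotypes_path,phenotypes_path Input files, or
#'   `NULL` to simulate.
#' @param genotypes_format `"vcf"` or `"dosage_tsv"`.
#' @param sample_call_rate,variant_call_rate,hwe_alpha,ibd_threshold QC
#'   thresholds (defaults 0.99, 0.99, 1e-6, 0.2).
#' @param lifetime_risk_f,lifetime_risk_m Cohort lifetime risks per 100,000
#'   (defaults 282 and 100).
#' @param pooled_low,pooled_high Decile ranges pooled in the risk table.
#' @param inject_artifacts Plant QC artifacts in the simulated cohort so
#'   the QC stage has work to do.
#' @param sim Optional [sim_config()] overriding the default simulation.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            weights_path = NULL, genotypes_path = NULL,
                            phenotypes_path = NULL,
                            genotypes_format = c("vcf", "dosage_tsv"),
                            sample_call_rate = 0.99,
                            variant_call_rate = 0.99,
                            hwe_alpha = 1e-6, ibd_threshold = 0.2,
                            ibd_min_variants = 500L,
                            lifetime_risk_f = 282, lifetime_risk_m = 100,
                            pooled_low = 1:3, pooled_high = 10L,
                            inject_artifacts = FALSE, sim = NULL) {
  genotypes_format <- match.arg(genotypes_format)
  thr <- c(sample_call_rate, variant_call_rate, hwe_alpha)
  if (any(!is.finite(thr)) || any(thr < 0 | thr > 1))
    stop("validation error: call-rate and HWE thresholds must lie in [0, 1]")
  if (!is.finite(ibd_threshold) || ibd_threshold < 0)
    stop("validation error: ibd_threshold must be >= 0")
  simulate <- is.null(genotypes_path)
  if (!simulate) {
    paths <- c(weights = weights_path, genotypes = genotypes_path,
               phenotypes = phenotypes_path)
    if (length(paths) < 3L || !all(file.exists(paths)))
      stop("validation error: weights, genotypes and phenotypes paths must ",
           "all exist when genotypes are supplied")
  }
  if (is.null(sim)) sim <- sim_config(seed = seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 weights_path = weights_path,
                 genotypes_path = genotypes_path,
                 phenotypes_path = phenotypes_path,
                 genotypes_format = genotypes_format,
                 sample_call_rate = sample_call_rate,
                 variant_call_rate = variant_call_rate,
                 hwe_alpha = hwe_alpha, ibd_threshold = ibd_threshold,
                 ibd_min_variants = as.integer(ibd_min_variants),
                 lifetime_risk_f = lifetime_risk_f,
                 lifetime_risk_m = lifetime_risk_m,
                 pooled_low = pooled_low, pooled_high = pooled_high,
                 inject_artifacts = isTRUE(inject_artifacts),
                 simulate = simulate, sim = sim),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; an optional
#' `sim` mapping is passed to [sim_config()]. Arguments supplied in `...`
#' override file values.
#'
#' @param path YAML file.
#' @param ... Overrides.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path, ...) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) y$sim <- do.call(sim_config, y$sim)
  y <- utils::modifyList(y, list(...))
  unknown <- setdiff(names(y), names(formals(pipeline_config)))
  if (length(unknown))
    stop("validation error: unknown configuration key(s): ",
         paste(unknown, collapse = ", "))
  do.call(pipeline_config, y)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full PRS lifetime-risk pipeline
#'
#' Stages: (1) simulate or load weights/genotypes/phenotypes; (2) genotype
#' QC ([apply_qc()]); (3) harmonization, scoring and control-based
#' standardization ([harmonize()], [compute_prs()], [standardize_prs()]);
#' (4) the decile lifetime-risk fit ([fit_decile_risk()]) with cumulative
#' risk-by-age curves; (5) the Cox association suite and per-decile tests.
#' Each stage writes its artifact under `config$out_dir`; a failing stage
#' halts the pipeline with the stage named, retaining earlier outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of class `prs_pipeline` with the per-stage
#'   objects (`panel`, `pheno`, `qc`, `prs`, `risk_fit`, `associations`,
#'   `decile_tests`, `paths`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stop("validation error: config must be a pipeline_config")
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  # stage 1: inputs
  inputs <- run_stage("simulate", {
    if (config$simulate) {
      panel <- generate_variant_panel(config$sim)
      cohort <- simulate_cohort(config$sim, panel)
      G <- cohort$genotypes; pheno <- cohort$pheno
      expected <- NULL
      if (config$inject_artifacts) {
        inj <- inject_qc_artifacts(G, pheno, seed = config$seed + 2L)
        G <- inj$genotypes; pheno <- inj$pheno
        expected <- inj$expected_exclusions
      }
      paths$weights <- file.path(out, "weights.tsv")
      paths$genotypes <- file.path(out, "genotypes.vcf")
      paths$phenotypes <- file.path(out, "phenotypes.csv")
      write_weights(panel, paths$weights)
      write_genotypes_vcf(G, panel, paths$genotypes)
      write_phenotypes(pheno, paths$phenotypes)
      list(panel = panel, G = G, pheno = pheno,
           meta = panel_variant_meta(panel), expected = expected)
    } else {
      panel <- read_weights(config$weights_path)
      geno <- read_genotypes(config$genotypes_path,
                             format = config$genotypes_format)
      pheno <- read_phenotypes(config$phenotypes_path)
      list(panel = panel, G = geno$genotypes, pheno = pheno,
           meta = geno$variant_meta, expected = NULL)
    }
  })

  # stage 2: genotype QC
  qc <- run_stage("qc", {
    ctrl_ids <- inputs$pheno$participant_id[inputs$pheno$status == "control"]
    res <- apply_qc(inputs$G, sample_thresh = config$sample_call_rate,
                    variant_thresh = config$variant_call_rate,
                    hwe_alpha = config$hwe_alpha,
                    ibd_thresh = config$ibd_threshold,
                    ibd_min_variants = config$ibd_min_variants,
                    control_ids = ctrl_ids)
    rep <- res$report
    excl <- rbind(
      if (nrow(rep$excluded_samples))
        cbind(type = "sample", rep$excluded_samples) else NULL,
      if (nrow(rep$excluded_variants))
        cbind(type = "variant", rep$excluded_variants) else NULL)
    paths$qc_report <- file.path(out, "qc_report.tsv")
    utils::write.table(
      if (is.null(excl)) data.frame(type = character(0), id = character(0),
                                    reason = character(0)) else excl,
      paths$qc_report, sep = "\t", quote = FALSE, row.names = FALSE)
    paths$qc_summary <- file.path(out, "qc_summary.json")
    jsonlite::write_json(
      list(thresholds = rep$thresholds,
           n_samples_retained = nrow(res$genotypes),
           n_variants_retained = ncol(res$genotypes),
           n_samples_excluded = nrow(rep$excluded_samples),
           n_variants_excluded = nrow(rep$excluded_variants)),
      paths$qc_summary, auto_unbox = TRUE, pretty = TRUE)
    res
  })
  Gq <- qc$genotypes
  pheno_q <- inputs$pheno[inputs$pheno$participant_id %in% rownames(Gq), ,
                          drop = FALSE]
  ctrl_q <- pheno_q$participant_id[pheno_q$status == "control"]

  # stage 3: PRS
  prs <- run_stage("prs", {
    h <- harmonize(inputs$panel, Gq, inputs$meta)
    scores <- compute_prs(Gq, h$panel, reference_ids = ctrl_q)
    scores <- standardize_prs(scores, reference_ids = ctrl_q)
    paths$harmonization_log <- file.path(out, "harmonization_log.tsv")
    utils::write.table(h$log, paths$harmonization_log, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths$prs <- file.path(out, "prs.tsv")
    write_prs_table(scores, paths$prs)
    list(scores = scores, harmonization = h)
  })

  # stage 4: lifetime risk
  risk <- run_stage("lifetime_risk", {
    idx <- match(pheno_q$participant_id, prs$scores$participant_id)
    fit <- fit_decile_risk(
      z = prs$scores$z_score[idx], sex = pheno_q$sex,
      status = pheno_q$status, onset = pheno_q$age_onset,
      lifetime_risk = c(F = config$lifetime_risk_f,
                        M = config$lifetime_risk_m),
      pooled = stats::setNames(
        list(config$pooled_low, config$pooled_high),
        c(paste0("deciles ", min(config$pooled_low), "-",
                 max(config$pooled_low)),
          paste0("deciles ", min(config$pooled_high), "-",
                 max(config$pooled_high)))))
    paths$decile_risk <- file.path(out, "decile_risk.tsv")
    utils::write.table(fit$table, paths$decile_risk, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths$decile_risk_json <- file.path(out, "decile_risk.json")
    jsonlite::write_json(list(table = fit$table, pooled = fit$pooled,
                              boundaries = fit$boundaries),
                         paths$decile_risk_json, pretty = TRUE,
                         digits = NA)
    # long-format cumulative risk curves, one group per decile per sex
    # (fit$decile is aligned with the rows of pheno_q)
    curves <- do.call(rbind, lapply(c("F", "M"), function(s) {
      tab <- fit$table[fit$table$sex == s, ]
      do.call(rbind, lapply(1:10, function(dd) {
        ages <- pheno_q$age_onset[pheno_q$status == "MS" &
                                    pheno_q$sex == s & fit$decile == dd]
        ages <- ages[!is.na(ages)]
        cv <- cumulative_risk_curve(ages, tab$risk_per_100k[dd],
                                    age_grid = 0:60)
        cbind(sex = s, decile = dd, cv)
      }))
    }))
    paths$risk_curves <- file.path(out, "risk_curves.tsv")
    utils::write.table(curves, paths$risk_curves, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    fit
  })

  # stage 5: associations
  assoc <- run_stage("associate", {
    pcs <- compute_pcs(Gq, k = 5L)
    suite <- run_association_suite(pheno_q, prs$scores, pcs)
    # risk$decile is aligned with pheno_q; reorder to the prs table
    dec <- risk$decile[match(prs$scores$participant_id,
                             pheno_q$participant_id)]
    dec_tests <- run_decile_tests(pheno_q, prs$scores, decile = dec,
                                  pcs = pcs)
    paths$associations <- file.path(out, "associations.tsv")
    utils::write.table(suite, paths$associations, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths$decile_associations <- file.path(out, "decile_associations.tsv")
    utils::write.table(dec_tests, paths$decile_associations, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(suite = suite, decile_tests = dec_tests, pcs = pcs)
  })

  paths$provenance <- file.path(out, "provenance.json")
  jsonlite::write_json(
    list(package = "msprisk",
         version = as.character(utils::packageVersion("msprisk")),
         seed = config$seed,
         thresholds = list(sample_call_rate = config$sample_call_rate,
                           variant_call_rate = config$variant_call_rate,
                           hwe_alpha = config$hwe_alpha,
                           ibd_threshold = config$ibd_threshold),
         lifetime_risk = list(F = config$lifetime_risk_f,
                              M = config$lifetime_risk_m),
         simulated = config$simulate,
         n_samples = nrow(inputs$G), n_variants = ncol(inputs$G)),
    paths$provenance, auto_unbox = TRUE, pretty = TRUE)

  structure(list(panel = inputs$panel, pheno = inputs$pheno,
                 expected_exclusions = inputs$expected, qc = qc,
                 prs = prs$scores, harmonization = prs$harmonization,
                 risk_fit = risk, associations = assoc$suite,
                 decile_tests = assoc$decile_tests, pcs = assoc$pcs,
                 paths = paths, config = config),
            class = "prs_pipeline")
}

#' @export
print.prs_pipeline <- function(x, ...) {
  cat("msprisk pipeline run (seed", x$config$seed, ")\n")
  cat(sprintf("  input: %d participants, %d panel variants\n",
              nrow(x$pheno), nrow(x$panel)))
  cat(sprintf("  post-QC: %d samples x %d variants\n",
              nrow(x$qc$genotypes), ncol(x$qc$genotypes)))
  cat("  decile risk fit:\n")
  print(x$risk_fit)
  invisible(x)
}
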
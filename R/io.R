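# Readers and writers for the pipeline's file formats: GWAS weights TSV,
# genotypes as VCF (via vcfR) or dosage TSV, phenotype CSV, and JSON
# summaries. The canonical variant key everywhere is chrom:pos:ref:alt with
# 1-based positions.

weights_columns <- c("variant_id", "chrom", "pos", "effect_allele",
                     "other_allele", "OR", "eaf")

#' Read a GWAS weights table
#'
#' Tab-separated with a header; required columns `variant_id`, `chrom`,
#' `pos`, `effect_allele`, `other_allele`, `OR`, `eaf`. The odds ratio is
#' converted to a log-OR weight. Rows with a nonpositive OR, identical or
#' non-ACGT alleles, or an allele frequency outside (0, 1) are rejected with
#' a message.
#'
#' @param path File path.
#' @return A `variant_panel` data frame (see [generate_variant_panel()]).
#' @export
read_weights <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(weights_columns, names(tab))
  if (length(missing_cols))
    stop("weights file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  ok_allele <- function(a) a %in% c("A", "C", "G", "T")
  bad <- !is.finite(tab$OR) | tab$OR <= 0 |
    !ok_allele(tab$effect_allele) | !ok_allele(tab$other_allele) |
    tab$effect_allele == tab$other_allele |
    !is.finite(tab$eaf) | tab$eaf <= 0 | tab$eaf >= 1
  if (any(bad)) {
    message(sum(bad), " weight row(s) rejected (nonpositive OR, invalid ",
            "alleles, or out-of-range frequency)")
    tab <- tab[!bad, , drop = FALSE]
  }
  panel <- data.frame(variant_id = as.character(tab$variant_id),
                      chrom = tab$chrom, pos = as.integer(tab$pos),
                      effect_allele = tab$effect_allele,
                      other_allele = tab$other_allele,
                      odds_ratio = tab$OR, weight = log(tab$OR),
                      eaf = tab$eaf, stringsAsFactors = FALSE)
  rownames(panel) <- NULL
  class(panel) <- c("variant_panel", "data.frame")
  panel
}

#' Write a GWAS weights table
#'
#' @param panel A `variant_panel`.
#' @param path Output path (TSV).
#' @export
write_weights <- function(panel, path) {
  out <- data.frame(variant_id = panel$variant_id, chrom = panel$chrom,
                    pos = panel$pos, effect_allele = panel$effect_allele,
                    other_allele = panel$other_allele,
                    OR = panel$odds_ratio, eaf = panel$eaf)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

panel_variant_meta <- function(panel) {
  data.frame(variant_id = panel$variant_id, chrom = panel$chrom,
             pos = panel$pos, ref = panel$other_allele,
             alt = panel$effect_allele, stringsAsFactors = FALSE)
}

#' Write hard-call genotypes as VCF
#'
#' One biallelic record per variant with a GT field; REF is the other
#' allele and ALT the (counted) effect allele, so dosages count ALT copies.
#'
#' @param G Samples x variants dosage matrix (hard calls; `NA` becomes
#'   `./.`).
#' @param meta A `variant_panel` or a `data.frame` with `variant_id`,
#'   `chrom`, `pos`, `ref`, `alt`, in the column order of `G`.
#' @param path Output path (plain-text `.vcf`).
#' @export
write_genotypes_vcf <- function(G, meta, path) {
  if (inherits(meta, "variant_panel")) meta <- panel_variant_meta(meta)
  if (!identical(meta$variant_id, colnames(G)))
    meta <- meta[match(colnames(G), meta$variant_id), , drop = FALSE]
  if (anyNA(meta$variant_id))
    stop("meta does not cover all genotyped variants")
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = ncol(G), ncol = nrow(G))
  hard <- round(t(G))
  ok <- !is.na(hard)
  gt[ok] <- gt_code[hard[ok] + 1L]
  header <- c("##fileformat=VCFv4.2",
              paste0("##contig=<ID=", sort(unique(meta$chrom)), ">"),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(G)), collapse = "\t"))
  body <- paste(meta$chrom, meta$pos, meta$variant_id, meta$ref, meta$alt,
                ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotypes from VCF or dosage TSV
#'
#' VCF is parsed with `vcfR`; the DS (dosage) FORMAT field is preferred when
#' present, otherwise GT is converted to effect-allele (ALT) dosage in
#' \{0, 1, 2\} with `./.` as missing. The dosage TSV dialect has variants in
#' rows (first column `variant_id` as `chrom:pos:ref:alt`) and participants
#' in columns.
#'
#' @param path File path.
#' @param format `"vcf"` or `"dosage_tsv"`.
#' @return A list with `genotypes` (samples x variants matrix) and
#'   `variant_meta` (`variant_id`, `chrom`, `pos`, `ref`, `alt`).
#' @export
read_genotypes <- function(path, format = c("vcf", "dosage_tsv")) {
  format <- match.arg(format)
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    meta <- data.frame(
      variant_id = paste(fix$CHROM, fix$POS, fix$REF, fix$ALT, sep = ":"),
      chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
      alt = fix$ALT, stringsAsFactors = FALSE)
    fmt <- v@gt[, "FORMAT"]
    if (any(vapply(strsplit(fmt, ":"), function(f) "DS" %in% f, TRUE))) {
      d <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
    } else {
      gt <- vcfR::extract.gt(v, element = "GT")
      code <- c("0/0" = 0, "0|0" = 0, "0/1" = 1, "1/0" = 1, "0|1" = 1,
                "1|0" = 1, "1/1" = 2, "1|1" = 2)
      d <- matrix(NA_real_, nrow = nrow(gt), ncol = ncol(gt),
                  dimnames = dimnames(gt))
      known <- !is.na(gt) & gt %in% names(code)
      d[known] <- code[gt[known]]
      bad <- !is.na(gt) & !gt %in% c(names(code), "./.", ".|.", ".")
      if (any(bad)) {
        w <- which(bad, arr.ind = TRUE)[1L, ]
        stop(sprintf("parse error: unrecognized GT '%s' at record %d",
                     gt[bad][1L], w[1L]))
      }
    }
    G <- t(d)
    colnames(G) <- meta$variant_id
    list(genotypes = G, variant_meta = meta)
  } else {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (names(tab)[1L] != "variant_id")
      stop("parse error: dosage TSV must start with a variant_id column")
    ids <- tab$variant_id
    G <- t(as.matrix(tab[, -1L, drop = FALSE]))
    colnames(G) <- ids
    parts <- strsplit(ids, ":", fixed = TRUE)
    if (any(lengths(parts) != 4L))
      stop("parse error: variant_id must be chrom:pos:ref:alt")
    meta <- data.frame(variant_id = ids,
                       chrom = vapply(parts, `[`, "", 1L),
                       pos = as.integer(vapply(parts, `[`, "", 2L)),
                       ref = vapply(parts, `[`, "", 3L),
                       alt = vapply(parts, `[`, "", 4L),
                       stringsAsFactors = FALSE)
    list(genotypes = G, variant_meta = meta)
  }
}

#' Write genotypes as a dosage TSV (variants in rows)
#'
#' @param G Samples x variants dosage matrix.
#' @param path Output path.
#' @export
write_dosage_tsv <- function(G, path) {
  out <- data.frame(variant_id = colnames(G), t(G), check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a phenotype table (CSV)
#'
#' Columns: `participant_id`, `sex`, `status`, `subtype`, `age_onset`,
#' `age_progression`, `age_visit`.
#'
#' @param path File path.
#' @return For the reader, the phenotype `data.frame`.
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(participant_id = "character"))
  need <- c("participant_id", "sex", "status", "subtype", "age_onset",
            "age_progression", "age_visit")
  missing_cols <- setdiff(need, names(ph))
  if (length(missing_cols))
    stop("phenotype file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  ph
}

#' @rdname read_phenotypes
#' @param pheno Phenotype `data.frame` to write.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.csv(pheno, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write a PRS table (TSV)
#'
#' @param prs `data.frame` with `participant_id`, `raw_score`, `z_score`.
#' @param path Output path.
#' @export
write_prs_table <- function(prs, path) {
  utils::write.table(prs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_prs_table
#' @export
read_prs_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(participant_id = "character"))
}
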
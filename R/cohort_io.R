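#' @title Cohort input/output
#' @description Readers and writers for the interchange formats of the
#'   analysis: a VCF 4.x genotype file, an ANNOVAR-style annotation TSV, a
#'   sample metadata TSV, and the findings / burden-result / ROH output
#'   tables. Coordinates are 1-based hg19 labels passed through verbatim.
#' @name cohort-io
NULL

PREDICTOR_COLS <- c("sift", "lrt", "mutation_assessor", "polyphen2_hvar",
                    "polyphen2_hdiv", "mutation_taster")
SUBGROUP_LEVELS <- c("sEOPD", "sLOPD", "FPD_AR", "FPD_AD",
                     "control1", "control2")

.parse_missing <- function(x) {
  x[x %in% c("NA", ".", "")] <- NA_character_
  x
}

.num_or_na <- function(x) suppressWarnings(as.numeric(.parse_missing(x)))

#' Read the sample metadata table
#'
#' Expects a TSV with columns `sample_id`, `status` (case/control),
#' `subgroup` (sEOPD, sLOPD, FPD_AR, FPD_AD, control1, control2), `age`,
#' `sex` (male/female), and `pc1`..`pc5`. `NA`, `.` and empty strings parse
#' as missing.
#'
#' @param path TSV path.
#' @return data.frame with typed columns.
#' @export
read_samples <- function(path) {
  df <- utils::read.delim(path, sep = "\t", colClasses = "character",
                          quote = "")
  needed <- c("sample_id", "status", "subgroup", "age", "sex",
              paste0("pc", 1:5))
  miss <- setdiff(needed, names(df))
  if (length(miss) > 0L) {
    stop("sample table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(
    sample_id = trimws(df$sample_id),
    status = df$status,
    subgroup = df$subgroup,
    age = .num_or_na(df$age),
    sex = ifelse(is.na(.parse_missing(df$sex)), NA_character_, df$sex),
    stringsAsFactors = FALSE
  )
  for (p in paste0("pc", 1:5)) out[[p]] <- .num_or_na(df[[p]])
  if (any(duplicated(out$sample_id))) {
    stop("duplicate sample_id in sample table", call. = FALSE)
  }
  if (!all(out$status %in% c("case", "control"))) {
    stop("status must be 'case' or 'control'", call. = FALSE)
  }
  if (!all(out$subgroup %in% SUBGROUP_LEVELS)) {
    stop("unknown subgroup label(s): ",
         paste(setdiff(unique(out$subgroup), SUBGROUP_LEVELS), collapse = ", "),
         call. = FALSE)
  }
  ctrl <- out$subgroup %in% c("control1", "control2")
  if (any(ctrl & out$status != "control") ||
      any(!ctrl & out$status != "case")) {
    stop("status inconsistent with subgroup (control1/control2 must be ",
         "controls; all other subgroups cases)", call. = FALSE)
  }
  out
}

.parse_gt_dosage <- function(gt, alt_index) {
  # gt: character vector of GT fields; returns dosage of allele `alt_index`
  gt <- sub(":.*$", "", gt)
  gt[gt %in% c(".", "./.", ".|.")] <- NA_character_
  sep <- grepl("[/|]", gt)
  if (any(!is.na(gt) & !sep)) {
    stop("haploid or malformed GT encountered (autosomal diploid data ",
         "required): '", gt[which(!is.na(gt) & !sep)[1]], "'", call. = FALSE)
  }
  alleles <- strsplit(gt, "[/|]")
  vapply(alleles, function(a) {
    if (length(a) == 0L || any(is.na(a))) return(NA_real_)
    if (any(a == ".")) return(NA_real_)
    ai <- suppressWarnings(as.integer(a))
    if (any(is.na(ai)) || length(ai) != 2L) {
      stop("malformed GT field", call. = FALSE)
    }
    sum(ai == alt_index)
  }, numeric(1))
}

#' Read cohort genotypes from a VCF
#'
#' Loads a VCF 4.x file, splits multi-allelic sites into biallelic records
#' (one record per alternate allele, genotype recoded as the dosage of that
#' allele, phase ignored), and joins the sample metadata table. Missing
#' genotypes become missing dosages. Sample order follows the sample table.
#'
#' @param vcf_path Path to a VCF (optionally bgzipped).
#' @param samples Path to the sample TSV, or a data.frame from
#'   [read_samples()].
#' @return A `cohort_data` list with elements `samples` (data.frame),
#'   `variants` (data.frame: chrom, pos, ref, alt, variant_id),
#'   `dosages` (samples x variants numeric matrix with entries 0/1/2/NA), and
#'   `annotations` (`NULL` until [annotate_cohort()] is called).
#' @export
read_cohort_vcf <- function(vcf_path, samples) {
  if (!file.exists(vcf_path)) stop("VCF not found: ", vcf_path, call. = FALSE)
  smp <- if (is.data.frame(samples)) samples else read_samples(samples)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt_raw <- vcfR::extract.gt(vcf, element = "GT", return.alleles = FALSE)
  if (is.null(dim(gt_raw))) {
    gt_raw <- matrix(gt_raw, nrow = nrow(fix),
                     dimnames = list(NULL, colnames(vcf@gt)[-1]))
  }
  vcf_samples <- colnames(gt_raw)
  unknown <- setdiff(vcf_samples, smp$sample_id)
  if (length(unknown) > 0L) {
    stop("VCF sample(s) absent from sample table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  keep <- smp$sample_id %in% vcf_samples
  if (!all(keep)) {
    message(sum(!keep), " sample(s) in the sample table have no genotypes; ",
            "dropped")
    smp <- smp[keep, , drop = FALSE]
  }
  gt_raw <- gt_raw[, smp$sample_id, drop = FALSE]

  var_list <- list()
  dos_list <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    for (k in seq_along(alts)) {
      alt <- alts[k]
      dos <- tryCatch(.parse_gt_dosage(gt_raw[i, ], k),
                      error = function(e) {
                        stop(sprintf("%s at %s:%s", conditionMessage(e),
                                     fix[i, "CHROM"], fix[i, "POS"]),
                             call. = FALSE)
                      })
      var_list[[length(var_list) + 1L]] <- data.frame(
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"], alt = alt, stringsAsFactors = FALSE)
      dos_list[[length(dos_list) + 1L]] <- dos
    }
  }
  variants <- do.call(rbind, var_list)
  variants$variant_id <- paste(variants$chrom, variants$pos,
                               variants$ref, variants$alt, sep = ":")
  dosages <- do.call(cbind, dos_list)
  dimnames(dosages) <- list(smp$sample_id, variants$variant_id)

  structure(list(samples = smp, variants = variants,
                 dosages = dosages, annotations = NULL),
            class = "cohort_data")
}

#' Read a variant annotation table
#'
#' Parses an ANNOVAR-style TSV with one row per biallelic variant. Required
#' columns: `chrom`, `pos`, `ref`, `alt`, `gene`, `exonic_function`,
#' `splice_offset`, `maf_exome_eas`, `maf_genome_eas`, `reve`, `cadd`, and the
#' six categorical predictor columns `sift`, `lrt`, `mutation_assessor`,
#' `polyphen2_hvar`, `polyphen2_hdiv`, `mutation_taster` (tokens `D` =
#' damaging, `T` = tolerated; `NA`/`.`/empty = missing). CADD enters the
#' seven-predictor support count through its numeric score (damaging at a
#' configurable phred cutoff), so it has no categorical column.
#'
#' @param path TSV path.
#' @return data.frame keyed by `variant_id` (`chrom:pos:ref:alt`), one row per
#'   variant; frequency and score columns numeric with `NA` for missing.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, sep = "\t", colClasses = "character",
                          quote = "")
  needed <- c("chrom", "pos", "ref", "alt", "gene", "exonic_function",
              "splice_offset", "maf_exome_eas", "maf_genome_eas", "reve",
              "cadd", PREDICTOR_COLS)
  miss <- setdiff(needed, names(df))
  if (length(miss) > 0L) {
    stop("annotation table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(
    variant_id = paste(df$chrom, df$pos, df$ref, df$alt, sep = ":"),
    chrom = df$chrom, pos = as.integer(df$pos), ref = df$ref, alt = df$alt,
    gene = trimws(df$gene),
    exonic_function = df$exonic_function,
    splice_offset = suppressWarnings(as.integer(.parse_missing(df$splice_offset))),
    maf_exome_eas = .num_or_na(df$maf_exome_eas),
    maf_genome_eas = .num_or_na(df$maf_genome_eas),
    reve = .num_or_na(df$reve),
    cadd = .num_or_na(df$cadd),
    stringsAsFactors = FALSE
  )
  for (p in PREDICTOR_COLS) {
    calls <- .parse_missing(df[[p]])
    bad <- calls[!is.na(calls) & !calls %in% c("D", "T")]
    if (length(bad) > 0L) {
      stop("predictor column '", p, "' has token(s) other than D/T/missing: ",
           paste(unique(bad), collapse = ", "), call. = FALSE)
    }
    out[[p]] <- calls
  }
  dup <- out$variant_id[duplicated(out$variant_id)]
  if (length(dup) > 0L) {
    stop("duplicate variant key(s) in annotation table: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  for (col in c("maf_exome_eas", "maf_genome_eas", "reve")) {
    v <- out[[col]]
    if (any(!is.na(v) & (v < 0 | v > 1))) {
      stop(col, " outside [0,1] for variant ",
           out$variant_id[which(!is.na(v) & (v < 0 | v > 1))[1]],
           call. = FALSE)
    }
  }
  if (any(!is.na(out$cadd) & out$cadd < 0)) {
    stop("negative CADD score in annotation table", call. = FALSE)
  }
  out
}

#' Attach (and classify) annotations on a cohort
#'
#' Joins an annotation table to the cohort's variants and runs
#' [classify_variants()]. Variants that are carried by at least one sample but
#' lack an annotation row are excluded from the cohort with a message; they
#' never reach prioritization or burden testing.
#'
#' @param cohort A `cohort_data` from [read_cohort_vcf()].
#' @param annotations data.frame from [read_annotations()].
#' @return The cohort with `annotations` set (classified, aligned to
#'   `variants`) and unannotated carried variants dropped.
#' @export
annotate_cohort <- function(cohort, annotations) {
  stopifnot(inherits(cohort, "cohort_data"))
  if (is.null(annotations$variant_id)) {
    annotations$variant_id <- paste(annotations$chrom, annotations$pos,
                                    annotations$ref, annotations$alt,
                                    sep = ":")
  }
  idx <- match(cohort$variants$variant_id, annotations$variant_id)
  unann <- is.na(idx)
  if (any(unann)) {
    carried <- colSums(cohort$dosages[, unann, drop = FALSE], na.rm = TRUE) > 0
    message(sum(unann), " variant(s) lack annotation (",
            sum(carried), " carried); excluded from analysis: ",
            paste(utils::head(cohort$variants$variant_id[unann], 5),
                  collapse = ", "))
    cohort$variants <- cohort$variants[!unann, , drop = FALSE]
    cohort$dosages <- cohort$dosages[, !unann, drop = FALSE]
    idx <- idx[!unann]
  }
  ann <- annotations[idx, , drop = FALSE]
  rownames(ann) <- NULL
  cohort$annotations <- classify_variants(ann)
  cohort
}

#' @export
print.cohort_data <- function(x, ...) {
  cat(sprintf("<cohort_data: %d samples (%d cases, %d controls), %d variants%s>\n",
              nrow(x$samples), sum(x$samples$status == "case"),
              sum(x$samples$status == "control"), nrow(x$variants),
              if (is.null(x$annotations)) ", unannotated" else ", annotated"))
  invisible(x)
}

.fmt_out <- function(x) {
  out <- as.character(x)
  ifelse(is.na(out) | out == "", ".", out)
}

#' Write candidate findings to TSV
#'
#' One row per finding; for compound-heterozygous findings the per-variant
#' fields are `;`-joined in variant order. Rows are ordered by (gene,
#' sample_id, first variant position) for deterministic output. Missing
#' values are written as `.`.
#'
#' @param findings data.frame of findings (see [ar_candidates()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_findings <- function(findings, path) {
  cols <- c("sample_id", "gene", "model", "variant_ids", "zygosity",
            "effective_maf", "cadd", "reve", "predictor_support",
            "acmg", "screened_out", "screen_reason")
  if (nrow(findings) > 0L) {
    ord <- order(findings$gene, findings$sample_id, findings$pos_min)
    out <- findings[ord, , drop = FALSE]
    df <- data.frame(lapply(cols, function(cl) .fmt_out(out[[cl]])),
                     stringsAsFactors = FALSE)
    names(df) <- cols
  } else {
    df <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)),
                                        cols))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read back a findings TSV written by [write_findings()]
#' @param path TSV path.
#' @return data.frame with the written columns (multi-valued fields still
#'   `;`-joined strings).
#' @export
read_findings <- function(path) {
  df <- utils::read.delim(path, sep = "\t", colClasses = "character",
                          quote = "")
  df$screened_out <- df$screened_out == "TRUE"
  df
}

#' Write burden-scan results to TSV
#'
#' Columns mirror the scan's result fields: gene, cohort, patient subgroup,
#' variant subgroup (class and MAF threshold), number of variants in the
#' cell, case and control carrier counts, SKAT-O p-value (full precision),
#' and the suggestive / significant flags. Untested cells (zero variants)
#' carry `.` in the numeric columns.
#'
#' @param results data.frame from [run_burden_scan()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_burden_table <- function(results, path) {
  cols <- c("gene", "cohort", "patient_subgroup", "variant_subgroup",
            "maf_threshold", "n_variants", "case_carriers",
            "control_carriers", "p_value", "rho_opt",
            "suggestive", "significant", "tested")
  if (nrow(results) > 0L) {
    df <- results[, cols, drop = FALSE]
    df$p_value <- ifelse(is.na(df$p_value), ".",
                         formatC(df$p_value, digits = 17, format = "g"))
    for (cl in cols) df[[cl]] <- .fmt_out(df[[cl]])
  } else {
    df <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)),
                                        cols))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read back a burden TSV written by [write_burden_table()]
#' @param path TSV path.
#' @return data.frame with numeric p-values restored at full precision.
#' @export
read_burden_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", colClasses = "character",
                          quote = "")
  df$p_value <- .num_or_na(df$p_value)
  df$maf_threshold <- .num_or_na(df$maf_threshold)
  df$rho_opt <- .num_or_na(df$rho_opt)
  df$n_variants <- as.integer(df$n_variants)
  df$case_carriers <- suppressWarnings(as.integer(.parse_missing(df$case_carriers)))
  df$control_carriers <- suppressWarnings(as.integer(.parse_missing(df$control_carriers)))
  df$suggestive <- df$suggestive == "TRUE"
  df$significant <- df$significant == "TRUE"
  df$tested <- df$tested == "TRUE"
  df
}

#' Write detected runs of homozygosity to TSV
#' @param intervals data.frame from [detect_roh()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roh_table <- function(intervals, path) {
  cols <- c("sample_id", "chrom", "start", "end", "n_snps", "length_mb")
  if (nrow(intervals) > 0L) {
    df <- intervals[, cols, drop = FALSE]
  } else {
    df <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)),
                                        cols))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
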
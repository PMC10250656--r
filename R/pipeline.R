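#' @title Pipeline orchestration
#' @description Runs the full analysis behind one entry point: read and
#'   annotate the cohort, prioritize candidates under both inheritance
#'   models, screen against controls, classify with the ACMG engine, detect
#'   runs of homozygosity in cases, and run the per-cohort burden scan.
#'   Every stage logs input/output counts; a resolved-config snapshot is
#'   written so a run can be reproduced exactly.
#' @name pipeline
NULL

#' Assemble a validated run configuration
#'
#' @param vcf,annotations,samples Input file paths.
#' @param panel Panel TSV path or `NULL` for the shipped 47-gene panel.
#' @param out_dir Output directory for the run.
#' @param acmg ACMG evidence configuration ([default_acmg_config()]).
#' @param burden Burden-scan configuration ([default_burden_config()]).
#' @param roh ROH parameters ([default_roh_params()]); `NULL` disables the
#'   ROH stage.
#' @param seed Integer seed recorded in the snapshot (the analysis stages
#'   are deterministic; the seed matters for simulation-backed runs).
#' @return A `run_config` list; referenced input paths are checked to exist.
#' @export
run_config <- function(vcf, annotations, samples, panel = NULL,
                       out_dir = tempfile("dytrun"),
                       acmg = default_acmg_config(),
                       burden = default_burden_config(),
                       roh = default_roh_params(), seed = 1L) {
  for (p in c(vcf = vcf, annotations = annotations, samples = samples)) {
    if (!file.exists(p)) {
      stop("input path does not exist: ", p, call. = FALSE)
    }
  }
  if (!is.null(panel) && !file.exists(panel)) {
    stop("panel path does not exist: ", panel, call. = FALSE)
  }
  structure(list(vcf = vcf, annotations = annotations, samples = samples,
                 panel = panel, out_dir = out_dir, acmg = acmg,
                 burden = burden, roh = roh, seed = as.integer(seed)),
            class = "run_config")
}

#' Subset a cohort to named samples
#' @param cohort A `cohort_data`.
#' @param sample_ids Character vector of sample ids to keep.
#' @return The subsetted `cohort_data`.
#' @export
subset_cohort <- function(cohort, sample_ids) {
  keep <- cohort$samples$sample_id %in% sample_ids
  cohort$samples <- cohort$samples[keep, , drop = FALSE]
  cohort$dosages <- cohort$dosages[cohort$samples$sample_id, , drop = FALSE]
  cohort
}

# the matched sporadic case-control pairs scanned by the burden stage
BURDEN_PAIRS <- list(c("sEOPD", "control1"), c("sLOPD", "control2"))

#' Human-readable summary of a burden scan
#'
#' @param results Burden data.frame (from [run_burden_scan()] or
#'   [read_burden_table()]).
#' @return Character vector of report lines listing tested cells and the
#'   suggestive (p < 0.05) and significant hits.
#' @export
burden_report <- function(results) {
  tested <- results[results$tested %in% TRUE, , drop = FALSE]
  lines <- c(sprintf("burden scan: %d cells, %d tested", nrow(results),
                     nrow(tested)))
  hits <- tested[tested$suggestive | tested$significant, , drop = FALSE]
  if (nrow(hits) == 0L) {
    lines <- c(lines, "no suggestive associations (p < 0.05)")
  } else {
    hits <- hits[order(hits$p_value), , drop = FALSE]
    lines <- c(lines, "suggestive associations (p < 0.05):",
               sprintf("  %s %s %s@%g p=%.4g%s", hits$gene,
                       hits$patient_subgroup, hits$variant_subgroup,
                       hits$maf_threshold, hits$p_value,
                       ifelse(hits$significant, " [significant]", "")))
  }
  lines
}

#' Run the full analysis pipeline
#'
#' Stages run in workflow order: variant extraction (VCF + annotations +
#' samples), candidate prioritization under the recessive and dominant
#' models with control screening and ACMG classification,
#' runs-of-homozygosity detection over case samples, and the SKAT-O burden
#' scan for each matched sporadic case-control pair present in the cohort
#' (sEOPD vs control group 1; sLOPD vs control group 2). Outputs
#' `findings.tsv`, `roh.tsv`, `burden.tsv`, `run.log`, and `config.yaml`
#' (all defaults materialized) in the run directory. A stage failure aborts
#' with a stage-named error and leaves a `FAILED` marker.
#'
#' @param config A `run_config`.
#' @return The run directory path, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  logmsg <- function(...) {
    line <- paste0(...)
    writeLines(line, log_con)
    message(line)
  }
  fail <- function(stage, e) {
    writeLines(paste0("FAILED at stage: ", stage),
               file.path(config$out_dir, "FAILED"))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  stage <- function(name, expr) {
    logmsg("[stage ", name, "]")
    tryCatch(expr, error = function(e) fail(name, e))
  }

  snapshot <- list(vcf = config$vcf, annotations = config$annotations,
                   samples = config$samples,
                   panel = if (is.null(config$panel)) "(shipped default)"
                           else config$panel,
                   out_dir = config$out_dir, seed = config$seed,
                   acmg = config$acmg, burden = config$burden,
                   roh = config$roh)
  yaml::write_yaml(snapshot, file.path(config$out_dir, "config.yaml"))

  panel <- if (is.null(config$panel)) dyt_panel() else
    load_panel(config$panel)
  logmsg("panel: ", nrow(panel), " genes")

  cohort <- stage("read", {
    ch <- read_cohort_vcf(config$vcf, config$samples)
    logmsg("read ", nrow(ch$samples), " samples, ", nrow(ch$variants),
           " variant records")
    annotate_cohort(ch, read_annotations(config$annotations))
  })
  logmsg("annotated variants: ", nrow(cohort$annotations),
         " (deleterious: ", sum(cohort$annotations$is_deleterious), ")")

  findings <- stage("prioritize", {
    f <- prioritize_candidates(cohort, panel, config$acmg)
    logmsg("candidate findings: ", nrow(f), " (retained after control ",
           "screen: ", sum(!f$screened_out), ")")
    f
  })
  write_findings(findings, file.path(config$out_dir, "findings.tsv"))

  roh <- stage("roh", {
    if (is.null(config$roh)) {
      data.frame()
    } else {
      r <- detect_roh_cohort(cohort, config$roh)
      logmsg("ROH intervals in cases: ", nrow(r))
      r
    }
  })
  write_roh_table(roh, file.path(config$out_dir, "roh.tsv"))

  burden <- stage("burden", {
    res <- list()
    for (pair in BURDEN_PAIRS) {
      smp <- cohort$samples
      ids <- smp$sample_id[smp$subgroup %in% pair]
      sub <- subset_cohort(cohort, ids)
      n_case <- sum(sub$samples$status == "case")
      n_ctrl <- sum(sub$samples$status == "control")
      if (n_case == 0L || n_ctrl == 0L) next
      logmsg("burden: ", pair[1], " (", n_case, ") vs ", pair[2],
             " (", n_ctrl, ")")
      res[[length(res) + 1L]] <- run_burden_scan(sub, panel, config$burden)
    }
    if (length(res) == 0L) {
      logmsg("burden: no matched case-control pair present; skipped")
      data.frame()
    } else {
      do.call(rbind, res)
    }
  })
  write_burden_table(burden, file.path(config$out_dir, "burden.tsv"))
  if (nrow(burden) > 0L) for (l in burden_report(burden)) logmsg(l)

  logmsg("pipeline complete")
  invisible(config$out_dir)
}
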
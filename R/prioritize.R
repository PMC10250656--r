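#' @title Candidate-finding prioritization under inheritance models
#' @description Enumerates potentially pathogenic candidate events in case
#'   samples: under the recessive model, deleterious homozygous variants and
#'   putative compound-heterozygous pairs (phase unconfirmed) with
#'   gnomAD-EAS MAF < 0.01; under the dominant model, deleterious
#'   heterozygous variants with MAF < 0.001. Findings are then screened
#'   against in-house controls and classified with the ACMG engine.
#' @name prioritize
NULL

.empty_findings <- function() {
  data.frame(sample_id = character(0), gene = character(0),
             model = character(0), variant_ids = character(0),
             pos_min = integer(0), zygosity = character(0),
             effective_maf = character(0), cadd = character(0),
             reve = character(0), predictor_support = character(0),
             acmg_by_variant = character(0), acmg = character(0),
             screened_out = logical(0), screen_reason = character(0),
             stringsAsFactors = FALSE)
}

.case_samples_for_model <- function(samples, model) {
  # FPD probands enter only the model matching their family's inheritance;
  # sporadic cases enter both models.
  excluded <- if (model == "AR") "FPD_AD" else "FPD_AR"
  samples$sample_id[samples$status == "case" & samples$subgroup != excluded]
}

.finding_row <- function(sample_id, gene, model, ann_rows, zygosity) {
  data.frame(
    sample_id = sample_id, gene = gene, model = model,
    variant_ids = paste(ann_rows$variant_id, collapse = ";"),
    pos_min = min(ann_rows$pos),
    zygosity = paste(zygosity, collapse = ";"),
    effective_maf = paste(ann_rows$effective_maf, collapse = ";"),
    cadd = paste(ifelse(is.na(ann_rows$cadd), ".", ann_rows$cadd),
                 collapse = ";"),
    reve = paste(ifelse(is.na(ann_rows$reve), ".", ann_rows$reve),
                 collapse = ";"),
    predictor_support = "", acmg_by_variant = "", acmg = "",
    screened_out = FALSE, screen_reason = NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Recessive-model candidate findings
#'
#' For every case sample (sporadic and recessive-family probands) and every
#' panel gene with recessive or dual inheritance, emits: an `AR_hom` finding
#' for each deleterious homozygous variant with effective gnomAD-EAS
#' MAF < 0.01, and an `AR_comphet` finding for each unordered pair of
#' distinct deleterious heterozygous variants in the gene, both with
#' MAF < 0.01. Phase is not required: compound-heterozygous states are
#' putative. Missing dosages are treated as non-carrier.
#'
#' @param cohort An annotated `cohort_data` ([annotate_cohort()]).
#' @param panel A `gene_panel`.
#' @return Findings data.frame, one row per event (a sample with three
#'   qualifying heterozygous variants in one gene yields three pair rows).
#' @export
ar_candidates <- function(cohort, panel) {
  stopifnot(inherits(cohort, "cohort_data"), !is.null(cohort$annotations))
  ann <- cohort$annotations
  genes <- panel_genes_for_model(panel, "AR")
  cases <- .case_samples_for_model(cohort$samples, "AR")
  rows <- list()
  eligible <- which(ann$is_deleterious & ann$effective_maf < 0.01 &
                      ann$gene %in% genes)
  for (g in unique(ann$gene[eligible])) {
    vidx <- eligible[ann$gene[eligible] == g]
    dos <- cohort$dosages[cases, vidx, drop = FALSE]
    for (s in seq_along(cases)) {
      d <- dos[s, ]
      hom <- vidx[which(!is.na(d) & d == 2)]
      for (v in hom) {
        rows[[length(rows) + 1L]] <-
          .finding_row(cases[s], g, "AR_hom", ann[v, , drop = FALSE], "Hom")
      }
      het <- vidx[which(!is.na(d) & d == 1)]
      if (length(het) >= 2L) {
        pairs <- utils::combn(het, 2L)
        for (k in seq_len(ncol(pairs))) {
          pr <- pairs[, k]
          rows[[length(rows) + 1L]] <-
            .finding_row(cases[s], g, "AR_comphet", ann[pr, , drop = FALSE],
                         c("Het", "Het"))
        }
      }
    }
  }
  if (length(rows) == 0L) return(.empty_findings())
  do.call(rbind, rows)
}

#' Dominant-model candidate findings
#'
#' For every case sample (sporadic and dominant-family probands) and every
#' panel gene with dominant or dual inheritance, emits an `AD_het` finding
#' for each deleterious heterozygous variant with effective gnomAD-EAS
#' MAF < 0.001. Genes with both inheritance patterns are evaluated under the
#' recessive and dominant models independently, each with its own criteria.
#'
#' @inheritParams ar_candidates
#' @return Findings data.frame.
#' @export
ad_candidates <- function(cohort, panel) {
  stopifnot(inherits(cohort, "cohort_data"), !is.null(cohort$annotations))
  ann <- cohort$annotations
  genes <- panel_genes_for_model(panel, "AD")
  cases <- .case_samples_for_model(cohort$samples, "AD")
  rows <- list()
  eligible <- which(ann$is_deleterious & ann$effective_maf < 0.001 &
                      ann$gene %in% genes)
  for (v in eligible) {
    d <- cohort$dosages[cases, v]
    carriers <- cases[!is.na(d) & d == 1]
    for (s in carriers) {
      rows[[length(rows) + 1L]] <-
        .finding_row(s, ann$gene[v], "AD_het", ann[v, , drop = FALSE], "Het")
    }
  }
  if (length(rows) == 0L) return(.empty_findings())
  do.call(rbind, rows)
}

.control_dosages <- function(cohort, variant_ids) {
  controls <- cohort$samples$sample_id[cohort$samples$status == "control"]
  cohort$dosages[controls, variant_ids, drop = FALSE]
}

#' Screen findings against in-house controls
#'
#' A dominant heterozygous finding is screened out if any control carries its
#' variant (dosage >= 1). A recessive finding is screened out only if some
#' control is biallelic for it: dosage 2 of the homozygous variant, or — for
#' a compound-heterozygous pair — a control carrying both pair members, or
#' homozygous for either. Heterozygous-only control carriage does not screen
#' a recessive finding.
#'
#' @param findings Findings data.frame from [ar_candidates()] /
#'   [ad_candidates()].
#' @param cohort The annotated `cohort_data` containing the control samples.
#' @return `findings` with `screened_out` and `screen_reason` filled in.
#' @export
control_screen <- function(findings, cohort) {
  if (nrow(findings) == 0L) return(findings)
  n_controls <- sum(cohort$samples$status == "control")
  if (n_controls == 0L) {
    warning("no control samples in cohort; findings retained unscreened")
    return(findings)
  }
  for (i in seq_len(nrow(findings))) {
    vids <- strsplit(findings$variant_ids[i], ";", fixed = TRUE)[[1]]
    cd <- .control_dosages(cohort, vids)
    model <- findings$model[i]
    if (model == "AD_het") {
      if (any(!is.na(cd) & cd >= 1)) {
        findings$screened_out[i] <- TRUE
        findings$screen_reason[i] <- "control carrier"
      }
    } else if (model == "AR_hom") {
      if (any(!is.na(cd) & cd == 2)) {
        findings$screened_out[i] <- TRUE
        findings$screen_reason[i] <- "control biallelic"
      }
    } else if (model == "AR_comphet") {
      hom_either <- apply(cd, 1, function(r) any(!is.na(r) & r == 2))
      both <- apply(cd, 1, function(r) all(!is.na(r) & r >= 1))
      if (any(hom_either | both)) {
        findings$screened_out[i] <- TRUE
        findings$screen_reason[i] <- "control biallelic"
      }
    }
  }
  findings
}

.ACMG_ORDER <- c(US = 1L, LP = 2L, P = 3L)

#' Annotate findings with predictor support and ACMG classes
#'
#' Fills `predictor_support`, per-variant ACMG classes, and the
#' finding-level class (the most pathogenic class among the finding's
#' variants). Screened-out findings are not classified.
#'
#' @param findings Findings data.frame (after [control_screen()]).
#' @param cohort The annotated `cohort_data`.
#' @param config ACMG configuration, see [default_acmg_config()].
#' @return `findings` with the classification columns filled.
#' @export
classify_findings <- function(findings, cohort,
                              config = default_acmg_config()) {
  if (nrow(findings) == 0L) return(findings)
  .validate_acmg_config(config)
  ann <- cohort$annotations
  has_controls <- sum(cohort$samples$status == "control") > 0L
  for (i in seq_len(nrow(findings))) {
    vids <- strsplit(findings$variant_ids[i], ";", fixed = TRUE)[[1]]
    idx <- match(vids, ann$variant_id)
    support <- predictor_support(ann[idx, , drop = FALSE],
                                 config$cadd_damaging)
    findings$predictor_support[i] <- paste(support, collapse = ";")
    if (isTRUE(findings$screened_out[i])) next
    model <- if (findings$model[i] == "AD_het") "AD" else "AR"
    classes <- vapply(idx, function(v) {
      carrier <- if (has_controls) {
        cd <- .control_dosages(cohort, ann$variant_id[v])
        any(!is.na(cd) & cd >= 1)
      } else FALSE
      acmg_classify_variant(ann[v, , drop = FALSE], model, carrier, config)
    }, character(1))
    findings$acmg_by_variant[i] <- paste(classes, collapse = ";")
    findings$acmg[i] <- names(.ACMG_ORDER)[max(.ACMG_ORDER[classes])]
  }
  findings
}

#' Full prioritization pass
#'
#' Runs [ar_candidates()] and [ad_candidates()], screens both sets against
#' controls, and classifies the survivors.
#'
#' @inheritParams classify_findings
#' @param panel A `gene_panel`.
#' @return Findings data.frame combining both models.
#' @export
prioritize_candidates <- function(cohort, panel,
                                  config = default_acmg_config()) {
  findings <- rbind(ar_candidates(cohort, panel),
                    ad_candidates(cohort, panel))
  findings <- control_screen(findings, cohort)
  classify_findings(findings, cohort, config)
}
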
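#' Default ACMG evidence configuration
#'
#' A reduced, configurable ACMG/AMP evidence engine. Three criteria are
#' operationalized from the annotation data alone:
#' \describe{
#'   \item{PVS1 (very strong)}{loss-of-function variant, optionally restricted
#'     to a per-gene allowlist of genes with an established loss-of-function
#'     disease mechanism (`lof_allowlist`; `NULL` = all panel genes).}
#'   \item{PM2 (moderate)}{absent from gnomAD East-Asian data (effective MAF
#'     at or below `max_maf`, default 0) and not carried by any in-house
#'     control.}
#'   \item{PP3 (supporting)}{damaging calls from at least `min_support` of the
#'     seven computational predictors (CADD, SIFT, LRT, MutationAssessor,
#'     PolyPhen2-HVAR, PolyPhen2-HDIV, MutationTaster); CADD counts as
#'     damaging at phred >= `cadd_damaging`.}
#' }
#' The combining table maps evidence-weight counts to classes. Pathogenic
#' requires very-strong plus at least one moderate criterion. Likely
#' pathogenic requires very-strong plus one supporting, or one moderate plus
#' a context-dependent number of supporting criteria: one under a dominant
#' model, two under a recessive model (so a novel damaging missense variant
#' is LP as a dominant heterozygous candidate but remains US as a biallelic
#' recessive candidate). Everything else is uncertain significance.
#'
#' @return A config list with elements `evidence`, `cadd_damaging`,
#'   `lof_allowlist`, `combining`.
#' @export
default_acmg_config <- function() {
  list(
    evidence = list(
      PVS1 = list(weight = "very_strong"),
      PM2 = list(weight = "moderate", max_maf = 0),
      PP3 = list(weight = "supporting", min_support = 4)
    ),
    cadd_damaging = 20,
    lof_allowlist = NULL,
    combining = list(
      P = list(c(very_strong = 1, moderate = 1)),
      LP = list(
        AR = list(c(very_strong = 1, supporting = 1),
                  c(moderate = 1, supporting = 2)),
        AD = list(c(very_strong = 1, supporting = 1),
                  c(moderate = 1, supporting = 1))
      )
    )
  )
}

ACMG_KNOWN_CODES <- c("PVS1", "PM2", "PP3")
ACMG_WEIGHTS <- c("very_strong", "strong", "moderate", "supporting")

.validate_acmg_config <- function(config) {
  unknown <- setdiff(names(config$evidence), ACMG_KNOWN_CODES)
  if (length(unknown) > 0L) {
    stop("unknown ACMG evidence code(s) in config: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (code in names(config$evidence)) {
    w <- config$evidence[[code]]$weight
    if (is.null(w) || !w %in% ACMG_WEIGHTS) {
      stop("evidence code ", code, " has no valid weight", call. = FALSE)
    }
  }
  invisible(config)
}

#' Count damaging computational-predictor calls
#'
#' Counts, out of the seven predictors (CADD plus six categorical tools), how
#' many call the variant damaging. The six categorical predictors contribute
#' when their call is `D`; CADD contributes when its phred score meets the
#' `cadd_damaging` cutoff (default 20). Missing calls never contribute.
#'
#' @param ann Annotation data.frame rows (needs `cadd` and the six predictor
#'   columns).
#' @param cadd_damaging CADD phred cutoff for a damaging call.
#' @return Integer vector in 0..7.
#' @export
predictor_support <- function(ann, cadd_damaging = 20) {
  n <- nrow(ann)
  support <- integer(n)
  for (p in PREDICTOR_COLS) {
    support <- support + as.integer(!is.na(ann[[p]]) & ann[[p]] == "D")
  }
  support + as.integer(!is.na(ann$cadd) & ann$cadd >= cadd_damaging)
}

.acmg_weight_counts <- function(ann_row, model, control_carrier, config) {
  counts <- stats::setNames(integer(length(ACMG_WEIGHTS)), ACMG_WEIGHTS)
  ev <- config$evidence
  if ("PVS1" %in% names(ev)) {
    allow <- config$lof_allowlist
    gene_ok <- is.null(allow) || ann_row$gene %in% allow
    if (isTRUE(ann_row$is_lof) && gene_ok) {
      counts[ev$PVS1$weight] <- counts[ev$PVS1$weight] + 1L
    }
  }
  if ("PM2" %in% names(ev)) {
    max_maf <- ev$PM2$max_maf
    if (is.null(max_maf)) max_maf <- 0
    if (ann_row$effective_maf <= max_maf && !control_carrier) {
      counts[ev$PM2$weight] <- counts[ev$PM2$weight] + 1L
    }
  }
  if ("PP3" %in% names(ev)) {
    min_s <- ev$PP3$min_support
    if (is.null(min_s)) min_s <- 4
    if (predictor_support(ann_row, config$cadd_damaging) >= min_s) {
      counts[ev$PP3$weight] <- counts[ev$PP3$weight] + 1L
    }
  }
  counts
}

.meets_rule <- function(counts, rule) {
  all(counts[names(rule)] >= rule)
}

#' Classify one variant under the reduced ACMG engine
#'
#' @param ann_row One classified annotation row (as in
#'   `cohort$annotations` after [annotate_cohort()]).
#' @param model Inheritance-model context, `"AR"` or `"AD"`; selects the
#'   context-specific likely-pathogenic combining rules.
#' @param control_carrier Is the variant carried (any dosage) by an in-house
#'   control?
#' @param config Evidence configuration, see [default_acmg_config()].
#' @return `"P"`, `"LP"`, or `"US"`.
#' @export
acmg_classify_variant <- function(ann_row, model = c("AR", "AD"),
                                  control_carrier = FALSE,
                                  config = default_acmg_config()) {
  model <- match.arg(model)
  .validate_acmg_config(config)
  counts <- .acmg_weight_counts(ann_row, model, control_carrier, config)
  for (rule in config$combining$P) {
    if (.meets_rule(counts, rule)) return("P")
  }
  lp_rules <- config$combining$LP
  if (!is.null(names(lp_rules)) && model %in% names(lp_rules)) {
    lp_rules <- lp_rules[[model]]
  }
  for (rule in lp_rules) {
    if (.meets_rule(counts, rule)) return("LP")
  }
  "US"
}
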
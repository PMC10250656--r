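#' @title Variant consequence classification and rarity flags
#' @description Helpers turning a variant annotation row into the flags used
#'   throughout prioritization and burden testing: loss-of-function (LoF),
#'   damaging missense (Dmis, ReVe >= 0.7), deleterious (Dmis or LoF), and
#'   rarity at the 0.01 / 0.001 gnomAD East-Asian MAF thresholds.
#' @name variant-classify
NULL

EXONIC_FUNCTIONS <- c("missense", "stopgain", "stoploss", "frameshift",
                      "splicing", "synonymous", "other")

#' Effective gnomAD-EAS allele frequency
#'
#' Combines the two gnomAD East-Asian frequency fields (exome and genome) into
#' a single conservative frequency: the maximum of the available values, or 0
#' when both are missing (a gnomAD-absent, "novel" variant).
#'
#' @param maf_exome_eas,maf_genome_eas Numeric vectors, `NA` for missing.
#' @return Numeric vector of frequencies in \[0, 1\].
#' @export
effective_maf <- function(maf_exome_eas, maf_genome_eas) {
  out <- pmax(ifelse(is.na(maf_exome_eas), 0, maf_exome_eas),
              ifelse(is.na(maf_genome_eas), 0, maf_genome_eas))
  out
}

#' Loss-of-function test
#'
#' A variant is loss-of-function if its exonic function is stopgain, stoploss
#' or frameshift, or if it is a splicing variant falling within two base pairs
#' of an exon-intron junction.
#'
#' @param exonic_function Character vector of consequence tokens.
#' @param splice_offset Signed integer distance (bp) to the nearest
#'   exon-intron junction; required for splicing variants.
#' @return Logical vector.
#' @export
is_lof <- function(exonic_function, splice_offset = NA_integer_) {
  splice_offset <- rep_len(splice_offset, length(exonic_function))
  splice <- exonic_function == "splicing"
  if (any(splice & is.na(splice_offset))) {
    stop("splicing variant without splice_offset: cannot apply the 2 bp rule",
         call. = FALSE)
  }
  exonic_function %in% c("stopgain", "stoploss", "frameshift") |
    (splice & !is.na(splice_offset) & abs(splice_offset) <= 2)
}

#' Damaging-missense test
#'
#' True for missense variants with ReVe score >= 0.7 (inclusive). A missense
#' variant lacking a ReVe score is not damaging missense.
#'
#' @param exonic_function Character vector of consequence tokens.
#' @param reve Numeric ReVe scores in \[0, 1\], `NA` when unavailable.
#' @return Logical vector.
#' @export
is_dmis <- function(exonic_function, reve) {
  reve <- rep_len(reve, length(exonic_function))
  exonic_function == "missense" & !is.na(reve) & reve >= 0.7
}

#' Classify annotated variants
#'
#' Computes, for each annotation row, the consequence and rarity flags that
#' define the analysis subgroups. Rarity uses strict `<` comparisons against
#' the 0.01 and 0.001 thresholds on the effective gnomAD-EAS frequency.
#'
#' @param ann Annotation data.frame as returned by [read_annotations()] (or
#'   any data.frame with columns `exonic_function`, `splice_offset`,
#'   `maf_exome_eas`, `maf_genome_eas`, `reve`).
#' @return `ann` with added logical columns `is_missense`, `is_lof`,
#'   `is_dmis`, `is_deleterious`, `rare_001`, `rare_0001` and numeric column
#'   `effective_maf`.
#' @export
classify_variants <- function(ann) {
  needed <- c("exonic_function", "splice_offset", "maf_exome_eas",
              "maf_genome_eas", "reve")
  miss <- setdiff(needed, names(ann))
  if (length(miss) > 0L) {
    stop("annotation table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(ann$exonic_function), EXONIC_FUNCTIONS)
  if (length(bad) > 0L) {
    stop("unknown exonic_function token(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ann$is_missense <- ann$exonic_function == "missense"
  ann$is_lof <- is_lof(ann$exonic_function, ann$splice_offset)
  ann$is_dmis <- is_dmis(ann$exonic_function, ann$reve)
  ann$is_deleterious <- ann$is_dmis | ann$is_lof
  ann$effective_maf <- effective_maf(ann$maf_exome_eas, ann$maf_genome_eas)
  ann$rare_001 <- ann$effective_maf < 0.01
  ann$rare_0001 <- ann$effective_maf < 0.001
  ann
}

#' Burden-subgroup membership of classified variants
#'
#' The burden scan tests each gene over the cells of
#' \{missense, Dmis, LoF, deleterious\} x \{MAF < 0.01, MAF < 0.001\}.
#' A variant enters a cell iff it carries the class flag and is rare at the
#' cell's threshold. The missense class ignores pathogenicity scores entirely.
#'
#' @param classified Output of [classify_variants()].
#' @return Logical matrix, one row per variant, columns
#'   `missense@0.01`, `missense@0.001`, `Dmis@0.01`, `Dmis@0.001`,
#'   `LoF@0.01`, `LoF@0.001`, `deleterious@0.01`, `deleterious@0.001`.
#' @export
subgroup_membership <- function(classified) {
  cls <- cbind(missense = classified$is_missense,
               Dmis = classified$is_dmis,
               LoF = classified$is_lof,
               deleterious = classified$is_deleterious)
  thr <- cbind(`0.01` = classified$rare_001,
               `0.001` = classified$rare_0001)
  out <- matrix(FALSE, nrow = nrow(cls),
                ncol = ncol(cls) * ncol(thr),
                dimnames = list(NULL, paste(rep(colnames(cls), each = 2),
                                            rep(colnames(thr), 4), sep = "@")))
  for (cl in colnames(cls)) {
    for (th in colnames(thr)) {
      out[, paste(cl, th, sep = "@")] <- cls[, cl] & thr[, th]
    }
  }
  out
}

#' Subgroup cell labels used by the burden scan
#' @return Character vector of the 8 `class@threshold` labels.
#' @export
subgroup_cells <- function() {
  paste(rep(c("missense", "Dmis", "LoF", "deleterious"), each = 2),
        rep(c("0.01", "0.001"), 4), sep = "@")
}
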
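#' @title Worked-example fixtures
#' @description Small deterministic cohorts encoding the reference candidate
#'   findings: the recessive biallelic candidates (two homozygous variants
#'   and three putative compound-heterozygous pairs in COL6A3 and TH), the
#'   dominant heterozygous candidates (four variants in ANO3, ADCY5 and
#'   SLC2A1 across five carriers), and a homozygosity-mapping case with an
#'   embedded 5.36 Mb homozygous tract on chromosome 2. Each fixture carries
#'   decoy variants engineered to fail exactly one filter (common frequency,
#'   low ReVe, synonymous consequence, unpaired heterozygote, control
#'   carriage, splice distance, off-panel gene, or mismatched inheritance
#'   mode), so a wrong filter shows up as a localized fixture failure.
#' @name fixtures
NULL

.fixture_covariates <- function(n) {
  i <- seq_len(n)
  out <- data.frame(age = 45 + round(8 * sin(i * 1.3), 1),
                    sex = ifelse(i %% 2 == 0, "female", "male"),
                    stringsAsFactors = FALSE)
  for (k in 1:5) out[[paste0("pc", k)]] <- round(sin(i * 0.61 * k + k), 4)
  out
}

.ann_row <- function(chrom, pos, ref, alt, gene, func, maf_ex, maf_gen,
                     cadd, reve, predictors = "D", splice_offset = NA) {
  row <- data.frame(chrom = chrom, pos = as.integer(pos), ref = ref,
                    alt = alt, gene = gene, exonic_function = func,
                    splice_offset = as.integer(splice_offset),
                    maf_exome_eas = maf_ex, maf_genome_eas = maf_gen,
                    reve = reve, cadd = cadd, stringsAsFactors = FALSE)
  for (p in PREDICTOR_COLS) row[[p]] <- predictors
  row
}

.fixture_samples <- function(case_ids, case_subgroups, n_controls,
                             control_subgroup = "control1") {
  ctrl_ids <- sprintf("CTRL-%02d", seq_len(n_controls))
  ids <- c(case_ids, ctrl_ids)
  df <- data.frame(sample_id = ids,
                   status = c(rep("case", length(case_ids)),
                              rep("control", n_controls)),
                   subgroup = c(case_subgroups,
                                rep(control_subgroup, n_controls)),
                   .fixture_covariates(length(ids)),
                   stringsAsFactors = FALSE)
  df
}

.table1_data <- function() {
  ann <- rbind(
    # reference recessive candidates
    .ann_row("chr2", 238275918, "C", "T", "COL6A3", "missense", 0.0063, 0.0099, 29.6, 0.851),  # p.A1638T
    .ann_row("chr2", 238283448, "G", "A", "COL6A3", "missense", 0.0021, 0.0012, 23.3, 0.728),  # p.R1096C
    .ann_row("chr2", 238266491, "G", "C", "COL6A3", "missense", 0.0003, 0.0006, 27.0, 0.766),  # p.P2169R
    .ann_row("chr2", 238249328, "G", "A", "COL6A3", "missense", 0, 0, 27.9, 0.889),            # p.T2744M
    .ann_row("chr2", 238277596, "G", "A", "COL6A3", "missense", 0, 0, 24.4, 0.856),            # p.R1504W
    .ann_row("chr2", 238270387, "G", "T", "COL6A3", "missense", 0, 0, 21.8, 0.763),            # p.P2051T
    .ann_row("chr11", 2192961, "G", "C", "TH", "missense", 0.0001, NA, 26.0, 0.777),           # p.S19C
    # decoys: each fails exactly one recessive-model filter
    .ann_row("chr2", 238200100, "A", "G", "COL6A3", "missense", 0.05, 0.05, 25, 0.9, "T"),     # common
    .ann_row("chr2", 238200200, "A", "G", "COL6A3", "missense", 0, 0, 25, 0.30, "T"),          # low ReVe
    .ann_row("chr2", 238200300, "A", "G", "COL6A3", "synonymous", 0, 0, 2, NA, "T"),           # synonymous
    .ann_row("chr2", 238200400, "A", "G", "COL6A3", "missense", 0.001, 0.001, 25, 0.85, "T"),  # unpaired het
    .ann_row("chr2", 238200500, "A", "G", "COL6A3", "missense", 0.002, 0.002, 25, 0.88, "T"),  # control-biallelic
    .ann_row("chr2", 238200600, "A", "G", "COL6A3", "splicing", 0, 0, 25, NA, "T", splice_offset = 3),  # 3 bp from junction
    .ann_row("chr5", 10000100, "A", "G", "FAKE1", "missense", 0, 0, 25, 0.9, "T"),             # off-panel gene
    .ann_row("chr11", 26669000, "A", "G", "ANO3", "missense", 0, 0, 25, 0.9, "T"),             # dominant-only gene, homozygous
    .ann_row("chr2", 238200700, "A", "G", "COL6A3", "missense", 0, 0, 25, NA, "T")             # missing ReVe
  )
  case_ids <- c("AR-146", "EOPD-0488", "EOPD-1304", "EOPD-0766", "LOPD-0390",
                sprintf("DECOY-%02d", 1:10), sprintf("FILL-%02d", 1:5))
  case_sub <- c("FPD_AR", "sEOPD", "sEOPD", "sEOPD", "sLOPD",
                rep("sEOPD", 10), rep("sEOPD", 5))
  samples <- .fixture_samples(case_ids, case_sub, n_controls = 30)
  G <- matrix(0, nrow = nrow(samples), ncol = nrow(ann),
              dimnames = list(samples$sample_id, NULL))
  G["AR-146", 1] <- 2
  G["EOPD-0488", 2] <- 1; G["EOPD-0488", 3] <- 1
  G["EOPD-1304", 2] <- 1; G["EOPD-1304", 4] <- 1
  G["EOPD-0766", 5] <- 1; G["EOPD-0766", 6] <- 1
  G["LOPD-0390", 7] <- 2
  G["DECOY-01", 8] <- 2    # common hom
  G["DECOY-02", 9] <- 2    # low-ReVe hom
  G["DECOY-03", 10] <- 2   # synonymous hom
  G["DECOY-04", 11] <- 1   # single het, no partner
  G["DECOY-05", 12] <- 2   # hom, but a control is also hom
  G["DECOY-06", 13] <- 2   # splicing 3 bp away
  G["DECOY-07", 14] <- 2   # off-panel gene
  G["DECOY-08", 15] <- 2   # hom in a dominant-only gene
  G["DECOY-09", 16] <- 2   # missense without ReVe
  G["DECOY-10", 3] <- 1; G["DECOY-10", 8] <- 1  # pair with a common partner
  G["CTRL-01", 12] <- 2    # control biallelic for the DECOY-05 variant
  G["CTRL-02", 1] <- 1     # het-only control carriage never screens AR
  list(samples = samples, ann = ann, G = G)
}

.table2_data <- function() {
  ann <- rbind(
    # reference dominant candidates
    .ann_row("chr11", 26621198, "G", "A", "ANO3", "stopgain", NA, NA, 41, 0.740),    # p.W591X
    .ann_row("chr11", 26669285, "G", "A", "ANO3", "missense", 0, 0, 23.7, 0.768),    # p.G820S
    .ann_row("chr3", 123044224, "C", "T", "ADCY5", "missense", 0, 0, 31, 0.854),     # p.R678H
    .ann_row("chr1", 43392818, "C", "T", "SLC2A1", "missense", 0, NA, 26.3, 0.812),  # p.R458Q
    # decoys: each fails exactly one dominant-model filter
    .ann_row("chr11", 26600100, "A", "G", "ANO3", "missense", 0.0021, 0.0012, 25, 0.9, "T"),  # fails MAF < 0.001
    .ann_row("chr11", 26600200, "A", "G", "ANO3", "missense", 0, 0, 25, 0.9, "T"),            # control carrier
    .ann_row("chr11", 26600300, "A", "G", "ANO3", "missense", 0, 0, 25, 0.4, "T"),            # low ReVe
    .ann_row("chr11", 26600400, "A", "G", "ANO3", "synonymous", 0, 0, 2, NA, "T"),            # synonymous
    .ann_row("chr11", 26600500, "A", "G", "ANO3", "missense", 0, 0, 25, 0.9, "T"),            # homozygous state
    .ann_row("chr11", 26600600, "A", "G", "ANO3", "splicing", 0, 0, 25, NA, "T", splice_offset = 3),
    .ann_row("chr5", 10000100, "A", "G", "FAKE1", "missense", 0, 0, 25, 0.9, "T"),            # off-panel gene
    .ann_row("chr11", 2192000, "A", "G", "TH", "missense", 0, 0, 25, 0.9, "T")                # recessive-only gene
  )
  case_ids <- c("EOPD-0001", "EOPD-0190", "EOPD-1469", "LOPD-1445",
                "LOPD-0694", sprintf("DECOY-%02d", 11:18),
                sprintf("FILL-%02d", 1:5))
  case_sub <- c("sEOPD", "sEOPD", "sEOPD", "sLOPD", "sLOPD",
                rep("sEOPD", 8), rep("sEOPD", 5))
  samples <- .fixture_samples(case_ids, case_sub, n_controls = 30)
  G <- matrix(0, nrow = nrow(samples), ncol = nrow(ann),
              dimnames = list(samples$sample_id, NULL))
  G["EOPD-0001", 1] <- 1
  G["EOPD-0190", 2] <- 1; G["EOPD-1469", 2] <- 1
  G["LOPD-1445", 3] <- 1
  G["LOPD-0694", 4] <- 1
  G["DECOY-11", 5] <- 1
  G["DECOY-12", 6] <- 1; G["CTRL-01", 6] <- 1  # screened by control carrier
  G["DECOY-13", 7] <- 1
  G["DECOY-14", 8] <- 1
  G["DECOY-15", 9] <- 2
  G["DECOY-16", 10] <- 1
  G["DECOY-17", 11] <- 1
  G["DECOY-18", 12] <- 1
  list(samples = samples, ann = ann, G = G)
}

.roh_case_data <- function() {
  # homozygous tract spanning chr2:237614085-242978914 around the COL6A3
  # p.A1638T position; heterozygous background on chr11
  tract_pos <- sort(unique(c(round(seq(237614085, 242978914,
                                       length.out = 151)), 238275918)))
  n_tract <- length(tract_pos)
  ann_tract <- do.call(rbind, lapply(seq_len(n_tract), function(i) {
    if (tract_pos[i] == 238275918) {
      .ann_row("chr2", tract_pos[i], "C", "T", "COL6A3", "missense",
               0.0063, 0.0099, 29.6, 0.851)
    } else {
      .ann_row("chr2", tract_pos[i], "A", "G", "COL6A3", "synonymous",
               0.2, 0.2, 1, NA, "T")
    }
  }))
  bg_pos <- 2192961 + (0:59) * 1000
  ann_bg <- do.call(rbind, lapply(bg_pos, function(p) {
    .ann_row("chr11", p, "A", "G", "TH", "synonymous", 0.3, 0.3, 1, NA, "T")
  }))
  ann <- rbind(ann_tract, ann_bg)
  samples <- .fixture_samples(c("AR-146"), c("FPD_AR"), n_controls = 1)
  G <- matrix(0, nrow = 2, ncol = nrow(ann),
              dimnames = list(samples$sample_id, NULL))
  G["AR-146", seq_len(n_tract)] <- 2
  G["AR-146", n_tract + seq_along(bg_pos)] <- 1
  G["CTRL-01", seq_len(n_tract)] <- 1
  list(samples = samples, ann = ann, G = G)
}

#' Build a worked-example fixture cohort on disk
#'
#' @param which `"table1_ar"` (recessive biallelic candidates plus decoys),
#'   `"table2_ad"` (dominant heterozygous candidates plus decoys), or
#'   `"roh_case"` (embedded homozygous tract).
#' @param dir Output directory.
#' @return Named list of written paths (`vcf`, `annotations`, `samples`),
#'   invisibly.
#' @export
make_example_fixture <- function(which = c("table1_ar", "table2_ad",
                                         "roh_case"),
                               dir = tempfile(which)) {
  which <- match.arg(which)
  dat <- switch(which,
                table1_ar = .table1_data(),
                table2_ad = .table2_data(),
                roh_case = .roh_case_data())
  write_cohort_files(dir, dat$samples, dat$ann, dat$G)
}

#' Load a worked-example fixture as an annotated cohort
#'
#' Convenience wrapper: builds the fixture, reads it back through the
#' standard readers, and attaches the annotations.
#'
#' @inheritParams make_example_fixture
#' @return An annotated `cohort_data`.
#' @export
load_example_fixture <- function(which = c("table1_ar", "table2_ad",
                                         "roh_case")) {
  which <- match.arg(which)
  paths <- make_example_fixture(which)
  cohort <- read_cohort_vcf(paths$vcf, paths$samples)
  annotate_cohort(cohort, read_annotations(paths$annotations))
}
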
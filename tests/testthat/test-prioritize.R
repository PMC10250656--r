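random_test_cohort <- function(seed, n_samples = 20, n_variants = 30) {
  set.seed(seed)
  ann <- random_annotations(n_variants, seed = seed + 1000)
  ann <- ann[ann$exonic_function != "splicing" |
               !is.na(ann$splice_offset), , drop = FALSE]
  ann$pos <- seq_len(nrow(ann)) * 100L
  n_ctrl <- max(2L, n_samples %/% 4L)
  n_case <- n_samples - n_ctrl
  samples <- data.frame(
    sample_id = sprintf("S%02d", seq_len(n_samples)),
    status = c(rep("case", n_case), rep("control", n_ctrl)),
    subgroup = c(sample(c("sEOPD", "sLOPD", "FPD_AR", "FPD_AD"), n_case,
                        replace = TRUE), rep("control1", n_ctrl)),
    age = 50, sex = "male", pc1 = 0, pc2 = 0, pc3 = 0, pc4 = 0, pc5 = 0,
    stringsAsFactors = FALSE)
  dos <- matrix(sample(c(0, 0, 0, 1, 1, 2, NA), n_samples * nrow(ann),
                       replace = TRUE), nrow = n_samples)
  make_test_cohort(samples, ann, dos)
}

test_that("recessive candidates match the brute-force enumeration oracle", {
  panel <- dyt_panel()
  for (seed in c(1, 2, 3, 4)) {
    co <- random_test_cohort(seed)
    got <- ar_candidates(co, panel)
    expect_equal(finding_keys(got), oracle_ar_keys(co, panel),
                 info = paste("seed", seed))
  }
})

test_that("no finding ever violates its model's frequency threshold", {
  panel <- dyt_panel()
  for (seed in 5:8) {
    co <- random_test_cohort(seed)
    f <- rbind(ar_candidates(co, panel), ad_candidates(co, panel))
    if (nrow(f) == 0L) next
    for (i in seq_len(nrow(f))) {
      vids <- strsplit(f$variant_ids[i], ";", fixed = TRUE)[[1]]
      mafs <- co$annotations$effective_maf[match(vids,
                                                 co$annotations$variant_id)]
      lim <- if (f$model[i] == "AD_het") 0.001 else 0.01
      expect_true(all(mafs < lim))
      expect_true(all(co$annotations$is_deleterious[
        match(vids, co$annotations$variant_id)]))
    }
  }
})

test_that("dominant model requires heterozygous state and the strict threshold", {
  samples <- data.frame(sample_id = c("P1", "C1"),
                        status = c("case", "control"),
                        subgroup = c("sEOPD", "control1"),
                        age = 50, sex = "male", pc1 = 0, pc2 = 0, pc3 = 0,
                        pc4 = 0, pc5 = 0, stringsAsFactors = FALSE)
  ann <- random_annotations(2, seed = 9)
  ann$gene <- "ANO3"; ann$exonic_function <- "missense"
  ann$reve <- 0.9; ann$splice_offset <- NA
  ann$maf_exome_eas <- c(0, 0.0021); ann$maf_genome_eas <- c(0, 0.0012)
  # homozygous state in a dominant-only gene: no dominant finding
  co <- make_test_cohort(samples, ann, matrix(c(2, 0, 0, 0), nrow = 2))
  expect_equal(nrow(ad_candidates(co, dyt_panel())), 0L)
  # heterozygous but at 0.0021 > 0.001: no dominant finding
  co2 <- make_test_cohort(samples, ann, matrix(c(0, 0, 1, 0), nrow = 2))
  expect_equal(nrow(ad_candidates(co2, dyt_panel())), 0L)
  # heterozygous and novel: one finding
  co3 <- make_test_cohort(samples, ann, matrix(c(1, 0, 0, 0), nrow = 2))
  expect_equal(nrow(ad_candidates(co3, dyt_panel())), 1L)
})

test_that("control screening is monotone in control carriage", {
  co <- load_example_fixture("table1_ar")
  panel <- dyt_panel()
  f0 <- control_screen(ar_candidates(co, panel), co)
  # add a control homozygous for the retained homozygous candidate
  co2 <- co
  co2$dosages["CTRL-03", "chr2:238275918:C:T"] <- 2
  f1 <- control_screen(ar_candidates(co2, panel), co2)
  k0 <- finding_keys(f0[f0$screened_out, , drop = FALSE])
  k1 <- finding_keys(f1[f1$screened_out, , drop = FALSE])
  expect_true(all(k0 %in% k1))
  expect_true(length(k1) > length(k0))
  # het-only control carriage never screens a recessive finding
  co3 <- co
  co3$dosages["CTRL-03", "chr2:238275918:C:T"] <- 1
  f2 <- control_screen(ar_candidates(co3, panel), co3)
  expect_equal(finding_keys(f2[f2$screened_out, , drop = FALSE]), k0)
})

test_that("a cohort without controls leaves findings unscreened with a warning", {
  co <- load_example_fixture("table1_ar")
  keep <- co$samples$status == "case"
  co$samples <- co$samples[keep, ]
  co$dosages <- co$dosages[co$samples$sample_id, ]
  f <- ar_candidates(co, dyt_panel())
  expect_warning(out <- control_screen(f, co), "no control")
  expect_false(any(out$screened_out))
})

test_that("predictor support counts damaging calls across the seven tools", {
  ann <- random_annotations(3, seed = 2)
  for (p in c("sift", "lrt", "mutation_assessor", "polyphen2_hvar",
              "polyphen2_hdiv", "mutation_taster")) {
    ann[[p]] <- c("D", NA, "T")
  }
  ann$cadd <- c(29.6, NA, 29.6)
  expect_equal(predictor_support(ann), c(7L, 0L, 1L))
  # the CADD cutoff is configurable
  expect_equal(predictor_support(ann, cadd_damaging = 30), c(6L, 0L, 0L))
})

test_that("ACMG engine is deterministic, order-independent, and validated", {
  co <- load_example_fixture("table2_ad")
  panel <- dyt_panel()
  f <- control_screen(ad_candidates(co, panel), co)
  a1 <- classify_findings(f, co)
  a2 <- classify_findings(f[rev(seq_len(nrow(f))), ], co)
  expect_equal(sort(paste(a1$variant_ids, a1$acmg)),
               sort(paste(a2$variant_ids, a2$acmg)))
  bad <- default_acmg_config()
  bad$evidence$PS4 <- list(weight = "strong")
  expect_error(classify_findings(f, co, bad), "unknown ACMG evidence")
})

test_that("compound heterozygotes are reported per pair", {
  samples <- data.frame(sample_id = c("P1", "C1"),
                        status = c("case", "control"),
                        subgroup = c("sEOPD", "control1"),
                        age = 50, sex = "male", pc1 = 0, pc2 = 0, pc3 = 0,
                        pc4 = 0, pc5 = 0, stringsAsFactors = FALSE)
  ann <- random_annotations(3, seed = 3)
  ann$gene <- "TH"; ann$exonic_function <- "missense"; ann$reve <- 0.9
  ann$splice_offset <- NA
  ann$maf_exome_eas <- 0; ann$maf_genome_eas <- 0
  co <- make_test_cohort(samples, ann,
                         matrix(c(1, 0, 1, 0, 1, 0), nrow = 2))
  f <- ar_candidates(co, dyt_panel())
  # three heterozygous variants in one gene yield all three pairs
  expect_equal(nrow(f), 3L)
  expect_true(all(f$model == "AR_comphet"))
})
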
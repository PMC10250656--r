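test_that("identical configs regenerate byte-identical files", {
  cfg <- sim_config(n_cases = 20, n_controls = 20, genes = c("TH", "ANO3"),
                    variants_per_gene = 10, seed = 42)
  p1 <- simulate_cohort(cfg, dir = tempfile())
  p2 <- simulate_cohort(cfg, dir = tempfile())
  for (k in c("vcf", "annotations", "samples")) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]))
  }
  # a different seed changes the output
  p3 <- simulate_cohort(sim_config(n_cases = 20, n_controls = 20,
                                   genes = c("TH", "ANO3"),
                                   variants_per_gene = 10, seed = 43),
                        dir = tempfile())
  expect_false(identical(readLines(p1$vcf), readLines(p3$vcf)))
})

test_that("the damaging-missense fraction matches the configured mix", {
  cfg <- sim_config(n_cases = 20, n_controls = 20,
                    genes = paste0("G", 1:25), variants_per_gene = 40,
                    class_mix = c(missense = 0.3, Dmis = 0.4, LoF = 0.1,
                                  synonymous = 0.2),
                    seed = 8)
  co <- simulate_cohort(cfg, as_cohort = TRUE)
  m <- nrow(co$annotations)
  expect_equal(m, 1000L)
  frac <- mean(co$annotations$is_dmis)
  ci <- qbinom(c(0.005, 0.995), m, 0.4) / m
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})

test_that("under the null, case and control carrier rates are balanced", {
  cfg <- sim_config(n_cases = 400, n_controls = 400, seed = 15)
  co <- simulate_cohort(cfg, as_cohort = TRUE)
  is_case <- co$samples$status == "case"
  for (g in unique(co$annotations$gene)) {
    vids <- co$annotations$variant_id[co$annotations$gene == g &
                                        co$annotations$is_deleterious]
    if (length(vids) == 0L) next
    carrier <- rowSums(co$dosages[, vids, drop = FALSE] >= 1) > 0
    tab <- table(factor(carrier, c(FALSE, TRUE)),
                 factor(is_case, c(FALSE, TRUE)))
    p <- suppressWarnings(stats::chisq.test(tab)$p.value)
    if (!is.nan(p)) expect_gt(p, 1e-4)
  }
})

test_that("simulated allele frequencies converge to the configured values", {
  cfg <- sim_config(n_cases = 2500, n_controls = 2500,
                    genes = c("TH", "ANO3"), variants_per_gene = 15,
                    maf_range = c(5e-3, 2e-2), maf_missing_rate = 0,
                    seed = 23)
  co <- simulate_cohort(cfg, as_cohort = TRUE)
  target <- co$annotations$effective_maf
  obs <- colMeans(co$dosages) / 2
  se <- sqrt(target * (1 - target) / (2 * nrow(co$samples)))
  expect_true(all(abs(obs - target) < 4 * se + 1e-4))
})

test_that("simulated files pass the readers without warnings", {
  cfg <- sim_config(n_cases = 15, n_controls = 15, genes = c("TH", "SPR"),
                    variants_per_gene = 8, seed = 3)
  paths <- simulate_cohort(cfg, dir = tempfile())
  expect_no_warning({
    co <- read_cohort_vcf(paths$vcf, paths$samples)
    co <- annotate_cohort(co, read_annotations(paths$annotations))
  })
  expect_equal(nrow(co$annotations), nrow(co$variants))
})

test_that("an infeasible configuration is rejected", {
  cfg <- sim_config(n_cases = 50, n_controls = 10, base_prevalence = 1e-6,
                    genes = "TH", variants_per_gene = 5, seed = 1)
  expect_error(simulate_cohort(cfg, as_cohort = TRUE), "infeasible")
})

test_that("config validation rejects malformed mixes", {
  expect_error(sim_config(class_mix = c(missense = 0.5, Dmis = 0.5,
                                        LoF = 0.2, synonymous = 0.1)),
               "class_mix")
  expect_error(sim_config(n_cases = 0), "n_cases")
  expect_error(sim_config(effect_spec = c(NOTAGENE = 1)), "effect_spec")
})

test_that("each recessive-fixture decoy fails exactly its targeted filter", {
  co <- load_example_fixture("table1_ar")
  ann <- co$annotations
  a <- function(id) ann[ann$variant_id == id, ]
  # common frequency: deleterious but not rare
  d1 <- a("chr2:238200100:A:G")
  expect_true(d1$is_deleterious); expect_false(d1$rare_001)
  # low ReVe: rare missense but not deleterious
  d2 <- a("chr2:238200200:A:G")
  expect_true(d2$rare_001); expect_false(d2$is_deleterious)
  # synonymous: not deleterious despite rarity
  d3 <- a("chr2:238200300:A:G")
  expect_true(d3$rare_001); expect_false(d3$is_deleterious)
  # splice distance 3 bp: not loss-of-function
  d6 <- a("chr2:238200600:A:G")
  expect_false(d6$is_lof); expect_true(d6$rare_001)
  # missing ReVe: not damaging missense
  d9 <- a("chr2:238200700:A:G")
  expect_false(d9$is_dmis); expect_true(d9$rare_001)
  # unpaired het, control-biallelic, off-panel, and dominant-gene decoys
  # are variant-eligible (deleterious and rare) so only the targeted
  # zygosity/screen/panel rule can reject them
  for (id in c("chr2:238200400:A:G", "chr2:238200500:A:G",
               "chr5:10000100:A:G", "chr11:26669000:A:G")) {
    expect_true(a(id)$is_deleterious & a(id)$rare_001, label = id)
  }
  # end to end: no decoy sample retains a finding
  f <- prioritize_candidates(co, dyt_panel())
  kept <- unique(f$sample_id[!f$screened_out])
  expect_false(any(grepl("^DECOY", kept)))
  # ... and the control-biallelic decoy is present but screened
  d5 <- f[f$sample_id == "DECOY-05", ]
  expect_equal(nrow(d5), 1L)
  expect_true(d5$screened_out)
  expect_equal(d5$screen_reason, "control biallelic")
})

test_that("each dominant-fixture decoy fails exactly its targeted filter", {
  co <- load_example_fixture("table2_ad")
  ann <- co$annotations
  a <- function(id) ann[ann$variant_id == id, ]
  e1 <- a("chr11:26600100:A:G")  # fails the 0.001 threshold only
  expect_true(e1$is_deleterious && e1$rare_001 && !e1$rare_0001)
  e3 <- a("chr11:26600300:A:G")  # low ReVe
  expect_true(e3$rare_0001); expect_false(e3$is_deleterious)
  e4 <- a("chr11:26600400:A:G")  # synonymous
  expect_false(e4$is_deleterious)
  e6 <- a("chr11:26600600:A:G")  # splice distance
  expect_false(e6$is_lof)
  f <- prioritize_candidates(co, dyt_panel())
  kept <- unique(f$sample_id[!f$screened_out])
  expect_false(any(grepl("^DECOY", kept)))
  e2 <- f[f$sample_id == "DECOY-12", ]  # control carrier, screened
  expect_equal(nrow(e2), 1L)
  expect_true(e2$screened_out)
  expect_equal(e2$screen_reason, "control carrier")
})

test_that("the study-scale cohort profile is available for scaling", {
  prof <- study_cohort_profile()
  expect_equal(sum(prof[c("sEOPD", "sLOPD", "FPD_AR", "FPD_AD")]), 3959L)
  expect_equal(sum(prof[c("control1", "control2")]), 2931L)
})
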
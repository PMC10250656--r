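#' @title Synthetic case-control cohort generation
#' @description Generates fully synthetic cohorts in exactly the interchange
#'   formats the readers consume (VCF + annotation TSV + sample TSV):
#'   Hardy-Weinberg genotypes at rare simulated population frequencies,
#'   logistic case assignment with covariates and optional spiked per-gene
#'   carrier effects, and annotation fields drawn consistently with the
#'   configured consequence-class mix. Also builds small deterministic
#'   fixtures that encode the worked candidate-variant examples, each
#'   accompanied by decoy variants engineered to fail exactly one filter.
#' @name synthetic-cohort
NULL

#' Simulation configuration
#'
#' Defaults describe a desk-scale sporadic early-onset cohort: 200 cases and
#' 200 controls, 10 panel genes, 30 variants per gene with population
#' frequencies log-uniform on \[1e-4, 5e-3\], consequence-class mix 45%
#' non-damaging missense / 20% damaging missense / 10% loss-of-function /
#' 25% synonymous, no gene effects and no confounding. The study-scale
#' cohort shapes are available through [study_cohort_profile()].
#'
#' @param n_cases,n_controls Cohort sizes (>= 1).
#' @param genes Character vector of gene symbols to simulate (default: the
#'   first 10 genes of the shipped panel).
#' @param variants_per_gene Variants simulated per gene.
#' @param maf_range Two-element range for log-uniform population frequencies.
#' @param class_mix Named proportions (`missense`, `Dmis`, `LoF`,
#'   `synonymous`) summing to 1; `missense` here means missense with
#'   ReVe < 0.7.
#' @param effect_spec Named numeric vector of per-gene log-odds for carrying
#'   at least one deleterious variant of the gene; `NULL` = all zero (null
#'   model).
#' @param covariate_spec List: `age_mean` (default 43, early-onset-like),
#'   `age_sd` (8), `sex_p` (0.5), `beta_age`, `beta_sex` (confounding
#'   coefficients, default 0).
#' @param case_subgroup,control_subgroup Subgroup labels for the generated
#'   samples.
#' @param maf_missing_rate Probability that a variant's gnomAD frequency
#'   fields are missing (a "novel" variant).
#' @param base_prevalence Baseline case probability in the source population
#'   the case-control sample is drawn from.
#' @param seed Integer seed; the generator is deterministic given the config.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_cases = 200, n_controls = 200, genes = NULL,
                       variants_per_gene = 30,
                       maf_range = c(1e-4, 5e-3),
                       class_mix = c(missense = 0.45, Dmis = 0.2,
                                     LoF = 0.1, synonymous = 0.25),
                       effect_spec = NULL,
                       covariate_spec = list(age_mean = 43, age_sd = 8,
                                             sex_p = 0.5, beta_age = 0,
                                             beta_sex = 0),
                       case_subgroup = "sEOPD",
                       control_subgroup = "control1",
                       maf_missing_rate = 0.02,
                       base_prevalence = 0.35,
                       seed = 1L) {
  if (is.null(genes)) genes <- dyt_panel()$symbol[1:10]
  stopifnot(n_cases >= 1, n_controls >= 1, variants_per_gene >= 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5)
  if (!setequal(names(class_mix),
                c("missense", "Dmis", "LoF", "synonymous")) ||
      any(class_mix < 0) || any(class_mix > 1) ||
      abs(sum(class_mix) - 1) > 1e-8) {
    stop("class_mix must be proportions over missense/Dmis/LoF/synonymous ",
         "summing to 1", call. = FALSE)
  }
  if (!is.null(effect_spec) &&
      length(setdiff(names(effect_spec), genes)) > 0L) {
    stop("effect_spec names must be simulated genes", call. = FALSE)
  }
  structure(list(n_cases = n_cases, n_controls = n_controls, genes = genes,
                 variants_per_gene = variants_per_gene,
                 maf_range = maf_range, class_mix = class_mix,
                 effect_spec = effect_spec, covariate_spec = covariate_spec,
                 case_subgroup = case_subgroup,
                 control_subgroup = control_subgroup,
                 maf_missing_rate = maf_missing_rate,
                 base_prevalence = base_prevalence,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Study-scale cohort shape
#'
#' The full-scale subgroup sizes of the study design this generator
#' emulates: two sporadic case-control cohorts plus familial probands.
#'
#' @return Named integer vector with elements `sEOPD`, `sLOPD`, `FPD_AR`,
#'   `FPD_AD`, `control1`, `control2`.
#' @export
study_cohort_profile <- function() {
  c(sEOPD = 1508L, sLOPD = 1962L, FPD_AR = 153L, FPD_AD = 336L,
    control1 = 1652L, control2 = 1279L)
}

.rand_alleles <- function(m) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  list(ref = ref, alt = unname(alt))
}

.draw_predictors <- function(deleterious, m) {
  p_damaging <- ifelse(deleterious, 0.85, 0.15)
  out <- list()
  for (p in PREDICTOR_COLS) {
    out[[p]] <- ifelse(stats::runif(m) < p_damaging, "D", "T")
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Simulate a synthetic case-control cohort to disk
#'
#' Genotypes are drawn per variant under Hardy-Weinberg equilibrium at its
#' simulated population frequency in a source population; case status is
#' assigned by a logistic model combining the baseline prevalence, optional
#' covariate effects, and per-gene log-odds for carriers of deleterious
#' variants; the case-control sample is then drawn from the population.
#' Annotation gnomAD frequencies equal the simulated population frequency
#' (with optional missingness); ReVe scores are drawn so that the damaging
#' missense fraction matches `class_mix`. Output is byte-identical for
#' identical configs.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param as_cohort If `TRUE`, skip the file round-trip and return the
#'   annotated `cohort_data` directly (identical content; used by simulation
#'   loops where file parsing would dominate runtime).
#' @return Named list of the three written paths (`vcf`, `annotations`,
#'   `samples`), invisibly; or a `cohort_data` when `as_cohort = TRUE`.
#' @export
simulate_cohort <- function(config, dir = tempfile("simcohort"),
                            as_cohort = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genes <- config$genes
  mpg <- config$variants_per_gene
  m <- length(genes) * mpg

  variants <- data.frame(
    chrom = rep(paste0("chr", (seq_along(genes) - 1L) %% 22L + 1L),
                each = mpg),
    pos = as.integer(rep(seq_along(genes) * 1e7, each = mpg) +
                       rep(seq_len(mpg) * 150L, length(genes))),
    gene = rep(genes, each = mpg), stringsAsFactors = FALSE)
  al <- .rand_alleles(m)
  variants$ref <- al$ref; variants$alt <- al$alt

  lr <- log10(config$maf_range)
  maf <- 10^stats::runif(m, lr[1], lr[2])
  cls <- sample(names(config$class_mix), m, replace = TRUE,
                prob = config$class_mix)
  exonic <- ifelse(cls %in% c("missense", "Dmis"), "missense",
                   ifelse(cls == "synonymous", "synonymous", NA))
  lof_type <- sample(c("stopgain", "frameshift", "splicing"), m,
                     replace = TRUE)
  exonic[cls == "LoF"] <- lof_type[cls == "LoF"]
  splice_offset <- rep(NA_integer_, m)
  spl <- exonic == "splicing"
  splice_offset[spl] <- sample(c(-2L, -1L, 1L, 2L), sum(spl), replace = TRUE)
  reve <- rep(NA_real_, m)
  reve[cls == "missense"] <- stats::runif(sum(cls == "missense"), 0, 0.699)
  reve[cls == "Dmis"] <- stats::runif(sum(cls == "Dmis"), 0.7, 1)
  deleterious <- cls %in% c("Dmis", "LoF")
  cadd <- ifelse(deleterious, stats::runif(m, 20, 40), stats::runif(m, 0, 19))
  preds <- .draw_predictors(deleterious, m)
  hide <- stats::runif(m) < config$maf_missing_rate
  maf_ann <- ifelse(hide, NA_real_, signif(maf, 4))

  # source population, sampled until both strata are filled
  cs <- config$covariate_spec
  need_case <- config$n_cases; need_ctrl <- config$n_controls
  pool_n <- 4L * (need_case + need_ctrl)
  G_keep <- NULL; meta_keep <- NULL
  for (round in 1:25) {
    Gp <- matrix(stats::rbinom(pool_n * m, 2, rep(maf, each = pool_n)),
                 nrow = pool_n)
    age <- stats::rnorm(pool_n, cs$age_mean, cs$age_sd)
    sex <- ifelse(stats::runif(pool_n) < cs$sex_p, "male", "female")
    pcs <- matrix(stats::rnorm(pool_n * 5), ncol = 5)
    eta <- stats::qlogis(config$base_prevalence) +
      cs$beta_age * (age - cs$age_mean) / cs$age_sd +
      cs$beta_sex * (sex == "female")
    if (!is.null(config$effect_spec)) {
      for (g in names(config$effect_spec)) {
        vsel <- which(variants$gene == g & deleterious)
        if (length(vsel) > 0L) {
          carrier <- rowSums(Gp[, vsel, drop = FALSE] >= 1) > 0
          eta <- eta + config$effect_spec[[g]] * carrier
        }
      }
    }
    status <- ifelse(stats::runif(pool_n) < stats::plogis(eta),
                     "case", "control")
    meta <- data.frame(status = status, age = round(age, 1), sex = sex,
                       stringsAsFactors = FALSE)
    for (k in 1:5) meta[[paste0("pc", k)]] <- round(pcs[, k], 4)
    take_case <- which(status == "case")[seq_len(min(need_case,
                                                     sum(status == "case")))]
    take_ctrl <- which(status == "control")[seq_len(min(need_ctrl,
                                                        sum(status == "control")))]
    take <- c(take_case, take_ctrl)
    G_keep <- rbind(G_keep, Gp[take, , drop = FALSE])
    meta_keep <- rbind(meta_keep, meta[take, , drop = FALSE])
    need_case <- need_case - length(take_case)
    need_ctrl <- need_ctrl - length(take_ctrl)
    if (need_case == 0L && need_ctrl == 0L) break
  }
  if (need_case > 0L || need_ctrl > 0L) {
    stop("infeasible simulation config: could not fill both strata ",
         "(effect sizes or prevalence too extreme)", call. = FALSE)
  }
  ord <- order(meta_keep$status != "case")
  meta_keep <- meta_keep[ord, , drop = FALSE]
  G_keep <- G_keep[ord, , drop = FALSE]
  is_case <- meta_keep$status == "case"
  samples <- data.frame(
    sample_id = ifelse(is_case,
                       sprintf("CASE-%04d", cumsum(is_case)),
                       sprintf("CTRL-%04d", cumsum(!is_case))),
    status = meta_keep$status,
    subgroup = ifelse(is_case, config$case_subgroup,
                      config$control_subgroup),
    meta_keep[, c("age", "sex", paste0("pc", 1:5))],
    stringsAsFactors = FALSE)

  ann <- data.frame(variants[, c("chrom", "pos", "ref", "alt", "gene")],
                    exonic_function = exonic, splice_offset = splice_offset,
                    maf_exome_eas = maf_ann, maf_genome_eas = maf_ann,
                    reve = round(reve, 4), cadd = round(cadd, 1),
                    preds, stringsAsFactors = FALSE)
  rownames(G_keep) <- samples$sample_id
  if (as_cohort) {
    variant_id <- paste(ann$chrom, ann$pos, ann$ref, ann$alt, sep = ":")
    ord2 <- order(ann$chrom, ann$pos, ann$ref, ann$alt)
    vdf <- data.frame(ann[ord2, c("chrom", "pos", "ref", "alt")],
                      variant_id = variant_id[ord2],
                      stringsAsFactors = FALSE)
    dos <- G_keep[, ord2, drop = FALSE]
    colnames(dos) <- vdf$variant_id
    ann2 <- ann[ord2, , drop = FALSE]
    ann2$variant_id <- vdf$variant_id
    cohort <- structure(list(samples = samples, variants = vdf,
                             dosages = dos,
                             annotations = classify_variants(ann2)),
                        class = "cohort_data")
    return(cohort)
  }
  write_cohort_files(dir, samples, ann, G_keep)
}

#' Write a cohort triple (VCF, annotation TSV, sample TSV)
#'
#' @param dir Output directory.
#' @param samples Sample data.frame (columns of [read_samples()]).
#' @param ann Annotation data.frame (columns of [read_annotations()]),
#'   ordered as the columns of `dosages`.
#' @param dosages Samples x variants dosage matrix (0/1/2/NA).
#' @return Named list of written paths, invisibly.
#' @export
write_cohort_files <- function(dir, samples, ann, dosages) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vcf_path <- file.path(dir, "cohort.vcf")
  ann_path <- file.path(dir, "annotations.tsv")
  smp_path <- file.path(dir, "samples.tsv")

  gt <- matrix("./.", nrow = nrow(dosages), ncol = ncol(dosages))
  gt[!is.na(dosages) & dosages == 0] <- "0/0"
  gt[!is.na(dosages) & dosages == 1] <- "0/1"
  gt[!is.na(dosages) & dosages == 2] <- "1/1"
  ord <- order(ann$chrom, ann$pos, ann$ref, ann$alt)
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples$sample_id), collapse = "\t"))
  # one biallelic record per annotation row, position-sorted
  body <- vapply(ord, function(j) {
    paste(c(ann$chrom[j], ann$pos[j], ".", ann$ref[j], ann$alt[j], ".",
            "PASS", ".", "GT", gt[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), vcf_path)

  ann_out <- ann[ord, , drop = FALSE]
  for (cl in names(ann_out)) {
    ann_out[[cl]] <- ifelse(is.na(ann_out[[cl]]), "NA",
                            as.character(ann_out[[cl]]))
  }
  utils::write.table(ann_out, ann_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  smp_out <- samples
  for (cl in names(smp_out)) {
    smp_out[[cl]] <- ifelse(is.na(smp_out[[cl]]), "NA",
                            as.character(smp_out[[cl]]))
  }
  utils::write.table(smp_out, smp_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(vcf = vcf_path, annotations = ann_path, samples = smp_path))
}

#' Simulate genotype dosages under Hardy-Weinberg equilibrium
#'
#' Convenience generator for calibration studies: an n x m dosage matrix
#' with independent variants at the given population frequencies.
#'
#' @param n Number of samples.
#' @param maf Vector of m allele frequencies.
#' @return n x m integer matrix of dosages.
#' @export
simulate_dosages <- function(n, maf) {
  matrix(stats::rbinom(n * length(maf), 2, rep(maf, each = n)), nrow = n)
}
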
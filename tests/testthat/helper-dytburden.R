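# shared helpers: in-code fixtures and independent brute-force oracles

# minimal VCF writer for reader tests
write_mini_vcf <- function(records, sample_ids, path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}

mini_sample_table <- function(sample_ids, status = "case",
                              subgroup = "sEOPD",
                              path = tempfile(fileext = ".tsv")) {
  n <- length(sample_ids)
  df <- data.frame(sample_id = sample_ids,
                   status = rep_len(status, n),
                   subgroup = rep_len(subgroup, n),
                   age = 50 + seq_len(n), sex = rep_len(c("male", "female"), n),
                   stringsAsFactors = FALSE)
  for (k in 1:5) df[[paste0("pc", k)]] <- round(sin(seq_len(n) * k), 3)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# build an annotated in-memory cohort from raw pieces
make_test_cohort <- function(samples, ann, dosages) {
  ann$variant_id <- paste(ann$chrom, ann$pos, ann$ref, ann$alt, sep = ":")
  variants <- ann[, c("chrom", "pos", "ref", "alt", "variant_id")]
  dimnames(dosages) <- list(samples$sample_id, ann$variant_id)
  structure(list(samples = samples, variants = variants, dosages = dosages,
                 annotations = classify_variants(ann)),
            class = "cohort_data")
}

# random annotation table for property tests
random_annotations <- function(n, seed) {
  set.seed(seed)
  funcs <- sample(c("missense", "stopgain", "stoploss", "frameshift",
                    "splicing", "synonymous", "other"), n, replace = TRUE)
  off <- ifelse(funcs == "splicing",
                sample(c(-4:-1, 1:4), n, replace = TRUE), NA_integer_)
  maf1 <- ifelse(runif(n) < 0.2, NA,
                 10^runif(n, -5, -1))
  maf2 <- ifelse(runif(n) < 0.2, NA, 10^runif(n, -5, -1))
  reve <- ifelse(funcs == "missense" & runif(n) > 0.1, runif(n), NA)
  ann <- data.frame(chrom = "chr1", pos = seq_len(n) * 100, ref = "A",
                    alt = "G", gene = sample(c("TH", "ANO3", "ADCY5"), n,
                                             replace = TRUE),
                    exonic_function = funcs, splice_offset = off,
                    maf_exome_eas = maf1, maf_genome_eas = maf2,
                    reve = reve, cadd = runif(n, 0, 40),
                    stringsAsFactors = FALSE)
  for (p in c("sift", "lrt", "mutation_assessor", "polyphen2_hvar",
              "polyphen2_hdiv", "mutation_taster")) {
    ann[[p]] <- sample(c("D", "T", NA), n, replace = TRUE)
  }
  ann
}

# brute-force recessive-candidate oracle: enumerate every
# sample x gene x variant (and variant-pair) combination directly
oracle_ar_keys <- function(cohort, panel) {
  ann <- cohort$annotations
  genes <- panel$symbol[panel$inheritance %in% c("AR", "BOTH")]
  cases <- cohort$samples$sample_id[cohort$samples$status == "case" &
                                      cohort$samples$subgroup != "FPD_AD"]
  keys <- character(0)
  for (s in cases) {
    for (g in genes) {
      vs <- which(ann$gene == g & ann$is_deleterious &
                    ann$effective_maf < 0.01)
      for (v in vs) {
        d <- cohort$dosages[s, ann$variant_id[v]]
        if (!is.na(d) && d == 2) {
          keys <- c(keys, paste(s, g, "AR_hom", ann$variant_id[v]))
        }
      }
      hets <- vs[vapply(vs, function(v) {
        d <- cohort$dosages[s, ann$variant_id[v]]
        !is.na(d) && d == 1
      }, logical(1))]
      if (length(hets) >= 2) {
        for (i in seq_len(length(hets) - 1)) {
          for (j in seq(i + 1, length(hets))) {
            ids <- sort(ann$variant_id[c(hets[i], hets[j])])
            keys <- c(keys, paste(s, g, "AR_comphet",
                                  paste(ids, collapse = "+")))
          }
        }
      }
    }
  }
  sort(keys)
}

finding_keys <- function(findings) {
  sort(vapply(seq_len(nrow(findings)), function(i) {
    ids <- sort(strsplit(findings$variant_ids[i], ";", fixed = TRUE)[[1]])
    paste(findings$sample_id[i], findings$gene[i], findings$model[i],
          paste(ids, collapse = "+"))
  }, character(1)))
}

# brute-force ROH SNP-marking oracle (nested loops, no cumulative sums)
oracle_roh_marks <- function(dosage, params) {
  n <- length(dosage)
  w <- params$window_snps
  if (n < w) return(rep(FALSE, n))
  n_win <- n - w + 1
  ok <- logical(n_win)
  for (i in seq_len(n_win)) {
    win <- dosage[i:(i + w - 1)]
    ok[i] <- sum(!is.na(win) & win == 1) <= params$max_het &&
      sum(is.na(win)) <= params$max_missing
  }
  marks <- logical(n)
  for (j in seq_len(n)) {
    wins <- max(1, j - w + 1):min(n_win, j)
    marks[j] <- mean(ok[wins]) >= params$threshold
  }
  marks
}
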
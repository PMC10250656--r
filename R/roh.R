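#' Default runs-of-homozygosity parameters
#'
#' PLINK-style sliding-window defaults: 50-SNP windows, at most 1
#' heterozygous and 5 missing calls per homozygous-compatible window, a SNP
#' is in a run when at least 5% of its overlapping windows are compatible,
#' and reported runs span at least 1 Mb and 50 SNPs.
#'
#' @return Named list of parameters.
#' @export
default_roh_params <- function() {
  list(window_snps = 50L, max_het = 1L, max_missing = 5L,
       threshold = 0.05, min_length_bp = 1e6, min_snps = 50L)
}

#' Detect runs of homozygosity for one sample
#'
#' Sliding-window homozygosity scan in the PLINK style. Windows of
#' `window_snps` consecutive variants are homozygous-compatible when they
#' contain at most `max_het` heterozygous and `max_missing` missing calls.
#' Each SNP is scored by the fraction of windows overlapping it that are
#' compatible; SNPs at or above `threshold` are marked, and maximal runs of
#' marked SNPs spanning at least `min_length_bp` (end minus start) and
#' `min_snps` variants are reported. Chromosomes with fewer variants than
#' one window yield no calls.
#'
#' @param variants data.frame with `chrom` and `pos`, sorted by (chrom, pos).
#' @param dosages Numeric vector of this sample's dosages (0/1/2/NA) aligned
#'   to `variants`.
#' @param params Parameter list, see [default_roh_params()].
#' @param sample_id Label copied into the output.
#' @return data.frame with columns `sample_id`, `chrom`, `start`, `end`
#'   (1-based, closed), `n_snps`, `length_bp`, `length_mb`.
#' @export
detect_roh <- function(variants, dosages, params = default_roh_params(),
                       sample_id = NA_character_) {
  stopifnot(length(dosages) == nrow(variants))
  out <- list()
  for (chrom in unique(variants$chrom)) {
    sel <- which(variants$chrom == chrom)
    pos <- variants$pos[sel]
    if (is.unsorted(pos, strictly = FALSE)) {
      stop("variants on ", chrom, " are not position-sorted", call. = FALSE)
    }
    d <- dosages[sel]
    n <- length(d)
    w <- params$window_snps
    if (n < w) next
    het <- !is.na(d) & d == 1
    mis <- is.na(d)
    # window i covers SNPs i..i+w-1; compatible iff few hets and missing
    cum_het <- c(0, cumsum(het))
    cum_mis <- c(0, cumsum(mis))
    n_win <- n - w + 1L
    starts <- seq_len(n_win)
    win_ok <- (cum_het[starts + w] - cum_het[starts]) <= params$max_het &
      (cum_mis[starts + w] - cum_mis[starts]) <= params$max_missing
    # per-SNP fraction of overlapping windows that are compatible
    cum_ok <- c(0, cumsum(win_ok))
    snp_idx <- seq_len(n)
    lo <- pmax(1L, snp_idx - w + 1L)
    hi <- pmin(n_win, snp_idx)
    n_overlap <- hi - lo + 1L
    n_ok <- cum_ok[hi + 1L] - cum_ok[lo]
    marked <- n_overlap > 0L & (n_ok / n_overlap) >= params$threshold
    # maximal runs of marked SNPs
    r <- rle(marked)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1L
    for (k in which(r$values)) {
      i1 <- starts_i[k]; i2 <- ends_i[k]
      len_bp <- pos[i2] - pos[i1]
      n_snps <- i2 - i1 + 1L
      if (len_bp >= params$min_length_bp && n_snps >= params$min_snps) {
        out[[length(out) + 1L]] <- data.frame(
          sample_id = sample_id, chrom = chrom,
          start = pos[i1], end = pos[i2], n_snps = n_snps,
          length_bp = len_bp, length_mb = len_bp / 1e6,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(sample_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_snps = integer(0), length_bp = numeric(0),
                      length_mb = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Detect runs of homozygosity for every sample in a cohort
#'
#' @param cohort A `cohort_data`.
#' @param params Parameter list, see [default_roh_params()].
#' @param samples Optional character vector restricting which samples are
#'   scanned (default: all case samples).
#' @return Combined data.frame of intervals across samples.
#' @export
detect_roh_cohort <- function(cohort, params = default_roh_params(),
                              samples = NULL) {
  stopifnot(inherits(cohort, "cohort_data"))
  if (is.null(samples)) {
    samples <- cohort$samples$sample_id[cohort$samples$status == "case"]
  }
  ord <- order(cohort$variants$chrom, cohort$variants$pos)
  variants <- cohort$variants[ord, , drop = FALSE]
  res <- lapply(samples, function(s) {
    detect_roh(variants, cohort$dosages[s, ord], params, sample_id = s)
  })
  do.call(rbind, res)
}

#' Locate a variant inside detected ROH intervals
#'
#' @param chrom,pos Variant coordinate (1-based).
#' @param intervals ROH data.frame from [detect_roh()] (one sample's
#'   intervals).
#' @return The containing interval row (chromosome match and
#'   `start <= pos <= end`, closed ends), or `NULL` when the variant lies in
#'   no interval.
#' @export
variant_in_roh <- function(chrom, pos, intervals) {
  hit <- which(intervals$chrom == chrom & intervals$start <= pos &
                 intervals$end >= pos)
  if (length(hit) == 0L) return(NULL)
  intervals[hit[1], , drop = FALSE]
}
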
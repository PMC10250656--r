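#' Load a gene panel with inheritance modes
#'
#' Reads a two-column tab-separated panel definition (`symbol<TAB>inheritance`)
#' into a validated `gene_panel` object. Inheritance tokens are matched
#' case-insensitively against `AR` (autosomal recessive), `AD` (autosomal
#' dominant) and `BOTH` (genes with reports of both inheritance patterns in
#' dystonia). Gene symbols are trimmed of surrounding whitespace but otherwise
#' treated as opaque, case-sensitive join keys.
#'
#' @param source Path to a panel TSV, or a data.frame with columns
#'   `symbol` and `inheritance`.
#' @param name Free-text panel name.
#' @param extra_genes Optional data.frame (`symbol`, `inheritance`) of genes to
#'   append to the loaded panel.
#' @return A `gene_panel`: a data.frame with columns `symbol` (character) and
#'   `inheritance` (factor with levels AR/AD/BOTH), row order as in `source`.
#' @examples
#' panel <- dyt_panel()
#' nrow(panel)
#' panel_summary(panel)
#' @export
load_panel <- function(source, name = NULL, extra_genes = NULL) {
  if (is.character(source) && length(source) == 1L) {
    if (!file.exists(source)) {
      stop("panel file not found: ", source, call. = FALSE)
    }
    df <- utils::read.delim(source, header = TRUE, sep = "\t",
                            colClasses = "character", quote = "")
    if (is.null(name)) name <- basename(source)
  } else if (is.data.frame(source)) {
    df <- source
    if (is.null(name)) name <- "inline panel"
  } else {
    stop("source must be a file path or a data.frame", call. = FALSE)
  }
  if (!all(c("symbol", "inheritance") %in% names(df))) {
    stop("panel must have columns 'symbol' and 'inheritance'", call. = FALSE)
  }
  if (!is.null(extra_genes)) {
    df <- rbind(df[, c("symbol", "inheritance")],
                extra_genes[, c("symbol", "inheritance")])
  }
  if (nrow(df) == 0L) {
    stop("panel is empty: no genes defined", call. = FALSE)
  }

  symbol <- trimws(as.character(df$symbol))
  inh_raw <- trimws(as.character(df$inheritance))
  inh <- toupper(inh_raw)

  bad <- which(!inh %in% c("AR", "AD", "BOTH"))
  if (length(bad) > 0L) {
    stop(sprintf("unknown inheritance token '%s' at panel row %d",
                 inh_raw[bad[1]], bad[1]), call. = FALSE)
  }
  if (any(!nzchar(symbol))) {
    stop("empty gene symbol at panel row ", which(!nzchar(symbol))[1],
         call. = FALSE)
  }
  dup <- symbol[duplicated(symbol)]
  if (length(dup) > 0L) {
    stop("duplicate gene symbol in panel: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }

  panel <- data.frame(symbol = symbol,
                      inheritance = factor(inh, levels = c("AR", "AD", "BOTH")),
                      stringsAsFactors = FALSE)
  attr(panel, "panel_name") <- name
  class(panel) <- c("gene_panel", "data.frame")
  panel
}

#' Default DYT gene panel
#'
#' The package's shipped panel of 47 autosomal dystonia-related genes:
#' 19 autosomal recessive, 25 autosomal dominant, and 3 genes (VPS16, SPR,
#' ADCY5) with both inheritance patterns reported. GCH1 is deliberately not a
#' member; use `extra_genes` to add genes.
#'
#' @inheritParams load_panel
#' @return A `gene_panel` of 47 genes (more if `extra_genes` is given).
#' @export
dyt_panel <- function(extra_genes = NULL) {
  path <- system.file("extdata", "dyt_panel.tsv", package = "dytburden",
                      mustWork = TRUE)
  load_panel(path, name = "DYT-47", extra_genes = extra_genes)
}

#' Count panel genes by inheritance mode
#'
#' @param panel A `gene_panel`.
#' @return Named integer vector with elements `AR`, `AD`, `BOTH`; the values
#'   sum to `nrow(panel)`.
#' @export
panel_summary <- function(panel) {
  stopifnot(inherits(panel, "gene_panel"))
  tab <- table(panel$inheritance)
  c(AR = as.integer(tab[["AR"]]),
    AD = as.integer(tab[["AD"]]),
    BOTH = as.integer(tab[["BOTH"]]))
}

#' Panel genes evaluated under a given inheritance model
#'
#' Genes flagged `BOTH` participate in both the recessive and the dominant
#' prioritization passes.
#'
#' @param panel A `gene_panel`.
#' @param model `"AR"` or `"AD"`.
#' @return Character vector of gene symbols.
#' @export
panel_genes_for_model <- function(panel, model = c("AR", "AD")) {
  model <- match.arg(model)
  panel$symbol[panel$inheritance %in% c(model, "BOTH")]
}

#' @export
print.gene_panel <- function(x, ...) {
  cnt <- panel_summary(x)
  cat(sprintf("<gene_panel '%s': %d genes (AR %d, AD %d, BOTH %d)>\n",
              attr(x, "panel_name"), nrow(x), cnt["AR"], cnt["AD"], cnt["BOTH"]))
  invisible(x)
}
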
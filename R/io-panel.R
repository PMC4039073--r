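#' Genes whose focal amplifications are validated by immunohistochemistry
#'
#' Focal gains/amplifications of these genes can be checked at the
#' protein level, so qualifying events trigger an automatic request to
#' the pathologists.
#'
#' @return Character vector of gene symbols.
#' @export
ihc_validatable_genes <- function() {
  c("ALK", "BRAF", "EGFR", "ERBB2", "KIT", "MET", "PDGFRA", "PDGFRB", "PTEN")
}

.pathways <- c("HORMONE_RECEPTOR", "PI3K_AKT_MTOR", "MAPK", "OTHER")

#' Read a gene panel from a BED-plus file
#'
#' The panel file is BED with three extra columns:
#' `chrom start end symbol pathway ihc_flag`, coordinates 0-based
#' half-open as in BED. `pathway` is one of HORMONE_RECEPTOR,
#' PI3K_AKT_MTOR, MAPK, OTHER; `ihc_flag` is 0/1.
#'
#' @param path Panel file path.
#' @return data.frame with columns `symbol`, `chrom`, `start`, `end`,
#'   `pathway`, `ihc_validatable` (logical), `in_panel` (all TRUE);
#'   class `gene_panel`.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "symbol",
                                        "pathway", "ihc_flag"))
  if (!nrow(df)) stop("empty panel: ", path)
  df$chrom <- sub("^chr", "", as.character(df$chrom))
  bad <- setdiff(unique(df$chrom), assembly_chromosomes())
  if (length(bad)) stop("unknown chromosome(s) in panel: ", paste(bad, collapse = ", "))
  if (any(df$start < 0 | df$start >= df$end)) {
    stop("invalid panel interval (require start < end), first bad symbol: ",
         df$symbol[which(df$start >= df$end)[1]])
  }
  dup <- df$symbol[duplicated(df$symbol)]
  if (length(dup)) stop("duplicate gene symbol(s) in panel: ", paste(unique(dup), collapse = ", "))
  badp <- setdiff(unique(df$pathway), .pathways)
  if (length(badp)) stop("unknown pathway(s): ", paste(badp, collapse = ", "))
  panel <- data.frame(symbol = df$symbol, chrom = df$chrom,
                      start = df$start, end = df$end, pathway = df$pathway,
                      ihc_validatable = as.logical(as.integer(df$ihc_flag)),
                      in_panel = TRUE, stringsAsFactors = FALSE)
  class(panel) <- c("gene_panel", "data.frame")
  panel
}

#' The bundled default 76-gene panel
#'
#' A constructed stand-in panel of 76 well-known cancer genes covering
#' the hormone-receptor, PI3K/AKT/mTOR and MAP-kinase pathways, with
#' approximate hg19 coordinates (the file is labelled synthetic: it is
#' representative, not a published assay design). Its IHC-validatable
#' set is exactly [ihc_validatable_genes()].
#'
#' @return A `gene_panel` data.frame with 76 rows.
#' @export
default_panel <- function() {
  path <- system.file("extdata", "synthetic_panel_76.bed", package = "mtbpipe",
                      mustWork = TRUE)
  read_panel(path)
}

#' Write a gene panel in BED-plus format
#'
#' @param panel A `gene_panel` data.frame as returned by [read_panel()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_panel <- function(panel, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%d",
                   panel$chrom, as.integer(panel$start), as.integer(panel$end),
                   panel$symbol, panel$pathway, as.integer(panel$ihc_validatable))
  writeLines(lines, path)
  invisible(path)
}
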
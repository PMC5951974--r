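# SNP catalog I/O and annotation tallies. The catalog is a TSV with the
# column set SNP_ID, Genome_pos, Mut_type, Mut_base, Mut_pro, Ref_Gene,
# Product, COG_categories, KO_No., Pathway_No. (plus an optional Verified
# passthrough column); "-" or empty marks a missing annotation.

.CATALOG_COLS <- c("SNP_ID", "Genome_pos", "Mut_type", "Mut_base", "Mut_pro",
                   "Ref_Gene", "Product", "COG_categories", "KO_No.",
                   "Pathway_No.")

.canon_mut_type <- function(x) {
  m <- c("syn" = "synonymous", "synonymous" = "synonymous",
         "non-syn" = "non-synonymous", "nonsyn" = "non-synonymous",
         "non-synonymous" = "non-synonymous",
         "nonsense" = "nonsense", "intergenic" = "intergenic")
  m[tolower(trimws(x))]
}

.is_blank <- function(x) is.na(x) | x %in% c("", "-", "–", "—")

#' Load a SNP catalog
#'
#' @param path TSV path (see package notes for the column set). The bundled
#'   example lives at
#'   `system.file("extdata", "snp_catalog.tsv", package = "hostdrift")`.
#' @return data.frame of class `snp_catalog`, with parsed helper columns
#'   `mut_type` (canonical token), `ref_base`, `alt_base`.
#' @export
load_snp_catalog <- function(path) {
  x <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  miss <- setdiff(.CATALOG_COLS, names(x))
  if (length(miss)) stop("catalog lacks columns: ", paste(miss, collapse = ", "))
  pos <- suppressWarnings(as.integer(x$Genome_pos))
  if (anyNA(pos))
    stop("non-integer Genome_pos at catalog row ", which(is.na(pos))[1L])
  mt <- .canon_mut_type(x$Mut_type)
  if (anyNA(mt))
    stop("bad Mut_type token at catalog row ", which(is.na(mt))[1L],
         " ('", x$Mut_type[which(is.na(mt))[1L]], "')")
  ba <- strsplit(x$Mut_base, "-", fixed = TRUE)
  if (any(lengths(ba) != 2L))
    stop("bad Mut_base at catalog row ", which(lengths(ba) != 2L)[1L])
  x$Genome_pos <- pos
  x$mut_type <- unname(mt)
  x$ref_base <- toupper(vapply(ba, `[`, "", 1L))
  x$alt_base <- toupper(vapply(ba, `[`, "", 2L))
  class(x) <- c("snp_catalog", "data.frame")
  x
}

#' Tally a SNP catalog
#'
#' Reproduces the headline bookkeeping of a catalog: total SNPs, counts per
#' effect class, distinct genes among non-intergenic SNPs, genes with COG /
#' KO annotations, and the number of distinct pathway identifiers parsed
#' from bracketed lists such as `Metabolism[PATH:ko00052,ko00520]`.
#'
#' @param catalog a [load_snp_catalog()] result (or empty data.frame).
#' @return list of class `catalog_tally`.
#' @export
tally_snp_catalog <- function(catalog) {
  if (nrow(catalog) == 0L) {
    return(structure(list(n_snps = 0L,
                          by_type = c(synonymous = 0L, `non-synonymous` = 0L,
                                      nonsense = 0L, intergenic = 0L),
                          n_genes = 0L, n_cog_genes = 0L, n_ko_genes = 0L,
                          n_pathways = 0L, pathway_ids = character(0)),
                     class = "catalog_tally"))
  }
  types <- c("synonymous", "non-synonymous", "nonsense", "intergenic")
  by_type <- vapply(types, function(t) sum(catalog$mut_type == t), 0L)
  coding <- catalog[catalog$mut_type != "intergenic", , drop = FALSE]
  genes <- unique(coding$Ref_Gene[!.is_blank(coding$Ref_Gene)])
  cog_genes <- unique(coding$Ref_Gene[!.is_blank(coding$COG_categories)])
  ko_genes <- unique(coding$Ref_Gene[!.is_blank(coding$`KO_No.`)])
  pw <- unlist(regmatches(catalog$`Pathway_No.`,
                          gregexpr("ko[0-9]+", catalog$`Pathway_No.`)))
  structure(list(n_snps = nrow(catalog), by_type = by_type,
                 n_genes = length(genes), n_cog_genes = length(cog_genes),
                 n_ko_genes = length(ko_genes),
                 n_pathways = length(unique(pw)),
                 pathway_ids = sort(unique(pw))),
            class = "catalog_tally")
}

#' @export
print.catalog_tally <- function(x, ...) {
  cat("SNP catalog:", x$n_snps, "SNPs (",
      paste(sprintf("%d %s", x$by_type, names(x$by_type)), collapse = ", "),
      ")\n")
  cat("  distinct genes (non-intergenic):", x$n_genes,
      "| COG-annotated:", x$n_cog_genes, "| KO-assigned:", x$n_ko_genes,
      "| pathways:", x$n_pathways, "\n")
  invisible(x)
}

#' Write annotated SNP records in catalog (TSV) format
#' @param snps records from [annotate_effect()].
#' @param path output TSV.
#' @export
write_snp_catalog <- function(snps, path) {
  disp_type <- c(synonymous = "Syn", `non-synonymous` = "Non-syn",
                 nonsense = "Nonsense", intergenic = "Intergenic")
  blank <- function(x) ifelse(nzchar(x), x, "-")
  tab <- data.frame(
    SNP_ID = snps$snp_id,
    Genome_pos = snps$genome_pos,
    Mut_type = disp_type[snps$mut_type],
    Mut_base = paste0(snps$ref_base, "-", snps$alt_base),
    Mut_pro = blank(snps$protein_change),
    Ref_Gene = blank(snps$gene_id),
    Product = blank(snps$product),
    COG_categories = blank(snps$cog),
    `KO_No.` = blank(snps$ko),
    `Pathway_No.` = blank(snps$pathways),
    check.names = FALSE
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
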
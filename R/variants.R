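# SNP identification from contig-vs-reference alignments, the three
# retention filters (call quality > 20, pair depth > 10, non-repeat), and
# codon-level effect classification under the bacterial genetic code.

#' Bacterial genetic code (translation table 11)
#' @return named character vector, codon -> amino acid (`*` = stop).
#' @export
bacterial_code <- function() Biostrings::getGeneticCode("11")

# Greedy mutually-exclusive block selection: hits accepted by descending
# score unless they overlap an accepted hit by more than `overlap_tol` bp on
# the query or the subject axis (delta-filter-like 1-to-1 policy).
one_to_one_blocks <- function(hits, overlap_tol = 20L) {
  if (!nrow(hits)) return(hits)
  segs <- attr(hits, "segments")
  acc <- logical(nrow(hits))
  ovl <- function(a1, a2, b1, b2) pmax(0L, pmin(a2, b2) - pmax(a1, b1) + 1L)
  for (i in seq_len(nrow(hits))) {  # already score-sorted
    h <- hits[i, ]
    prev <- which(acc)
    bad <- FALSE
    for (j in prev) {
      g <- hits[j, ]
      if (g$query_id == h$query_id &&
          ovl(g$qstart, g$qend, h$qstart, h$qend) > overlap_tol) { bad <- TRUE; break }
      if (g$subject_id == h$subject_id &&
          ovl(g$sstart, g$send, h$sstart, h$send) > overlap_tol) { bad <- TRUE; break }
    }
    acc[i] <- !bad
  }
  out <- hits[acc, , drop = FALSE]
  attr(out, "segments") <- segs[acc]
  class(out) <- class(hits)
  out
}

#' Call candidate SNPs from contigs aligned to the reference
#'
#' Aligns contigs to the reference, reduces hits to mutually-best 1-to-1
#' blocks, and emits one candidate per mismatch column (indel columns are
#' ignored: substitutions only). Candidates sharing coordinate and alleles
#' (e.g. from overlapping contigs) are deduplicated.
#'
#' @param contigs named character vector of contig sequences.
#' @param reference a `ReferenceGenome` or named character vector.
#' @param min_identity,max_evalue alignment thresholds (defaults 90 / 1e-5).
#' @param overlap_tol tolerated 1-to-1 block overlap in bp (default 20).
#' @param k seed k-mer length.
#' @return data.frame with `replicon_id`, `pos`, `ref_base`, `alt_base`,
#'   `n_contigs` (supporting contigs), sorted by position.
#' @export
call_raw_snps <- function(contigs, reference, min_identity = 90,
                          max_evalue = 1e-5, overlap_tol = 20L, k = 15L) {
  reps <- .as_replicons(reference)
  hits <- local_align(contigs, reps, min_identity = min_identity,
                      max_evalue = max_evalue, k = k)
  blocks <- one_to_one_blocks(hits, overlap_tol)
  segs <- attr(blocks, "segments")
  ref_ints <- lapply(reps, dna_to_int)

  cand <- list()
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    qseq <- contigs[[b$query_id]]
    if (b$strand == "-") qseq <- revcomp(qseq)
    qi <- dna_to_int(qseq)
    si <- ref_ints[[b$subject_id]]
    sg <- segs[[i]]
    for (s in seq_len(nrow(sg))) {
      qa <- qi[sg$qstart[s]:(sg$qstart[s] + sg$length[s] - 1L)]
      sa <- si[sg$sstart[s]:(sg$sstart[s] + sg$length[s] - 1L)]
      d <- which(qa != sa & qa < 4L & sa < 4L)
      if (length(d)) {
        cand[[length(cand) + 1L]] <- data.frame(
          replicon_id = b$subject_id,
          pos = sg$sstart[s] + d - 1L,
          ref_base = substring(.int_chr_str(), sa[d] + 1L, sa[d] + 1L),
          alt_base = substring(.int_chr_str(), qa[d] + 1L, qa[d] + 1L)
        )
      }
    }
  }
  if (!length(cand)) {
    return(data.frame(replicon_id = character(0), pos = integer(0),
                      ref_base = character(0), alt_base = character(0),
                      n_contigs = integer(0)))
  }
  x <- do.call(rbind, cand)
  key <- paste(x$replicon_id, x$pos, x$ref_base, x$alt_base)
  n_sup <- table(key)
  x <- x[!duplicated(key), , drop = FALSE]
  x$n_contigs <- as.integer(n_sup[paste(x$replicon_id, x$pos, x$ref_base, x$alt_base)])
  x <- x[order(x$replicon_id != "chromosome", x$replicon_id, x$pos), , drop = FALSE]
  rownames(x) <- NULL
  x
}

.int_chr_str <- function() "ACGTN"

#' Build a repeat mask by reference self-alignment
#'
#' A position is masked iff it lies in a self-alignment hit (reference
#' against itself, the trivial identity diagonal excluded) with identity
#' >= `min_identity` and length >= `min_length` - this captures the
#' multi-copy rRNA loci and the plasmid-chromosome homologous segments.
#'
#' @param reference `ReferenceGenome` or named character vector.
#' @param min_identity percent identity threshold (default 95).
#' @param min_length minimum repeat length in bp (default 100).
#' @param k seed k-mer length.
#' @return data.frame of class `repeat_mask` (`replicon_id`, `start`,
#'   `end`), merged and sorted.
#' @export
build_repeat_mask <- function(reference, min_identity = 95, min_length = 100L,
                              k = 15L) {
  reps <- .as_replicons(reference)
  iv <- list()
  add <- function(rep_id, s, e) {
    iv[[length(iv) + 1L]] <<- data.frame(replicon_id = rep_id,
                                         start = as.integer(s),
                                         end = as.integer(e))
  }
  nm <- names(reps)
  for (i in seq_along(reps)) {
    for (j in i:length(reps)) {
      hits <- local_align(reps[i], reps[j], min_identity = min_identity,
                          max_evalue = 1e-5, k = k, min_length = min_length,
                          exclude_self_diagonal = (i == j))
      hits <- hits[hits$length >= min_length, , drop = FALSE]
      for (r in seq_len(nrow(hits))) {
        add(nm[i], hits$qstart[r], hits$qend[r])
        add(nm[j], hits$sstart[r], hits$send[r])
      }
    }
  }
  if (!length(iv)) {
    out <- data.frame(replicon_id = character(0), start = integer(0),
                      end = integer(0))
  } else {
    x <- do.call(rbind, iv)
    out <- do.call(rbind, lapply(split(x, x$replicon_id), function(g) {
      m <- merge_intervals(g[, c("start", "end")])
      data.frame(replicon_id = g$replicon_id[1L], m)
    }))
    rownames(out) <- NULL
  }
  class(out) <- c("repeat_mask", "data.frame")
  out
}

#' Filter candidate SNPs by call quality, pair depth and repeat status
#'
#' Retention requires `quality > min_quality` AND `depth > min_depth`
#' (strict inequalities) AND the position lying outside the repeat mask.
#'
#' @param candidates data.frame with `quality` and `depth` columns (see
#'   [snp_support()]).
#' @param repeat_mask a [build_repeat_mask()] result.
#' @param min_quality Phred quality threshold (default 20, exclusive).
#' @param min_depth read-pair depth threshold (default 10, exclusive).
#' @return retained candidates; attribute `"rejected"` holds the removed
#'   rows with a `reason` column.
#' @export
filter_snps <- function(candidates, repeat_mask, min_quality = 20,
                        min_depth = 10) {
  if (!nrow(candidates)) return(candidates)
  if (is.null(candidates$quality) || is.null(candidates$depth))
    stop("candidates lack quality/depth columns; run snp_support() first")
  in_rep <- logical(nrow(candidates))
  for (rn in unique(candidates$replicon_id)) {
    sel <- candidates$replicon_id == rn
    mk <- repeat_mask[repeat_mask$replicon_id == rn, c("start", "end"), drop = FALSE]
    in_rep[sel] <- positions_in_intervals(candidates$pos[sel], mk)
  }
  ok <- candidates$quality > min_quality & candidates$depth > min_depth & !in_rep
  reason <- ifelse(in_rep, "repeat",
                   ifelse(candidates$depth <= min_depth, "depth",
                          ifelse(candidates$quality <= min_quality, "quality", "")))
  out <- candidates[ok, , drop = FALSE]
  rej <- candidates[!ok, , drop = FALSE]
  if (nrow(rej)) rej$reason <- reason[!ok]
  attr(out, "rejected") <- rej
  rownames(out) <- NULL
  out
}

#' Codon-level effect of a substitution
#'
#' Classifies a substitution against a set of gene models on one replicon:
#' inside a CDS the affected codon is mutated respecting strand and frame
#' and translated with the bacterial code; outside all genes the call is
#' intergenic. Protein change is written `refAA` + codon index + `altAA`,
#' with `X` for a stop (e.g. `Q808X`).
#'
#' @param sequence replicon sequence (character string).
#' @param gene_models data.frame with `gene_id`, `start`, `end`, `strand`
#'   (CDS length must be a multiple of 3).
#' @param pos 1-based position of the substitution.
#' @param ref_base,alt_base alleles on the reference strand.
#' @param code genetic code (default [bacterial_code()]).
#' @return list with `mut_type`, `protein_change`, `gene_id`, `codon_index`.
#' @export
snp_effect <- function(sequence, gene_models, pos, ref_base, alt_base,
                       code = bacterial_code()) {
  if (pos < 1L || pos > nchar(sequence))
    stop("position ", pos, " outside replicon (length ", nchar(sequence), ")")
  if (ref_base == alt_base) stop("ref and alt alleles are identical")
  g <- gene_models[gene_models$start <= pos & gene_models$end >= pos, , drop = FALSE]
  if (!nrow(g)) {
    return(list(mut_type = "intergenic", protein_change = "",
                gene_id = "", codon_index = NA_integer_))
  }
  g <- g[1L, ]
  glen <- g$end - g$start + 1L
  if (glen %% 3L != 0L)
    stop("CDS ", g$gene_id, " length not a multiple of 3")
  off <- if (g$strand == "+") pos - g$start + 1L else g$end - pos + 1L
  ci <- (off - 1L) %/% 3L + 1L
  if (g$strand == "+") {
    cs <- g$start + 3L * (ci - 1L)
    codon_ref <- substr(sequence, cs, cs + 2L)
    within <- pos - cs + 1L
    codon_alt <- codon_ref
    substr(codon_alt, within, within) <- alt_base
  } else {
    ce <- g$end - 3L * (ci - 1L)
    codon_ref <- revcomp(substr(sequence, ce - 2L, ce))
    within <- ce - pos + 1L
    codon_alt <- codon_ref
    substr(codon_alt, within, within) <- chartr("ACGT", "TGCA", alt_base)
  }
  aa_ref <- unname(code[codon_ref])
  aa_alt <- unname(code[codon_alt])
  disp <- function(a) if (a == "*") "X" else a
  mut_type <- if (aa_ref == aa_alt) "synonymous"
    else if (aa_alt == "*") "nonsense"
    else "non-synonymous"
  list(mut_type = mut_type,
       protein_change = paste0(disp(aa_ref), ci, disp(aa_alt)),
       gene_id = g$gene_id, codon_index = ci)
}

#' Annotate filtered SNPs with effect class and gene context
#'
#' @param reference a `ReferenceGenome`.
#' @param snps data.frame of filtered candidates (`replicon_id`, `pos`,
#'   `ref_base`, `alt_base`, optionally `depth`/`quality`).
#' @return data.frame of SNP records: `snp_id`, `replicon_id`, `genome_pos`,
#'   `mut_type`, `ref_base`, `alt_base`, `protein_change`, `gene_id`,
#'   `product`, `cog`, `ko`, `pathways`, `depth`, `quality`.
#' @export
annotate_effect <- function(reference, snps) {
  n <- nrow(snps)
  cols <- c("mut_type", "protein_change", "gene_id", "product", "cog", "ko", "pathways")
  out <- snps
  for (cl in cols) out[[cl]] <- character(n)
  for (i in seq_len(n)) {
    rn <- snps$replicon_id[i]
    gm <- reference$gene_models[reference$gene_models$replicon_id == rn, , drop = FALSE]
    e <- snp_effect(reference$replicons[[rn]], gm, snps$pos[i],
                    snps$ref_base[i], snps$alt_base[i])
    out$mut_type[i] <- e$mut_type
    out$protein_change[i] <- e$protein_change
    out$gene_id[i] <- e$gene_id
    if (nzchar(e$gene_id)) {
      gi <- gm[gm$gene_id == e$gene_id, ]
      out$product[i] <- gi$product
      out$cog[i] <- gi$cog
      out$ko[i] <- gi$ko
      out$pathways[i] <- gi$pathways
    }
  }
  out$snp_id <- sprintf("SNP%02d", seq_len(n))
  out$genome_pos <- out$pos
  keep <- c("snp_id", "replicon_id", "genome_pos", "mut_type", "ref_base",
            "alt_base", "protein_change", "gene_id", "product", "cog", "ko",
            "pathways", intersect(c("depth", "quality"), names(out)))
  out[, keep]
}

#' Export SNP records as a minimal VCF 4.2
#' @param snps annotated SNP records ([annotate_effect()]).
#' @param reference a `ReferenceGenome` (for contig headers).
#' @param path output file.
#' @export
write_snps_vcf <- function(snps, reference, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", names(reference$replicons),
                       nchar(reference$replicons)),
               "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Supporting read pairs\">",
               "##INFO=<ID=EFF,Number=1,Type=String,Description=\"Effect class\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(snps)) {
    dp <- if (!is.null(snps$depth)) snps$depth else "."
    q <- if (!is.null(snps$quality)) sprintf("%.0f", snps$quality) else "."
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t%s\tPASS\tDP=%s;EFF=%s",
                       snps$replicon_id, snps$genome_pos, snps$snp_id,
                       snps$ref_base, snps$alt_base, q, dp, snps$mut_type), con)
  }
  invisible(path)
}
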
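# Synthetic multi-replicon reference genome: one chromosome plus seven
# plasmids, near-identical multi-copy 23S-like rRNA genes, and
# plasmid<->chromosome homologous segments. Emulates the architecture of a
# 3 Mb-class Lactobacillus genome at a configurable desk scale.

.PRODUCT_VOCAB <- c(
  "membrane protein", "phosphatidic acid phosphatase", "epimerase",
  "hypothetical protein", "phosphohydrolase", "amino acid aminotransferase",
  "23S rRNA methyltransferase", "1-deoxy-D-xylulose-5-phosphate synthase",
  "ribonucleotide reductase assembly protein", "orotidine 5'-phosphate decarboxylase",
  "cell wall anchor protein", "oligoendopeptidase", "excinuclease ABC subunit A",
  "ABC transporter permease", "ABC exporter subunit", "GTP-binding protein",
  "galactosidase", "sugar transporter", "dihydroxyacetone kinase", "transposase"
)

#' Reference genome configuration
#'
#' Desk-scale defaults: a 200 kb chromosome at 44.5% GC carrying five
#' near-identical 2923-bp 23S-like rRNA copies, and seven plasmids of 5-60 kb,
#' three of which (p2, p4, p7) carry large segments homologous to the
#' chromosome at ~95% identity.
#'
#' @param chromosome_length chromosome size in bp (>= 30 kb).
#' @param gc target GC fraction, in (0.2, 0.8).
#' @param n_rrna number of rRNA copies (default 5).
#' @param rrna_length rRNA gene length in bp (default 2923).
#' @param plasmids data.frame with columns `id`, `length`,
#'   `homology_fraction` (fraction of the plasmid homologous to the
#'   chromosome), `n_genes`.
#' @param gene_length_range CDS length range in bp (rounded to codons).
#' @param intergenic_range intergenic spacer length range in bp.
#' @param homology_identity identity of plasmid-chromosome homologous
#'   segments (default 0.95; must be >= 0.90).
#' @return list of class `ref_config`.
#' @export
ref_config <- function(chromosome_length = 200000L,
                       gc = 0.445,
                       n_rrna = 5L,
                       rrna_length = 2923L,
                       plasmids = default_plasmid_specs(),
                       gene_length_range = c(300L, 3000L),
                       intergenic_range = c(50L, 300L),
                       homology_identity = 0.95) {
  cfg <- list(
    chromosome_length = as.integer(chromosome_length), gc = gc,
    n_rrna = as.integer(n_rrna), rrna_length = as.integer(rrna_length),
    plasmids = plasmids, gene_length_range = as.integer(gene_length_range),
    intergenic_range = as.integer(intergenic_range),
    homology_identity = homology_identity
  )
  class(cfg) <- "ref_config"
  cfg
}

#' Default seven-plasmid specification
#' @return data.frame of plasmid id, length, homology_fraction, n_genes.
#' @export
default_plasmid_specs <- function() {
  data.frame(
    id = paste0("p", 1:7),
    length = c(60000L, 35000L, 25000L, 20000L, 12000L, 8000L, 5000L),
    homology_fraction = c(0, 0.5, 0, 0.5, 0, 0, 0.5),
    n_genes = c(15L, 10L, 8L, 8L, 4L, 3L, 2L)
  )
}

#' Compact configuration for fast simulations
#'
#' Same architecture as [ref_config()] at roughly half the sequence volume
#' (80 kb chromosome, 54 kb of plasmids); used for read-level simulation
#' studies where total throughput matters more than genome size.
#' @export
compact_ref_config <- function() {
  ref_config(
    chromosome_length = 80000L,
    plasmids = data.frame(
      id = paste0("p", 1:7),
      length = c(18000L, 12000L, 6000L, 10000L, 5000L, 5000L, 8000L),
      homology_fraction = c(0, 0.5, 0, 0.5, 0, 0, 0.5),
      n_genes = c(6L, 4L, 3L, 3L, 2L, 2L, 2L)
    )
  )
}

# Sample one CDS of `len` bp (multiple of 3): ATG start, non-stop internal
# codons weighted toward the GC target, one terminal stop codon.
.sample_cds <- function(len, gc) {
  stopifnot(len %% 3L == 0L, len >= 9L)
  codons <- apply(expand.grid(.BASES, .BASES, .BASES, stringsAsFactors = FALSE),
                  1L, function(r) paste0(r[3L], r[2L], r[1L]))
  stops <- c("TAA", "TAG", "TGA")
  ok <- setdiff(codons, stops)
  w_base <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  w <- vapply(ok, function(cd) prod(w_base[strsplit(cd, "")[[1L]]]), numeric(1))
  n_mid <- len / 3L - 2L
  mid <- sample(ok, n_mid, replace = TRUE, prob = w)
  paste0("ATG", paste(mid, collapse = ""), sample(stops, 1L))
}

.rand_range <- function(rng) sample(rng[1L]:rng[2L], 1L)

# Lay out one replicon: alternating intergenic spacers and CDS features;
# rRNA copies (chromosome only) are dropped in at evenly spread anchors.
# Returns sequence string plus gene/rRNA coordinate tables.
.layout_replicon <- function(id, len, cfg, n_genes = Inf, rrna_seqs = NULL,
                             reserve_tail = 0L) {
  pieces <- character(0)
  genes <- list()
  rrnas <- list()
  pos <- 1L
  usable <- len - reserve_tail
  n_r <- length(rrna_seqs)
  anchors <- if (n_r) as.integer(round(usable * (seq_len(n_r) - 0.5) / n_r)) else integer(0)
  next_r <- 1L
  g <- 0L
  repeat {
    gap <- .rand_range(cfg$intergenic_range)
    pieces <- c(pieces, random_dna(gap, cfg$gc))
    pos <- pos + gap
    if (next_r <= n_r && pos >= anchors[next_r] - cfg$rrna_length) {
      rs <- rrna_seqs[[next_r]]
      if (pos + nchar(rs) - 1L > usable) break
      pieces <- c(pieces, rs)
      rrnas[[next_r]] <- data.frame(replicon_id = id, start = pos,
                                    end = pos + nchar(rs) - 1L,
                                    strand = sample(c("+", "-"), 1L))
      pos <- pos + nchar(rs)
      next_r <- next_r + 1L
      next
    }
    if (g >= n_genes) {
      if (pos > usable - cfg$gene_length_range[1L]) break
      # gene budget exhausted: pad with intergenic sequence
      pad <- min(500L, usable - pos + 1L)
      pieces <- c(pieces, random_dna(pad, cfg$gc))
      pos <- pos + pad
      if (pos > usable) break
      next
    }
    glen <- 3L * (.rand_range(cfg$gene_length_range) %/% 3L)
    glen <- max(glen, 300L)
    if (pos + glen - 1L > usable) break
    cds <- .sample_cds(glen, cfg$gc)
    strand <- sample(c("+", "-"), 1L)
    pieces <- c(pieces, if (strand == "+") cds else revcomp(cds))
    g <- g + 1L
    genes[[g]] <- data.frame(replicon_id = id, start = pos,
                             end = pos + glen - 1L, strand = strand)
    pos <- pos + glen
  }
  if (pos <= len) pieces <- c(pieces, random_dna(len - pos + 1L, cfg$gc))
  # trailing overshoot is always intergenic spacer: trim to the exact length
  list(
    sequence = substr(paste(pieces, collapse = ""), 1L, len),
    genes = if (length(genes)) do.call(rbind, genes) else NULL,
    rrnas = if (length(rrnas)) do.call(rbind, rrnas) else NULL
  )
}

# Nudge the realized GC of `seq` toward `gc` by flipping bases at positions
# not covered by `protected` intervals.
.adjust_gc <- function(seq, gc, protected) {
  v <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(v)
  free <- which(!positions_in_intervals(seq_len(n), protected))
  is_gc <- v %in% c("G", "C")
  need <- round(gc * n) - sum(is_gc)
  if (need > 0L) {
    cand <- free[!is_gc[free]]
    flip <- sample(cand, min(need, length(cand)))
    v[flip] <- sample(c("G", "C"), length(flip), replace = TRUE)
  } else if (need < 0L) {
    cand <- free[is_gc[free]]
    flip <- sample(cand, min(-need, length(cand)))
    v[flip] <- sample(c("A", "T"), length(flip), replace = TRUE)
  }
  paste(v, collapse = "")
}

#' Build a synthetic multi-replicon reference genome
#'
#' Generates the chromosome and plasmids described by `config`, with gene
#' models (CDS, bacterial genetic code, no internal stops), `n_rrna`
#' near-identical rRNA copies (pairwise identity > 99.9%), and
#' plasmid-to-chromosome homologous segments at ~95% identity recorded in a
#' homology map. All coordinates are 1-based inclusive; replicons are linear.
#' Deterministic for a fixed seed.
#'
#' @param config a [ref_config()].
#' @param seed integer RNG seed.
#' @return object of class `ReferenceGenome`: list with `replicons` (named
#'   character vector), `roles`, `gene_models`, `rrna_copies`,
#'   `repeat_regions`, `homology_map`.
#' @examples
#' ref <- build_reference(compact_ref_config(), seed = 42)
#' ref
#' @export
build_reference <- function(config = ref_config(), seed = 1L) {
  cfg <- config
  if (cfg$gc <= 0.2 || cfg$gc >= 0.8) stop("GC target must lie in (0.2, 0.8)")
  if (cfg$chromosome_length < 30000L) stop("chromosome must be >= 30 kb")
  if (any(cfg$plasmids$length >= cfg$chromosome_length))
    stop("plasmids must be shorter than the chromosome")
  if (cfg$homology_identity < 0.90)
    stop("homologous segments must be generated at >= 90% identity")

  with_seed(seed, {
    # rRNA master + copies: first copy exact, others one substitution each,
    # so any two copies differ by at most 2 bases (> 99.9% identity).
    master <- random_dna(cfg$rrna_length, cfg$gc)
    rrna_seqs <- lapply(seq_len(cfg$n_rrna), function(i) {
      if (i == 1L) master else mutate_bases(master, 1L)
    })

    chrom <- .layout_replicon("chromosome", cfg$chromosome_length, cfg,
                              rrna_seqs = rrna_seqs)
    if (is.null(chrom$rrnas) || nrow(chrom$rrnas) != cfg$n_rrna)
      stop("chromosome too short to place all rRNA copies")

    protected <- rbind(chrom$genes[, c("start", "end")],
                       chrom$rrnas[, c("start", "end")])
    chrom_seq <- .adjust_gc(chrom$sequence, cfg$gc, protected)

    replicons <- c(chromosome = chrom_seq)
    roles <- c(chromosome = "chromosome")
    gene_tabs <- list(chrom$genes)
    homology <- list()

    for (i in seq_len(nrow(cfg$plasmids))) {
      ps <- cfg$plasmids[i, ]
      hom_len <- as.integer(round(ps$homology_fraction * ps$length))
      body_len <- ps$length - hom_len
      if (body_len > 0L) {
        lay <- .layout_replicon(ps$id, body_len, cfg, n_genes = ps$n_genes)
        body <- lay$sequence
        gene_tabs <- c(gene_tabs, list(lay$genes))
      } else body <- ""
      if (hom_len > 0L) {
        # copy a chromosome interval clear of the rRNA loci
        for (try in 1:200) {
          cs <- sample.int(cfg$chromosome_length - hom_len + 1L, 1L)
          ce <- cs + hom_len - 1L
          hit <- any(cs <= chrom$rrnas$end & ce >= chrom$rrnas$start)
          if (!hit) break
        }
        n_sub <- as.integer(round((1 - cfg$homology_identity) * hom_len))
        seg <- mutate_bases(substr(chrom_seq, cs, ce), n_sub)
        homology[[length(homology) + 1L]] <- data.frame(
          plasmid_id = ps$id,
          p_start = body_len + 1L, p_end = ps$length,
          c_start = cs, c_end = ce
        )
        pseq <- paste0(body, seg)
      } else pseq <- body
      replicons[[ps$id]] <- pseq
      roles[[ps$id]] <- "plasmid"
    }

    gene_models <- do.call(rbind, Filter(Negate(is.null), gene_tabs))
    gene_models$gene_id <- sprintf("g%04d", seq_len(nrow(gene_models)))
    gene_models$product <- sample(.PRODUCT_VOCAB, nrow(gene_models), replace = TRUE)
    has_cog <- runif(nrow(gene_models)) < 0.6
    gene_models$cog <- ifelse(has_cog,
      sprintf("COG%04d[%s]", sample.int(5000L, nrow(gene_models), replace = TRUE),
              sample(strsplit("CDEFGHIKLMPQRT", "")[[1L]], nrow(gene_models), replace = TRUE)),
      "")
    has_ko <- has_cog & runif(nrow(gene_models)) < 0.85
    gene_models$ko <- ifelse(has_ko,
      sprintf("K%05d", sample.int(25000L, nrow(gene_models), replace = TRUE)), "")
    gene_models$pathways <- ifelse(has_ko & runif(nrow(gene_models)) < 0.7,
      sprintf("Metabolism[PATH:ko%05d]", sample(c(52L, 240L, 520L, 550L, 620L, 730L, 900L, 2010L, 3420L),
                                                nrow(gene_models), replace = TRUE)), "")
    gene_models <- gene_models[, c("gene_id", "replicon_id", "start", "end",
                                   "strand", "product", "cog", "ko", "pathways")]
    rownames(gene_models) <- NULL

    hom_map <- if (length(homology)) do.call(rbind, homology) else
      data.frame(plasmid_id = character(0), p_start = integer(0),
                 p_end = integer(0), c_start = integer(0), c_end = integer(0))

    # repeat annotation: rRNA loci plus both sides of each homologous segment
    rep_reg <- rbind(
      data.frame(replicon_id = "chromosome", start = chrom$rrnas$start,
                 end = chrom$rrnas$end),
      if (nrow(hom_map)) data.frame(replicon_id = "chromosome",
                                    start = hom_map$c_start, end = hom_map$c_end),
      if (nrow(hom_map)) data.frame(replicon_id = hom_map$plasmid_id,
                                    start = hom_map$p_start, end = hom_map$p_end)
    )

    ref <- list(
      replicons = replicons, roles = roles, gene_models = gene_models,
      rrna_copies = chrom$rrnas, repeat_regions = rep_reg,
      homology_map = hom_map, gc_target = cfg$gc, config = cfg, seed = seed
    )
    class(ref) <- "ReferenceGenome"
    ref
  })
}

#' @export
print.ReferenceGenome <- function(x, ...) {
  lens <- nchar(x$replicons)
  cat("ReferenceGenome:", length(x$replicons), "replicons,",
      format(sum(lens), big.mark = ","), "bp total\n")
  cat("  chromosome:", format(lens[["chromosome"]], big.mark = ","), "bp; GC",
      sprintf("%.1f%%", 100 * gc_content(x$replicons[["chromosome"]])), "\n")
  pl <- names(x$replicons)[x$roles == "plasmid"]
  cat("  plasmids:", paste(sprintf("%s (%s bp)", pl,
      format(lens[pl], big.mark = ",")), collapse = ", "), "\n")
  cat("  genes:", nrow(x$gene_models), "; rRNA copies:", nrow(x$rrna_copies),
      sprintf("(%d bp)", x$rrna_copies$end[1] - x$rrna_copies$start[1] + 1L), "\n")
  invisible(x)
}

#' Write a reference genome to disk
#'
#' FASTA for the sequence, TSV for the gene models
#' (gene_id, replicon, start, end, strand, product, cog, ko, pathways).
#' @param ref a `ReferenceGenome`.
#' @param fasta,genes_tsv output paths (NULL to skip either).
#' @export
write_reference <- function(ref, fasta = NULL, genes_tsv = NULL) {
  if (!is.null(fasta)) write_fasta(ref$replicons, fasta)
  if (!is.null(genes_tsv)) {
    utils::write.table(ref$gene_models, genes_tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(ref)
}
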
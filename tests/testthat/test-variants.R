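test_that("a contig identical to a reference slice yields no candidates", {
  ref <- test_ref()
  ctg <- c(c1 = substr(ref$replicons[["chromosome"]], 10001, 25000))
  expect_equal(nrow(call_raw_snps(ctg, ref)), 0)
})

test_that("a single planted substitution is called at its exact coordinate", {
  ref <- test_ref()
  ctg <- substr(ref$replicons[["chromosome"]], 10001, 25000)
  rb <- substr(ctg, 5000, 5000)
  ab <- setdiff(c("A", "C", "G", "T"), rb)[1]
  substr(ctg, 5000, 5000) <- ab
  cand <- call_raw_snps(c(c1 = ctg), ref)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$pos, 15000)
  expect_equal(cand$ref_base, rb)
  expect_equal(cand$alt_base, ab)
  # minus-strand contig gives the identical call
  cand2 <- call_raw_snps(c(c1 = revcomp(ctg)), ref)
  expect_equal(cand2[, c("pos", "ref_base", "alt_base")],
               cand[, c("pos", "ref_base", "alt_base")])
})

test_that("overlapping contigs covering the same SNP deduplicate to one candidate", {
  ref <- test_ref()
  chr <- ref$replicons[["chromosome"]]
  rb <- substr(chr, 12000, 12000)
  ab <- setdiff(c("A", "C", "G", "T"), rb)[1]
  mut <- chr
  substr(mut, 12000, 12000) <- ab
  # overlap of 20 bp around the SNP stays within the 1-to-1 tolerance
  ctgs <- c(a = substr(mut, 10001, 12010), b = substr(mut, 11991, 14000))
  cand <- call_raw_snps(ctgs, ref)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$n_contigs, 2)
})

test_that("repeat mask covers all rRNA copies and homologous segments", {
  ref <- test_ref()
  mask <- test_mask()
  mc <- mask[mask$replicon_id == "chromosome", ]
  rr <- ref$rrna_copies
  for (i in seq_len(nrow(rr)))
    expect_true(any(mc$start <= rr$start[i] & mc$end >= rr$end[i]))
  hm <- ref$homology_map
  for (i in seq_len(nrow(hm))) {
    mp <- mask[mask$replicon_id == hm$plasmid_id[i], ]
    cov <- interval_length(pmax(mp$start, hm$p_start[i]),
                           pmin(mp$end, hm$p_end[i]))
    expect_gt(cov / (hm$p_end[i] - hm$p_start[i] + 1), 0.95)
  }
})

test_that("sequences without duplications yield an empty mask; duplicates are masked", {
  set.seed(31)
  clean <- c(chr = hostdrift:::random_dna(50000, 0.45))
  expect_equal(nrow(build_repeat_mask(clean)), 0)
  dup <- hostdrift:::random_dna(200, 0.45)
  g <- c(chr = paste0(hostdrift:::random_dna(3000, 0.45), dup,
                      hostdrift:::random_dna(3000, 0.45), dup,
                      hostdrift:::random_dna(1000, 0.45)))
  m <- build_repeat_mask(g)
  expect_true(hostdrift:::positions_in_intervals(3100, m[, c("start", "end")]))
  expect_true(hostdrift:::positions_in_intervals(6400, m[, c("start", "end")]))
})

test_that("SNP filters apply strict depth/quality thresholds and the repeat mask", {
  mask <- data.frame(replicon_id = "chromosome", start = 5000L, end = 6000L)
  class(mask) <- c("repeat_mask", "data.frame")
  cand <- data.frame(
    replicon_id = "chromosome",
    pos = c(100L, 200L, 5500L, 300L),
    ref_base = "A", alt_base = "G",
    depth = c(10L, 11L, 50L, 50L),
    quality = c(60, 25, 60, 20)
  )
  kept <- filter_snps(cand, mask)
  # depth 10 rejected (strict > 10); quality 20 rejected (strict > 20);
  # repeat-masked rejected; depth 11 / quality 25 retained
  expect_equal(kept$pos, 200L)
  rej <- attr(kept, "rejected")
  expect_setequal(rej$reason, c("depth", "repeat", "quality"))
})

test_that("the retained SNP set shrinks as thresholds tighten", {
  set.seed(40)
  mask <- data.frame(replicon_id = "chromosome", start = 1L, end = 1L)
  cand <- data.frame(replicon_id = "chromosome", pos = sample(10:10000, 200),
                     ref_base = "A", alt_base = "C",
                     depth = sample(5:60, 200, TRUE),
                     quality = runif(200, 0, 60))
  prev <- Inf
  for (md in c(5, 10, 20, 40)) {
    n <- nrow(filter_snps(cand, mask, min_depth = md))
    expect_lte(n, prev)
    prev <- n
  }
  prev <- Inf
  for (mq in c(5, 20, 40, 55)) {
    n <- nrow(filter_snps(cand, mask, min_quality = mq))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("worked codon substitutions reproduce the canonical classifications", {
  # CGT codon 61, C>T at codon position 1 -> R61C (non-synonymous)
  cx <- make_codon_context("CGT", 61)
  e <- snp_effect(cx$sequence, cx$gene_models, cx$codon_start, "C", "T")
  expect_equal(e$mut_type, "non-synonymous")
  expect_equal(e$protein_change, "R61C")
  # CAA codon 808, C>T -> TAA stop -> Q808X (nonsense)
  cx <- make_codon_context("CAA", 808)
  e <- snp_effect(cx$sequence, cx$gene_models, cx$codon_start, "C", "T")
  expect_equal(e$mut_type, "nonsense")
  expect_equal(e$protein_change, "Q808X")
  # GTG codon 474, G>T at codon position 3 -> GTT -> V474V (synonymous)
  cx <- make_codon_context("GTG", 474)
  e <- snp_effect(cx$sequence, cx$gene_models, cx$codon_start + 2, "G", "T")
  expect_equal(e$mut_type, "synonymous")
  expect_equal(e$protein_change, "V474V")
  # outside all genes -> intergenic, empty protein change
  e <- snp_effect(cx$sequence, cx$gene_models, 10, "A", "G")
  expect_equal(e$mut_type, "intergenic")
  expect_equal(e$protein_change, "")
})

test_that("effect classification handles minus-strand genes and bad input", {
  cx <- make_codon_context("CGT", 10, n_codons = 20)
  # place the same gene on the minus strand of the reverse-complemented context
  seq_rc <- revcomp(cx$sequence)
  L <- nchar(cx$sequence)
  gm <- cx$gene_models
  gm_rc <- data.frame(gene_id = "g1", replicon_id = "chr",
                      start = L - gm$end + 1, end = L - gm$start + 1,
                      strand = "-", product = "t", cog = "", ko = "",
                      pathways = "")
  pos_rc <- L - cx$codon_start + 1
  e <- snp_effect(seq_rc, gm_rc, pos_rc, "G", "A")  # complement of C>T
  expect_equal(e$mut_type, "non-synonymous")
  expect_equal(e$protein_change, "R10C")
  expect_error(snp_effect(cx$sequence, cx$gene_models, 1e6, "A", "G"),
               "outside replicon")
  bad_gm <- transform(cx$gene_models, end = end - 1)
  expect_error(snp_effect(cx$sequence, bad_gm, cx$codon_start, "C", "T"),
               "multiple of 3")
})

test_that("classifier agrees with whole-gene translation on planted SNPs", {
  ref <- test_ref()
  spec <- catalog_event_spec(ref, test_catalog(), seed = 55)
  gm <- ref$gene_models[ref$gene_models$replicon_id == "chromosome", ]
  chr <- ref$replicons[["chromosome"]]
  for (i in seq_len(nrow(spec))) {
    e <- snp_effect(chr, gm, spec$pos[i], spec$ref_base[i], spec$alt_base[i])
    if (e$mut_type == "intergenic") {
      expect_equal(spec$intended_class[i], "intergenic")
      next
    }
    g <- gm[gm$gene_id == e$gene_id, ]
    expect_equal(e$mut_type, effect_oracle(chr, g, spec$pos[i], spec$alt_base[i]))
  }
})

test_that("VCF export carries coordinates, alleles and effect classes", {
  ref <- test_ref()
  snps <- data.frame(snp_id = c("SNP01", "SNP02"), replicon_id = "chromosome",
                     genome_pos = c(1000L, 2000L), mut_type = c("nonsense", "synonymous"),
                     ref_base = c("C", "G"), alt_base = c("T", "A"),
                     depth = c(50L, 60L), quality = c(60, 60))
  f <- tempfile(fileext = ".vcf")
  write_snps_vcf(snps, ref, f)
  lines <- readLines(f)
  expect_true(any(grepl("^##fileformat=VCFv4.2$", lines)))
  body <- utils::read.delim(f, comment.char = "#", header = FALSE)
  expect_equal(body$V2, c(1000L, 2000L))
  expect_true(all(grepl("EFF=", body$V8)))
})
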
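test_that("reference build honours its architectural contract", {
  ref <- test_ref()
  expect_s3_class(ref, "ReferenceGenome")
  expect_length(ref$replicons, 8)
  expect_equal(sum(ref$roles == "chromosome"), 1)
  # five rRNA copies of the configured length, pairwise > 99.9% identical
  rr <- ref$rrna_copies
  expect_equal(nrow(rr), 5)
  expect_true(all(rr$end - rr$start + 1 == 2923))
  seqs <- substring(ref$replicons[["chromosome"]], rr$start, rr$end)
  for (i in 1:4) for (j in (i + 1):5) {
    d <- sum(utf8ToInt(seqs[i]) != utf8ToInt(seqs[j]))
    expect_lte(d, 2)
  }
  # GC within 1% of target
  expect_lt(abs(gc_content(ref$replicons[["chromosome"]]) - 0.445), 0.01)
  # gene models: CDS length divisible by 3, no internal stop
  gm <- ref$gene_models
  expect_true(all((gm$end - gm$start + 1) %% 3 == 0))
  code <- bacterial_code()
  for (i in sample(nrow(gm), 10)) {
    g <- gm[i, ]
    cds <- substr(ref$replicons[[g$replicon_id]], g$start, g$end)
    if (g$strand == "-") cds <- revcomp(cds)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                             genetic.code = code))
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
  }
  # homologous segments align at >= 90% identity
  hm <- ref$homology_map
  expect_gt(nrow(hm), 0)
  for (i in seq_len(nrow(hm))) {
    a <- substr(ref$replicons[[hm$plasmid_id[i]]], hm$p_start[i], hm$p_end[i])
    b <- substr(ref$replicons[["chromosome"]], hm$c_start[i], hm$c_end[i])
    ident <- mean(utf8ToInt(a) == utf8ToInt(b))
    expect_gte(ident, 0.90)
  }
})

test_that("reference build is deterministic and writes byte-identical FASTA", {
  ref2 <- build_reference(compact_ref_config(), seed = 42)
  expect_identical(test_ref()$replicons, ref2$replicons)
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_reference(test_ref(), fasta = f1)
  write_reference(ref2, fasta = f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  rt <- read_fasta(f1)
  expect_identical(unname(rt), unname(test_ref()$replicons))
})

test_that("fully homologous plasmid is covered by the homology map", {
  cfg <- ref_config(chromosome_length = 40000L,
                    plasmids = data.frame(id = "p2", length = 5000L,
                                          homology_fraction = 1.0, n_genes = 0L))
  ref <- build_reference(cfg, seed = 3)
  hm <- ref$homology_map[ref$homology_map$plasmid_id == "p2", ]
  expect_equal(interval_length(hm$p_start, hm$p_end), 5000)
})

test_that("reference build rejects invalid configurations", {
  expect_error(build_reference(ref_config(gc = 0.85), seed = 1), "GC")
  bad <- ref_config(chromosome_length = 40000L,
                    plasmids = data.frame(id = "p1", length = 50000L,
                                          homology_fraction = 0, n_genes = 1L))
  expect_error(build_reference(bad, seed = 1), "shorter than the chromosome")
})

test_that("planting no events returns the reference unchanged", {
  out <- plant_events(test_ref(), event_spec(), seed = 1)
  expect_identical(out$genome, test_ref()$replicons)
})

test_that("complete plasmid loss removes the replicon with truth PLR 1", {
  out <- plant_events(test_ref(), event_spec(
    plasmid_losses = list(list(plasmid_id = "p4", mode = "complete"))), seed = 1)
  expect_length(out$genome, 7)
  expect_false("p4" %in% names(out$genome))
  expect_equal(out$truth$plasmid_losses$plr, 1.0)
})

test_that("length conservation holds for combined events", {
  ref <- test_ref()
  hgt <- make_hgt_fragment(ref, seed = 5)
  ins <- pick_insertion_site(ref, seed = 5)
  out <- plant_events(ref, event_spec(
    plasmid_losses = list(list(plasmid_id = "p1", mode = "partial", plr = 0.3)),
    acquisitions = list(list(sequence = hgt$fragment,
                             replicon_id = "chromosome", pos = ins))), seed = 5)
  deleted <- sum(out$truth$plasmid_losses$del_end -
                 out$truth$plasmid_losses$del_start + 1)
  inserted <- sum(out$truth$acquisitions$length)
  expect_equal(sum(nchar(out$genome)),
               sum(nchar(ref$replicons)) - deleted + inserted)
})

test_that("an unachievable intended effect class is rejected with a diagnostic", {
  ref <- test_ref()
  gm <- ref$gene_models[ref$gene_models$replicon_id == "chromosome", ]
  # find a coding site where the substitution is synonymous, then demand nonsense
  g <- gm[gm$strand == "+", ][1, ]
  found <- NULL
  for (p in seq(g$start, g$end - 3)) {
    rb <- substr(ref$replicons[["chromosome"]], p, p)
    ab <- setdiff(c("A", "C", "G", "T"), rb)[1]
    e <- snp_effect(ref$replicons[["chromosome"]], gm, p, rb, ab)
    if (e$mut_type == "synonymous") { found <- list(p = p, rb = rb, ab = ab); break }
  }
  expect_error(plant_events(ref, event_spec(snps = data.frame(
    replicon_id = "chromosome", pos = found$p, ref_base = found$rb,
    alt_base = found$ab, intended_class = "nonsense")), seed = 1),
    "not achievable")
})

test_that("catalog-driven event specs realize every intended class", {
  spec <- catalog_event_spec(test_ref(), test_catalog(), seed = 99)
  expect_equal(nrow(spec), 19)
  expect_equal(as.integer(table(spec$intended_class)[c("synonymous", "non-synonymous",
                                                       "nonsense", "intergenic")]),
               c(7L, 9L, 2L, 1L))
  out <- plant_events(test_ref(), event_spec(snps = spec), seed = 99)
  expect_identical(out$truth$snps$effect_class, spec$intended_class)
})

test_that("read simulation matches the requested depth arithmetic", {
  g <- c(chr = hostdrift:::random_dna(100000, 0.45))
  rs <- simulate_reads(g, depth = 100, error_rate = 0, seed = 8)
  # pairs ~ depth * L / (2 * read_length)
  expect_equal(length(rs$r1), round(100 * 1e5 / 202), tolerance = 0.05)
  realized <- length(rs$r1) * 2 * 101 / 1e5
  expect_lt(abs(realized - 100) / 100, 0.05)
  expect_error(simulate_reads(g, depth = 0, seed = 1), "positive")
  expect_error(simulate_reads(c(chr = strrep("ACGT", 50)), seed = 1),
               "shorter than the mean insert")
})

test_that("error-free reads substring-match the genome or its reverse complement", {
  g <- c(chr = hostdrift:::random_dna(3000, 0.5))
  rs <- simulate_reads(g, depth = 5, error_rate = 0, seed = 21)
  both <- paste0(g[["chr"]], "#", revcomp(g[["chr"]]))
  for (r in c(rs$r1[1:20], rs$r2[1:20]))
    expect_true(grepl(r, both, fixed = TRUE))
  # determinism
  rs2 <- simulate_reads(g, depth = 5, error_rate = 0, seed = 21)
  expect_identical(rs, rs2)
})

test_that("read simulation injects errors at the requested rate", {
  g <- c(chr = hostdrift:::random_dna(20000, 0.5))
  rs <- simulate_reads(g, depth = 20, error_rate = 0.01, seed = 4)
  both <- paste0(g[["chr"]], "#", revcomp(g[["chr"]]))
  frac_exact <- mean(vapply(rs$r1, function(r) grepl(r, both, fixed = TRUE), TRUE))
  # P(read error-free) = 0.99^101 ~ 0.36
  expect_gt(frac_exact, 0.25)
  expect_lt(frac_exact, 0.5)
  # error positions carry downgraded qualities
  expect_true(any(grepl("+", rs$q1, fixed = TRUE)))
})

test_that("contig shearing partitions each replicon without chimeras", {
  ref <- test_ref()
  ctg <- shear_contigs(ref, mean_contig = 1e6, random_orientation = FALSE,
                       seed = 2)
  # one contig per replicon reconstructs the genome
  expect_length(ctg, 8)
  mp <- attr(ctg, "map")
  for (rn in names(ref$replicons)) {
    joined <- paste(ctg[mp$contig[mp$replicon == rn]], collapse = "")
    expect_identical(joined, unname(ref$replicons[[rn]]))
  }
  # gap bookkeeping
  ctg2 <- shear_contigs(ref, mean_contig = 10000, gap = 500, seed = 2)
  n_gaps <- length(ctg2) - 8
  expect_gte(sum(nchar(ctg2)), sum(nchar(ref$replicons)) - n_gaps * 500)
  # every contig maps back at 100% identity, never across replicons
  mp2 <- attr(ctg2, "map")
  for (i in sample(length(ctg2), 5)) {
    h <- local_align(ctg2[i], ref$replicons, min_identity = 99.9)
    expect_gte(nrow(h), 1)
    expect_equal(h$subject_id[1], mp2$replicon[i])
  }
})

test_that("FASTQ round trip preserves sequences", {
  g <- c(chr = hostdrift:::random_dna(2000, 0.5))
  rs <- simulate_reads(g, depth = 3, seed = 13)
  d <- tempfile()
  paths <- write_reads(rs, d, "x")
  back <- read_fastq_pair(file.path(d, "x_R1.fastq"), file.path(d, "x_R2.fastq"))
  expect_identical(back$r1, rs$r1)
  expect_identical(back$r2, rs$r2)
})
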
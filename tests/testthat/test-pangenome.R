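test_that("exact reference shears are entirely core", {
  ref <- test_ref()
  ctg <- shear_contigs(ref, mean_contig = 15000, seed = 5)
  part <- delineate_core(ctg, ref)
  expect_equal(part$core_bp, part$total_bp)
  expect_equal(nrow(part$specific), 0)
  expect_equal(part$specific_bp + part$dropped_bp, 0)
})

test_that("a 1-kb insertion surfaces as one strain-specific fragment", {
  ref <- test_ref()
  set.seed(14)
  ins <- hostdrift:::random_dna(1000, 0.45)
  chr <- ref$replicons[["chromosome"]]
  ctg <- c(c1 = paste0(substr(chr, 20001, 25000), ins, substr(chr, 25001, 30000)))
  part <- delineate_core(ctg, ref)
  expect_equal(nrow(part$specific), 1)
  expect_lt(abs(part$specific$length - 1000), 20)
  expect_equal(part$core_bp + part$specific_bp + part$dropped_bp, part$total_bp)
})

test_that("a contig below the identity threshold is entirely strain-specific", {
  ref <- test_ref()
  set.seed(15)
  ctg <- c(c1 = hostdrift:::mutate_bases(
    substr(ref$replicons[["chromosome"]], 30001, 35000), 1000))  # 80% identity
  part <- delineate_core(ctg, ref)
  expect_equal(part$core_bp, 0)
  expect_equal(part$specific_bp, 5000)
})

test_that("partition conservation holds across sheared strains", {
  ref <- test_ref()
  for (s in 1:3) {
    out <- plant_events(ref, event_spec(
      plasmid_losses = list(list(plasmid_id = "p1", mode = "partial", plr = 0.4))),
      seed = s)
    ctg <- shear_contigs(out$genome, mean_contig = 12000, seed = s)
    part <- delineate_core(ctg, ref)
    expect_equal(part$core_bp + part$specific_bp + part$dropped_bp,
                 part$total_bp)
  }
})

test_that("identical fragments from several strains collapse to one accessory record", {
  set.seed(20)
  frag <- hostdrift:::random_dna(1000, 0.45)
  tab <- data.frame(strain_id = paste0("S", 1:5),
                    fragment_id = paste0("f", 1:5), sequence = frag)
  acc <- build_accessory(tab)
  expect_equal(nrow(acc), 1)
  expect_equal(acc$n_members, 5)
  expect_setequal(acc$members[[1]], paste0("S", 1:5))
})

test_that("fragments merge at 95% identity but not at 50% overlap", {
  set.seed(21)
  a <- hostdrift:::random_dna(1000, 0.45)
  b <- hostdrift:::mutate_bases(a, 50)  # 95% identity, full length
  # oracle confirms the pairwise identity used for the clustering decision
  expect_gt(sw_oracle(a, b)$identity, 90)
  acc <- build_accessory(data.frame(strain_id = c("S1", "S2"),
                                    fragment_id = c("fa", "fb"),
                                    sequence = c(a, b)))
  expect_equal(nrow(acc), 1)
  expect_equal(acc$cluster_size, 2)
  # only 50% of the shorter sequence shared -> fails match length >= 85%
  c1 <- paste0(substr(a, 1, 500), hostdrift:::random_dna(500, 0.45))
  acc2 <- build_accessory(data.frame(strain_id = c("S1", "S2"),
                                     fragment_id = c("fa", "fc"),
                                     sequence = c(a, c1)))
  expect_equal(nrow(acc2), 2)
})

test_that("accessory clustering is idempotent and order-invariant", {
  set.seed(22)
  base <- hostdrift:::random_dna(800, 0.45)
  tab <- data.frame(
    strain_id = c("S1", "S2", "S3", "S4"),
    fragment_id = c("f1", "f2", "f3", "f4"),
    sequence = c(base, hostdrift:::mutate_bases(base, 40),
                 hostdrift:::random_dna(600, 0.45),
                 hostdrift:::random_dna(400, 0.45)))
  acc <- build_accessory(tab)
  # idempotence
  again <- build_accessory(data.frame(
    strain_id = vapply(acc$members, `[`, "", 1L),
    fragment_id = acc$fragment_id, sequence = acc$sequence))
  expect_equal(again$fragment_id, acc$fragment_id)
  expect_equal(again$sequence, acc$sequence)
  # order invariance
  for (perm in 1:3) {
    shuf <- tab[sample(nrow(tab)), ]
    acc2 <- build_accessory(shuf)
    expect_equal(acc2$fragment_id, acc$fragment_id)
    expect_equal(acc2$members, acc$members)
  }
})

test_that("source assignment distinguishes plasmid-born, homologous and novel", {
  ref <- test_ref()
  set.seed(23)
  verbatim <- substr(ref$replicons[["p1"]], 2001, 3000)
  chrom_like <- substr(ref$replicons[["chromosome"]], 50001, 51000)
  novel <- hostdrift:::random_dna(700, 0.45)
  acc <- build_accessory(data.frame(
    strain_id = "S1", fragment_id = c("fp", "fc", "fn"),
    sequence = c(verbatim, chrom_like, novel)))
  acc <- assign_source(acc, ref)
  src <- setNames(acc$source, substr(acc$fragment_id, 1, 2))
  expect_equal(unname(src["fp"]), "plasmid-born(p1)")
  expect_equal(unname(src["fc"]), "chromosome-homologous")
  expect_equal(unname(src["fn"]), "novel")
  expect_equal(acc$best_hit_feature[acc$fragment_id == "fn"], "")
  expect_true(is.na(acc$best_hit_identity[acc$fragment_id == "fn"]))
})

test_that("the 23S-like acquired fragment is novel with ~90% rRNA homology", {
  ref <- test_ref()
  hgt <- make_hgt_fragment(ref, seed = 42)
  acc <- build_accessory(data.frame(strain_id = "S6", fragment_id = "acq",
                                    sequence = hgt$fragment))
  acc <- assign_source(acc, ref)
  expect_equal(acc$source, "novel")
  expect_match(acc$best_hit_feature, "23S_rRNA")
  expect_gt(acc$best_hit_identity, 85)
  expect_lt(acc$best_hit_identity, 90)
  h <- detect_acquisitions(acc, ref, donor_db = hgt$donor)
  expect_equal(nrow(h), 1)
  expect_match(h$ref_homolog, "23S_rRNA")
  expect_gt(h$donor_identity, 95)
  expect_lt(h$donor_identity, 99)
})

test_that("accessory outputs write as FASTA and membership matrix", {
  set.seed(24)
  tab <- data.frame(strain_id = c("S1", "S2"), fragment_id = c("f1", "f2"),
                    sequence = c(hostdrift:::random_dna(500, 0.5),
                                 hostdrift:::random_dna(400, 0.5)))
  acc <- build_accessory(tab)
  fa <- tempfile(fileext = ".fasta"); ms <- tempfile(fileext = ".tsv")
  write_accessory(acc, fasta = fa, membership_tsv = ms,
                  strains = c("S1", "S2", "S3"))
  seqs <- read_fasta(fa)
  expect_length(seqs, 2)
  mm <- utils::read.delim(ms, check.names = FALSE)
  expect_equal(dim(mm), c(2, 4))
  expect_equal(sum(mm$S3), 0)
})
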
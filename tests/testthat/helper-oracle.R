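# Independent oracles, kept free of the package's alignment code paths.

# Full Smith-Waterman via Biostrings::pairwiseAlignment with the same scoring
# scheme as the seed-and-extend aligner (match +1, mismatch -2, affine 5/2).
sw_oracle <- function(q, s) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  al <- Biostrings::pairwiseAlignment(pattern = q, subject = s,
                                      type = "local",
                                      substitutionMatrix = mat,
                                      gapOpening = 5, gapExtension = 2)
  list(score = Biostrings::score(al),
       identity = Biostrings::pid(al, type = "PID1"))
}

# Brute-force effect classification: translate the whole gene before and
# after the substitution and diff the protein sequences.
effect_oracle <- function(sequence, gene, pos, alt_base) {
  code <- Biostrings::getGeneticCode("11")
  cds <- function(seq) {
    x <- substr(seq, gene$start, gene$end)
    if (gene$strand == "-") x <- hostdrift::revcomp(x)
    x
  }
  mutated <- sequence
  substr(mutated, pos, pos) <- alt_base
  tr <- function(x) as.character(Biostrings::translate(
    Biostrings::DNAString(x), genetic.code = code, if.fuzzy.codon = "X"))
  p0 <- tr(cds(sequence))
  p1 <- tr(cds(mutated))
  d <- which(strsplit(p0, "")[[1]] != strsplit(p1, "")[[1]])
  if (length(d) == 0) return("synonymous")
  if (substr(p1, d[1], d[1]) == "*") return("nonsense")
  "non-synonymous"
}

# Construct a plus-strand gene context with a chosen codon at a chosen codon
# index, padded with a neutral codon, inside intergenic flanks.
make_codon_context <- function(codon, codon_index, n_codons = NULL,
                               flank = 120) {
  if (is.null(n_codons)) n_codons <- codon_index + 2
  pad <- "CTG"  # leucine, no stop reachable by accident in the pad
  body <- c("ATG", rep(pad, codon_index - 2), codon,
            rep(pad, n_codons - codon_index - 1), "TAA")
  gene_seq <- paste(body, collapse = "")
  seq <- paste0(strrep("A", flank), gene_seq, strrep("A", flank))
  gm <- data.frame(gene_id = "g1", replicon_id = "chr",
                   start = flank + 1, end = flank + nchar(gene_seq),
                   strand = "+", product = "test", cog = "", ko = "",
                   pathways = "")
  list(sequence = seq, gene_models = gm,
       codon_start = flank + 1 + 3 * (codon_index - 1))
}
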
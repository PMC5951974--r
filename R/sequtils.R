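# Low-level DNA helpers. Sequences are plain uppercase character strings
# internally (ACGTN); Biostrings handles file formats and translation tables.

.BASES <- c("A", "C", "G", "T")

.base_lut <- local({
  lut <- rep(NA_integer_, 256L)
  lut[utf8ToInt("A")] <- 0L; lut[utf8ToInt("a")] <- 0L
  lut[utf8ToInt("C")] <- 1L; lut[utf8ToInt("c")] <- 1L
  lut[utf8ToInt("G")] <- 2L; lut[utf8ToInt("g")] <- 2L
  lut[utf8ToInt("T")] <- 3L; lut[utf8ToInt("t")] <- 3L
  lut[utf8ToInt("N")] <- 4L; lut[utf8ToInt("n")] <- 4L
  lut
})

.int_chr <- utf8ToInt("ACGTN")

# One string -> integer vector (A=0 C=1 G=2 T=3 N=4).
dna_to_int <- function(x) {
  v <- .base_lut[utf8ToInt(x)]
  if (anyNA(v)) stop("sequence contains characters outside ACGTN")
  v
}

int_to_dna <- function(v) intToUtf8(.int_chr[v + 1L])

#' Reverse complement of a DNA string
#' @param x single character string over ACGTN.
#' @export
revcomp <- function(x) {
  intToUtf8(rev(utf8ToInt(chartr("ACGTNacgtn", "TGCANTGCAN", x))))
}

# Random DNA of length n at the given GC fraction (uses the current RNG state).
random_dna <- function(n, gc = 0.5) {
  if (n <= 0L) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(.BASES, n, replace = TRUE, prob = p), collapse = "")
}

# Substitute exactly n_sub positions (to a uniformly random different base);
# returns the mutated string. Uses current RNG state.
mutate_bases <- function(x, n_sub, at = NULL) {
  v <- strsplit(x, "", fixed = TRUE)[[1L]]
  if (is.null(at)) at <- sample.int(length(v), n_sub) else stopifnot(length(at) == n_sub)
  for (i in at) v[i] <- sample(setdiff(.BASES, v[i]), 1L)
  paste(v, collapse = "")
}

gc_content <- function(x) {
  v <- dna_to_int(x)
  mean(v == 1L | v == 2L)
}

# ---- k-mer machinery (shared by the aligner and the read mapper) ------------

# Numeric 2-bit k-mer codes for every window of `ints`; windows containing N
# are NA. k <= 16 keeps codes exact in doubles.
kmer_codes <- function(ints, k) {
  n <- length(ints)
  if (n < k) return(numeric(0))
  m <- n - k + 1L
  codes <- numeric(m)
  bad <- ints >= 4L
  for (j in seq_len(k)) codes <- codes * 4 + ints[j:(m + j - 1L)]
  if (any(bad)) {
    cs <- cumsum(bad)
    nbad <- cs[k:n] - c(0, cs)[1:m]
    codes[nbad > 0L] <- NA_real_
  }
  codes
}

# All (query position, subject position) pairs whose k-mers are identical.
# k-mers occurring more than `max_hits` times in the subject are skipped
# (soft masking of high-frequency seeds, as BLAST does).
seed_matches <- function(qcodes, scodes, max_hits = 256L) {
  sv <- which(!is.na(scodes))
  if (length(sv) == 0L) return(cbind(qpos = integer(0), spos = integer(0)))
  o <- order(scodes[sv])
  ss <- scodes[sv][o]
  sp <- sv[o]
  qv <- which(!is.na(qcodes))
  if (length(qv) == 0L) return(cbind(qpos = integer(0), spos = integer(0)))
  qc <- qcodes[qv]
  hi <- findInterval(qc, ss)
  lo <- findInterval(qc - 0.5, ss)
  cnt <- hi - lo
  keep <- cnt > 0L & cnt <= max_hits
  if (!any(keep)) return(cbind(qpos = integer(0), spos = integer(0)))
  reps <- cnt[keep]
  qpos <- rep.int(qv[keep], reps)
  idx <- sequence(reps) + rep.int(lo[keep], reps)
  cbind(qpos = qpos, spos = sp[idx])
}

# ---- FASTA / FASTQ ----------------------------------------------------------

#' Read a FASTA file into a named character vector
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write named sequences to FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read paired FASTQ files
#' @param r1,r2 FASTQ paths (`_R1`/`_R2` mates, Phred+33).
#' @return list with character vectors `r1`, `r2` (sequences only).
#' @export
read_fastq_pair <- function(r1, r2) {
  f <- function(p) toupper(as.character(Biostrings::readDNAStringSet(p, format = "fastq")))
  a <- f(r1); b <- f(r2)
  if (length(a) != length(b)) stop("mate files differ in read count")
  list(r1 = unname(a), r2 = unname(b))
}

# Plain-text FASTQ writer (Phred+33); record names carry /1 /2 suffixes.
write_fastq <- function(seqs, quals, ids, path) {
  stopifnot(length(seqs) == length(quals), length(seqs) == length(ids))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", quals), con)
  invisible(path)
}
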
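# Paired-end short-read simulation and assembly emulation (contig shearing).

.as_replicons <- function(genome) {
  if (inherits(genome, "ReferenceGenome")) return(genome$replicons)
  if (is.character(genome)) {
    if (length(genome) == 0L) return(stats::setNames(character(0), character(0)))
    if (is.null(names(genome))) names(genome) <- paste0("seq", seq_along(genome))
    return(genome)
  }
  stop("genome must be a ReferenceGenome or a named character vector")
}

.revcomp_vec <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate paired-end reads
#'
#' Illumina-like paired reads: fragments sampled uniformly per replicon
#' (count proportional to length so that mean depth matches `depth`), insert
#' sizes normal around `mean_insert`, mates on opposite strands, fragment
#' orientation random. Base-call errors are uniform substitutions at
#' `error_rate`; quality strings are constant Q40 with error positions
#' downgraded to Q10 (Phred+33). Deterministic for a fixed seed.
#'
#' @param genome `ReferenceGenome` or named character vector.
#' @param read_length read length in bp (default 101).
#' @param mean_insert,sd_insert insert-size distribution in bp (default
#'   350 / 35). `read_length` must not exceed `mean_insert` and every
#'   replicon must be at least `mean_insert` long.
#' @param depth target mean per-base depth (default 100).
#' @param error_rate per-base substitution error probability (default 0).
#' @param seed integer seed.
#' @param prefix read-name prefix.
#' @return list of class `read_set`: `r1`, `r2`, `q1`, `q2`, `ids`, `params`.
#' @export
simulate_reads <- function(genome, read_length = 101L, mean_insert = 350L,
                           sd_insert = 35L, depth = 100, error_rate = 0,
                           seed = 1L, prefix = "rd") {
  reps <- .as_replicons(genome)
  if (depth <= 0) stop("depth must be positive")
  if (read_length > mean_insert) stop("read_length must not exceed mean_insert")
  lens <- nchar(reps)
  if (any(lens < mean_insert))
    stop("replicon(s) shorter than the mean insert size: ",
         paste(names(reps)[lens < mean_insert], collapse = ", "))

  with_seed(seed, {
    r1 <- r2 <- character(0)
    ids <- character(0)
    n_err1 <- n_err2 <- list()
    for (rn in names(reps)) {
      s <- reps[[rn]]
      L <- nchar(s)
      n <- as.integer(round(depth * L / (2 * read_length)))
      if (n == 0L) next
      ins <- as.integer(round(stats::rnorm(n, mean_insert, sd_insert)))
      ins <- pmin(pmax(ins, read_length), L)
      start <- 1L + as.integer(floor(stats::runif(n) * (L - ins + 1)))
      left <- substring(s, start, start + read_length - 1L)
      right <- .revcomp_vec(substring(s, start + ins - read_length, start + ins - 1L))
      flip <- stats::runif(n) < 0.5
      a <- ifelse(flip, right, left)
      b <- ifelse(flip, left, right)
      r1 <- c(r1, a)
      r2 <- c(r2, b)
      ids <- c(ids, sprintf("%s_%s_%06d", prefix, rn, seq_len(n)))
    }
    np <- length(r1)
    q1 <- rep(strrep(rawToChar(as.raw(33L + 40L)), read_length), np)
    q2 <- q1
    if (error_rate > 0 && np > 0L) {
      inject <- function(reads, quals) {
        k <- stats::rbinom(length(reads), read_length, error_rate)
        for (i in which(k > 0L)) {
          at <- sample.int(read_length, k[i])
          reads[i] <- mutate_bases(reads[i], k[i], at = at)
          for (p in at) substr(quals[i], p, p) <- rawToChar(as.raw(33L + 10L))
        }
        list(reads, quals)
      }
      a <- inject(r1, q1); r1 <- a[[1L]]; q1 <- a[[2L]]
      b <- inject(r2, q2); r2 <- b[[1L]]; q2 <- b[[2L]]
    }
    structure(list(r1 = r1, r2 = r2, q1 = q1, q2 = q2, ids = ids,
                   params = list(read_length = as.integer(read_length),
                                 mean_insert = as.integer(mean_insert),
                                 sd_insert = sd_insert, depth = depth,
                                 error_rate = error_rate, seed = seed)),
              class = "read_set")
  })
}

#' @export
print.read_set <- function(x, ...) {
  cat("read_set:", length(x$r1), "pairs of", x$params$read_length,
      "bp (insert", x$params$mean_insert, "bp, error rate",
      x$params$error_rate, ")\n")
  invisible(x)
}

#' Write a read set as paired FASTQ
#'
#' Files are `<prefix>_R1.fastq` / `<prefix>_R2.fastq`, Phred+33.
#' @param reads a `read_set`.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return paths of the two files, invisibly.
#' @export
write_reads <- function(reads, dir, prefix = "reads") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, paste0(prefix, "_R1.fastq"))
  p2 <- file.path(dir, paste0(prefix, "_R2.fastq"))
  write_fastq(reads$r1, reads$q1, paste0(reads$ids, "/1"), p1)
  write_fastq(reads$r2, reads$q2, paste0(reads$ids, "/2"), p2)
  invisible(c(p1, p2))
}

#' Shear a genome into assembly-like contigs
#'
#' Emulates a short-read assembly by partitioning each replicon into
#' error-free contigs at random breakpoints (plus any forced breakpoints,
#' e.g. at repeat or insertion junctions where real assemblers break), with
#' an optional fixed gap swallowed at each internal junction. Contigs never
#' join sequence from two replicons; orientation is randomized.
#'
#' @param genome `ReferenceGenome` or named character vector (typically a
#'   derived strain genome).
#' @param mean_contig target contig length in bp.
#' @param min_contig minimum contig length in bp.
#' @param gap bp removed at each internal junction (default 0).
#' @param breakpoints named list (by replicon) of positions after which a
#'   contig boundary is forced.
#' @param random_orientation reverse-complement contigs at random?
#' @param seed integer seed.
#' @return named character vector of contigs with attribute `"map"`
#'   (data.frame contig, replicon, start, end, strand).
#' @export
shear_contigs <- function(genome, mean_contig = 20000L, min_contig = 500L,
                          gap = 0L, breakpoints = NULL,
                          random_orientation = TRUE, seed = 1L) {
  reps <- .as_replicons(genome)
  with_seed(derive_seed(seed, 7L), {
    out <- character(0)
    map <- list()
    idx <- 0L
    for (rn in names(reps)) {
      L <- nchar(reps[[rn]])
      cuts <- integer(0)
      pos <- 0L
      repeat {
        step <- max(min_contig,
                    as.integer(round(mean_contig * stats::runif(1, 0.6, 1.4))))
        pos <- pos + step
        if (pos >= L - min_contig) break
        cuts <- c(cuts, pos)
      }
      if (!is.null(breakpoints[[rn]]))
        cuts <- c(cuts, as.integer(breakpoints[[rn]]))
      cuts <- sort(unique(cuts[cuts >= 1L & cuts < L]))
      starts <- c(1L, cuts + 1L)
      ends <- c(cuts, L)
      # swallow `gap` bp at the start of every contig after the first
      if (gap > 0L && length(starts) > 1L)
        starts[-1L] <- pmin(starts[-1L] + as.integer(gap), ends[-1L])
      for (i in seq_along(starts)) {
        if (ends[i] - starts[i] + 1L < 1L) next
        idx <- idx + 1L
        cseq <- substr(reps[[rn]], starts[i], ends[i])
        strand <- "+"
        if (random_orientation && stats::runif(1) < 0.5) {
          cseq <- revcomp(cseq)
          strand <- "-"
        }
        nm <- sprintf("ctg%04d_%s", idx, rn)
        out[[nm]] <- cseq
        map[[idx]] <- data.frame(contig = nm, replicon = rn,
                                 start = starts[i], end = ends[i],
                                 strand = strand)
      }
    }
    attr(out, "map") <- do.call(rbind, map)
    out
  })
}
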
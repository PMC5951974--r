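# Read pseudo-mapping: exact k-mer anchoring plus full-length mismatch
# verification. Each read is assigned to its unique best location; reads with
# tied best placements (multi-copy rRNA, unresolved repeats) are discarded
# from depth tracks, which deliberately depresses depth in repeats - the
# repeat filter of the variant stage exploits this.

# Per-read 2-bit codes of the k bases starting at column `o` of matrix M.
.read_codes <- function(M, o, k) {
  codes <- numeric(nrow(M))
  bad <- rep(FALSE, nrow(M))
  for (j in seq_len(k)) {
    col <- M[, o + j - 1L]
    bad <- bad | col >= 4L
    codes <- codes * 4 + col
  }
  codes[bad] <- NA_real_
  codes
}

#' Map paired reads to one or more reference sequences
#'
#' @param reads a `read_set` (from [simulate_reads()]), a list with elements
#'   `r1`/`r2`, or a length-2 character vector of FASTQ paths.
#' @param genomes `ReferenceGenome` or named character vector of reference
#'   sequences.
#' @param k anchor k-mer length (default 21).
#' @param max_mismatch maximum mismatches for a valid placement (default 5).
#' @param seed_offsets read positions where anchor k-mers are taken
#'   (default 1 and 51, so one anchor survives a single error).
#' @return object of class `map_result`: per-replicon integer depth tracks,
#'   a placements table, mapped/ambiguous/unmapped counts, and the encoded
#'   reads (used by [snp_support()]).
#' @export
map_reads <- function(reads, genomes, k = 21L, max_mismatch = 5L,
                      seed_offsets = c(1L, 51L)) {
  reps <- .as_replicons(genomes)
  if (length(reps) == 0L) stop("no reference sequences loaded")
  if (is.character(reads) && length(reads) == 2L)
    reads <- read_fastq_pair(reads[1L], reads[2L])
  r_all <- c(reads$r1, reads$r2)
  np <- length(reads$r1)
  pair_id <- c(seq_len(np), seq_len(np))

  lens <- nchar(reps)
  if (length(r_all) == 0L) {
    depth <- lapply(lens, function(L) integer(L))
    return(structure(list(depth = depth, placements = NULL,
                          counts = c(mapped = 0L, ambiguous = 0L, unmapped = 0L),
                          n_pairs = 0L, read_length = NA_integer_),
                     class = "map_result"))
  }
  L <- nchar(r_all[1L])
  if (!all(nchar(r_all) == L)) stop("reads must have uniform length")
  if (L < k) stop("read length below anchor k-mer size")
  seed_offsets <- seed_offsets[seed_offsets + k - 1L <= L]

  # concatenated reference with N spacers; global -> local via offsets
  spacer <- strrep("N", k)
  conc <- paste(unlist(reps), collapse = spacer)
  ci <- dna_to_int(conc)
  offs <- cumsum(c(1L, (lens + k)[-length(lens)]))  # global start per replicon
  s_codes <- kmer_codes(ci, k)
  sv <- which(!is.na(s_codes))
  so <- order(s_codes[sv])
  ss <- s_codes[sv][so]
  sp <- sv[so]

  n <- length(r_all)
  F <- matrix(.base_lut[utf8ToInt(paste(r_all, collapse = ""))],
              nrow = n, ncol = L, byrow = TRUE)
  F[is.na(F)] <- 4L
  R <- F[, L:1L, drop = FALSE]
  R[R < 4L] <- 3L - R[R < 4L]

  lookup <- function(codes, o) {
    qv <- which(!is.na(codes))
    if (!length(qv)) return(NULL)
    qc <- codes[qv]
    hi <- findInterval(qc, ss)
    lo <- findInterval(qc - 0.5, ss)
    cnt <- hi - lo
    keep <- cnt > 0L
    if (!any(keep)) return(NULL)
    reps_n <- cnt[keep]
    read <- rep.int(qv[keep], reps_n)
    idx <- sequence(reps_n) + rep.int(lo[keep], reps_n)
    start <- sp[idx] - (o - 1L)
    ok <- start >= 1L & start + L - 1L <= length(ci)
    cbind(read = read[ok], start = start[ok])
  }

  place <- list()
  for (strand in c("+", "-")) {
    M <- if (strand == "+") F else R
    cand <- NULL
    for (o in seed_offsets) {
      cand <- rbind(cand, lookup(.read_codes(M, o, k), o))
    }
    if (is.null(cand) || nrow(cand) == 0L) next
    key <- cand[, "read"] * 1e7 + cand[, "start"]
    cand <- cand[!duplicated(key), , drop = FALSE]
    mm <- integer(nrow(cand))
    rd <- cand[, "read"]
    stt <- cand[, "start"]
    for (j in seq_len(L)) {
      mm <- mm + (ci[stt + j - 1L] != M[cbind(rd, j)])
    }
    ok <- mm <= max_mismatch
    if (any(ok))
      place[[strand]] <- data.frame(read = rd[ok], start = stt[ok],
                                    strand = strand, mism = mm[ok])
  }

  pl <- if (length(place)) do.call(rbind, place) else
    data.frame(read = integer(0), start = integer(0),
               strand = character(0), mism = integer(0))

  mapped <- ambiguous <- 0L
  best <- NULL
  if (nrow(pl)) {
    o <- order(pl$read, pl$mism)
    pl <- pl[o, , drop = FALSE]
    first <- !duplicated(pl$read)
    bm <- pl$mism[first][match(pl$read, pl$read[first])]
    at_best <- pl$mism == bm
    nb <- tapply(at_best, pl$read, sum)
    uniq_reads <- as.integer(names(nb)[nb == 1L])
    ambiguous <- sum(nb > 1L)
    best <- pl[first & pl$read %in% uniq_reads, , drop = FALSE]
    mapped <- nrow(best)
  }
  unmapped <- n - mapped - ambiguous

  depth <- lapply(lens, function(x) integer(x))
  placements <- NULL
  if (!is.null(best) && nrow(best)) {
    ri <- findInterval(best$start, offs)
    local <- best$start - offs[ri] + 1L
    # drop placements straddling a spacer (start in one replicon, end beyond)
    inside <- local + L - 1L <= lens[ri]
    best <- best[inside, , drop = FALSE]
    ri <- ri[inside]; local <- local[inside]
    placements <- data.frame(read = best$read, pair = pair_id[best$read],
                             replicon = names(reps)[ri], start = local,
                             strand = best$strand, mismatches = best$mism)
    for (i in seq_along(reps)) {
      sel <- ri == i
      if (!any(sel)) next
      st <- local[sel]
      en <- st + L
      tb1 <- tabulate(st, nbins = lens[i] + 1L)
      tb2 <- tabulate(en, nbins = lens[i] + 1L)
      depth[[i]] <- cumsum(tb1 - tb2)[seq_len(lens[i])]
    }
  }
  names(depth) <- names(reps)

  structure(list(depth = depth, placements = placements,
                 counts = c(mapped = mapped, ambiguous = as.integer(ambiguous),
                            unmapped = as.integer(unmapped)),
                 n_pairs = np, read_length = L,
                 reads_fwd = F, reads_rev = R),
            class = "map_result")
}

#' @export
print.map_result <- function(x, ...) {
  cat("map_result:", x$n_pairs, "pairs;",
      x$counts[["mapped"]], "reads mapped,",
      x$counts[["ambiguous"]], "ambiguous (discarded),",
      x$counts[["unmapped"]], "unmapped\n")
  for (rn in names(x$depth))
    cat(sprintf("  %-12s mean depth %7.2f\n", rn, mean(x$depth[[rn]])))
  invisible(x)
}

#' Per-pair support for candidate SNPs
#'
#' For each candidate position, counts the distinct read pairs covering it
#' and those supporting the alternate allele, and assigns a Phred-scaled
#' call quality: -10 log10 P(>= alt-supporting pairs by chance | depth,
#' base error 0.01), capped at 60.
#'
#' @param map a `map_result` against the reference.
#' @param candidates data.frame with `replicon_id`, `pos`, `alt_base`
#'   (from [call_raw_snps()]).
#' @return `candidates` with columns `depth`, `alt_support`, `quality` added.
#' @export
snp_support <- function(map, candidates) {
  n <- nrow(candidates)
  depth <- alt <- integer(n)
  qual <- numeric(n)
  L <- map$read_length
  pl <- map$placements
  for (i in seq_len(n)) {
    p <- candidates$pos[i]
    sel <- which(pl$replicon == candidates$replicon_id[i] &
                 pl$start <= p & pl$start + L - 1L >= p)
    if (!length(sel)) { qual[i] <- 0; next }
    rows <- pl[sel, , drop = FALSE]
    off <- p - rows$start + 1L
    base <- integer(nrow(rows))
    fwd <- rows$strand == "+"
    if (any(fwd))
      base[fwd] <- map$reads_fwd[cbind(rows$read[fwd], off[fwd])]
    if (any(!fwd))
      base[!fwd] <- map$reads_rev[cbind(rows$read[!fwd], off[!fwd])]
    altc <- .base_lut[utf8ToInt(candidates$alt_base[i])]
    depth[i] <- length(unique(rows$pair))
    alt[i] <- length(unique(rows$pair[base == altc]))
    if (alt[i] > 0L) {
      pv <- stats::pbinom(alt[i] - 1L, depth[i], 0.01, lower.tail = FALSE)
      qual[i] <- min(60, -10 * log10(max(pv, 1e-300)))
    }
  }
  candidates$depth <- depth
  candidates$alt_support <- alt
  candidates$quality <- qual
  candidates
}

#' Write depth tracks as bedGraph (0-based half-open)
#' @param map a `map_result` (or named list of depth vectors).
#' @param path output file.
#' @export
write_depth_bedgraph <- function(map, path) {
  depth <- if (inherits(map, "map_result")) map$depth else map
  con <- file(path, "w")
  on.exit(close(con))
  for (rn in names(depth)) {
    r <- rle(depth[[rn]])
    en <- cumsum(r$lengths)
    st <- en - r$lengths  # 0-based starts
    writeLines(paste(rn, st, en, r$values, sep = "\t"), con)
  }
  invisible(path)
}
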
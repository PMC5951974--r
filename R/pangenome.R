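# Core / accessory genome delineation: contig bases shared with the
# reference at >= 90% identity (e-value < 1e-5) are core; the complement,
# split at unaligned gaps and cleaned of sub-200-bp slivers, is the
# strain-specific sequence. Strain-specific fragments from all strains are
# deduplicated (identity >= 90% over >= 85% of the shorter sequence, single
# linkage) into the non-redundant accessory genome.

#' Partition contigs into core and strain-specific sequence
#'
#' @param contigs named character vector of one strain's contigs.
#' @param reference `ReferenceGenome` or named character vector.
#' @param min_identity,max_evalue core-alignment thresholds (90 / 1e-5).
#' @param min_fragment minimum reportable strain-specific fragment, bp
#'   (default 200; shorter slivers are dropped but accounted for).
#' @param k seed k-mer length.
#' @return list of class `core_partition`: `core` (data.frame contig,
#'   start, end), `specific` (data.frame fragment_id, contig, start, end,
#'   length, sequence), and the bp bookkeeping `total_bp`, `core_bp`,
#'   `specific_bp`, `dropped_bp` (which always sum: core + specific +
#'   dropped = total).
#' @export
delineate_core <- function(contigs, reference, min_identity = 90,
                           max_evalue = 1e-5, min_fragment = 200L, k = 15L) {
  reps <- .as_replicons(reference)
  hits <- local_align(contigs, reps, min_identity = min_identity,
                      max_evalue = max_evalue, k = k)
  core <- list()
  specific <- list()
  core_bp <- specific_bp <- dropped_bp <- 0L
  for (cn in names(contigs)) {
    L <- nchar(contigs[[cn]])
    h <- hits[hits$query_id == cn, , drop = FALSE]
    cov <- if (nrow(h)) merge_intervals(data.frame(start = h$qstart, end = h$qend))
           else data.frame(start = integer(0), end = integer(0))
    if (nrow(cov)) {
      core[[length(core) + 1L]] <- data.frame(contig = cn, cov)
      core_bp <- core_bp + sum(cov$end - cov$start + 1L)
    }
    gaps <- complement_intervals(cov, L)
    for (gi in seq_len(nrow(gaps))) {
      glen <- gaps$end[gi] - gaps$start[gi] + 1L
      if (glen < min_fragment) { dropped_bp <- dropped_bp + glen; next }
      specific_bp <- specific_bp + glen
      specific[[length(specific) + 1L]] <- data.frame(
        fragment_id = sprintf("%s:%d-%d", cn, gaps$start[gi], gaps$end[gi]),
        contig = cn, start = gaps$start[gi], end = gaps$end[gi],
        length = glen,
        sequence = substr(contigs[[cn]], gaps$start[gi], gaps$end[gi])
      )
    }
  }
  structure(list(
    core = if (length(core)) do.call(rbind, core) else
      data.frame(contig = character(0), start = integer(0), end = integer(0)),
    specific = if (length(specific)) do.call(rbind, specific) else
      data.frame(fragment_id = character(0), contig = character(0),
                 start = integer(0), end = integer(0), length = integer(0),
                 sequence = character(0)),
    total_bp = sum(nchar(contigs)), core_bp = core_bp,
    specific_bp = specific_bp, dropped_bp = dropped_bp
  ), class = "core_partition")
}

# simple union-find
.uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Build the non-redundant accessory genome
#'
#' Single-linkage clustering of strain-specific fragments under the joint
#' criterion identity >= `min_identity` over an alignment covering at least
#' `min_len_frac` of the shorter fragment. One representative (the longest
#' member; ties broken lexicographically by fragment id) is kept per
#' cluster; member strains are the union of contributors. The result is
#' invariant to input order (fragments are canonically ordered first) and
#' idempotent.
#'
#' @param fragments data.frame with columns `strain_id`, `fragment_id`,
#'   `sequence` (e.g. stacked `specific` tables from [delineate_core()]).
#' @param min_identity percent identity for redundancy (default 90).
#' @param min_len_frac alignment length fraction of the shorter sequence
#'   (default 0.85).
#' @param k seed k-mer length.
#' @return data.frame of class `accessory_genome`: `fragment_id`,
#'   `sequence`, `length`, `n_members`, `members` (list column of strain
#'   ids), `cluster_size`.
#' @export
build_accessory <- function(fragments, min_identity = 90, min_len_frac = 0.85,
                            k = 15L) {
  empty <- data.frame(fragment_id = character(0), sequence = character(0),
                      length = integer(0), n_members = integer(0),
                      cluster_size = integer(0))
  if (is.null(fragments) || nrow(fragments) == 0L) {
    empty$members <- list()
    class(empty) <- c("accessory_genome", "data.frame")
    return(empty)
  }
  f <- fragments
  f$length <- nchar(f$sequence)
  f <- f[order(-f$length, f$fragment_id, f$strain_id), , drop = FALSE]
  n <- nrow(f)
  parent <- seq_len(n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (.uf_find(parent, i) == .uf_find(parent, j)) next
      shorter <- min(f$length[i], f$length[j])
      linked <- if (f$sequence[i] == f$sequence[j]) TRUE else {
        h <- local_align(c(a = f$sequence[i]), c(b = f$sequence[j]),
                         min_identity = min_identity, max_evalue = 10, k = k)
        any(h$length >= min_len_frac * shorter)
      }
      if (linked) parent[.uf_find(parent, j)] <- .uf_find(parent, i)
    }
  }
  root <- vapply(seq_len(n), function(i) .uf_find(parent, i), 0L)
  out <- lapply(unique(root), function(r) {
    m <- f[root == r, , drop = FALSE]
    rep_row <- m[1L, ]  # canonical order: longest, then lexicographic
    data.frame(fragment_id = rep_row$fragment_id,
               sequence = rep_row$sequence, length = rep_row$length,
               n_members = length(unique(m$strain_id)),
               cluster_size = nrow(m))
  })
  out <- do.call(rbind, out)
  out$members <- lapply(unique(root), function(r)
    sort(unique(f$strain_id[root == r])))
  out <- out[order(out$fragment_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("accessory_genome", "data.frame")
  out
}

#' Assign a genomic source to each accessory fragment
#'
#' A fragment aligning at >= `min_identity` over >= `min_len_frac` of its
#' length to a plasmid is plasmid-born; to the chromosome only,
#' chromosome-homologous; to neither, novel. The best reference hit is
#' recorded even below the thresholds (down to `floor_identity`), including
#' any overlapping rRNA copy or gene model - the input the HGT stage needs.
#'
#' @param accessory an `accessory_genome`.
#' @param reference a `ReferenceGenome`.
#' @param min_identity,min_len_frac source thresholds (90 / 0.85).
#' @param floor_identity reporting floor for the best hit (default 50).
#' @param k seed k-mer length.
#' @return `accessory` with columns `source`, `best_hit_replicon`,
#'   `best_hit_start`, `best_hit_end`, `best_hit_identity`,
#'   `best_hit_feature` added.
#' @export
assign_source <- function(accessory, reference, min_identity = 90,
                          min_len_frac = 0.85, floor_identity = 50, k = 15L) {
  n <- nrow(accessory)
  src <- character(n)
  bh_rep <- bh_feat <- character(n)
  bh_s <- bh_e <- rep(NA_integer_, n)
  bh_id <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    frag <- accessory$sequence[i]
    flen <- accessory$length[i]
    hits <- local_align(c(frag = frag), reference$replicons,
                        min_identity = floor_identity, max_evalue = 1e-5, k = k)
    strong <- hits[hits$identity >= min_identity &
                   hits$length >= min_len_frac * flen, , drop = FALSE]
    roles <- reference$roles[strong$subject_id]
    src[i] <- if (nrow(strong) && any(roles == "plasmid")) {
      sprintf("plasmid-born(%s)", strong$subject_id[which(roles == "plasmid")[1L]])
    } else if (nrow(strong)) "chromosome-homologous" else "novel"
    if (nrow(hits)) {
      b <- hits[1L, ]
      bh_rep[i] <- b$subject_id
      bh_s[i] <- b$sstart; bh_e[i] <- b$send
      bh_id[i] <- b$identity
      rr <- reference$rrna_copies
      rr <- rr[rr$replicon_id == b$subject_id &
               rr$start <= b$send & rr$end >= b$sstart, , drop = FALSE]
      if (nrow(rr)) {
        bh_feat[i] <- sprintf("23S_rRNA(%s:%d-%d)", rr$replicon_id[1L],
                              rr$start[1L], rr$end[1L])
      } else {
        gm <- reference$gene_models
        gm <- gm[gm$replicon_id == b$subject_id &
                 gm$start <= b$send & gm$end >= b$sstart, , drop = FALSE]
        if (nrow(gm)) bh_feat[i] <- gm$gene_id[1L]
      }
    }
  }
  accessory$source <- src
  accessory$best_hit_replicon <- bh_rep
  accessory$best_hit_start <- bh_s
  accessory$best_hit_end <- bh_e
  accessory$best_hit_identity <- bh_id
  accessory$best_hit_feature <- bh_feat
  accessory
}

#' Write the accessory genome as multi-FASTA plus a membership matrix
#' @param accessory an `accessory_genome`.
#' @param fasta,membership_tsv output paths (NULL to skip either).
#' @param strains optional full strain list for the matrix columns.
#' @export
write_accessory <- function(accessory, fasta = NULL, membership_tsv = NULL,
                            strains = NULL) {
  if (!is.null(fasta) && nrow(accessory)) {
    seqs <- accessory$sequence
    names(seqs) <- accessory$fragment_id
    write_fasta(seqs, fasta)
  }
  if (!is.null(membership_tsv)) {
    if (is.null(strains)) strains <- sort(unique(unlist(accessory$members)))
    m <- sapply(strains, function(s)
      as.integer(vapply(accessory$members, function(mm) s %in% mm, TRUE)))
    m <- matrix(m, nrow = nrow(accessory),
                dimnames = list(accessory$fragment_id, strains))
    utils::write.table(data.frame(fragment_id = rownames(m), m,
                                  check.names = FALSE),
                       membership_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(accessory)
}

#' Export core intervals as BED (0-based half-open)
#' @param partition a `core_partition`.
#' @param path output BED.
#' @export
write_core_bed <- function(partition, path) {
  x <- partition$core
  writeLines(paste(x$contig, x$start - 1L, x$end, sep = "\t"), path)
  invisible(path)
}
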
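# Seed-and-extend local nucleotide alignment: exact k-mer seeds, collinear
# same-diagonal joining, X-drop ungapped extension, and cross-diagonal
# chaining with affine gap costs. Behaves like ungapped-parameter BLASTn at
# the ~90% identity regime this package works in; e-values use the
# Karlin-Altschul formula with fixed ungapped nucleotide parameters
# (lambda = 1.28, K = 0.46) and are approximate by design - thresholding
# behaviour, not exact BLAST e-values, is the contract.

.KA_LAMBDA <- 1.28
.KA_K <- 0.46

.default_align_params <- function(k = 15L, xdrop = 30L, max_gap = 100L,
                                  gap_open = 5L, gap_ext = 2L,
                                  min_length = 30L, max_seed_hits = 256L) {
  list(k = as.integer(k), xdrop = xdrop, max_gap = max_gap,
       gap_open = gap_open, gap_ext = gap_ext, min_length = min_length,
       max_seed_hits = max_seed_hits)
}

# Collapse seed pairs into maximal exact runs on each diagonal.
.collapse_seeds <- function(seeds, k) {
  d <- seeds[, "spos"] - seeds[, "qpos"]
  o <- order(d, seeds[, "qpos"])
  q <- seeds[o, "qpos"]
  dd <- d[o]
  new <- c(TRUE, diff(dd) != 0 | diff(q) > k)
  last <- c(new[-1L], TRUE)
  qs <- q[new]
  qe <- q[last] + k - 1L
  data.frame(qs = qs, qe = qe, ss = qs + dd[new], se = qe + dd[new],
             matches = qe - qs + 1L, mism = 0L)
}

# Merge runs on the same diagonal when the intervening region scores no
# worse than -xdrop under match +1 / mismatch -2.
.join_runs <- function(runs, qi, si, xdrop) {
  runs <- runs[order(runs$ss - runs$qs, runs$qs), , drop = FALSE]
  keep <- logical(nrow(runs))
  cur <- runs[1L, ]
  out <- list()
  push <- function(r) out[[length(out) + 1L]] <<- r
  for (i in seq_len(nrow(runs))[-1L]) {
    r <- runs[i, ]
    same_diag <- (r$ss - r$qs) == (cur$ss - cur$qs)
    if (same_diag && r$qs > cur$qe) {
      g <- r$qs - cur$qe - 1L
      if (g == 0L) m <- 0L else {
        a <- qi[(cur$qe + 1L):(r$qs - 1L)]
        b <- si[(cur$se + 1L):(r$ss - 1L)]
        m <- sum(a != b | a >= 4L)
      }
      if (g - 3L * m >= -xdrop) {
        cur$qe <- r$qe; cur$se <- r$se
        cur$matches <- cur$matches + (g - m) + r$matches
        cur$mism <- cur$mism + m + r$mism
        next
      }
    }
    push(cur)
    cur <- r
  }
  push(cur)
  do.call(rbind, out)
}

# Ungapped X-drop extension of one run end; returns steps taken and
# mismatches within them.
.xdrop_extend <- function(qi, si, qpos, spos, dir, xdrop, window = 200L) {
  total <- 0L
  mism <- 0L
  repeat {
    if (dir > 0L) {
      w <- min(window, length(qi) - qpos, length(si) - spos)
      if (w <= 0L) break
      a <- qi[(qpos + 1L):(qpos + w)]
      b <- si[(spos + 1L):(spos + w)]
    } else {
      w <- min(window, qpos - 1L, spos - 1L)
      if (w <= 0L) break
      a <- qi[(qpos - 1L):(qpos - w)]
      b <- si[(spos - 1L):(spos - w)]
    }
    bad <- a != b | a >= 4L
    sc <- cumsum(ifelse(bad, -2L, 1L))
    drop <- cummax(sc) - sc >= xdrop
    t <- if (any(drop)) which(drop)[1L] else w
    best <- which.max(sc[seq_len(t)])
    if (sc[best] <= 0L) best <- 0L
    if (best > 0L) {
      total <- total + best
      mism <- mism + sum(bad[seq_len(best)])
      qpos <- qpos + dir * best
      spos <- spos + dir * best
    }
    if (best < w || any(drop)) break
  }
  list(steps = total, mism = mism)
}

# Chain extended runs across nearby diagonals (affine gap cost), greedily
# extracting disjoint maximal chains. Returns a list of integer vectors of
# run indices.
.chain_runs <- function(runs, max_gap, gap_open, gap_ext) {
  n <- nrow(runs)
  o <- order(runs$qs, runs$ss)
  runs <- runs[o, , drop = FALSE]
  base <- runs$matches - 2L * runs$mism
  score <- base
  prev <- rep(NA_integer_, n)
  if (n > 1L) {
    for (i in 2:n) {
      for (j in 1:(i - 1L)) {
        qg <- runs$qs[i] - runs$qe[j] - 1L
        sg <- runs$ss[i] - runs$se[j] - 1L
        if (qg < 0L || sg < 0L || qg > max_gap || sg > max_gap) next
        dgap <- abs(qg - sg)
        cost <- 2L * min(qg, sg) + if (dgap > 0L) gap_open + gap_ext * dgap else 0L
        cand <- score[j] + base[i] - cost
        if (cand > score[i]) { score[i] <- cand; prev[i] <- j }
      }
    }
  }
  used <- logical(n)
  chains <- list()
  for (i in order(score, decreasing = TRUE)) {
    if (used[i]) next
    ch <- integer(0)
    node <- i
    ok <- TRUE
    while (!is.na(node)) {
      if (used[node]) { ok <- FALSE; break }
      ch <- c(node, ch)
      node <- prev[node]
    }
    if (!ok) next
    used[ch] <- TRUE
    chains[[length(chains) + 1L]] <- o[ch]
  }
  chains
}

# Align integer-encoded query vs subject, one orientation. Returns a list of
# hits, each a list(stats = named numeric, segments = data.frame).
.align_ints <- function(qi, si, scodes, p, drop_diag0 = FALSE) {
  qcodes <- kmer_codes(qi, p$k)
  seeds <- seed_matches(qcodes, scodes, p$max_seed_hits)
  if (drop_diag0)
    seeds <- seeds[seeds[, "spos"] != seeds[, "qpos"], , drop = FALSE]
  if (nrow(seeds) == 0L) return(list())
  runs <- .collapse_seeds(seeds, p$k)
  runs <- .join_runs(runs, qi, si, p$xdrop)
  for (i in seq_len(nrow(runs))) {
    L <- .xdrop_extend(qi, si, runs$qs[i], runs$ss[i], -1L, p$xdrop)
    R <- .xdrop_extend(qi, si, runs$qe[i], runs$se[i], +1L, p$xdrop)
    runs$qs[i] <- runs$qs[i] - L$steps
    runs$ss[i] <- runs$ss[i] - L$steps
    runs$qe[i] <- runs$qe[i] + R$steps
    runs$se[i] <- runs$se[i] + R$steps
    runs$matches[i] <- runs$matches[i] + (L$steps - L$mism) + (R$steps - R$mism)
    runs$mism[i] <- runs$mism[i] + L$mism + R$mism
  }
  chains <- .chain_runs(runs, p$max_gap, p$gap_open, p$gap_ext)
  lapply(chains, function(ix) {
    rr <- runs[ix, , drop = FALSE]
    rr <- rr[order(rr$qs), , drop = FALSE]
    matches <- sum(rr$matches)
    mism <- sum(rr$mism)
    gapcols <- 0L
    gapopens <- 0L
    score <- matches - 2L * mism
    if (nrow(rr) > 1L) {
      for (i in 2:nrow(rr)) {
        qg <- rr$qs[i] - rr$qe[i - 1L] - 1L
        sg <- rr$ss[i] - rr$se[i - 1L] - 1L
        mm <- min(qg, sg)
        dg <- abs(qg - sg)
        mism <- mism + mm
        gapcols <- gapcols + dg
        if (dg > 0L) gapopens <- gapopens + 1L
        score <- score - 2L * mm - if (dg > 0L) p$gap_open + p$gap_ext * dg else 0L
      }
    }
    cols <- matches + mism + gapcols
    list(stats = c(qstart = rr$qs[1L], qend = rr$qe[nrow(rr)],
                   sstart = rr$ss[1L], send = rr$se[nrow(rr)],
                   matches = matches, mismatches = mism,
                   gapopens = gapopens, length = cols,
                   identity = 100 * matches / cols, score = score),
         segments = data.frame(qstart = rr$qs, sstart = rr$ss,
                               length = rr$qe - rr$qs + 1L))
  })
}

.revcomp_ints <- function(v) {
  w <- rev(v)
  ifelse(w < 4L, 3L - w, 4L)
}

#' Local alignment of nucleotide sequences
#'
#' Aligns every query against every subject on both strands and reports
#' local alignment hits passing the identity, e-value and length filters,
#' sorted by score (descending). Identity is matches over alignment columns
#' (mismatch and gap columns included). Query coordinates of minus-strand
#' hits are reported on the original query; the per-hit ungapped segment
#' decomposition (attribute `"segments"`) is in aligned orientation.
#'
#' @param query,subject named character vectors of DNA sequences (a single
#'   unnamed string is accepted).
#' @param min_identity minimum percent identity (default 90).
#' @param max_evalue maximum e-value (default 1e-5).
#' @param k seed k-mer length (default 15).
#' @param min_length minimum alignment length in columns (default 30).
#' @param xdrop X-drop threshold for ungapped extension (match +1,
#'   mismatch -2).
#' @param max_gap maximum per-side gap bridged when chaining (bp).
#' @param gap_open,gap_ext affine gap penalties (default 5 / 2).
#' @param max_n_frac maximum tolerated N fraction per sequence.
#' @param exclude_self_diagonal drop the trivial self-match when a sequence
#'   is compared against itself (same name, identical sequence).
#' @return data.frame of class `alignment_hits` with columns `query_id`,
#'   `subject_id`, `identity`, `length`, `mismatches`, `gapopens`, `qstart`,
#'   `qend`, `sstart`, `send`, `strand`, `evalue`, `score`; attribute
#'   `"segments"` holds one data.frame per row.
#' @export
local_align <- function(query, subject, min_identity = 90, max_evalue = 1e-5,
                        k = 15L, min_length = 30L, xdrop = 30L, max_gap = 100L,
                        gap_open = 5L, gap_ext = 2L, max_n_frac = 0.5,
                        exclude_self_diagonal = FALSE) {
  if (is.null(names(query)) && is.character(query))
    names(query) <- paste0("query", seq_along(query))
  if (is.null(names(subject)) && is.character(subject))
    names(subject) <- paste0("subject", seq_along(subject))
  if (any(!nzchar(query)) || any(!nzchar(subject)))
    stop("empty sequence")
  p <- .default_align_params(k = k, xdrop = xdrop, max_gap = max_gap,
                             gap_open = gap_open, gap_ext = gap_ext,
                             min_length = min_length)
  check_n <- function(x, lab) {
    v <- dna_to_int(x)
    if (mean(v >= 4L) > max_n_frac) stop(lab, ": N fraction exceeds ", max_n_frac)
    v
  }
  s_ints <- lapply(subject, check_n, lab = "subject")
  s_codes <- lapply(s_ints, kmer_codes, k = p$k)

  rows <- list()
  segs <- list()
  for (qn in names(query)) {
    qi <- check_n(query[[qn]], "query")
    qlen <- length(qi)
    qi_rc <- .revcomp_ints(qi)
    for (sn in names(subject)) {
      self <- exclude_self_diagonal && identical(query[[qn]], subject[[sn]])
      m <- qlen
      n <- length(s_ints[[sn]])
      for (strand in c("+", "-")) {
        vi <- if (strand == "+") qi else qi_rc
        hits <- .align_ints(vi, s_ints[[sn]], s_codes[[sn]], p,
                            drop_diag0 = self && strand == "+")
        for (h in hits) {
          st <- h$stats
          ev <- .KA_K * m * n * exp(-.KA_LAMBDA * st[["score"]])
          if (st[["identity"]] < min_identity || ev > max_evalue ||
              st[["length"]] < p$min_length) next
          qs <- st[["qstart"]]; qe <- st[["qend"]]
          if (strand == "-") { tmp <- qs; qs <- qlen - qe + 1L; qe <- qlen - tmp + 1L }
          rows[[length(rows) + 1L]] <- data.frame(
            query_id = qn, subject_id = sn,
            identity = st[["identity"]], length = st[["length"]],
            mismatches = st[["mismatches"]], gapopens = st[["gapopens"]],
            qstart = qs, qend = qe,
            sstart = st[["sstart"]], send = st[["send"]],
            strand = strand, evalue = ev, score = st[["score"]]
          )
          segs[[length(segs) + 1L]] <- h$segments
        }
      }
    }
  }
  if (!length(rows)) {
    out <- data.frame(query_id = character(0), subject_id = character(0),
                      identity = numeric(0), length = integer(0),
                      mismatches = integer(0), gapopens = integer(0),
                      qstart = integer(0), qend = integer(0),
                      sstart = integer(0), send = integer(0),
                      strand = character(0), evalue = numeric(0),
                      score = numeric(0))
    attr(out, "segments") <- list()
    class(out) <- c("alignment_hits", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  o <- order(out$score, decreasing = TRUE)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "segments") <- segs[o]
  class(out) <- c("alignment_hits", "data.frame")
  out
}

#' Write alignment hits in 12-column tabular (outfmt-6 compatible) format
#'
#' Minus-strand hits follow the BLAST convention of swapped subject
#' coordinates; score is converted to a bit score.
#' @param hits an `alignment_hits` data.frame.
#' @param path output TSV.
#' @export
write_hits <- function(hits, path) {
  bits <- (.KA_LAMBDA * hits$score - log(.KA_K)) / log(2)
  ss <- ifelse(hits$strand == "-", hits$send, hits$sstart)
  se <- ifelse(hits$strand == "-", hits$sstart, hits$send)
  tab <- data.frame(hits$query_id, hits$subject_id,
                    sprintf("%.2f", hits$identity), hits$length,
                    hits$mismatches, hits$gapopens, hits$qstart, hits$qend,
                    ss, se, format(hits$evalue, digits = 3), round(bits, 1))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
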
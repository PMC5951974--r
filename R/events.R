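# Derived-strain construction: plant substitutions, plasmid losses and an
# acquired (HGT-like) fragment into a reference genome, recording every event
# in a ground-truth ledger used by the recovery tests.

#' Specify events for a derived strain
#'
#' @param snps data.frame with columns `replicon_id`, `pos`, `ref_base`,
#'   `alt_base` and optionally `intended_class` (one of `synonymous`,
#'   `non-synonymous`, `nonsense`, `intergenic`). NULL for none.
#' @param plasmid_losses list of lists with fields `plasmid_id`,
#'   `mode` (`"complete"` or `"partial"`), and for partial losses either
#'   `plr` (target loss fraction; a contiguous region is chosen) or
#'   `intervals` (data.frame of `start`,`end` to delete).
#' @param acquisitions list of lists with fields `sequence` (donor-derived
#'   DNA), `replicon_id`, `pos` (inserted after this reference position).
#' @return list of class `event_spec`.
#' @export
event_spec <- function(snps = NULL, plasmid_losses = NULL, acquisitions = NULL) {
  structure(list(snps = snps, plasmid_losses = plasmid_losses,
                 acquisitions = acquisitions),
            class = "event_spec")
}

#' Plant events into a reference genome
#'
#' Applies the specification in order SNPs -> acquisitions -> plasmid losses.
#' Every SNP's reference base is checked against the genome and, when an
#' intended effect class is given, the realized codon-level effect must match
#' it or the event is rejected with a diagnostic. Complete plasmid loss
#' removes the replicon; partial loss deletes the requested intervals and the
#' realized PLR (deleted length / plasmid length) is recorded.
#'
#' @param ref a `ReferenceGenome`.
#' @param spec an [event_spec()].
#' @param seed integer seed (used when partial-loss intervals are chosen).
#' @param strain_id label recorded in the truth ledger.
#' @return list with `genome` (named character vector of derived replicons)
#'   and `truth` (class `TruthRecord`).
#' @export
plant_events <- function(ref, spec, seed = 1L, strain_id = "strain") {
  genome <- ref$replicons
  truth <- list(strain_id = strain_id,
                snps = NULL, plasmid_losses = NULL, acquisitions = NULL)

  if (!is.null(spec$snps) && nrow(spec$snps) > 0L) {
    sn <- spec$snps
    eff <- character(nrow(sn))
    prot <- character(nrow(sn))
    for (i in seq_len(nrow(sn))) {
      r <- sn$replicon_id[i]; p <- sn$pos[i]
      if (!r %in% names(genome)) stop("unknown replicon: ", r)
      have <- substr(genome[[r]], p, p)
      if (have != sn$ref_base[i])
        stop(sprintf("SNP at %s:%d: reference base is %s, spec says %s",
                     r, p, have, sn$ref_base[i]))
      gm <- ref$gene_models[ref$gene_models$replicon_id == r, , drop = FALSE]
      e <- snp_effect(ref$replicons[[r]], gm, p, sn$ref_base[i], sn$alt_base[i])
      if (!is.null(sn$intended_class) && !is.na(sn$intended_class[i]) &&
          e$mut_type != sn$intended_class[i])
        stop(sprintf(
          "SNP at %s:%d (%s>%s): intended class '%s' is not achievable here (realized '%s')",
          r, p, sn$ref_base[i], sn$alt_base[i], sn$intended_class[i], e$mut_type))
      substr(genome[[r]], p, p) <- sn$alt_base[i]
      eff[i] <- e$mut_type
      prot[i] <- e$protein_change
    }
    sn$effect_class <- eff
    sn$protein_change <- prot
    truth$snps <- sn
  }

  if (!is.null(spec$acquisitions) && length(spec$acquisitions) > 0L) {
    acq <- list()
    for (a in spec$acquisitions) {
      r <- a$replicon_id
      frag <- toupper(a$sequence)
      p <- a$pos
      s <- genome[[r]]
      if (p < 0L || p > nchar(s)) stop("acquisition position outside replicon")
      genome[[r]] <- paste0(substr(s, 1L, p), frag, substr(s, p + 1L, nchar(s)))
      acq[[length(acq) + 1L]] <- data.frame(
        replicon_id = r, ref_pos = p, length = nchar(frag),
        derived_start = p + 1L, derived_end = p + nchar(frag)
      )
    }
    truth$acquisitions <- do.call(rbind, acq)
  }

  if (!is.null(spec$plasmid_losses) && length(spec$plasmid_losses) > 0L) {
    pls <- list()
    with_seed(derive_seed(seed, 97L), {
      for (ev in spec$plasmid_losses) {
        pid <- ev$plasmid_id
        if (!pid %in% names(genome)) stop("unknown plasmid: ", pid)
        if (identical(ref$roles[[pid]], "chromosome"))
          stop("cannot delete the chromosome")
        plen <- nchar(ref$replicons[[pid]])
        if (identical(ev$mode, "complete")) {
          genome <- genome[names(genome) != pid]
          pls[[length(pls) + 1L]] <- data.frame(
            plasmid_id = pid, mode = "complete", plr = 1.0,
            del_start = 1L, del_end = plen)
        } else if (identical(ev$mode, "partial")) {
          if (!is.null(ev$intervals)) {
            iv <- merge_intervals(ev$intervals)
          } else {
            dlen <- as.integer(round(ev$plr * plen))
            if (dlen < 1L || dlen >= plen)
              stop("partial-loss PLR must leave a remainder in (0, 1)")
            st <- sample.int(plen - dlen + 1L, 1L)
            iv <- data.frame(start = st, end = st + dlen - 1L)
          }
          if (any(iv$start < 1L) || any(iv$end > plen))
            stop("deletion intervals outside plasmid ", pid)
          keep <- complement_intervals(iv, plen)
          genome[[pid]] <- paste(substring(genome[[pid]], keep$start, keep$end),
                                 collapse = "")
          pls[[length(pls) + 1L]] <- data.frame(
            plasmid_id = pid, mode = "partial",
            plr = interval_length(iv$start, iv$end) / plen,
            del_start = iv$start, del_end = iv$end)
        } else stop("loss mode must be 'complete' or 'partial'")
      }
    })
    truth$plasmid_losses <- do.call(rbind, pls)
  }

  class(truth) <- "TruthRecord"
  list(genome = genome, truth = truth)
}

#' @export
print.TruthRecord <- function(x, ...) {
  cat("TruthRecord for", x$strain_id, "\n")
  cat("  SNPs:", if (is.null(x$snps)) 0L else nrow(x$snps), "\n")
  if (!is.null(x$plasmid_losses))
    cat("  plasmid losses:",
        paste(sprintf("%s (%s, PLR %.3f)", x$plasmid_losses$plasmid_id,
                      x$plasmid_losses$mode, x$plasmid_losses$plr),
              collapse = "; "), "\n")
  if (!is.null(x$acquisitions))
    cat("  acquisitions:", nrow(x$acquisitions), "fragment(s),",
        sum(x$acquisitions$length), "bp\n")
  invisible(x)
}

#' Write a truth record as JSON
#' @param truth a `TruthRecord`.
#' @param path output file.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

# Positions on a replicon excluded from SNP planting: annotated repeats plus a
# safety margin, and the replicon ends (read-coverage edge effects).
.blocked_intervals <- function(ref, replicon_id, margin = 150L, edge = 300L) {
  len <- nchar(ref$replicons[[replicon_id]])
  rr <- ref$repeat_regions[ref$repeat_regions$replicon_id == replicon_id, , drop = FALSE]
  iv <- data.frame(start = pmax(1L, rr$start - margin),
                   end = pmin(len, rr$end + margin))
  iv <- rbind(iv, data.frame(start = c(1L, len - edge + 1L),
                             end = c(edge, len)))
  merge_intervals(iv)
}

#' Derive an event specification from a SNP catalog
#'
#' For each catalog row, finds a chromosome site carrying the catalog's
#' reference base where substituting the alternate base realizes the
#' catalog's effect class (synonymous / non-synonymous / nonsense inside a
#' CDS; intergenic outside all gene models). Sites avoid annotated repeats
#' (with a 150-bp margin), the replicon ends, the terminal stop codon, and
#' each coding SNP is placed in a distinct gene, mirroring the catalog's
#' one-gene-per-SNP structure.
#'
#' @param ref a `ReferenceGenome`.
#' @param catalog a catalog from [load_snp_catalog()].
#' @param seed integer seed.
#' @return data.frame usable as the `snps` slot of [event_spec()].
#' @export
catalog_event_spec <- function(ref, catalog, seed = 1L) {
  chrom <- "chromosome"
  seq <- ref$replicons[[chrom]]
  gm <- ref$gene_models[ref$gene_models$replicon_id == chrom, , drop = FALSE]
  blocked <- .blocked_intervals(ref, chrom)
  seq_int <- dna_to_int(seq)

  with_seed(derive_seed(seed, 11L), {
    used_genes <- character(0)
    used_pos <- integer(0)
    rows <- list()
    g_ok <- gm
    for (i in seq_len(nrow(catalog))) {
      ref_b <- catalog$ref_base[i]; alt_b <- catalog$alt_base[i]
      cls <- catalog$mut_type[i]
      found <- FALSE
      if (cls == "intergenic") {
        cand <- which(seq_int == .base_lut[utf8ToInt(ref_b)])
        cand <- cand[!positions_in_intervals(cand, blocked)]
        cand <- cand[!positions_in_intervals(cand, gm[, c("start", "end")])]
        cand <- setdiff(cand, used_pos)
        if (length(cand)) {
          p <- sample(cand, 1L)
          rows[[i]] <- data.frame(replicon_id = chrom, pos = p,
                                  ref_base = ref_b, alt_base = alt_b,
                                  intended_class = cls)
          used_pos <- c(used_pos, p)
          found <- TRUE
        }
      } else {
        for (gi in sample(seq_len(nrow(g_ok)))) {
          g <- g_ok[gi, ]
          if (g$gene_id %in% used_genes) next
          # skip the terminal stop codon; sites must clear the repeat margin
          body <- if (g$strand == "+") c(g$start, g$end - 3L) else c(g$start + 3L, g$end)
          cand <- body[1L] - 1L + which(seq_int[body[1L]:body[2L]] ==
                                          .base_lut[utf8ToInt(ref_b)])
          cand <- cand[!positions_in_intervals(cand, blocked)]
          cand <- setdiff(cand, used_pos)
          if (!length(cand)) next
          for (p in sample(cand, min(length(cand), 40L))) {
            e <- snp_effect(seq, gm, p, ref_b, alt_b)
            if (e$mut_type == cls) {
              rows[[i]] <- data.frame(replicon_id = chrom, pos = p,
                                      ref_base = ref_b, alt_base = alt_b,
                                      intended_class = cls)
              used_genes <- c(used_genes, g$gene_id)
              used_pos <- c(used_pos, p)
              found <- TRUE
              break
            }
          }
          if (found) break
        }
      }
      if (!found)
        stop("no site found realizing ", cls, " for ", ref_b, ">", alt_b,
             " (catalog row ", i, ")")
    }
    out <- do.call(rbind, rows)
    out$snp_id <- catalog$SNP_ID
    out
  })
}

#' Construct the acquired 23S-like fragment and its donor gene
#'
#' Emulates a horizontally acquired rRNA fragment: the 609-bp interval
#' 1215-1823 of the reference's first 23S-like rRNA copy is mutated with 64
#' quasi-uniformly spread substitutions (realized identity just below 90%
#' against every rRNA copy, so the fragment falls outside the >= 90% core
#' threshold), and a full-length donor rRNA gene is built around the
#' fragment with a further ~3% divergence, so the fragment shows ~97%
#' identity to the donor and ~90% to the host 23S - the signature of a
#' cross-species transfer.
#'
#' @param ref a `ReferenceGenome`.
#' @param seed integer seed.
#' @param window 1-based inclusive interval on the rRNA gene (default
#'   c(1215, 1823)).
#' @param n_sub_host substitutions distinguishing fragment from host rRNA
#'   (default 65 over 609 bp, placed clear of the fragment ends so the
#'   full-length alignment is recovered and its identity stays below the
#'   core threshold against every rRNA copy).
#' @param donor_divergence further divergence of the donor copy (default 0.03).
#' @return list with `fragment` (DNA string), `donor` (named character
#'   vector, a donor rRNA gene FASTA-ready), `window`, `rrna_interval`.
#' @export
make_hgt_fragment <- function(ref, seed = 1L, window = c(1215L, 1823L),
                              n_sub_host = 65L, donor_divergence = 0.03) {
  rr <- ref$rrna_copies[1L, ]
  gene <- substr(ref$replicons[[rr$replicon_id]], rr$start, rr$end)
  if (nchar(gene) < window[2L]) stop("rRNA gene shorter than requested window")
  with_seed(derive_seed(seed, 23L), {
    host_win <- substr(gene, window[1L], window[2L])
    L <- nchar(host_win)
    at <- sample(6:(L - 5L), n_sub_host)
    fragment <- mutate_bases(host_win, length(at), at = at)
    # donor gene: fragment sits in the window; donor drifts ~3% from it
    n_d <- as.integer(round(donor_divergence * nchar(fragment)))
    donor_win <- mutate_bases(fragment, n_d)
    flank_l <- mutate_bases(substr(gene, 1L, window[1L] - 1L),
                            as.integer(round(0.1 * (window[1L] - 1L))))
    flank_r <- mutate_bases(substr(gene, window[2L] + 1L, nchar(gene)),
                            as.integer(round(0.1 * (nchar(gene) - window[2L]))))
    donor <- paste0(flank_l, donor_win, flank_r)
    list(fragment = fragment,
         donor = c(donor_23S_rRNA = donor),
         window = window,
         rrna_interval = rr)
  })
}

#' Choose an intergenic insertion site for an acquired fragment
#'
#' @param ref a `ReferenceGenome`.
#' @param seed integer seed.
#' @param margin clearance from genes and annotated repeats, bp.
#' @return a single chromosome position (fragment inserted after it).
#' @export
pick_insertion_site <- function(ref, seed = 1L, margin = 200L) {
  chrom <- "chromosome"
  len <- nchar(ref$replicons[[chrom]])
  gm <- ref$gene_models[ref$gene_models$replicon_id == chrom, , drop = FALSE]
  free <- NULL
  for (m in unique(pmin(margin, c(margin, 100L, 50L, 20L)))) {
    blocked <- merge_intervals(rbind(
      .blocked_intervals(ref, chrom, margin = max(m, 150L), edge = 1000L),
      data.frame(start = pmax(1L, gm$start - m),
                 end = pmin(len, gm$end + m)),
      data.frame(start = pmax(1L, ref$rrna_copies$start - m),
                 end = pmin(len, ref$rrna_copies$end + m))
    ))
    free <- complement_intervals(blocked, len)
    if (nrow(free)) break
  }
  if (nrow(free) == 0L) stop("no intergenic insertion site available")
  with_seed(derive_seed(seed, 31L), {
    free <- free[free$end - free$start >= 2L, , drop = FALSE]
    r <- free[sample.int(nrow(free), 1L), ]
    sample(r$start:r$end, 1L)
  })
}
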
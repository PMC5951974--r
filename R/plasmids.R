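# Replicon dynamics: coverage-breadth presence calls (> 80% present,
# < 20% absent, in between explicitly ambiguous), the plasmid loss ratio
# (PLR = missing length / plasmid length) with its loss-type classification,
# in-silico confirmation of entire loss via plasmid-specific regions, and
# acquired-fragment (HGT) flagging.

#' Coverage breadth of a depth track
#'
#' @param depth integer/numeric vector of per-position depth.
#' @param intervals optional data.frame (`start`, `end`) restricting the
#'   computation; default whole track.
#' @return fraction of positions with depth >= 1.
#' @export
coverage_breadth <- function(depth, intervals = NULL) {
  if (is.null(intervals)) return(mean(depth >= 1))
  m <- merge_intervals(intervals)
  pos <- unlist(Map(seq.int, m$start, m$end))
  mean(depth[pos] >= 1)
}

#' Presence call from coverage breadth
#'
#' Breadth above `present` is present, below `absent` is absent; the band in
#' between is reported as ambiguous rather than forced to a binary call.
#'
#' @param breadth numeric vector of breadth fractions.
#' @param present,absent thresholds (defaults 0.8 / 0.2, strict).
#' @return character vector: `present` / `absent` / `ambiguous`.
#' @export
call_presence <- function(breadth, present = 0.8, absent = 0.2) {
  if (present <= absent) stop("presence threshold must exceed absence threshold")
  ifelse(breadth > present, "present",
         ifelse(breadth < absent, "absent", "ambiguous"))
}

#' Missing intervals from a depth track
#'
#' Maximal runs of zero depth at least `min_run` bp long, smoothing over the
#' short random gaps expected at finite depth.
#'
#' @param depth per-position depth vector.
#' @param min_run minimum zero-run length in bp (default 300).
#' @return data.frame `start`, `end`.
#' @export
missing_intervals <- function(depth, min_run = 300L) {
  r <- rle(depth == 0)
  en <- cumsum(r$lengths)
  st <- en - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  data.frame(start = st[keep], end = en[keep])
}

#' Plasmid loss ratio
#' @param missing data.frame of missing intervals (`start`, `end`).
#' @param plasmid_length plasmid length in bp (> 0).
#' @return PLR in `[0, 1]`.
#' @export
compute_plr <- function(missing, plasmid_length) {
  if (plasmid_length <= 0L) stop("plasmid length must be positive")
  if (is.null(missing) || nrow(missing) == 0L) return(0)
  if (any(missing$start < 1L) || any(missing$end > plasmid_length))
    stop("missing intervals outside plasmid")
  interval_length(missing$start, missing$end) / plasmid_length
}

#' Classify a plasmid loss ratio
#'
#' Bins: 0 = none; (0, 0.7) = `<70%`; `[0.7, 0.8)` = `70-80%`;
#' `[0.8, 0.9)` = `80-90%`; `[0.9, 1)` = `90-100%`; 1 = complete. The four
#' non-trivial types match the observed loss classes; the `90-100%` bin
#' makes the classifier total over `[0, 1]`.
#'
#' @param plr numeric vector of loss ratios in `[0, 1]`.
#' @return character vector of loss classes.
#' @export
classify_loss <- function(plr) {
  if (any(plr < 0 | plr > 1)) stop("PLR must lie in [0, 1]")
  out <- character(length(plr))
  out[plr == 0] <- "none"
  out[plr > 0 & plr < 0.7] <- "<70%"
  out[plr >= 0.7 & plr < 0.8] <- "70-80%"
  out[plr >= 0.8 & plr < 0.9] <- "80-90%"
  out[plr >= 0.9 & plr < 1] <- "90-100%"
  out[plr == 1] <- "complete"
  out
}

#' Confirm entire plasmid loss via plasmid-specific regions
#'
#' Mirrors the two-step logic of coverage screening followed by
#' plasmid-specific PCR: the whole-plasmid coverage call must be absent, and
#' the plasmid-specific regions (the plasmid minus its chromosome-homologous
#' segments) must be essentially uncovered (breadth below
#' `max_specific_breadth`; a partially retained plasmid would still amplify
#' from its remaining specific regions, so the screening-level `absent`
#' threshold is deliberately not enough for confirmation). A plasmid with no
#' specific region cannot be confirmed either way and returns
#' `"indeterminate"`.
#'
#' @param map a `map_result` against the reference.
#' @param reference a `ReferenceGenome`.
#' @param plasmid_id plasmid replicon id.
#' @param present,absent breadth thresholds (defaults 0.8 / 0.2).
#' @param max_specific_breadth maximum specific-region breadth compatible
#'   with entire loss (default 0.02).
#' @return `"confirmed"`, `"not-confirmed"` or `"indeterminate"`.
#' @export
confirm_entire_loss <- function(map, reference, plasmid_id,
                                present = 0.8, absent = 0.2,
                                max_specific_breadth = 0.02) {
  plen <- nchar(reference$replicons[[plasmid_id]])
  hm <- reference$homology_map
  hm <- hm[hm$plasmid_id == plasmid_id, , drop = FALSE]
  specific <- complement_intervals(
    data.frame(start = hm$p_start, end = hm$p_end), plen)
  if (nrow(specific) == 0L) return("indeterminate")
  depth <- map$depth[[plasmid_id]]
  whole <- call_presence(coverage_breadth(depth), present, absent)
  spec_b <- coverage_breadth(depth, specific)
  if (spec_b < max_specific_breadth && whole == "absent") "confirmed"
  else "not-confirmed"
}

#' Per-plasmid loss report for one strain
#'
#' @param map a `map_result` of the strain's reads against the reference.
#' @param reference a `ReferenceGenome`.
#' @param min_run zero-run smoothing for missing intervals (default 300 bp).
#' @param present,absent presence thresholds.
#' @param strain_id label for the report.
#' @return data.frame of class `plasmid_report`: plasmid, length, breadth,
#'   mean depth, presence call, PLR, loss class, entire-loss confirmation.
#' @export
plasmid_report <- function(map, reference, min_run = 300L,
                           present = 0.8, absent = 0.2, strain_id = "strain") {
  plasmids <- names(reference$replicons)[reference$roles == "plasmid"]
  rows <- lapply(plasmids, function(p) {
    depth <- map$depth[[p]]
    plen <- length(depth)
    miss <- missing_intervals(depth, min_run)
    plr <- compute_plr(miss, plen)
    data.frame(strain_id = strain_id, plasmid_id = p, length = plen,
               breadth = coverage_breadth(depth),
               mean_depth = mean(depth),
               call = call_presence(coverage_breadth(depth), present, absent),
               plr = plr, loss_class = classify_loss(plr),
               entire_loss = confirm_entire_loss(map, reference, p,
                                                 present, absent))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("plasmid_report", "data.frame")
  out
}

#' Presence calls for accessory fragments from a fragment mapping
#'
#' Reads should be mapped against the accessory sequences together with the
#' reference replicons, so that reads from near-identical reference loci
#' (e.g. the rRNA copies an acquired fragment resembles) resolve to their
#' true origin instead of piling onto the fragment.
#'
#' @param map a `map_result` whose targets include the accessory fragments.
#' @param targets fragment ids to report (default: every mapping target).
#' @param present,absent thresholds.
#' @return data.frame `target_id`, `breadth`, `mean_depth`, `call`.
#' @export
fragment_presence <- function(map, targets = NULL, present = 0.8, absent = 0.2) {
  if (is.null(targets)) targets <- names(map$depth)
  rows <- lapply(targets, function(t) {
    b <- coverage_breadth(map$depth[[t]])
    data.frame(target_id = t, breadth = b, mean_depth = mean(map$depth[[t]]),
               call = call_presence(b, present, absent))
  })
  do.call(rbind, rows)
}

#' Detect acquired (HGT-candidate) fragments
#'
#' Accessory fragments with source `novel` are horizontal-acquisition
#' candidates; their best reference homolog is reported at any identity at
#' or above the reporting floor, and, when a donor database is supplied,
#' the best donor hit as well. No taxonomic inference is attempted.
#'
#' @param accessory an [assign_source()]-annotated `accessory_genome`.
#' @param reference a `ReferenceGenome` (unused beyond validation; homolog
#'   fields come from the source assignment).
#' @param donor_db optional named character vector of donor sequences.
#' @param floor_identity reporting floor (default 50).
#' @param k seed k-mer length.
#' @return data.frame of class `hgt_candidates`: fragment_id, length,
#'   carriers, reference homolog and identity, donor id and identity.
#' @export
detect_acquisitions <- function(accessory, reference, donor_db = NULL,
                                floor_identity = 50, k = 15L) {
  nov <- accessory[accessory$source == "novel", , drop = FALSE]
  if (nrow(nov) == 0L) {
    return(structure(data.frame(fragment_id = character(0), length = integer(0),
                                carriers = character(0),
                                ref_homolog = character(0),
                                ref_identity = numeric(0),
                                donor_id = character(0),
                                donor_identity = numeric(0)),
                     class = c("hgt_candidates", "data.frame")))
  }
  rows <- lapply(seq_len(nrow(nov)), function(i) {
    ref_id <- if (!is.na(nov$best_hit_identity[i]) &&
                  nov$best_hit_identity[i] >= floor_identity)
      nov$best_hit_identity[i] else NA_real_
    ref_feat <- if (!is.na(ref_id)) nov$best_hit_feature[i] else ""
    donor_id <- ""
    donor_ident <- NA_real_
    if (!is.null(donor_db)) {
      h <- local_align(c(frag = nov$sequence[i]), donor_db,
                       min_identity = floor_identity, max_evalue = 1e-5, k = k)
      if (nrow(h)) {
        donor_id <- h$subject_id[1L]
        donor_ident <- h$identity[1L]
      }
    }
    data.frame(fragment_id = nov$fragment_id[i], length = nov$length[i],
               carriers = paste(nov$members[[i]], collapse = ","),
               ref_homolog = ref_feat, ref_identity = ref_id,
               donor_id = donor_id, donor_identity = donor_ident)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("hgt_candidates", "data.frame")
  out
}
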
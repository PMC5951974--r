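# End-to-end orchestration: build the reference, derive strains with planted
# events, simulate reads/contigs, then run mapping -> SNPs -> pan-genome ->
# plasmid presence/PLR -> HGT detection -> per-strain variation matrix.
# Every stage is deterministic under the configured seed.

#' Pipeline configuration
#'
#' All numeric thresholds default to the values the analysis is defined
#' with: core alignment identity >= 90% at e-value < 1e-5, accessory
#' deduplication at >= 90% identity over >= 85% of the shorter fragment,
#' presence breadth > 0.8 / absence < 0.2, SNP call quality > 20 and pair
#' depth > 10, ANI species cutoff 95%.
#'
#' @param ref_config a [ref_config()] (default [compact_ref_config()]).
#' @param strains named list of per-strain event descriptors; each is a
#'   list that may contain `snps` (a data.frame for [event_spec()], or
#'   `"catalog"` to plant the full SNP catalog), `plasmid_losses`
#'   (see [event_spec()]), and `acquisition` (logical: insert the
#'   23S-like donor fragment).
#' @param read_params list: `read_length`, `mean_insert`, `sd_insert`,
#'   `depth`, `error_rate`.
#' @param thresholds named list of analysis thresholds (see Details).
#' @param contig_params list: `mean_contig`, `min_contig`, `gap`.
#' @param seed master seed; per-strain seeds are derived from it.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(ref_config = compact_ref_config(),
                            strains = default_strain_specs(),
                            read_params = list(read_length = 101L,
                                               mean_insert = 350L,
                                               sd_insert = 35L,
                                               depth = 100, error_rate = 0),
                            thresholds = list(),
                            contig_params = list(mean_contig = 20000L,
                                                 min_contig = 1000L, gap = 0L),
                            seed = 1L) {
  th <- list(core_identity = 90, core_evalue = 1e-5,
             dedup_identity = 90, dedup_len_frac = 0.85,
             presence = 0.8, absence = 0.2,
             snp_quality = 20, snp_depth = 10,
             ani_cutoff = 95, min_fragment = 200L, min_zero_run = 300L,
             repeat_identity = 95, repeat_length = 100L,
             hgt_floor_identity = 50)
  th[names(thresholds)] <- thresholds
  if (th$presence <= th$absence)
    stop("invalid presence thresholds: presence (", th$presence,
         ") must exceed absence (", th$absence, ")")
  stopifnot(th$core_identity > 0, th$core_identity <= 100,
            th$dedup_len_frac > 0, th$dedup_len_frac <= 1,
            th$snp_depth >= 0, th$ani_cutoff > 0, th$ani_cutoff <= 100)
  structure(list(ref_config = ref_config, strains = strains,
                 read_params = read_params, thresholds = th,
                 contig_params = contig_params, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Default six-strain simulated cohort
#'
#' One no-event strain, one carrying the full SNP catalog, one complete
#' plasmid loss (p4), partial losses at PLR 0.75 and 0.85 (p1), and one
#' strain combining a PLR 0.5 partial loss (p2) with the acquired 23S-like
#' fragment.
#' @export
default_strain_specs <- function() {
  list(
    S1 = list(),
    S2 = list(snps = "catalog"),
    S3 = list(plasmid_losses = list(list(plasmid_id = "p4", mode = "complete"))),
    S4 = list(plasmid_losses = list(list(plasmid_id = "p1", mode = "partial", plr = 0.75))),
    S5 = list(plasmid_losses = list(list(plasmid_id = "p1", mode = "partial", plr = 0.85))),
    S6 = list(plasmid_losses = list(list(plasmid_id = "p2", mode = "partial", plr = 0.5)),
              acquisition = TRUE)
  )
}

#' Run the full simulated-cohort analysis
#'
#' Stages, in order: reference build, repeat mask, per-strain event
#' planting / contig shearing / read simulation / read mapping / SNP calling
#' and filtering / core-accessory partition, then cohort-level accessory
#' clustering, source assignment, fragment presence, plasmid-loss reports,
#' HGT detection and the per-strain variation matrix. Outputs are
#' reproducible bit-for-bit for a fixed seed.
#'
#' @param config a [pipeline_config()].
#' @param catalog SNP catalog used when a strain plants `"catalog"` SNPs
#'   (default: the bundled catalog).
#' @param outdir optional directory; when given, stage outputs are written
#'   (FASTA/TSV/BED/VCF/JSON) together with an effective-threshold log.
#' @param verbose print stage progress.
#' @return list of class `cohort_result`.
#' @export
run_cohort <- function(config, catalog = NULL, outdir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  th <- config$thresholds
  say <- function(...) if (verbose) message(format(Sys.time(), "%H:%M:%S "), ...)

  say("building reference")
  ref <- build_reference(config$ref_config, seed = config$seed)
  mask <- build_repeat_mask(ref, min_identity = th$repeat_identity,
                            min_length = th$repeat_length)
  hgt <- make_hgt_fragment(ref, seed = config$seed)
  ins_pos <- pick_insertion_site(ref, seed = config$seed)

  if (is.null(catalog) &&
      any(vapply(config$strains, function(s) identical(s$snps, "catalog"), TRUE)))
    catalog <- load_snp_catalog(system.file("extdata", "snp_catalog.tsv",
                                            package = "hostdrift"))

  strains <- list()
  frag_tabs <- list()
  for (sn in names(config$strains)) {
    say("strain ", sn)
    sp <- config$strains[[sn]]
    sseed <- derive_seed(config$seed, match(sn, names(config$strains)))
    snps <- NULL
    if (!is.null(sp$snps)) {
      snps <- if (identical(sp$snps, "catalog"))
        catalog_event_spec(ref, catalog, seed = sseed) else sp$snps
    }
    acq <- NULL
    if (isTRUE(sp$acquisition))
      acq <- list(list(sequence = hgt$fragment, replicon_id = "chromosome",
                       pos = ins_pos))
    spec <- event_spec(snps = snps, plasmid_losses = sp$plasmid_losses,
                       acquisitions = acq)
    planted <- plant_events(ref, spec, seed = sseed, strain_id = sn)

    # assemblers break at inserted-fragment junctions: force breakpoints there
    bps <- NULL
    if (!is.null(planted$truth$acquisitions)) {
      a <- planted$truth$acquisitions
      bps <- split(c(a$derived_start - 1L, a$derived_end), a$replicon_id)
    }
    contigs <- shear_contigs(planted$genome,
                             mean_contig = config$contig_params$mean_contig,
                             min_contig = config$contig_params$min_contig,
                             gap = config$contig_params$gap,
                             breakpoints = bps, seed = sseed)
    rp <- config$read_params
    reads <- simulate_reads(planted$genome, read_length = rp$read_length,
                            mean_insert = rp$mean_insert,
                            sd_insert = rp$sd_insert, depth = rp$depth,
                            error_rate = rp$error_rate, seed = sseed,
                            prefix = sn)
    map <- map_reads(reads, ref)

    cand <- call_raw_snps(contigs, ref, min_identity = th$core_identity,
                          max_evalue = th$core_evalue)
    cand <- snp_support(map, cand)
    kept <- filter_snps(cand, mask, min_quality = th$snp_quality,
                        min_depth = th$snp_depth)
    records <- annotate_effect(ref, kept)

    part <- delineate_core(contigs, ref, min_identity = th$core_identity,
                           max_evalue = th$core_evalue,
                           min_fragment = th$min_fragment)
    if (nrow(part$specific))
      frag_tabs[[sn]] <- data.frame(strain_id = sn,
                                    part$specific[, c("fragment_id", "sequence")])
    plas <- plasmid_report(map, ref, min_run = th$min_zero_run,
                           present = th$presence, absent = th$absence,
                           strain_id = sn)
    strains[[sn]] <- list(truth = planted$truth, snps = records,
                          candidates = cand, plasmids = plas,
                          partition = part, map_counts = map$counts,
                          reads = reads, contigs = contigs)
  }

  say("accessory genome")
  frags <- if (length(frag_tabs)) do.call(rbind, frag_tabs) else NULL
  accessory <- build_accessory(frags, min_identity = th$dedup_identity,
                               min_len_frac = th$dedup_len_frac)
  accessory <- assign_source(accessory, ref,
                             min_identity = th$dedup_identity,
                             min_len_frac = th$dedup_len_frac,
                             floor_identity = th$hgt_floor_identity)
  hgt_cands <- detect_acquisitions(accessory, ref, donor_db = hgt$donor,
                                   floor_identity = th$hgt_floor_identity)

  # fragment presence per strain against the accessory genome
  frag_presence <- NULL
  if (nrow(accessory)) {
    acc_seqs <- accessory$sequence
    names(acc_seqs) <- accessory$fragment_id
    # reference replicons included so reads from near-identical reference
    # loci do not pile onto homologous accessory fragments
    fp <- lapply(names(strains), function(sn) {
      m <- map_reads(strains[[sn]]$reads, c(acc_seqs, ref$replicons))
      cbind(strain_id = sn,
            fragment_presence(m, targets = names(acc_seqs),
                              present = th$presence, absent = th$absence))
    })
    frag_presence <- do.call(rbind, fp)
  }

  res <- structure(list(reference = ref, repeat_mask = mask,
                        strains = strains, accessory = accessory,
                        hgt = hgt_cands, hgt_truth = hgt,
                        fragment_presence = frag_presence,
                        thresholds = th, seed = config$seed),
                   class = "cohort_result")
  res$variation_matrix <- render_variation_matrix(res)

  if (!is.null(outdir)) .write_cohort_outputs(res, outdir)
  res
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("cohort_result:", length(x$strains), "strains vs",
      length(x$reference$replicons), "replicons (seed", x$seed, ")\n")
  for (sn in names(x$strains)) {
    s <- x$strains[[sn]]
    lost <- s$plasmids[s$plasmids$loss_class != "none", , drop = FALSE]
    cat(sprintf("  %-4s %2d SNPs; %s\n", sn, nrow(s$snps),
                if (nrow(lost)) paste(sprintf("%s %s", lost$plasmid_id,
                                              lost$loss_class), collapse = ", ")
                else "no plasmid loss"))
  }
  cat("  accessory fragments:", nrow(x$accessory),
      "| HGT candidates:", nrow(x$hgt), "\n")
  invisible(x)
}

#' Per-strain variation matrix
#'
#' Rows are strains (input order = sampling order); columns are the SNP ids
#' observed across the cohort (values 0/1), one loss-class column per
#' plasmid, and an acquisition flag. Column order is deterministic.
#'
#' @param result a `cohort_result`.
#' @return data.frame, one row per strain.
#' @export
render_variation_matrix <- function(result) {
  ref <- result$reference
  plasmids <- names(ref$replicons)[ref$roles == "plasmid"]
  all_snps <- unique(do.call(rbind, lapply(result$strains, function(s)
    s$snps[, c("replicon_id", "genome_pos", "ref_base", "alt_base")])))
  if (!is.null(all_snps) && nrow(all_snps)) {
    all_snps <- all_snps[order(all_snps$replicon_id, all_snps$genome_pos), , drop = FALSE]
    snp_cols <- sprintf("%s:%d:%s>%s", all_snps$replicon_id,
                        all_snps$genome_pos, all_snps$ref_base,
                        all_snps$alt_base)
  } else snp_cols <- character(0)
  rows <- lapply(names(result$strains), function(sn) {
    s <- result$strains[[sn]]
    have <- if (nrow(s$snps)) sprintf("%s:%d:%s>%s", s$snps$replicon_id,
                                      s$snps$genome_pos, s$snps$ref_base,
                                      s$snps$alt_base) else character(0)
    r <- as.data.frame(as.list(stats::setNames(as.integer(snp_cols %in% have),
                                               snp_cols)),
                       check.names = FALSE, optional = TRUE)
    if (!length(snp_cols)) r <- data.frame(row.names = 1L)
    for (p in plasmids) {
      pr <- s$plasmids[s$plasmids$plasmid_id == p, ]
      r[[paste0("loss_", p)]] <- if (nrow(pr)) pr$loss_class else "none"
    }
    acq <- result$fragment_presence
    r$acquisition <- if (!is.null(acq))
      as.integer(any(acq$strain_id == sn & acq$call == "present")) else 0L
    cbind(data.frame(strain_id = sn), r)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.write_cohort_outputs <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_reference(res$reference, fasta = file.path(outdir, "reference.fasta"),
                  genes_tsv = file.path(outdir, "gene_models.tsv"))
  utils::write.table(res$repeat_mask, file.path(outdir, "repeat_mask.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (sn in names(res$strains)) {
    s <- res$strains[[sn]]
    sd <- file.path(outdir, sn)
    dir.create(sd, showWarnings = FALSE)
    if (nrow(s$snps)) {
      write_snp_catalog(s$snps, file.path(sd, "snps.tsv"))
      write_snps_vcf(s$snps, res$reference, file.path(sd, "snps.vcf"))
    }
    utils::write.table(s$plasmids, file.path(sd, "plasmid_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_truth_json(s$truth, file.path(sd, "truth.json"))
  }
  if (nrow(res$accessory))
    write_accessory(res$accessory,
                    fasta = file.path(outdir, "accessory.fasta"),
                    membership_tsv = file.path(outdir, "accessory_membership.tsv"),
                    strains = names(res$strains))
  utils::write.table(res$variation_matrix,
                     file.path(outdir, "variation_matrix.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  # effective thresholds, each exactly once
  writeLines(sprintf("%s\t%s", names(res$thresholds),
                     vapply(res$thresholds, format, "")),
             file.path(outdir, "thresholds.log"))
  invisible(outdir)
}
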
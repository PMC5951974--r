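# Cohort-level screening and evolutionary-rate arithmetic: the ANI
# descendant screen (isolates below the 95% species cutoff, or with
# undefined ANI, are excluded from comparative analysis) and the
# per-generation mutation-rate estimate with its spontaneous-rate benchmark.

#' Read a cohort manifest
#'
#' @param path TSV with columns `isolate_id`, `subject_id`, `trial`,
#'   `timepoint`, `genome_size`, `gc_percent`, `ani_vs_reference` (empty /
#'   NA = ANI undefined). A synthetic example manifest is bundled at
#'   `system.file("extdata", "cohort_manifest_synthetic.tsv",
#'   package = "hostdrift")`.
#' @return data.frame of class `cohort_manifest`.
#' @export
read_cohort_manifest <- function(path) {
  x <- utils::read.delim(path, check.names = FALSE)
  need <- c("isolate_id", "subject_id", "trial", "timepoint",
            "genome_size", "gc_percent", "ani_vs_reference")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("manifest lacks columns: ", paste(miss, collapse = ", "))
  if (!all(x$trial %in% 1:3)) stop("trial must be 1, 2 or 3")
  x$ani_vs_reference <- suppressWarnings(as.numeric(x$ani_vs_reference))
  class(x) <- c("cohort_manifest", "data.frame")
  x
}

#' ANI descendant screen
#'
#' Retains isolates with `ani_vs_reference >= cutoff`; isolates below the
#' cutoff, or with undefined ANI (no alignable fragments), are excluded.
#'
#' @param manifest a [read_cohort_manifest()] data.frame.
#' @param cutoff species-level ANI cutoff in percent (default 95).
#' @return manifest with a logical `retained` column; attribute
#'   `"exclusions"` is a data.frame of excluded isolates with reasons.
#' @export
screen_descendants <- function(manifest, cutoff = 95) {
  ani <- manifest$ani_vs_reference
  retained <- !is.na(ani) & ani >= cutoff
  manifest$retained <- retained
  ex <- manifest[!retained, , drop = FALSE]
  ex$reason <- ifelse(is.na(ex$ani_vs_reference), "ANI undefined",
                      sprintf("ANI %.1f%% below %g%% cutoff",
                              ex$ani_vs_reference, cutoff))
  attr(manifest, "exclusions") <- ex
  manifest
}

#' Write a screening report
#' @param screened a [screen_descendants()] result.
#' @param path output TSV.
#' @export
write_screening_report <- function(screened, path) {
  utils::write.table(screened, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Per-generation mutation rate
#'
#' The rate is the maximum SNP count per strain divided by the number of
#' generations elapsed, compared against the spontaneous-rate benchmark of
#' 0.0033 changes per generation. The generation count is always an
#' explicit input - it is an assumption, never inferred.
#'
#' @param max_snps_per_strain largest SNP count observed in any strain.
#' @param generations generations elapsed (> 0).
#' @param benchmark spontaneous mutation rate, changes per generation
#'   (default 0.0033).
#' @return list of class `mutation_rate`: `rate`, `benchmark`, `flag`
#'   (`"at or below spontaneous rate"` / `"above spontaneous rate"`).
#' @examples
#' estimate_mutation_rate(2, 690)  # 0.0029 per generation
#' @export
estimate_mutation_rate <- function(max_snps_per_strain, generations,
                                   benchmark = 0.0033) {
  if (generations <= 0) stop("generations must be positive")
  if (max_snps_per_strain < 0) stop("SNP count cannot be negative")
  rate <- max_snps_per_strain / generations
  structure(list(rate = rate, benchmark = benchmark,
                 max_snps = max_snps_per_strain, generations = generations,
                 flag = if (rate <= benchmark) "at or below spontaneous rate"
                        else "above spontaneous rate"),
            class = "mutation_rate")
}

#' @export
print.mutation_rate <- function(x, ...) {
  cat(sprintf("mutation rate: %.4f changes/generation (%d SNPs / %d generations)\n",
              x$rate, x$max_snps, x$generations))
  cat("  ", x$flag, sprintf("(benchmark %.4f)\n", x$benchmark))
  invisible(x)
}

#' Persistence summary of an abundance time series
#'
#' @param timepoints strictly increasing numeric vector (days or weeks).
#' @param log10_abundance log10 colony content per gram at each timepoint.
#' @param detection_limit detection limit on the same log10 scale
#'   (required; abundance must exceed it to count as detectable).
#' @return list: `last_detectable` (greatest timepoint with abundance above
#'   the limit; `NA` if never detected), `peak` and `peak_timepoint`.
#' @export
persistence_summary <- function(timepoints, log10_abundance, detection_limit) {
  if (length(timepoints) != length(log10_abundance))
    stop("timepoints and abundances differ in length")
  if (any(diff(timepoints) <= 0)) stop("timepoints must be strictly increasing")
  det <- log10_abundance > detection_limit
  list(
    last_detectable = if (any(det)) max(timepoints[det]) else NA_real_,
    peak = max(log10_abundance),
    peak_timepoint = timepoints[which.max(log10_abundance)],
    detection_limit = detection_limit
  )
}
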
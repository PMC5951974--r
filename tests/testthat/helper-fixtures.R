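# Shared fixtures, built once per test run and cached.

.fix_env <- new.env(parent = emptyenv())

fix_once <- function(name, expr) {
  if (!exists(name, envir = .fix_env)) assign(name, expr, envir = .fix_env)
  get(name, envir = .fix_env)
}

# Compact reference shared across test files.
test_ref <- function() fix_once("ref", build_reference(compact_ref_config(), seed = 42))

test_mask <- function() fix_once("mask", build_repeat_mask(test_ref()))

test_catalog <- function() fix_once("catalog", load_snp_catalog(
  system.file("extdata", "snp_catalog.tsv", package = "hostdrift")))

# Small configuration for cheap end-to-end determinism runs.
mini_pipeline_config <- function(seed = 3L) {
  rc <- ref_config(
    chromosome_length = 40000L,
    plasmids = data.frame(
      id = paste0("p", 1:7),
      length = c(8000L, 6000L, 3000L, 5000L, 2000L, 2000L, 3000L),
      homology_fraction = c(0, 0.5, 0, 0.5, 0, 0, 0.5),
      n_genes = c(3L, 2L, 1L, 2L, 1L, 1L, 1L)
    )
  )
  pipeline_config(
    ref_config = rc,
    strains = list(
      A = list(),
      B = list(plasmid_losses = list(list(plasmid_id = "p4", mode = "complete")))
    ),
    read_params = list(read_length = 101L, mean_insert = 350L, sd_insert = 35L,
                      depth = 30, error_rate = 0),
    contig_params = list(mean_contig = 10000L, min_contig = 500L, gap = 0L),
    seed = seed
  )
}
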
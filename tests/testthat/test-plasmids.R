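test_that("coverage breadth and presence calls follow the stated thresholds", {
  expect_equal(coverage_breadth(rep(5L, 100)), 1.0)
  expect_equal(coverage_breadth(rep(0L, 100)), 0.0)
  d <- c(rep(2L, 70), rep(0L, 30))
  expect_equal(coverage_breadth(d), 0.7)
  expect_equal(coverage_breadth(d, data.frame(start = 1, end = 50)), 1.0)
  expect_equal(call_presence(0.95), "present")
  expect_equal(call_presence(0.10), "absent")
  expect_equal(call_presence(0.50), "ambiguous")
  # strictness at the boundaries
  expect_equal(call_presence(0.8), "ambiguous")
  expect_equal(call_presence(0.2), "ambiguous")
  expect_error(call_presence(0.5, present = 0.2, absent = 0.8), "must exceed")
})

test_that("missing intervals keep only zero-runs above the smoothing length", {
  d <- c(rep(1L, 100), rep(0L, 299), rep(1L, 50), rep(0L, 300), rep(1L, 100))
  mi <- missing_intervals(d, min_run = 300)
  expect_equal(nrow(mi), 1)
  expect_equal(mi$start, 450)
  expect_equal(mi$end, 749)
})

test_that("PLR arithmetic and classification match the loss-type bins", {
  expect_equal(compute_plr(data.frame(start = 1, end = 20000), 20000), 1.0)
  expect_equal(compute_plr(NULL, 1000), 0)
  # an 8.47-kb missing region of a 20-kb plasmid
  plr <- compute_plr(data.frame(start = 1001, end = 9470), 20000)
  expect_equal(plr, 0.4235)
  expect_equal(classify_loss(plr), "<70%")
  expect_equal(classify_loss(c(1, 0.85, 0.75, 0.5, 0.95, 0)),
               c("complete", "80-90%", "70-80%", "<70%", "90-100%", "none"))
  expect_error(compute_plr(data.frame(start = 1, end = 10), 0), "positive")
  expect_error(classify_loss(1.2), "0, 1")
})

test_that("loss classification is total, deterministic and partitions [0,1]", {
  grid <- c(0, 1e-9, seq(0.001, 0.999, by = 0.0101), 0.7, 0.8, 0.9,
            1 - 1e-9, 1)
  cls <- classify_loss(grid)
  expect_false(any(cls == ""))
  expect_identical(cls, classify_loss(grid))
  bins <- list(none = c(0, 0), `<70%` = c(1e-12, 0.7 - 1e-12),
               `70-80%` = c(0.7, 0.8 - 1e-12),
               `80-90%` = c(0.8, 0.9 - 1e-12),
               `90-100%` = c(0.9, 1 - 1e-12), complete = c(1, 1))
  for (b in names(bins))
    expect_true(all(classify_loss(bins[[b]]) == b))
})

test_that("entire-loss confirmation requires uncovered specific regions", {
  ref <- test_ref()
  # strain with intact genome: nothing confirmed
  rs <- simulate_reads(ref, depth = 30, seed = 33)
  m <- map_reads(rs, ref)
  expect_equal(confirm_entire_loss(m, ref, "p4"), "not-confirmed")
  # strain without p4: confirmed
  out <- plant_events(ref, event_spec(
    plasmid_losses = list(list(plasmid_id = "p4", mode = "complete"))), seed = 33)
  m2 <- map_reads(simulate_reads(out$genome, depth = 30, seed = 34), ref)
  expect_equal(confirm_entire_loss(m2, ref, "p4"), "confirmed")
  rep2 <- plasmid_report(m2, ref, strain_id = "X")
  expect_equal(rep2$call[rep2$plasmid_id == "p4"], "absent")
  expect_equal(rep2$loss_class[rep2$plasmid_id == "p4"], "complete")
  # confirmation implies the complete loss class across the report
  conf <- rep2[rep2$entire_loss == "confirmed", ]
  expect_true(all(conf$loss_class == "complete"))
})

test_that("a fully chromosome-homologous plasmid is indeterminate", {
  cfg <- ref_config(chromosome_length = 40000L,
                    plasmids = data.frame(id = "p2", length = 5000L,
                                          homology_fraction = 1.0, n_genes = 0L))
  ref <- build_reference(cfg, seed = 4)
  m <- map_reads(simulate_reads(ref, depth = 20, seed = 4), ref)
  expect_equal(confirm_entire_loss(m, ref, "p2"), "indeterminate")
})

test_that("a partial loss produces the expected breadth deficit", {
  ref <- test_ref()
  out <- plant_events(ref, event_spec(
    plasmid_losses = list(list(plasmid_id = "p1", mode = "partial", plr = 0.3))),
    seed = 35)
  m <- map_reads(simulate_reads(out$genome, depth = 100, seed = 35), ref)
  b <- coverage_breadth(m$depth[["p1"]])
  expect_lt(abs(b - 0.7), 0.02)
  rep1 <- plasmid_report(m, ref, strain_id = "X")
  expect_lt(abs(rep1$plr[rep1$plasmid_id == "p1"] - 0.3), 0.02)
  expect_equal(rep1$entire_loss[rep1$plasmid_id == "p1"], "not-confirmed")
})
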
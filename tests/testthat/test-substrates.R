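# Synthetic substrate generation: planted GC clusters, mismatch annotation,
# forked duplexes, seeded trace sets.

test_that("planted GC clusters put windowed-GC maxima at the requested centers", {
  hp <- make_hairpin(174,
                     gc_clusters = list(list(center = 55, width = 10, gc = 0.9),
                                        list(center = 90, width = 10, gc = 0.9),
                                        list(center = 120, width = 10, gc = 0.9)),
                     background_gc = 0.35, seed = 1)
  wgc <- windowed_gc(hp, window = 10)
  for (ctr in c(55, 90, 120)) {
    near <- wgc[abs(wgc$position - ctr) <= 8, ]
    expect_lte(abs(near$position[which.max(near$gc)] - ctr), 2)
    # realized cluster GC within 0.1 of the request (exact-count construction)
    expect_lte(abs(max(near$gc) - 0.9), 0.1)
  }
  # background stays well below cluster level
  far <- wgc[apply(abs(outer(wgc$position, c(55, 90, 120), "-")), 1, min) > 15, ]
  expect_lt(mean(far$gc), 0.6)
})

test_that("degenerate compositions and determinism behave", {
  at <- make_hairpin(20, background_gc = 0, seed = 3)
  expect_false(grepl("[GC]", at$stem_sequence))
  expect_identical(make_hairpin(60, seed = 7)$stem_sequence,
                   make_hairpin(60, seed = 7)$stem_sequence)
  expect_false(identical(make_hairpin(60, seed = 7)$stem_sequence,
                         make_hairpin(60, seed = 8)$stem_sequence))
  expect_error(make_hairpin(0), "positive")
  expect_error(make_hairpin(100, gc_clusters = list(
    list(center = 50, width = 20, gc = 0.9),
    list(center = 55, width = 20, gc = 0.9))), "overlap")
  expect_error(make_hairpin(100, gc_clusters = list(
    list(center = 99, width = 10, gc = 0.9))), "fit")
})

test_that("mismatch variants annotate eligible positions without touching the stem", {
  hp <- default_hairpin()
  bases <- strsplit(hp$stem_sequence, "")[[1]]
  pos_c <- which(bases == "C")[5]
  mm <- make_mismatch_variant(hp, pos_c)
  expect_identical(mm$stem_sequence, hp$stem_sequence)
  expect_identical(mm$mismatch_positions, pos_c)
  # ineligible position is replaced by the nearest stem C, and recorded
  pos_a <- which(bases != "C")[5]
  mm2 <- make_mismatch_variant(hp, pos_a)
  expect_true(bases[mm2$mismatch_positions] == "C")
  expect_identical(attr(mm2, "substituted"), pos_a)
  # empty request is the identity
  expect_identical(make_mismatch_variant(hp, integer(0)), hp)
  expect_error(make_mismatch_variant(hp, 999), "range")
  # three mismatches as used for homology-disruption substrates
  mm3 <- make_mismatch_variant(hp, c(90, 104, 124))
  expect_length(mm3$mismatch_positions, 3)
})

test_that("forks carry exactly the requested GC count", {
  for (gc in c(0, 12, 16, 26, 33)) {
    fk <- make_fork(gc, seed = gc + 1)
    expect_equal(fk$gc_count, gc)
    expect_equal(nchar(fk$duplex_sequence), 33)
  }
  expect_equal(make_fork(26)$gc_percent, 79)
  expect_equal(make_fork(12)$gc_percent, 36)
  expect_equal(make_fork(16)$gc_percent, 48)
  expect_false(grepl("[GC]", make_fork(0)$duplex_sequence))
  expect_error(make_fork(34), "0, 33")
})

test_that("trace sets are reproducible and carry usable ground truth", {
  cfg <- calibrated_config()
  ts1 <- generate_trace_set(hp174, cfg, meas_config(), n_traces = 3, seed = 5)
  ts2 <- generate_trace_set(hp174, cfg, meas_config(), n_traces = 3, seed = 5)
  expect_equal(ts1, ts2)
  expect_length(unique(vapply(ts1, function(x) sum(x$extension_nm),
                              numeric(1))), 3)
  # zero noise renders the exact ground-truth staircase
  ts0 <- generate_trace_set(hp174, cfg, quiet_meas(), n_traces = 1, seed = 9)
  tr <- ts0[[1]]
  traj <- attr(tr, "trajectory")
  pos <- trajectory_position(traj, pmax(tr$time_s - attr(tr, "pad_s"), 0))
  expect_equal(tr$extension_nm, nm_per_bp(quiet_meas()) * pos, tolerance = 1e-12)
})

test_that("simulated ensemble reproduces the calibration target rate", {
  cfg <- calibrated_config()
  ts <- generate_trace_set(hp174, cfg, quiet_meas(), n_traces = 60, seed = 11)
  tot <- vapply(ts, function(tr) max(attr(tr, "trajectory")$times), numeric(1))
  # pooled (time-weighted) ensemble rate, the quantity calibration targets
  pooled <- length(tot) * 174 / sum(tot)
  sem_pooled <- stats::sd(174 / tot) / sqrt(length(tot))
  expect_lt(abs(pooled - cfg$target_mean_rate), 3 * sem_pooled)
})
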
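# Event classification: trace geometry conventions, the 1D/3D cutoff, the
# groove/hop segmentation with its smoothing rules, flips, and statistics.

test_that("helix-trace coordinates follow the (Z, d, phi) conventions", {
  mk_traj <- function(xyz) {
    structure(list(frames = array(t(xyz), dim = c(1, 3, nrow(xyz))),
                   n_frames = nrow(xyz), frame_ns = 50),
              class = "cg_trajectory")
  }
  groove <- list(slope = 2 * pi / 33.2, phase0 = 0, repeat_bp = 10,
                 rise = 3.32)
  tr <- compute_helix_trace(mk_traj(rbind(c(0, 5, 12), c(5, 0, 0),
                                          c(0, 0, 3))),
                            list(1L), groove)
  f <- tr$frames
  expect_equal(f$Z, c(12, 0, 3))
  expect_equal(f$d, c(5, 5, 0))
  expect_equal(f$phi[1], 0)            # aligned with the (0, 1) reference
  expect_equal(abs(f$phi[2]), pi / 2)  # sign carried by the x component
  expect_equal(sign(f$phi[2]), 1)
  expect_true(is.na(f$phi[3]))         # on-axis: phi undefined
  expect_error(compute_helix_trace(mk_traj(rbind(c(0, 5, 12))), list(),
                                   groove), "at least one")
})

test_that("the 1D/3D split uses a closed 32 A threshold", {
  tr <- manual_trace(Z = c(0, 0, 0), d = c(33, 31, 32), phi = c(0, 0, 0))
  expect_equal(classify_1d_3d(tr), c("3D", "1D", "1D"))
})

test_that("groove calibration fitted from phosphates matches the generator", {
  for (n_bp in c(20, 50)) {
    for (phase in c(0, 1.1)) {
      dna <- generate_ideal_bdna(dna_geometry(n_bp = n_bp,
                                              groove_phase = phase))
      cal <- calibrate_groove(dna)
      expect_equal(cal$slope, dna$groove$slope, tolerance = 1e-9)
      expect_equal(cgslide:::.wrap_angle(cal$phase0 - dna$groove$phase0), 0,
                   tolerance = 1e-9)
      expect_equal(cal$repeat_bp, 10, tolerance = 1e-9)
    }
  }
})

test_that("the classifier recovers oracle labels and event counts", {
  plan <- list(oracle_segment("groove", 30, 2),
               oracle_segment("hop", 5, 10),
               oracle_segment("groove", 25, -1),
               oracle_segment("threeD", 10),
               oracle_segment("groove", 20, 1),
               oracle_segment("hop", 4, -8),
               oracle_segment("groove", 16, 0.5))
  # noise-free: labels match exactly, event counts match the plan
  tr <- generate_oracle_trace(plan, frame_ns = 50, noise_bp = 0)
  seg <- segment_events(tr)
  expect_identical(seg$labels, tr$true_labels)
  expect_equal(sum(seg$events$type == "groove"), 4)
  expect_equal(sum(seg$events$type == "hop"), 2)

  # with sub-tolerance noise: at least 99% frame agreement
  trn <- generate_oracle_trace(plan, frame_ns = 50, noise_bp = 0.4, seed = 2)
  segn <- segment_events(trn)
  expect_gte(mean(segn$labels == trn$true_labels), 0.99)
  expect_equal(sum(segn$events$type == "hop"), 2)
})

test_that("hops spanning under 1 bp merge into flanking groove tracking", {
  plan <- list(oracle_segment("groove", 30, 2),
               oracle_segment("hop", 5, 0.9),
               oracle_segment("groove", 30, 1))
  tr <- generate_oracle_trace(plan)
  seg <- segment_events(tr)
  expect_equal(nrow(seg$events), 1)
  expect_equal(seg$events$type, "groove")
})

test_that("groove tracking under 0.5 ns is relabeled as hopping", {
  # finer frame clock so sub-ns events are resolvable
  plan <- list(oracle_segment("hop", 0.05, 3),
               oracle_segment("groove", 4e-4, 0),   # 0.4 ns
               oracle_segment("hop", 0.05, 3))
  tr <- generate_oracle_trace(plan, frame_ns = 0.1)
  seg <- segment_events(tr, min_1d_ns = 5)
  expect_true(all(seg$events$type == "hop"))
  expect_equal(nrow(seg$events), 1) # merged into one hop
})

test_that("smoothing reaches a fixed point (no sub-threshold events remain)", {
  set.seed(4)
  plan <- list(oracle_segment("groove", 10, 1),
               oracle_segment("hop", 2, 6),
               oracle_segment("groove", 0.2, 0.2),
               oracle_segment("hop", 1.5, -7),
               oracle_segment("groove", 12, 1))
  tr <- generate_oracle_trace(plan, frame_ns = 50, noise_bp = 0.4)
  seg <- segment_events(tr)
  hops <- seg$events[seg$events$type == "hop", ]
  grooves <- seg$events[seg$events$type == "groove", ]
  expect_true(all(abs(hops$span_bp) >= 1))
  expect_true(all(grooves$duration_us * 1e3 >= 0.5))
  # re-running the segmentation is deterministic
  expect_identical(segment_events(tr), seg)
})

test_that("every frame carries exactly one label from {3D, groove, hop}", {
  plan <- list(oracle_segment("groove", 20, 1),
               oracle_segment("threeD", 7),
               oracle_segment("hop", 5, 9),
               oracle_segment("groove", 20, -2))
  tr <- generate_oracle_trace(plan, noise_bp = 0.3, seed = 6)
  seg <- segment_events(tr)
  expect_length(seg$labels, nrow(tr$frames))
  expect_true(all(seg$labels %in% c("3D", "groove", "hop")))
})

test_that("flips are detected with debouncing", {
  plan <- list(oracle_segment("groove", 100, 2))
  tr <- generate_oracle_trace(plan, regions = 2, flip_times_us = 40)
  flips <- detect_flips(tr)
  expect_length(flips, 1)
  expect_equal(flips, 40, tolerance = 0.1)

  none <- generate_oracle_trace(plan, regions = 2)
  expect_length(detect_flips(none), 0)

  # a single-frame inversion is noise, not a flip
  blip <- generate_oracle_trace(plan, regions = 2)
  f2 <- blip$frames$region == 2
  z2 <- blip$frames$Z[f2]
  z1 <- blip$frames$Z[!f2]
  z2[500] <- z1[500] + 5
  blip$frames$Z[f2] <- z2
  expect_length(detect_flips(blip), 0)

  mono <- generate_oracle_trace(plan)
  expect_message(out <- detect_flips(mono), "dimeric")
  expect_length(out, 0)
})

test_that("event statistics report rates and long-hop counts", {
  ev <- data.frame(region = 1, type = c("hop", "groove", "hop", "hop"),
                   start_frame = 1, end_frame = 2,
                   start_us = 0, end_us = 1,
                   duration_us = c(100, 200, 100, 100),
                   span_bp = c(4, 2, -6, 12))
  st <- event_statistics(ev)
  expect_equal(st$time_1d_us, 500)
  expect_equal(st$k_hop_per_ms, 3 / 0.5)           # 3 hops in 0.5 ms of 1D time
  expect_equal(st$long_hop_per_ms, 2 / 0.5)        # spans {6, 12} exceed 5 bp
  expect_equal(st$hop$mean_span_bp, mean(c(4, 6, 12)))
  expect_equal(st$groove$n, 1)
  expect_true(is.na(st$groove$sd_duration_us))

  # 2 hops in 0.5 ms -> 4 per ms
  ev2 <- data.frame(region = 1, type = c("hop", "hop"),
                    start_frame = 1, end_frame = 2, start_us = 0, end_us = 1,
                    duration_us = c(250, 250), span_bp = c(10, 10))
  expect_equal(event_statistics(ev2)$k_hop_per_ms, 4)

  empty <- ev[0, ]
  st0 <- event_statistics(empty)
  expect_equal(st0$groove$n, 0)
  expect_true(is.na(st0$k_hop_per_ms))
  expect_true(is.na(st0$groove$mean_duration_us))
})

test_that("k_hop is invariant under uniform time rescaling", {
  plan <- list(oracle_segment("groove", 30, 2),
               oracle_segment("hop", 5, 10),
               oracle_segment("groove", 30, 1))
  t1 <- generate_oracle_trace(plan, frame_ns = 50)
  t2 <- generate_oracle_trace(plan, frame_ns = 50)
  scale <- 3
  t2$frames$time_us <- t2$frames$time_us * scale
  t2$frame_ns <- t2$frame_ns * scale
  s1 <- event_statistics(segment_events(t1)$events)
  s2 <- event_statistics(segment_events(t2, min_1d_ns = 5 * scale)$events)
  expect_equal(s2$k_hop_per_ms * scale, s1$k_hop_per_ms, tolerance = 1e-9)
})
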
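test_that("minimum-image distance honours periodicity and symmetry", {
  box <- c(10, 10, 10)
  expect_equal(min_image_distance(c(1, 2, 3), c(1, 2, 3), box), 0)
  expect_equal(min_image_distance(c(0.1, 5, 5), c(9.9, 5, 5), box), 0.2)
  withr::local_seed(41)
  for (i in 1:20) {
    a <- runif(3, 0, 10); b <- runif(3, 0, 10)
    expect_equal(min_image_distance(a, b, box),
                 min_image_distance(b, a, box))
    expect_lte(min_image_distance(a, b, box),
               sqrt(sum((box / 2)^2)) + 1e-12)
    # invariant under integer box translations of either point
    k <- sample(-3:3, 3, replace = TRUE)
    expect_equal(min_image_distance(a + k * box, b, box),
                 min_image_distance(a, b, box), tolerance = 1e-12)
  }
})

test_that("contact frequencies equal the planted schedule exactly", {
  spec <- sample_traj_spec(8, n_frames = 101)
  g <- generate_trajectory(spec)
  p <- contact_params(analysis_window_ns = 200)
  prof <- residue_lipid_contact_frequency(g$traj, p)
  truth <- g$truth$residues
  expect_equal(prof$residue, truth$residue)
  expect_equal(prof$frequency_any, 100 * truth$frac_any)
  expect_equal(prof$frequency_PS, 100 * truth$frac_PS)
  expect_equal(prof$frequency_PC, 100 * truth$frac_PC)
  expect_equal(prof$frequency_acyl, 100 * truth$frac_acyl)
  expect_equal(attr(prof, "n_frames"), 101L)
  # a trajectory with no lipid contacts gives all-zero frequencies
  g0 <- generate_trajectory(traj_spec(n_frames = 11, residues = 1:4,
                                      seed = 2))
  prof0 <- residue_lipid_contact_frequency(
    g0$traj, contact_params(analysis_window_ns = 20))
  expect_true(all(prof0$frequency_any == 0))
  # window longer than the trajectory is an error
  expect_error(residue_lipid_contact_frequency(g0$traj, contact_params()),
               "window")
})

test_that("PS-only schedules give frequency_PS == frequency_any, PC == 0", {
  cs <- data.frame(residue = rep(1:2, each = 5), frame = rep(1:5, 2),
                   class = "PS", region = "headgroup")
  g <- generate_trajectory(traj_spec(n_frames = 10, residues = 1:3,
                                     contact_schedule = cs, seed = 5))
  prof <- residue_lipid_contact_frequency(
    g$traj, contact_params(analysis_window_ns = 18))
  expect_equal(prof$frequency_PS, prof$frequency_any)
  expect_true(all(prof$frequency_PC == 0))
})

test_that("contact time series counts scheduled residues per frame", {
  cs <- data.frame(residue = c(34, 37, 39), frame = 2,
                   class = "PS", region = "headgroup")
  g <- generate_trajectory(traj_spec(n_frames = 4, residues = c(34, 37, 39),
                                     contact_schedule = cs, seed = 6))
  se <- residues_in_contact_timeseries(g$traj, contact_params())
  expect_equal(se$n_contacts, c(0L, 3L, 0L, 0L))
  expect_equal(se$time_ns, c(0, 2, 4, 6))
  # time-average over a trailing window equals the hand sum
  expect_equal(mean(se$n_contacts[se$time_ns >= 2]), 1)
})

test_that("replicate aggregation computes mean, SE and windowed summaries", {
  s1 <- data.frame(time_ns = c(0, 2, 4), n_contacts = c(2L, 2L, 2L),
                   replicate = 1L)
  s2 <- data.frame(time_ns = c(0, 2, 4), n_contacts = c(4L, 4L, 4L),
                   replicate = 2L)
  agg <- aggregate_replicates(list(s1, s2), window_ns = 4)
  expect_equal(agg$curve$mean, c(3, 3, 3))
  expect_equal(agg$curve$se, c(1, 1, 1))  # SD sqrt(2)/sqrt(2)
  expect_equal(agg$replicate_means, c(2, 4))
  expect_equal(agg$mean, 3)
  expect_equal(agg$sd, sd(c(2, 4)))
  # identical replicates -> zero SE
  agg0 <- aggregate_replicates(list(s1, s1), window_ns = 4)
  expect_true(all(agg0$curve$se == 0))
  expect_error(aggregate_replicates(list(s1)), "two replicates")
  s3 <- s2; s3$time_ns <- c(0, 2, 5)
  expect_error(aggregate_replicates(list(s1, s3)), "grids")
})

test_that("condition comparison uses the one-tailed reduced-binding test", {
  a <- c(5, 6, 7); b <- c(1, 2, 3)
  res <- compare_conditions(a, b)
  # closed-form pooled t oracle
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(res$statistic, t_hand, tolerance = 1e-10)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, pt(t_hand, 4, lower.tail = FALSE),
               tolerance = 1e-12)
  # identical groups: t = 0, one-tailed p = 0.5
  res0 <- compare_conditions(c(2, 2), c(2, 2))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 0.5)
  # swapped direction gives the complement for continuous t
  expect_equal(compare_conditions(b, a)$p_value,
               1 - res$p_value, tolerance = 1e-12)
})

test_that("coordination events equal the run-length oracle", {
  withr::local_seed(42)
  times <- seq(0, by = 2, length.out = 50)
  for (i in 1:100) {
    d <- runif(50, 0.1, 0.6)
    ev <- coordination_events_from_series(d, times, 0.35)
    oracle <- runs_oracle(d < 0.35)
    if (is.null(oracle)) {
      expect_equal(nrow(ev), 0L)
    } else {
      expect_equal(ev$start, unname(oracle[, "start"]))
      expect_equal(ev$end, unname(oracle[, "end"]))
      expect_equal(ev$duration_ns,
                   (oracle[, "end"] - oracle[, "start"] + 1) * 2,
                   ignore_attr = TRUE)
    }
  }
  # the worked boundary case: frames 10-12 below cutoff at dt = 2 ns
  d <- rep(0.5, 30); d[10:12] <- 0.3
  ev <- coordination_events_from_series(d, times[1:30], 0.35)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$duration_ns, 6)
})

test_that("trajectory event detection matches the planted ion schedule", {
  spec <- traj_spec(n_frames = 40, residues = 1:3, n_ions = 2,
                    ion_schedule = data.frame(ion = c(1, 1, 2),
                                              start = c(5, 20, 11),
                                              end = c(7, 20, 14)),
                    seed = 12)
  g <- generate_trajectory(spec)
  out <- detect_coordination_events(g$traj, contact_params())
  truth <- g$truth$events
  expect_equal(nrow(out$events), nrow(truth))
  expect_equal(out$events$start, truth$start)
  expect_equal(out$events$end, truth$end)
  expect_equal(out$events$duration_ns, truth$duration_ns)
  expect_equal(out$events$lipid_resno, truth$lipid_resno)
  # outside planted episodes ions are held > 0.5 nm from any lipid atom
  on_frames <- unlist(mapply(seq, truth$start, truth$end))
  off <- !(seq_len(40) %in% on_frames)
  per_ion <- split(out$nearest_lipid$distance_nm, out$nearest_lipid$ion)
  for (k in 1:2) {
    sched_k <- truth[truth$ion == k, ]
    on_k <- unlist(mapply(seq, sched_k$start, sched_k$end))
    expect_true(all(per_ion[[k]][-on_k] > 0.5))
  }
  # no ions -> empty results, not an error
  g0 <- generate_trajectory(traj_spec(n_frames = 5, residues = 1:2,
                                      seed = 3))
  out0 <- detect_coordination_events(g0$traj, contact_params())
  expect_equal(nrow(out0$events), 0L)
  expect_equal(nrow(out0$nearest_lipid), 0L)
})
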
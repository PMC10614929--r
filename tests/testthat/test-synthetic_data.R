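test_that("scene generation is deterministic and truth matches the spec", {
  sp <- sample_scene_spec(5, channels = c("proteinA", "proteinB"))
  a <- generate_guv_scene(sp)
  b <- generate_guv_scene(sp)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth, b$truth)
  expect_equal(nrow(a$truth$guvs), 10L)
  expect_equal(a$truth$proportion_with_puncta[["proteinA"]], 0.7)
  expect_equal(a$truth$proportion_with_puncta[["proteinB"]], 0.5)
  # planted colocalization: 4 coincident pairs, 7 GUVs with any punctum
  expect_equal(sum(a$truth$colocalization$n_colocalized), 4L)
  expect_equal(sum(a$truth$colocalization$n_max), 7L)
})

test_that("noiseless scene puts the protein-channel maximum at the punctum", {
  guvs <- data.frame(center_row = 40, center_col = 40, radius = 15,
                     ring_amplitude = 140, ring_thickness = 1.6)
  sp <- scene_spec(80, 80, guvs,
                   puncta = list(proteinA = data.frame(
                     guv = 1, angle = pi / 4, amplitude = 200, sigma = 2)),
                   noise_sigma = 0, background_offset = 10, seed = 1)
  sc <- generate_guv_scene(sp)
  ch <- get_channel(sc$image, "proteinA")
  pk <- which(ch == max(ch), arr.ind = TRUE)[1, ] - 1L  # 0-based
  truth <- sc$truth$puncta$proteinA
  expect_lt(abs(pk[["row"]] - truth$center_row), 1)
  expect_lt(abs(pk[["col"]] - truth$center_col), 1)
  # off-structure pixels of a noiseless scene equal the background offset
  expect_equal(ch[1:5, 1:5], matrix(10, 5, 5))
  lipid <- get_channel(sc$image, "lipid")
  expect_equal(lipid[1:5, 1:5], matrix(10, 5, 5))
})

test_that("scene spec validates geometry and parameters", {
  guvs <- data.frame(center_row = 10, center_col = 10, radius = 15,
                     ring_amplitude = 100, ring_thickness = 2)
  expect_error(scene_spec(64, 64, guvs), "inside the frame")
  guvs$center_row <- 32; guvs$center_col <- 32
  expect_error(scene_spec(64, 64, guvs,
                          puncta = list(proteinA = data.frame(
                            guv = 1, angle = 0, amplitude = 10, sigma = 0))),
               class = "guvmem_parameter_error")
})

test_that("trajectory truth equals the schedule and brute-force distances", {
  spec <- traj_spec(
    n_frames = 4, residues = 1:3,
    contact_schedule = data.frame(residue = c(1, 1, 1, 2),
                                  frame = c(1, 2, 4, 3),
                                  class = c("PS", "PS", "PC", "PS"),
                                  region = c("headgroup", "acyl",
                                             "headgroup", "headgroup")),
    seed = 3)
  g <- generate_trajectory(spec)
  tr <- g$truth$residues
  expect_equal(tr$frac_any, c(3 / 4, 1 / 4, 0))
  expect_equal(tr$frac_PS, c(2 / 4, 1 / 4, 0))
  expect_equal(tr$frac_PC, c(1 / 4, 0, 0))
  expect_equal(tr$frac_acyl, c(1 / 4, 0, 0))
  # brute-force distance check of every frame against the schedule
  at <- g$traj$atoms
  lipid <- which(at$category %in% c("lipid_PS", "lipid_PC"))
  for (f in 1:4) for (r in 1:3) {
    ra <- which(at$category == "protein" & at$resno == r)
    dmin <- min(min_image_distance(
      matrix(g$traj$coords[ra, , f], ncol = 3)[rep(1, length(lipid)), ],
      matrix(g$traj$coords[lipid, , f], ncol = 3), g$traj$box[f, ]))
    scheduled <- any(spec$contact_schedule$residue == r &
                     spec$contact_schedule$frame == f)
    expect_identical(dmin < 0.40, scheduled)
    if (scheduled) expect_gt(dmin, 0.7 * 0.40)
    else expect_lt(dmin, 3 * 0.40 + 1e-9)
  }
})

test_that("ion schedules become events with the planted durations", {
  spec <- traj_spec(n_frames = 20, residues = 1:2, n_ions = 2,
                    ion_schedule = data.frame(ion = c(1, 1, 2),
                                              start = c(10, 15, 3),
                                              end = c(12, 15, 4)),
                    seed = 9)
  g <- generate_trajectory(spec)
  ev <- g$truth$events
  expect_equal(nrow(ev), 3L)
  expect_equal(ev$duration_ns[ev$ion == 1], c(6, 2))  # 3 and 1 frames at 2 ns
  expect_equal(ev$t_start_ns[ev$ion == 2], (3 - 1) * 2)
  # empty schedules give zero-contact truth
  g0 <- generate_trajectory(traj_spec(n_frames = 5, residues = 1:2, seed = 1))
  expect_true(all(g0$truth$residues$frac_any == 0))
  expect_equal(nrow(g0$truth$events), 0L)
})

test_that("trajectory generation is deterministic and validates schedules", {
  spec <- sample_traj_spec(4, n_frames = 30)
  a <- generate_trajectory(spec)
  b <- generate_trajectory(spec)
  expect_identical(a$traj$coords, b$traj$coords)
  expect_error(traj_spec(n_frames = 5, residues = 1:2,
                         contact_schedule = data.frame(
                           residue = 1, frame = 6, class = "PS",
                           region = "headgroup")),
               class = "guvmem_parameter_error")
  expect_error(traj_spec(n_frames = 5, residues = 1:2, n_ions = 1,
                         ion_schedule = data.frame(ion = 1, start = 1,
                                                   end = 7)),
               class = "guvmem_parameter_error")
})
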
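test_that("planted GUVs are recovered exactly on noiseless scenes", {
  for (s in 1:3) {
    sp <- sample_scene_spec(s)
    sp$noise_sigma <- 0
    sc <- generate_guv_scene(sp)
    det <- detect_guvs(sc$image, r_min = 8, r_max = 18)
    m <- match_detections(det, sc$truth$guvs)
    expect_equal(m$recall, 1.0)
    expect_equal(m$precision, 1.0)
  }
})

test_that("blank images yield no detections", {
  expect_equal(nrow(detect_guvs(matrix(37, 64, 64), 5, 15)), 0L)
})

test_that("detection is equivariant under integer translations", {
  guvs <- data.frame(center_row = 30, center_col = 30, radius = 12,
                     ring_amplitude = 140, ring_thickness = 1.6)
  render <- function(dr, dc) {
    g <- guvs; g$center_row <- g$center_row + dr
    g$center_col <- g$center_col + dc
    sp <- scene_spec(100, 100, g, noise_sigma = 0, background_offset = 20,
                     seed = 1)
    get_channel(generate_guv_scene(sp)$image, "lipid")
  }
  d0 <- detect_guvs(render(0, 0), 8, 18)
  for (shift in list(c(5, 0), c(0, 7), c(13, 21))) {
    d1 <- detect_guvs(render(shift[1L], shift[2L]), 8, 18)
    expect_equal(d1$center_row, d0$center_row + shift[1L])
    expect_equal(d1$center_col, d0$center_col + shift[2L])
    expect_equal(d1$radius, d0$radius, tolerance = 1e-9)
  }
})

test_that("edge policy drops circles whose box exits the frame", {
  guvs <- data.frame(center_row = c(13, 50), center_col = c(30, 70),
                     radius = c(11, 11), ring_amplitude = 140,
                     ring_thickness = 1.6)
  sp <- scene_spec(100, 100, guvs, noise_sigma = 0, background_offset = 20,
                   seed = 1, allow_edge = TRUE)
  lipid <- get_channel(generate_guv_scene(sp)$image, "lipid")
  # the first GUV's refined bbox starts ~2 px from the frame edge; with a
  # padless radius window both are found, but a circle whose box exits is
  # dropped under "exclude"
  inc <- detect_guvs(lipid, 8, 18, edge_policy = "include")
  expect_equal(nrow(inc), 2L)
  near_edge <- scene_spec(100, 100,
                          transform(guvs, center_row = c(9, 50)),
                          noise_sigma = 0, background_offset = 20, seed = 1,
                          allow_edge = TRUE)
  lipid2 <- get_channel(generate_guv_scene(near_edge)$image, "lipid")
  exc <- detect_guvs(lipid2, 8, 18, edge_policy = "exclude")
  expect_equal(nrow(exc), 1L)
  expect_equal(exc$center_row, 50, tolerance = 1)
})

test_that("imported detections are validated, clipped and sorted", {
  reg <- data.frame(center_row = c(50, 10, 90), center_col = c(50, 10, 90),
                    radius = c(9, 9, 9),
                    r0 = c(41, 1, 81), r1 = c(60, 20, 100),
                    c0 = c(41, 1, 81), c1 = c(60, 20, 100))
  rec <- detection_record("img", reg)
  out <- import_detections(rec, c(100, 100))
  expect_equal(nrow(out), 3L)
  expect_equal(out$center_row, c(10, 50, 90))  # sorted by (row, col)
  # fully outside -> dropped with warning
  reg2 <- rbind(reg, data.frame(center_row = 300, center_col = 300,
                                radius = 9, r0 = 291, r1 = 310, c0 = 291,
                                c1 = 310))
  expect_warning(out2 <- import_detections(detection_record("img", reg2),
                                           c(100, 100)), "outside")
  expect_equal(nrow(out2), 3L)
  # partially outside: dropped under exclude, clipped under include
  reg3 <- rbind(reg, data.frame(center_row = 2, center_col = 50, radius = 9,
                                r0 = -7, r1 = 12, c0 = 41, c1 = 60))
  expect_equal(nrow(import_detections(detection_record("img", reg3),
                                      c(100, 100))), 3L)
  inc <- import_detections(detection_record("img", reg3), c(100, 100),
                           edge_policy = "include")
  expect_equal(nrow(inc), 4L)
  expect_equal(min(inc$r0), 0)
  # JSON round trip preserves geometry through the import path
  tf <- withr::local_tempfile(fileext = ".json")
  write_detections(rec, tf)
  expect_equal(import_detections(read_detections(tf), c(100, 100)), out)
})
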
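test_that("Li threshold handles degenerate and separable cases", {
  expect_equal(compute_li_threshold(matrix(7, 4, 4)), 7)
  two <- matrix(c(rep(10, 100), rep(200, 100)), 10, 20)
  t2 <- compute_li_threshold(two)
  expect_gt(t2, 10); expect_lt(t2, 200)
  expect_error(compute_li_threshold(matrix(numeric(0), 0, 0)), "empty")
})

test_that("Li threshold equals the exhaustive cross-entropy minimizer", {
  withr::local_seed(21)
  for (i in 1:25) {
    crop <- matrix(sample(0:255, 300, replace = TRUE), 15, 20)
    # same optimal background/foreground partition as the per-pixel oracle
    expect_identical(crop <= compute_li_threshold(crop),
                     crop <= li_oracle(crop))
  }
})

test_that("Otsu threshold equals the exhaustive within-variance minimizer", {
  withr::local_seed(22)
  half <- matrix(c(rep(0L, 50), rep(255L, 50)), 10, 10)
  expect_equal(compute_otsu_threshold(half), otsu_oracle(half))
  expect_error(compute_otsu_threshold(matrix(9L, 5, 5)),
               class = "guvmem_no_foreground")
  for (i in 1:25) {
    crop <- matrix(sample(0:255, 300, replace = TRUE), 15, 20)
    expect_equal(compute_otsu_threshold(crop), otsu_oracle(crop))
  }
})

test_that("preprocessing fixes zero crops and preserves spot locations", {
  params <- pipeline_params()
  z <- matrix(0, 30, 30)
  expect_true(all(preprocess_crop(z, 0, params) == 0L))
  expect_true(all(preprocess_crop(z + 5, 10, params) == 0L))  # all below bg
  # noiseless single-Gaussian-spot crop: argmax survives the full chain
  rows <- matrix(0:29, 30, 30); cols <- t(rows)
  spot <- 150 * exp(-((rows - 11)^2 + (cols - 17)^2) / (2 * 2^2))
  proc <- preprocess_crop(round(spot), 0, params)
  am_in <- which(spot == max(spot), arr.ind = TRUE)
  am_out <- which(proc == max(proc), arr.ind = TRUE)
  expect_true(any(abs(am_out[, 1] - am_in[1, 1]) <= 1 &
                  abs(am_out[, 2] - am_in[1, 2]) <= 1))
})

test_that("components larger than 5 px are kept, smaller rejected", {
  mask <- matrix(FALSE, 12, 12)
  mask[2:3, 2:3] <- TRUE            # area 4
  mask[6, 2:6] <- TRUE              # area 5: rejected ("larger than 5")
  mask[9:10, 8:10] <- TRUE          # area 6: kept
  pk <- label_puncta(mask)
  expect_length(pk, 1L)
  expect_equal(pk[[1L]]$area, 6L)
  expect_equal(pk[[1L]]$bbox, c(r0 = 8, r1 = 10, c0 = 7, c1 = 10))
  expect_length(label_puncta(matrix(FALSE, 5, 5)), 0L)
})

test_that("labelling equals the flood-fill oracle at both connectivities", {
  withr::local_seed(23)
  params4 <- pipeline_params(connectivity = 4L, min_component_px = 0L)
  params8 <- pipeline_params(connectivity = 8L, min_component_px = 0L)
  for (i in 1:20) {
    mask <- matrix(runif(400) < 0.35, 20, 20)
    for (conn in c(4L, 8L)) {
      pk <- label_puncta(mask, if (conn == 4L) params4 else params8)
      oracle <- flood_fill_oracle(mask, conn)
      oracle <- oracle[order(vapply(oracle, min, numeric(1)))]
      got <- lapply(pk, function(p)
        sort(as.integer(p$pixels[, 2L]) * nrow(mask) +
             as.integer(p$pixels[, 1L]) + 1L))
      got <- got[order(vapply(got, min, numeric(1)))]
      expect_equal(got, oracle)
    }
  }
})

test_that("raising the size threshold never increases the puncta count", {
  withr::local_seed(24)
  mask <- matrix(runif(900) < 0.45, 30, 30)
  counts <- vapply(0:12, function(m)
    length(label_puncta(mask, pipeline_params(min_component_px = m))),
    integer(1L))
  expect_true(all(diff(counts) <= 0))
})

test_that("per-GUV detection recovers planted puncta at high SNR", {
  sp <- sample_scene_spec(31, n_guvs = 4L, n_positive = 2L)
  sc <- generate_guv_scene(sp)
  regions <- sc$truth$guvs
  counts <- vapply(seq_len(nrow(regions)), function(g)
    length(detect_puncta_in_guv(sc$image, regions[g, ], "proteinA")),
    integer(1L))
  expect_equal(counts, c(1L, 1L, 0L, 0L))
  # the punctum bbox contains the planted center
  pk <- detect_puncta_in_guv(sc$image, regions[1, ], "proteinA")[[1L]]
  truth <- sc$truth$puncta$proteinA[1, ]
  expect_true(truth$center_row >= pk$bbox[["r0"]] &&
              truth$center_row < pk$bbox[["r1"]])
  expect_true(truth$center_col >= pk$bbox[["c0"]] &&
              truth$center_col < pk$bbox[["c1"]])
  # noiseless negative GUV has zero puncta
  spn <- sp; spn$noise_sigma <- 0
  scn <- generate_guv_scene(spn)
  expect_length(detect_puncta_in_guv(scn$image, regions[4, ], "proteinA"),
                0L)
})

test_that("two well-separated planted puncta are resolved as two", {
  guvs <- data.frame(center_row = 35, center_col = 35, radius = 14,
                     ring_amplitude = 140, ring_thickness = 1.6)
  sp <- scene_spec(70, 70, guvs,
                   puncta = list(proteinA = data.frame(
                     guv = 1, angle = c(0, pi), amplitude = 120, sigma = 2)),
                   noise_sigma = 4, background_offset = 20, seed = 2)
  sc <- generate_guv_scene(sp)
  pk <- detect_puncta_in_guv(sc$image, sc$truth$guvs[1, ], "proteinA")
  expect_length(pk, 2L)
})

test_that("proportion of GUVs with puncta follows its definition", {
  expect_equal(proportion_guvs_with_puncta(c(1, 0, 0, 2))$proportion, 0.5)
  expect_equal(proportion_guvs_with_puncta(c(0, 0, 0))$proportion, 0)
  expect_error(proportion_guvs_with_puncta(integer(0)), "zero GUVs")
})

test_that("colocalization counts follow the highest-channel rule", {
  mk <- function(r0, c0, size = 3L) {
    px <- as.matrix(expand.grid(row = r0:(r0 + size - 1L),
                                col = c0:(c0 + size - 1L)))
    guvmem:::new_punctum(px)
  }
  a <- list(mk(0, 0), mk(10, 10), mk(20, 20))
  expect_equal(colocalize(a, a)$proportion, 1.0)
  # A has 3, B has 2, exactly 2 of A's boxes overlap B's -> 2/3
  b <- list(mk(1, 1), mk(11, 11))
  cr <- colocalize(a, b)
  expect_equal(cr$n_colocalized, 2L)
  expect_equal(cr$proportion, 2 / 3)
  # symmetric under swapping channels
  expect_equal(colocalize(b, a)$proportion, cr$proportion)
  # disjoint boxes and empty channels
  d <- list(mk(40, 40))
  expect_equal(colocalize(a, d)$proportion, 0)
  expect_equal(colocalize(list(), list())$proportion, 0)
})

test_that("above-threshold particle area sums qualifying components", {
  img <- matrix(0, 20, 20)
  expect_equal(particle_area_above_threshold(img, 10), 0L)
  img[3:6, 3:6] <- 50                     # 16 px
  expect_equal(particle_area_above_threshold(img, 10), 16L)
  img[12:14, 12:14] <- 50                 # + 9 px
  img[18, 18:19] <- 50                    # + 2 px
  expect_equal(particle_area_above_threshold(img, 10), 27L)
  expect_equal(particle_area_above_threshold(img, 10, min_area = 9), 25L)
})
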
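geom <- test_geometry()

test_that("patch centers are spaced 36 deg apart and jittered as a whole ring", {
  spec <- patch_pattern_spec("/6", background = "black")
  jitters <- integer(0)
  for (seed in 1:8) {
    img <- render_patch_pattern(spec, seed, geom)
    ctr <- img$provenance$patch_centers_deg
    ang <- atan2(ctr$y, ctr$x) * 180 / pi
    steps <- diff(ang)
    steps <- ((steps + 180) %% 360) - 180
    expect_equal(abs(steps), rep(36, 9), tolerance = 1e-9)
    expect_true(img$provenance$jitter_deg %in% c(-12, 0, 12))
    # one patch sits at 12 o'clock +/- the ring jitter (angles wrap)
    target <- 90 + img$provenance$jitter_deg
    dev <- min(abs(((ang - target + 180) %% 360) - 180))
    expect_lt(dev, 1e-9)
    jitters <- c(jitters, img$provenance$jitter_deg)
    # radius of every center equals half the ring diameter
    expect_equal(sqrt(ctr$x^2 + ctr$y^2), rep(6.2, 10), tolerance = 1e-9)
  }
  expect_gt(length(unique(jitters)), 1L)
})

test_that("rendering is a pure function of spec and seed", {
  spec <- patch_pattern_spec("/4", background = "texture")
  a <- render_patch_pattern(spec, 7, geom)
  b <- render_patch_pattern(spec, 7, geom)
  expect_identical(a$luminance, b$luminance)
  expect_identical(a$chroma_x, b$chroma_x)
  c2 <- render_patch_pattern(spec, 8, geom)
  expect_false(identical(a$luminance, c2$luminance))
})

test_that("patch geometry exceeding the screen is rejected", {
  tiny <- display_geometry(69, 10, 10, 80, 80)
  expect_error(
    render_patch_pattern(patch_pattern_spec("/0"), 1, tiny),
    "exceeds screen bounds"
  )
})

test_that("ellipse texture uses exactly the eight luminance levels", {
  spec <- texture_spec("ellipse")
  img <- render_texture(spec, seed = 3, geom)
  expect_true(all(img$luminance %in% spec$luminance_levels))
  expect_gte(min(img$luminance), 0.23)
  expect_lte(max(img$luminance), 30.24)
  # several levels actually used
  expect_gt(length(unique(as.numeric(img$luminance))), 4L)
  expect_error(
    texture_spec(luminance_levels = c(1, 2, 3)),
    "exactly 8"
  )
})

test_that("square mask tiles the screen with axis-aligned 1.5 deg squares", {
  spec <- texture_spec("square")
  img <- render_texture(spec, seed = 5, geom)
  expect_true(all(img$luminance %in% spec$luminance_levels))
  # tiles are constant on aligned blocks: the first tile (1.5 deg = 12 px)
  side_px <- round(1.5 * geom$width_px / geom$width_deg)
  tile <- img$luminance[seq_len(side_px), seq_len(side_px)]
  expect_equal(length(unique(as.numeric(tile))), 1L)
  # and tile boundaries fall on the expected pitch along a row
  row <- img$luminance[1, ]
  changes <- which(diff(row) != 0)
  expect_true(all(changes %% side_px == 0))
})

test_that("full scramble permutes pixel values and protects fixation", {
  spec <- patch_pattern_spec("/6", background = "texture")
  img <- render_patch_pattern(spec, 2, geom)
  scr <- scramble_stimulus(img, seed = 9, mode = "full")
  expect_identical(
    sort(as.numeric(scr$luminance)),
    sort(as.numeric(img$luminance))
  )
  fix <- img$provenance$fixation_idx
  expect_identical(scr$luminance[fix], img$luminance[fix])
  expect_false(identical(scr$luminance, img$luminance))
})

test_that("patches-only scramble permutes patch pixels and blanks the rest", {
  spec <- patch_pattern_spec("/6", background = "black")
  img <- render_patch_pattern(spec, 2, geom)
  scr <- scramble_stimulus(img, seed = 9, mode = "patches_only",
    protect_fixation = FALSE
  )
  pidx <- img$provenance$patch_idx
  expect_identical(
    sort(as.numeric(scr$luminance[pidx])),
    sort(as.numeric(img$luminance[pidx]))
  )
  rest <- setdiff(seq_along(img$luminance), pidx)
  expect_true(all(scr$luminance[rest] == 0.05))
})

test_that("grating luminance profile, center trough and zero-contrast limit", {
  # full display resolution: the pixel nearest the center is the trough
  spec <- grating_spec(contrast = 0.5, overlay_patches = FALSE)
  full <- psycho_display()
  img <- render_grating(spec, geometry = full)
  ctr <- img$luminance[round(full$height_px / 2), round(full$width_px / 2)]
  expect_lt(ctr, 19.8)
  expect_equal(ctr, 19.8 * (1 - 0.5), tolerance = 0.01)
  flat <- render_grating(grating_spec(contrast = 0, overlay_patches = FALSE),
    geometry = geom
  )
  expect_true(all(abs(flat$luminance - 19.8) < 1e-12))
  withpatch <- render_grating(grating_spec(contrast = 0), 1, geom)
  outside <- withpatch$provenance$grating_idx
  expect_true(all(abs(withpatch$luminance[outside] - 19.8) < 1e-12))
  expect_error(grating_spec(contrast = 1.2), "contrast")
})

test_that("michelson measures match closed forms and the carrier contrast", {
  expect_equal(measure_michelson(matrix(5, 4, 4)), 0)
  expect_equal(measure_michelson(c(10, 30)), 0.5)
  expect_error(measure_michelson(matrix(0, 3, 3)), "all zero")
  expect_error(measure_michelson(matrix(1, 3, 3), region = integer(0)), "empty")

  for (C in c(0.34, 0.50, 0.66)) {
    img <- render_grating(grating_spec(contrast = C), seed = 1)
    m <- measure_michelson(img,
      region = img$provenance$grating_idx,
      method = "modulation", reference_luminance = 19.8
    )
    expect_equal(m, C, tolerance = 0.01)
  }
  # the plain min-max quotient of the enveloped grating understates the
  # carrier contrast by the envelope decay to the nearest crest
  img50 <- render_grating(grating_spec(contrast = 0.5), seed = 1)
  plain <- measure_michelson(img50, region = img50$provenance$grating_idx)
  env <- exp(-(1 / (2 * 0.67)) / 3.75)
  expect_equal(plain, 0.5 * (1 + env) / (2 - 0.5 * (1 - env)),
    tolerance = 0.01
  )
})

test_that("stimulus images round-trip through PNG + sidecar", {
  img <- render_patch_pattern(patch_pattern_spec("/6"), 4, geom)
  prefix <- file.path(withr::local_tempdir(), "stim")
  write_stimulus(img, prefix)
  back <- read_stimulus(prefix)
  expect_equal(back$luminance, img$luminance,
    tolerance = max(img$luminance) / 65535 * 2
  )
  expect_equal(back$chroma_x, img$chroma_x, tolerance = 1e-9)
  expect_equal(back$geometry$width_deg, img$geometry$width_deg)
  expect_equal(back$provenance$jitter_deg, img$provenance$jitter_deg)
})
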
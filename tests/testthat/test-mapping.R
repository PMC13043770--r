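# Shared small scenes for the mapping tests.
two_phase_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_stack(scene_spec(rows = 64, cols = 64,
        droplets = data.frame(row = c(20, 44), col = c(20, 44),
                              radius = c(10, 12), epsilon = c(30, 30),
                              peak = c(400, 400)),
        background_epsilon = 60, seed = 71L))
    cache
  }
})

test_that("threshold mask: methods, provenance and edge cases", {
  ax <- test_axis()
  cube <- array(rep(5, 8 * 8 * 32), c(8, 8, 32))
  st <- hyperspectral_stack(cube, ax)
  m_lo <- threshold_mask(st, "absolute", 1)
  expect_true(all(m_lo$include))
  expect_identical(m_lo$method, "absolute")
  expect_warning(m_hi <- threshold_mask(st, "absolute", 100),
                 "excludes every pixel")
  expect_false(any(m_hi$include))
  expect_error(threshold_mask(st, "quantile", 1.5), "\\(0, 1\\)")
})

test_that("raising the threshold never increases the included-pixel count", {
  sim <- two_phase_sim()
  counts <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(q)
    sum(threshold_mask(sim$stack, "quantile", q)$include), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("sedimenting-droplet artifact inflates phase and is excluded by default", {
  # artifact droplet at background-level counts with its early (blue)
  # channels missing: mean intensity drops below the median-based default
  # threshold while its apparent phase is inflated
  sc <- scene_spec(rows = 64, cols = 64,
                   droplets = data.frame(row = 20, col = 20, radius = 10,
                                         epsilon = 5, peak = 400),
                   artifact_droplets = data.frame(row = 46, col = 46,
                                                  radius = 9, epsilon = 5,
                                                  peak = 100, cutoff = 10),
                   seed = 77L)
  sim <- generate_stack(sc)
  ph <- phasor_image(sim$stack)
  clean <- generate_stack(scene_spec(rows = 64, cols = 64,
                   droplets = data.frame(row = c(20, 46), col = c(20, 46),
                                         radius = c(10, 9),
                                         epsilon = c(5, 5),
                                         peak = c(400, 100)),
                   seed = 77L))
  ph_clean <- phasor_image(clean$stack)
  art <- sim$labels == 2L
  # phase strictly inflated pixel-by-pixel relative to the intact twin scene
  expect_true(all(ph$phase[art] > ph_clean$phase[art]))
  # and the default threshold removes the artifact droplet
  mask <- threshold_mask(sim$stack)
  expect_false(any(mask$include[art]))
  expect_true(all(mask$include[sim$labels == 1L]))
})

test_that("noiseless uniform stack maps to its generating permittivity", {
  fm <- test_fm()
  ax <- test_axis()
  sp <- forward_spectrum(30, fm, ax, 100)
  cube <- array(rep(sp$intensities, each = 36), c(6, 6, 32))
  pmap <- permittivity_map(hyperspectral_stack(cube, ax), test_cal())
  expect_true(all(abs(pmap$epsilon - 30) < 1e-3))
  expect_false(any(pmap$clamped))
})

test_that("two-phase noisy stack: per-phase medians within 5 percent", {
  sim <- generate_stack(scene_spec(seed = 5L))  # eps 5 droplets on eps 60
  pmap <- permittivity_map(sim$stack, test_cal(),
                           threshold_mask(sim$stack))
  med_c <- stats::median(pmap$epsilon[sim$labels == 1L & pmap$valid])
  med_d <- stats::median(pmap$epsilon[sim$labels == 0L & pmap$valid])
  expect_lt(abs(med_c - 5) / 5, 0.05)
  expect_lt(abs(med_d - 60) / 60, 0.05)
})

test_that("all-excluded masks yield an empty map with a warning", {
  sim <- two_phase_sim()
  mask <- suppressWarnings(threshold_mask(sim$stack, "absolute", 1e9))
  expect_warning(pmap <- permittivity_map(sim$stack, test_cal(), mask),
                 "no valid included pixels")
  expect_true(all(is.na(pmap$epsilon)))
  expect_false(any(pmap$valid))
})

test_that("segmentation separates bright condensates from dim background", {
  sim <- generate_stack(scene_spec(rows = 64, cols = 64,
    droplets = data.frame(row = c(20, 44), col = c(20, 44),
                          radius = c(10, 12), epsilon = c(5, 5),
                          peak = c(400, 400)),
    background_peak = 50, seed = 81L))
  mask <- threshold_mask(sim$stack, "absolute", 0)
  seg <- segment_phases(sim$stack, mask)
  truth <- ifelse(sim$labels == 1L, 2L, 1L)
  expect_gte(mean(seg$labels == truth), 0.99)

  flipped <- segment_phases(sim$stack, mask, polarity = "dim")
  swap <- ifelse(seg$labels == 2L, 1L, ifelse(seg$labels == 1L, 2L, 0L))
  expect_identical(flipped$labels, swap)
})

test_that("unimodal intensity yields a single class with a warning", {
  sim <- generate_stack(scene_spec(rows = 32, cols = 32,
    droplets = data.frame(row = 1, col = 1, radius = 0.1,
                          epsilon = 60, peak = 100),
    background_peak = 100, seed = 91L))
  mask <- threshold_mask(sim$stack, "absolute", 0)
  expect_warning(seg <- segment_phases(sim$stack, mask), "not bimodal")
  expect_false(seg$bimodal)
  expect_identical(sum(seg$counts[c("condensate", "depleted")] > 0), 1L)
})

test_that("phase statistics: identity, null contrast and recovery", {
  fm <- test_fm()
  ax <- test_axis()
  # all pixels identical: mean-phase epsilon equals per-pixel epsilon
  sp <- forward_spectrum(40, fm, ax, 100)
  cube <- array(rep(sp$intensities, each = 16), c(4, 4, 32))
  cube[, 3:4, ] <- cube[, 3:4, ] * 5  # brighter half = "condensate"
  st <- hyperspectral_stack(cube, ax)
  mask <- threshold_mask(st, "absolute", 0)
  pmap <- permittivity_map(st, test_cal(), mask)
  seg <- segment_phases(st, mask)
  stt <- phase_statistics(pmap, seg)
  expect_equal(stt$per_label$epsilon_mean_phase,
               stt$per_label$epsilon_median, tolerance = 1e-9)
  expect_equal(stt$contrast, 0, tolerance = 1e-9)  # same eps in both phases

  # eps_c = 30 vs eps_d = 60: contrast -30 within 5%
  sim <- two_phase_sim()
  mask2 <- threshold_mask(sim$stack)
  pmap2 <- permittivity_map(sim$stack, test_cal(), mask2)
  seg2 <- segment_phases(sim$stack, mask2)
  st2 <- phase_statistics(pmap2, seg2)
  expect_lt(abs(st2$contrast - (-30)) / 30, 0.05)
  eps_c <- st2$per_label$epsilon_mean_phase[st2$per_label$label == "condensate"]
  expect_lt(abs(eps_c - 30) / 30, 0.05)
})

test_that("averaging order is immaterial for narrow phase distributions", {
  sim <- two_phase_sim()
  mask <- threshold_mask(sim$stack)
  pmap <- permittivity_map(sim$stack, test_cal(), mask)
  seg <- segment_phases(sim$stack, mask)
  sel <- seg$labels == 2L & pmap$valid  # condensate pixels: tight phase cloud
  expect_lt(stats::sd(pmap$phasor$phase[sel]), 0.05)
  e_mean_phase <- as.numeric(invert_to_epsilon(
    mean(pmap$phasor$phase[sel]), test_cal(), kind = "phase"))
  e_pixel_mean <- mean(pmap$epsilon[sel])
  expect_lt(abs(e_mean_phase - e_pixel_mean) / e_pixel_mean, 0.02)
})

test_that("pipeline is deterministic for identical scene and seed", {
  a <- generate_stack(scene_spec(rows = 48, cols = 48, seed = 13L))
  b <- generate_stack(scene_spec(rows = 48, cols = 48, seed = 13L))
  pa <- permittivity_map(a$stack, test_cal(), threshold_mask(a$stack))
  pb <- permittivity_map(b$stack, test_cal(), threshold_mask(b$stack))
  expect_identical(pa$epsilon, pb$epsilon)
  sa <- phase_statistics(pa, segment_phases(a$stack, threshold_mask(a$stack)))
  sb <- phase_statistics(pb, segment_phases(b$stack, threshold_mask(b$stack)))
  expect_identical(sa$contrast, sb$contrast)
})

test_that("connected condensate components are counted and border-flagged", {
  sim <- generate_stack(scene_spec(rows = 48, cols = 48,
    droplets = data.frame(row = c(14, 34, 2), col = c(14, 34, 46),
                          radius = c(7, 6, 4), epsilon = c(5, 5, 5),
                          peak = c(400, 400, 400)),
    background_peak = 50, seed = 15L))
  mask <- threshold_mask(sim$stack, "absolute", 0)
  seg <- segment_phases(sim$stack, mask)
  cc <- condensate_components(seg)
  expect_identical(nrow(cc$components), 3L)
  expect_identical(sum(cc$components$touches_border), 1L)
  expect_setequal(unique(as.vector(cc$component[seg$labels == 2L])),
                  cc$components$id)
})
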
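# --- IHC montage generation -------------------------------------------------

test_that("target_fraction 0 paints nothing", {
  sc <- make_ihc_montage(ihc_scene_spec(tile_px = 32, pixel_size = 6.8,
                                        target_fraction = 0, seed = 1))
  expect_equal(sc$true_fraction, 0)
  expect_true(all(sc$truth_mask == 0L))
  expect_equal(sum(classify_pixels(sc$image, at8_threshold())), 0)
})

test_that("default acquisition geometry covers 1.70 mm^2", {
  sc <- make_ihc_montage(ihc_scene_spec(n_structures = 0))
  expect_equal(dim(sc$image$rgb)[1:2], c(1536L, 1536L))
  expect_equal(round(montage_area_mm2(sc$image), 2), 1.70)
})

test_that("reported fraction equals an independent in-range pixel count", {
  # one plaque; oracle counts pixels inside the 4G8 box directly
  sc <- make_ihc_montage(ihc_scene_spec(tile_px = 48, pixel_size = 3,
                                        n_structures = 1,
                                        structure_kinds = "plaque",
                                        marker = "4G8", seed = 9))
  box <- g48_threshold()
  rgb <- sc$image$rgb
  inbox <- rgb[, , 1] >= box$r_range[1] & rgb[, , 1] <= box$r_range[2] &
    rgb[, , 2] >= box$g_range[1] & rgb[, , 2] <= box$g_range[2] &
    rgb[, , 3] >= box$b_range[1] & rgb[, , 3] <= box$b_range[2]
  expect_gt(sum(inbox), 0)
  expect_equal(sc$true_fraction, sum(inbox) / length(inbox))
})

test_that("generator and classifier are exact duals across random scenes", {
  set.seed(5)
  for (i in 1:8) {
    marker <- sample(c("AT8", "4G8"), 1)
    spec <- ihc_scene_spec(
      tile_px = 64, pixel_size = 6.8,
      n_structures = sample(3:25, 1),
      structure_kinds = if (marker == "AT8") c("tangle", "thread") else "plaque",
      n_specks = if (marker == "4G8") sample(2:5, 1) else 0,
      marker = marker, seed = sample.int(1e6, 1)
    )
    sc <- make_ihc_montage(spec)
    box <- if (marker == "AT8") at8_threshold() else g48_threshold()
    expect_identical(classify_pixels(sc$image, box), sc$truth_mask > 0L)
  }
})

test_that("APP specks are sub-100 um^2 and detached from other structures", {
  sc <- make_ihc_montage(ihc_scene_spec(tile_px = 64, pixel_size = 6.8,
                                        n_structures = 12,
                                        structure_kinds = "plaque",
                                        n_specks = 6, marker = "4G8",
                                        seed = 21))
  lab <- label_components(sc$truth_mask > 0L)
  for (k in seq_len(max(lab))) {
    vals <- unique(sc$truth_mask[lab == k])
    expect_length(vals, 1)  # never mixes speck and structure pixels
    if (vals == 2L) {
      expect_lt(sum(lab == k) * 6.8^2, 100)
    }
  }
})

test_that("unreachable target fractions are refused with the limit named", {
  expect_error(make_ihc_montage(ihc_scene_spec(tile_px = 32, pixel_size = 6.8,
                                               target_fraction = 0.5)),
               "0.35")
})

test_that("montage generation is reproducible for a fixed seed", {
  s <- ihc_scene_spec(tile_px = 48, pixel_size = 6.8, n_structures = 6,
                      seed = 33)
  expect_identical(make_ihc_montage(s), make_ihc_montage(s))
})

# --- vessel scenes ----------------------------------------------------------

test_that("vessel scene truth follows the SI formula and rejects bad specs", {
  expect_equal(vessel_scene_spec(100, 200)$true_si, 0.5)
  expect_equal(vessel_scene_spec(140, 200)$true_si, 0.3)
  expect_error(vessel_scene_spec(200, 100), "d_int < d_ext")
  expect_error(vessel_scene_spec(-5, 100))
  set.seed(2)
  for (i in 1:20) {
    de <- runif(1, 55, 400)
    di <- runif(1, 0.05, 0.95) * de
    si <- vessel_scene_spec(di, de)$true_si
    expect_gt(si, 0)
    expect_lt(si, 1)
  }
})

test_that("render-measure round trip recovers the configured SI", {
  v <- make_vessel_image(vessel_scene_spec(100, 200, pixel_size = 1, seed = 4))
  m <- measure_vessel(v$image)
  expect_lt(abs(m$d_ext - 200), 2)
  expect_lt(abs(m$d_int - 100), 2)
  expect_lt(abs(m$si - 0.5), 2 * 1 / 200 + 2 * 1 / 200)
})

# --- lesion masks -----------------------------------------------------------

test_that("empty lesion spec yields an empty mask and census", {
  lm <- make_lesion_mask(lesion_scene_spec(field_mm = 40))
  expect_false(any(lm$mask))
  expect_equal(nrow(census_lesions(lm)), 0)
})

test_that("single lesions come out at the requested diameter", {
  for (d in c(5, 15, 25)) {
    lm <- make_lesion_mask(lesion_scene_spec(field_mm = 60,
                                             lesion_diameters = d,
                                             px_per_mm = 4, seed = d))
    cen <- census_lesions(lm)
    expect_equal(nrow(cen), 1)
    expect_lt(abs(cen$diameter_mm - d) / d, 0.05)
  }
})

test_that("bridged lesion pairs form a single component, separate ones do not", {
  lb <- make_lesion_mask(lesion_scene_spec(field_mm = 80,
                                           lesion_diameters = c(12, 12),
                                           bridges = list(c(1, 2)),
                                           px_per_mm = 4, seed = 3))
  expect_equal(nrow(census_lesions(lb)), 1)
  ls <- make_lesion_mask(lesion_scene_spec(field_mm = 80,
                                           lesion_diameters = c(12, 12),
                                           px_per_mm = 4, seed = 3))
  expect_equal(nrow(census_lesions(ls)), 2)
})

test_that("lesion specs validate diameters, fit and bridge indices", {
  expect_error(lesion_scene_spec(field_mm = 40, lesion_diameters = -1), "> 0")
  expect_error(lesion_scene_spec(field_mm = 20, lesion_diameters = 19), "fit")
  expect_error(lesion_scene_spec(field_mm = 40, lesion_diameters = c(5, 5),
                                 bridges = list(c(1, 3))), "indices")
})

# --- cohorts ----------------------------------------------------------------

test_that("independent latents stay uncorrelated at large n", {
  id <- diag(5)
  dimnames(id) <- dimnames(default_latent_corr())
  co <- make_cohort(cohort_config(n_cases = 5000, latent_corr = id,
                                  group_shift = c(age = 0, hptau = 0,
                                                  abeta = 0, si = 0, wmh = 0),
                                  seed = 12))
  z <- attr(co, "latents")
  off <- cor(z)[upper.tri(diag(5))]
  expect_true(all(abs(off) < 0.1))
})

test_that("configured latent correlation is recovered by Monte Carlo", {
  lc <- default_latent_corr()
  lc["hptau", "wmh"] <- lc["wmh", "hptau"] <- 0.5
  co <- make_cohort(cohort_config(n_cases = 5000, latent_corr = lc,
                                  group_shift = c(age = 0, hptau = 0,
                                                  abeta = 0, si = 0, wmh = 0),
                                  seed = 13))
  z <- attr(co, "latents")
  expect_lt(abs(cor(z[, "hptau"], z[, "wmh"]) - 0.5), 0.03)
})

test_that("cohort composition, scales and determinism hold", {
  co <- make_cohort(cohort_config(n_cases = 36, prop_ad = 23 / 36, seed = 14))
  expect_equal(nrow(co), 36)
  expect_equal(sum(co$group == "AD"), 23)
  expect_true(all(co$hptau_total >= 0 & co$hptau_total <= 100))
  expect_true(all(co$si_total > 0 & co$si_total < 1))
  expect_true(all(co$arwmc_frontal %in% 0:3))
  co2 <- make_cohort(cohort_config(n_cases = 36, prop_ad = 23 / 36, seed = 14))
  expect_identical(co, co2)
})

test_that("a non-PSD latent matrix is rejected", {
  bad <- default_latent_corr()
  bad["age", "hptau"] <- bad["hptau", "age"] <- 0.99
  bad["age", "wmh"] <- bad["wmh", "age"] <- 0.99
  bad["hptau", "wmh"] <- bad["wmh", "hptau"] <- -0.9
  expect_error(cohort_config(latent_corr = bad), "positive semidefinite")
})
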
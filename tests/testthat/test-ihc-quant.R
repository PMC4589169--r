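mk_img <- function(r, g, b, pixel_size = 1, roi = NULL) {
  arr <- array(0L, c(nrow(r), ncol(r), 3))
  arr[, , 1] <- r
  arr[, , 2] <- g
  arr[, , 3] <- b
  montage_image(arr, pixel_size = pixel_size, roi_exclude = roi)
}
flat <- function(v, h = 4, w = 4) matrix(v, h, w)

test_that("pixel classification applies the inclusive RGB box", {
  at8 <- at8_threshold()
  img <- mk_img(flat(100), flat(100), flat(60))
  expect_true(all(classify_pixels(img, at8)))        # (100,100,60) in box
  img2 <- mk_img(flat(200), flat(100), flat(60))
  expect_false(any(classify_pixels(img2, at8)))      # R=200 out of 25-170
  white <- mk_img(flat(255), flat(255), flat(255))
  expect_equal(sum(classify_pixels(white, at8)), 0)
  # boundary values are inside (inclusive at both ends)
  img3 <- mk_img(flat(25), flat(156), flat(11))
  expect_true(all(classify_pixels(img3, at8)))
})

test_that("ROI-excluded pixels are neither positive nor measured", {
  roi <- matrix(FALSE, 4, 4)
  roi[1:2, ] <- TRUE
  img <- mk_img(flat(100), flat(100), flat(60), roi = roi)
  mask <- classify_pixels(img, at8_threshold())
  expect_false(any(mask[roi]))
  res <- percent_area(mask, img)
  expect_equal(res$measured_px, 8L)
  expect_equal(res$positive_px, 8L)
  expect_equal(res$percent_area, 100)
})

test_that("size filter drops components strictly below the threshold", {
  m <- matrix(FALSE, 40, 40)
  m[1, 1:33] <- TRUE           # 33 px: 99 um^2 at ps sqrt(3)
  m[20, 1:34] <- TRUE          # 34 px: 102 um^2
  ps <- sqrt(3)
  out <- filter_components(m, 100, ps)
  expect_equal(sum(out[1, ]), 0)
  expect_equal(sum(out[20, ]), 34)
  # threshold 0 and NA are identities; filtering is idempotent
  expect_identical(filter_components(m, 0, ps), m)
  expect_identical(filter_components(m, NA, ps), m)
  expect_identical(filter_components(out, 100, ps),
                   filter_components(filter_components(m, 100, ps), 100, ps))
})

test_that("surviving component census matches a flood-fill oracle", {
  set.seed(42)
  for (i in 1:10) {
    m <- random_mask(sample(16:64, 1), sample(16:64, 1), 0.25)
    ps <- runif(1, 0.8, 3)
    thr <- runif(1, 2, 30)
    out <- filter_components(m, thr, ps)
    ora <- flood_fill_label(m)
    keep_ora <- which(tabulate(ora[ora > 0]) * ps^2 >= thr)
    expect_equal(sum(out),
                 sum(ora %in% keep_ora & ora > 0))
    expect_equal(max(label_components(out)), length(keep_ora))
  }
})

test_that("widening ranges and lowering the size bar are monotone", {
  set.seed(7)
  sc <- make_ihc_montage(ihc_scene_spec(tile_px = 48, pixel_size = 6.8,
                                        n_structures = 8, marker = "AT8",
                                        seed = 77))
  narrow <- rgb_threshold(c(60, 120), c(60, 120), c(30, 90))
  wide <- rgb_threshold(c(25, 170), c(27, 156), c(11, 126))
  expect_lte(sum(classify_pixels(sc$image, narrow)),
             sum(classify_pixels(sc$image, wide)))
  m <- classify_pixels(sc$image, wide)
  expect_gte(sum(filter_components(m, 50, 6.8)),
             sum(filter_components(m, 200, 6.8)))
})

test_that("percent area is the positive share of measured pixels", {
  m <- matrix(FALSE, 10, 20)
  m[1:50] <- TRUE
  img <- mk_img(matrix(0, 10, 20), matrix(0, 10, 20), matrix(0, 10, 20))
  res <- percent_area(m, img)
  expect_equal(res$percent_area, 25)
  expect_equal(res$positive_px, 50L)
  expect_equal(res$measured_px, 200L)
  all_roi <- matrix(TRUE, 10, 20)
  img2 <- mk_img(matrix(0, 10, 20), matrix(0, 10, 20), matrix(0, 10, 20),
                 roi = all_roi)
  expect_error(percent_area(m, img2), "no measurable")
})

test_that("quantification refuses a size filter without a pixel scale", {
  img <- mk_img(flat(100), flat(100), flat(60), pixel_size = NA)
  expect_error(quantify_ihc(img, g48_threshold()), "no pixel scale")
  expect_silent(quantify_ihc(img, at8_threshold()))  # AT8 has no size filter
})

test_that("quantification recovers painted ground truth through the stack", {
  sc <- make_ihc_montage(ihc_scene_spec(tile_px = 64, pixel_size = 6.8,
                                        n_structures = 10,
                                        structure_kinds = "plaque",
                                        n_specks = 4, marker = "4G8",
                                        seed = 55))
  res <- quantify_ihc(sc$image, g48_threshold())
  expect_equal(res$positive_px, sum(sc$truth_mask == 1L))
  expect_equal(res$percent_area, 100 * sc$true_fraction_pathological)
  res_nofilter <- quantify_ihc(sc$image, rgb_threshold(c(50, 180), c(20, 168),
                                                       c(8, 139)))
  expect_equal(res_nofilter$positive_px, sum(sc$truth_mask > 0L))
})

test_that("sampling plan has 24 locations covering all six sections", {
  plan <- sampling_plan()
  expect_equal(nrow(plan), 24)
  expect_setequal(unique(plan$section),
                  c("prefrontal", "midfrontal", "entorhinal", "temporal",
                    "parietal", "occipital"))
  expect_setequal(unique(plan$location_class),
                  c("sulcus", "midsection", "gyrus"))
})

test_that("regional aggregation pools sections as specified", {
  plan <- sampling_plan()
  plan$percent_area <- 2
  agg <- aggregate_case(plan)
  expect_equal(unname(agg$regional), rep(2, 4))
  expect_equal(agg$total, 2)

  plan$percent_area <- rep(c(1, 1, 2, 2, 3, 4), each = 4)
  agg <- aggregate_case(plan)
  expect_equal(unname(agg$regional), c(1, 2, 3, 4))  # frontal..occipital
  expect_equal(agg$total, 2.5)

  set.seed(3)
  plan$percent_area <- runif(24, 0, 10)
  agg <- aggregate_case(plan)
  by_hand <- c(
    mean(plan$percent_area[plan$section %in% c("prefrontal", "midfrontal")]),
    mean(plan$percent_area[plan$section %in% c("entorhinal", "temporal")]),
    mean(plan$percent_area[plan$section == "parietal"]),
    mean(plan$percent_area[plan$section == "occipital"])
  )
  expect_equal(unname(agg$regional), by_hand)
  expect_equal(agg$total, mean(by_hand))

  expect_error(aggregate_case(plan[plan$section != "parietal", ]),
               "parietal")
})
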
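#' RGB threshold specification for DAB immunoreactivity
#'
#' A pixel is counted as immunopositive iff its red, green and blue values
#' each fall inside the corresponding inclusive range. The shipped defaults
#' are the standardised NIS-Elements-style boxes for the AT8
#' (hyperphosphorylated tau) and 4G8 (amyloid-beta) antibodies; 4G8
#' additionally carries a 100 um^2 minimum component area so that punctate
#' physiological APP staining is excluded from the amyloid burden.
#'
#' @param r_range,g_range,b_range inclusive integer ranges within 0..255.
#' @param min_component_area minimum physical component area in um^2, or
#'   `NA` for no size filtering.
#' @param marker label carried through to results ("AT8", "4G8", ...).
#' @return object of class `rgb_threshold`.
#' @examples
#' at8_threshold()
#' g48_threshold()$min_component_area  # 100 um^2 APP exclusion
#' @export
rgb_threshold <- function(r_range, g_range, b_range,
                          min_component_area = NA_real_,
                          marker = "custom") {
  chk <- function(x, nm) {
    if (length(x) != 2L || any(x < 0) || any(x > 255) || x[1] > x[2]) {
      stop(sprintf("%s must be an increasing inclusive range within [0, 255]", nm))
    }
    as.integer(x)
  }
  if (!is.na(min_component_area) && min_component_area < 0) {
    stop("min_component_area must be >= 0 (um^2) or NA")
  }
  structure(
    list(
      r_range = chk(r_range, "r_range"),
      g_range = chk(g_range, "g_range"),
      b_range = chk(b_range, "b_range"),
      min_component_area = as.numeric(min_component_area),
      marker = marker
    ),
    class = "rgb_threshold"
  )
}

#' @rdname rgb_threshold
#' @export
at8_threshold <- function() {
  rgb_threshold(c(25, 170), c(27, 156), c(11, 126),
                min_component_area = NA_real_, marker = "AT8")
}

#' @rdname rgb_threshold
#' @export
g48_threshold <- function() {
  rgb_threshold(c(50, 180), c(20, 168), c(8, 139),
                min_component_area = 100, marker = "4G8")
}

#' Construct an IHC montage image container
#'
#' @param rgb integer array `h x w x 3` with values in 0..255.
#' @param pixel_size physical pixel size in um/pixel (may be `NA` when the
#'   scale is unknown; size filtering then refuses to run).
#' @param roi_exclude optional logical matrix marking pixels excluded from
#'   measurement (white matter, meningeal structures); excluded pixels are
#'   removed from both numerator and denominator.
#' @return object of class `montage_image`.
#' @export
montage_image <- function(rgb, pixel_size = NA_real_, roi_exclude = NULL) {
  stopifnot(is.array(rgb), length(dim(rgb)) == 3L, dim(rgb)[3] == 3L)
  if (any(dim(rgb)[1:2] == 0L)) stop("raster must be nonempty")
  if (!is.na(pixel_size) && pixel_size <= 0) stop("pixel_size must be > 0 um/px")
  if (!is.null(roi_exclude)) {
    stopifnot(is.matrix(roi_exclude),
              all(dim(roi_exclude) == dim(rgb)[1:2]))
    mode(roi_exclude) <- "logical"
  }
  structure(
    list(rgb = rgb, pixel_size = as.numeric(pixel_size), roi_exclude = roi_exclude),
    class = "montage_image"
  )
}

#' Physical area of a montage in mm^2
#' @param image a `montage_image`.
#' @export
montage_area_mm2 <- function(image) {
  stopifnot(inherits(image, "montage_image"), !is.na(image$pixel_size))
  d <- dim(image$rgb)
  (d[1] * image$pixel_size / 1000) * (d[2] * image$pixel_size / 1000)
}

#' Classify pixels against an RGB threshold box
#'
#' @param image a `montage_image`.
#' @param spec an `rgb_threshold`.
#' @return logical matrix; ROI-excluded pixels are always `FALSE`.
#' @export
classify_pixels <- function(image, spec) {
  stopifnot(inherits(image, "montage_image"), inherits(spec, "rgb_threshold"))
  rgb <- image$rgb
  if (max(rgb) <= 1 && is.double(rgb) && any(rgb != trunc(rgb))) {
    stop("expected 8-bit RGB values in 0..255")
  }
  r <- rgb[, , 1L]
  g <- rgb[, , 2L]
  b <- rgb[, , 3L]
  pos <- r >= spec$r_range[1] & r <= spec$r_range[2] &
    g >= spec$g_range[1] & g <= spec$g_range[2] &
    b >= spec$b_range[1] & b <= spec$b_range[2]
  if (!is.null(image$roi_exclude)) {
    pos[image$roi_exclude] <- FALSE
  }
  pos
}

#' Remove immunopositive components below a physical size
#'
#' Connected components (8-connectivity) whose area is strictly below
#' `min_area_um2` are deleted; everything else is untouched. This is the APP
#' exclusion step of amyloid quantification.
#'
#' @param mask logical matrix.
#' @param min_area_um2 minimum area in um^2; `NA` or 0 leaves the mask as is.
#' @param pixel_size um/pixel; required whenever a positive threshold is set.
#' @return logical matrix.
#' @export
filter_components <- function(mask, min_area_um2, pixel_size) {
  stopifnot(is.matrix(mask))
  mode(mask) <- "logical"
  if (is.na(min_area_um2) || min_area_um2 == 0) {
    return(mask)
  }
  if (missing(pixel_size) || is.na(pixel_size) || pixel_size <= 0) {
    stop("size filtering requires a physical pixel scale (um/px)")
  }
  lab <- label_components(mask)
  if (max(lab) == 0L) {
    return(mask)
  }
  npx <- tabulate(lab[lab > 0L], nbins = max(lab))
  keep <- npx * pixel_size^2 >= min_area_um2
  out <- mask
  out[lab > 0L] <- keep[lab[lab > 0L]]
  out
}

#' Percent area covered by immunoreactivity
#'
#' @param mask logical positive-pixel mask aligned with `image`.
#' @param image the `montage_image` the mask was derived from.
#' @param marker marker label for the result.
#' @return an `ir_result`: list with `percent_area` (0..100), `positive_px`,
#'   `measured_px` and `marker`. Measured area excludes ROI-excluded pixels.
#' @export
percent_area <- function(mask, image, marker = "custom") {
  stopifnot(is.matrix(mask), inherits(image, "montage_image"),
            all(dim(mask) == dim(image$rgb)[1:2]))
  mode(mask) <- "logical"
  excl <- image$roi_exclude
  if (is.null(excl)) {
    measured <- length(mask)
    positive <- sum(mask)
  } else {
    measured <- sum(!excl)
    positive <- sum(mask & !excl)
  }
  if (measured == 0L) {
    stop("no measurable pixels: the whole field is ROI-excluded")
  }
  structure(
    list(
      percent_area = 100 * positive / measured,
      positive_px = as.integer(positive),
      measured_px = as.integer(measured),
      marker = marker
    ),
    class = "ir_result"
  )
}

#' One-call quantification: classify, size-filter, percent area
#'
#' @inheritParams classify_pixels
#' @return an `ir_result`.
#' @export
quantify_ihc <- function(image, spec) {
  if (!is.na(spec$min_component_area) && spec$min_component_area > 0 &&
      is.na(image$pixel_size)) {
    stop("threshold requests a size filter but the image has no pixel scale")
  }
  mask <- classify_pixels(image, spec)
  mask <- filter_components(mask, spec$min_component_area, image$pixel_size)
  percent_area(mask, image, marker = spec$marker)
}

# sections sampled per hemisphere and the regional pooling they feed
.sections <- c("prefrontal", "midfrontal", "entorhinal", "temporal",
               "parietal", "occipital")
.section_region <- c(
  prefrontal = "frontal", midfrontal = "frontal",
  entorhinal = "temporal", temporal = "temporal",
  parietal = "parietal", occipital = "occipital"
)

#' The 24-location cortical sampling plan
#'
#' Six cortical sections (prefrontal, midfrontal, entorhinal, temporal,
#' parietal, occipital), each sampled at four locations spanning the
#' sulcus-to-gyral-crest gradient of pathology (one sulcus, two midsection,
#' one gyral tip), for 24 sample areas per case and marker.
#'
#' @return data.frame with columns `section`, `location_class` (24 rows).
#' @export
sampling_plan <- function() {
  plan <- data.frame(
    section = rep(.sections, each = 4L),
    location_class = rep(c("sulcus", "midsection", "midsection", "gyrus"), 6L),
    stringsAsFactors = FALSE
  )
  plan
}

#' Aggregate per-location IR values into regional and total burden
#'
#' Frontal burden is the mean over the prefrontal and midfrontal locations,
#' temporal the mean over entorhinal plus temporal, parietal and occipital
#' stand alone; the total is the mean of the four regional values.
#'
#' @param per_location data.frame with columns `section` and `percent_area`
#'   (one row per sampled location, all six sections present).
#' @return list with `regional` (named numeric: frontal, temporal, parietal,
#'   occipital) and `total`.
#' @export
aggregate_case <- function(per_location) {
  stopifnot(is.data.frame(per_location),
            all(c("section", "percent_area") %in% names(per_location)))
  missing_sections <- setdiff(.sections, unique(per_location$section))
  if (length(missing_sections)) {
    stop("sampling plan incomplete; absent sections: ",
         paste(missing_sections, collapse = ", "))
  }
  unknown <- setdiff(unique(per_location$section), .sections)
  if (length(unknown)) {
    stop("unknown sections: ", paste(unknown, collapse = ", "))
  }
  region <- .section_region[per_location$section]
  regional <- c(tapply(per_location$percent_area, region, mean))
  regional <- regional[c("frontal", "temporal", "parietal", "occipital")]
  list(regional = regional, total = mean(regional))
}
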
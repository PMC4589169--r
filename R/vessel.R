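#' Sclerotic index of a vessel
#'
#' `SI = 1 - d_int / d_ext`: the fraction of the external vessel diameter
#' occupied by wall rather than lumen. Normal cerebral arteries and
#' arterioles sit around 0.2-0.3; wall thickening (fibrosis) drives SI up.
#'
#' @param d_int,d_ext internal (lumen) and external diameters, um. Vectorised.
#' @return numeric SI in (0, 1).
#' @export
sclerotic_index <- function(d_int, d_ext) {
  if (any(d_int <= 0) || any(d_ext <= 0)) {
    stop("diameters must be positive")
  }
  if (any(d_int >= d_ext)) {
    stop("internal diameter must be smaller than external diameter")
  }
  1 - d_int / d_ext
}

#' Severity band of a sclerotic index
#'
#' `<= 0.3` normal, `(0.3, 0.5]` mild-to-moderate small vessel disease,
#' `> 0.5` severe. The published band edges overlap at 0.3 and 0.5; this
#' implementation assigns the boundary value to the lower band.
#'
#' @param si numeric vector of SI values in (0, 1).
#' @return character vector in `c("normal", "mild_moderate", "severe")`.
#' @export
svd_band <- function(si) {
  if (any(si <= 0 | si >= 1)) stop("SI must lie in (0, 1)")
  out <- ifelse(si <= 0.3, "normal",
                ifelse(si <= 0.5, "mild_moderate", "severe"))
  out
}

#' Specification of a synthetic vessel cross-section
#'
#' An annular wall between two confocal ellipses sharing centre, orientation
#' and axis ratio, so that along every ray through the centre the
#' internal:external ratio — and hence the SI — is exactly `d_int / d_ext`
#' regardless of orientation.
#'
#' @param d_int,d_ext lumen and external diameters along the major axis, um.
#' @param eccentricity ellipse eccentricity in \[0, 1); 0 is circular.
#' @param rotation major-axis orientation, degrees.
#' @param pixel_size um/pixel of the rendered raster.
#' @param seed integer seed for the rendering noise.
#' @return object of class `vessel_scene_spec` with `true_si`.
#' @export
vessel_scene_spec <- function(d_int, d_ext, eccentricity = 0, rotation = 0,
                              pixel_size = 1, seed = 1L) {
  stopifnot(pixel_size > 0, eccentricity >= 0, eccentricity < 1)
  if (d_int <= 0 || d_ext <= 0 || d_int >= d_ext) {
    stop("need 0 < d_int < d_ext")
  }
  structure(
    list(d_int = d_int, d_ext = d_ext, eccentricity = eccentricity,
         rotation = rotation, pixel_size = pixel_size, seed = as.integer(seed),
         true_si = 1 - d_int / d_ext),
    class = "vessel_scene_spec"
  )
}

#' Render a synthetic H&E-like vessel cross-section
#'
#' @param spec a [vessel_scene_spec()].
#' @return list with `image` (a `vessel_image`: grey matrix in \[0,1\], dark
#'   wall on light background, plus `pixel_size`) and `true_si`.
#' @export
make_vessel_image <- function(spec) {
  stopifnot(inherits(spec, "vessel_scene_spec"))
  withr::with_seed(spec$seed, {
    ps <- spec$pixel_size
    a_ext <- spec$d_ext / 2
    b_ext <- a_ext * sqrt(1 - spec$eccentricity^2)
    side <- ceiling(spec$d_ext / ps * 1.5)
    side <- max(side, 24L)
    cy <- side / 2 + stats::runif(1, -0.5, 0.5)
    cx <- side / 2 + stats::runif(1, -0.5, 0.5)
    th <- spec$rotation * pi / 180
    ys <- (seq_len(side) - cy) * ps
    xs <- (seq_len(side) - cx) * ps
    Y <- matrix(ys, side, side)
    X <- matrix(xs, side, side, byrow = TRUE)
    U <- cos(th) * X + sin(th) * Y
    V <- -sin(th) * X + cos(th) * Y
    q <- (U / a_ext)^2 + (V / b_ext)^2   # <=1 inside external ellipse
    ratio2 <- (spec$d_int / spec$d_ext)^2
    wall <- q <= 1 & q > ratio2
    img <- matrix(0.92, side, side) + stats::rnorm(side^2, 0, 0.015)
    img[wall] <- 0.45 + stats::rnorm(sum(wall), 0, 0.03)
    img <- pmin(pmax(img, 0), 1)
    image <- structure(list(image = img, pixel_size = ps),
                       class = "vessel_image")
    list(image = image, true_si = spec$true_si, wall_mask = wall)
  })
}

# diameters along one orientation through (cy, cx), in pixels
.caliper_profile <- function(wall, cy, cx, theta, step = 0.25) {
  h <- nrow(wall)
  w <- ncol(wall)
  tmax <- sqrt(h^2 + w^2)
  t <- seq(-tmax, tmax, by = step)
  rr <- round(cy + t * sin(theta))
  cc <- round(cx + t * cos(theta))
  ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
  prof <- logical(length(t))
  prof[ok] <- wall[(cc[ok] - 1L) * h + rr[ok]]
  hit <- which(prof)
  if (length(hit) < 2L) {
    return(NULL)
  }
  d_ext_px <- (t[max(hit)] - t[min(hit)]) + 1  # + pixel extent
  # lumen = gap in the wall profile containing the centre
  centre_i <- which.min(abs(t))
  if (prof[centre_i]) {
    return(NULL)  # centre inside wall: not an annulus along this ray
  }
  lo <- centre_i
  while (lo > 1L && !prof[lo - 1L]) lo <- lo - 1L
  hi <- centre_i
  while (hi < length(prof) && !prof[hi + 1L]) hi <- hi + 1L
  if (lo == 1L || hi == length(prof)) {
    return(NULL)  # open gap: wall missing on one side
  }
  d_int_px <- (t[hi] - t[lo]) + 1
  c(d_int_px = d_int_px, d_ext_px = d_ext_px)
}

#' Measure a single vessel cross-section
#'
#' Thresholds the dark wall, then takes internal and external caliper
#' diameters along three orientations 60 degrees apart through the wall
#' centroid. Each orientation yields one SI; the vessel SI is their mean.
#' Vessels whose mean external diameter is 50 um or less are rejected as
#' ineligible for small-vessel-disease scoring.
#'
#' @param image a `vessel_image` (grey matrix in \[0,1\] + `pixel_size`), or
#'   the list returned by [make_vessel_image()].
#' @param wall_threshold grey level below which a pixel is wall.
#' @param angles the three measurement orientations, degrees.
#' @return object of class `vessel_measurement`: data.frame `measurements`
#'   (3 rows: angle, d_int, d_ext, si in um), `si` (mean of the three),
#'   `d_int`, `d_ext` (mean diameters, um).
#' @export
measure_vessel <- function(image, wall_threshold = 0.7,
                           angles = c(0, 60, 120)) {
  if (!inherits(image, "vessel_image") && !is.null(image$image) &&
      inherits(image$image, "vessel_image")) {
    image <- image$image
  }
  stopifnot(inherits(image, "vessel_image"), length(angles) == 3L)
  img <- image$image
  ps <- image$pixel_size
  wall <- img < wall_threshold
  if (!any(wall)) {
    stop("no annulus detected: no wall pixels below threshold")
  }
  wi <- which(wall)
  cy <- mean(((wi - 1L) %% nrow(img)) + 1L)
  cx <- mean(((wi - 1L) %/% nrow(img)) + 1L)
  rows <- lapply(angles, function(a) {
    p <- .caliper_profile(wall, cy, cx, a * pi / 180)
    if (is.null(p)) {
      stop("no annulus detected along orientation ", a,
           " degrees (no closed wall around a lumen)")
    }
    data.frame(angle = a,
               d_int = p[["d_int_px"]] * ps,
               d_ext = p[["d_ext_px"]] * ps)
  })
  m <- do.call(rbind, rows)
  m$si <- sclerotic_index(m$d_int, m$d_ext)
  d_ext_mean <- mean(m$d_ext)
  if (d_ext_mean <= 50) {
    stop("vessel ineligible: external diameter ", round(d_ext_mean, 1),
         " um is not > 50 um")
  }
  structure(
    list(measurements = m, si = mean(m$si),
         d_int = mean(m$d_int), d_ext = d_ext_mean),
    class = "vessel_measurement"
  )
}

#' Aggregate vessel SIs into regional means and a hemispheric total
#'
#' Eight vessels are measured per sampled white-matter block. The frontal
#' value pools the prefrontal and midfrontal blocks (16 vessels); temporal,
#' parietal and occipital each use their own 8; the total is the mean of the
#' four regional means.
#'
#' @param si_table data.frame with columns `block` (one of `prefrontal`,
#'   `midfrontal`, `temporal`, `parietal`, `occipital`) and `si`.
#' @param n_per_block required vessel count per block.
#' @return list with `regional` (named numeric) and `total`.
#' @export
aggregate_si <- function(si_table, n_per_block = 8L) {
  stopifnot(is.data.frame(si_table), all(c("block", "si") %in% names(si_table)))
  blocks <- c("prefrontal", "midfrontal", "temporal", "parietal", "occipital")
  missing_b <- setdiff(blocks, unique(si_table$block))
  if (length(missing_b)) {
    stop("missing white-matter blocks: ", paste(missing_b, collapse = ", "))
  }
  cnt <- table(factor(si_table$block, levels = blocks))
  if (any(cnt != n_per_block)) {
    bad <- names(cnt)[cnt != n_per_block]
    stop("expected ", n_per_block, " vessels per block; wrong count in: ",
         paste(bad, collapse = ", "))
  }
  frontal <- mean(si_table$si[si_table$block %in% c("prefrontal", "midfrontal")])
  regional <- c(
    frontal = frontal,
    temporal = mean(si_table$si[si_table$block == "temporal"]),
    parietal = mean(si_table$si[si_table$block == "parietal"]),
    occipital = mean(si_table$si[si_table$block == "occipital"])
  )
  list(regional = regional, total = mean(regional))
}
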
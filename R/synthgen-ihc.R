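#' Specification of a synthetic IHC montage scene
#'
#' Describes a 3x3-tile DAB-stained cortical field: how many immunopositive
#' structures of which morphological kinds to paint, at what acquisition
#' geometry. The default geometry (512 px tiles at 0.85 um/px) makes the
#' 3x3 montage cover 1.70 mm^2 of tissue. `app_speck` objects emulate
#' punctate physiological APP staining: they are painted inside the marker's
#' RGB box like real signal but are guaranteed an area strictly below
#' 100 um^2 and never touch (8-connectivity) any other painted structure, so
#' the amyloid size filter can remove them exactly.
#'
#' @param tile_px pixels per (square) tile side.
#' @param pixel_size um/pixel.
#' @param n_structures number of pathological structures (tangles, threads,
#'   plaques) to paint; ignored when `target_fraction` is given.
#' @param structure_kinds subset of `c("tangle","thread","plaque","app_speck")`.
#' @param target_fraction intended pathological (speck-excluded) positive-area
#'   fraction in \[0, 1\], or `NA` to paint exactly `n_structures` objects.
#'   Fractions above 0.35 are rejected as unreachable without merging the
#'   scene into one blob.
#' @param n_specks number of APP-like sub-100 um^2 confounders; defaults to
#'   `max(2, n_structures %/% 5)` when `"app_speck"` is in `structure_kinds`,
#'   else 0.
#' @param marker `"AT8"` or `"4G8"`: which RGB box the positive paint is
#'   sampled from.
#' @param seed integer seed; generation is bit-reproducible given the spec.
#' @return object of class `ihc_scene_spec`.
#' @export
ihc_scene_spec <- function(tile_px = 512L, pixel_size = 0.85,
                           n_structures = 30L,
                           structure_kinds = c("tangle", "thread", "plaque"),
                           target_fraction = NA_real_,
                           n_specks = NULL,
                           marker = c("AT8", "4G8"),
                           seed = 1L) {
  marker <- match.arg(marker)
  stopifnot(tile_px > 0, pixel_size > 0, n_structures >= 0)
  kinds <- match.arg(structure_kinds,
                     c("tangle", "thread", "plaque", "app_speck"),
                     several.ok = TRUE)
  if (!is.na(target_fraction) &&
      (target_fraction < 0 || target_fraction > 1)) {
    stop("target_fraction must lie in [0, 1]")
  }
  if (is.null(n_specks)) {
    n_specks <- if ("app_speck" %in% kinds) max(2L, n_structures %/% 5L) else 0L
  }
  structure(
    list(
      tile_px = as.integer(tile_px), pixel_size = pixel_size,
      n_structures = as.integer(n_structures),
      structure_kinds = setdiff(kinds, "app_speck"),
      n_specks = as.integer(n_specks),
      target_fraction = target_fraction,
      marker = marker, seed = as.integer(seed)
    ),
    class = "ihc_scene_spec"
  )
}

# paint colour sampled uniformly from the strict interior of the marker box
.sample_inbox <- function(n, box) {
  cbind(
    sample((box$r_range[1] + 1L):(box$r_range[2] - 1L), n, replace = TRUE),
    sample((box$g_range[1] + 1L):(box$g_range[2] - 1L), n, replace = TRUE),
    sample((box$b_range[1] + 1L):(box$b_range[2] - 1L), n, replace = TRUE)
  )
}

.inbox <- function(rgbm, box) {
  rgbm[, 1] >= box$r_range[1] & rgbm[, 1] <= box$r_range[2] &
    rgbm[, 2] >= box$g_range[1] & rgbm[, 2] <= box$g_range[2] &
    rgbm[, 3] >= box$b_range[1] & rgbm[, 3] <= box$b_range[2]
}

# pale haematoxylin-like counterstain; red channel held above both marker
# boxes so background can never classify positive, then verified anyway
.sample_background <- function(n, box) {
  cols <- cbind(
    sample(200:235, n, replace = TRUE),
    sample(185:225, n, replace = TRUE),
    sample(205:245, n, replace = TRUE)
  )
  bad <- .inbox(cols, box)
  while (any(bad)) {
    cols[bad, 1] <- sample(200:235, sum(bad), replace = TRUE)
    bad <- .inbox(cols, box)
  }
  cols
}

# ---- structure rasterisers: return linear pixel indices on an h x w canvas

# uniform coordinate with a clear failure when the canvas cannot hold the
# structure at this pixel scale
.place_coord <- function(lo, hi, what) {
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi) {
    stop("field too small to place a ", what, " at this pixel scale")
  }
  stats::runif(1, lo, hi)
}

.paint_tangle <- function(h, w, ps) {
  # flame-shaped soma: union of 2-3 offset small discs, ~5-10 um across
  cy <- .place_coord(6 / ps, h - 6 / ps, "tangle")
  cx <- .place_coord(6 / ps, w - 6 / ps, "tangle")
  r <- stats::runif(1, 2.5, 5) / ps
  idx <- disc_indices(h, w, cy, cx, r)
  for (k in seq_len(sample(1:2, 1))) {
    ang <- stats::runif(1, 0, 2 * pi)
    idx <- c(idx, disc_indices(h, w,
                               cy + 0.9 * r * sin(ang), cx + 0.9 * r * cos(ang),
                               r * stats::runif(1, 0.5, 0.8)))
  }
  unique(idx)
}

.paint_thread <- function(h, w, ps) {
  # neuropil thread: 1-px-wide meandering segment, 25-80 um long
  len_px <- max(4L, round(stats::runif(1, 25, 80) / ps))
  y <- .place_coord(3, h - 3, "thread")
  x <- .place_coord(3, w - 3, "thread")
  ang <- stats::runif(1, 0, 2 * pi)
  ys <- numeric(len_px)
  xs <- numeric(len_px)
  for (i in seq_len(len_px)) {
    ys[i] <- y
    xs[i] <- x
    ang <- ang + stats::rnorm(1, 0, 0.25)
    y <- min(max(y + sin(ang), 1), h)
    x <- min(max(x + cos(ang), 1), w)
  }
  ri <- round(ys)
  ci <- round(xs)
  unique((ci - 1L) * h + ri)
}

.paint_plaque <- function(h, w, ps) {
  # amyloid plaque: larger disc with a ragged rim
  r <- stats::runif(1, 9, 22) / ps
  cy <- .place_coord(r + 2, h - r - 2, "plaque")
  cx <- .place_coord(r + 2, w - r - 2, "plaque")
  idx <- disc_indices(h, w, cy, cx, r)
  for (k in seq_len(4L)) {
    ang <- stats::runif(1, 0, 2 * pi)
    idx <- c(idx, disc_indices(h, w,
                               cy + r * sin(ang), cx + r * cos(ang),
                               r * stats::runif(1, 0.2, 0.45)))
  }
  unique(idx)
}

.paint_speck <- function(h, w, ps, max_area_um2 = 100) {
  # punctate APP: disc trimmed so the painted area is strictly < 100 um^2
  if (ps^2 >= max_area_um2) {
    stop("pixel area ", ps^2, " um^2: cannot paint a speck below ",
         max_area_um2, " um^2 at this scale")
  }
  a <- stats::runif(1, min(25, max_area_um2 / 3), 0.85 * max_area_um2)
  r <- sqrt(a / pi) / ps
  cy <- .place_coord(r + 3, h - r - 3, "speck")
  cx <- .place_coord(r + 3, w - r - 3, "speck")
  idx <- unique(disc_indices(h, w, cy, cx, max(r, 0.6)))
  max_px <- ceiling(max_area_um2 / ps^2) - 1L
  if (length(idx) > max_px) idx <- idx[seq_len(max_px)]
  idx
}

.paint_structure <- function(kind, h, w, ps) {
  switch(kind,
    tangle = .paint_tangle(h, w, ps),
    thread = .paint_thread(h, w, ps),
    plaque = .paint_plaque(h, w, ps),
    stop("unknown structure kind: ", kind)
  )
}

# 8-neighbourhood dilation of a linear index set (for separation checks)
.dilate_idx <- function(idx, h, w) {
  r <- ((idx - 1L) %% h) + 1L
  c <- ((idx - 1L) %/% h) + 1L
  out <- integer(0)
  for (dr in -1:1) {
    for (dc in -1:1) {
      rr <- r + dr
      cc <- c + dc
      ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
      out <- c(out, (cc[ok] - 1L) * h + rr[ok])
    }
  }
  unique(out)
}

#' Generate a ground-truthed synthetic IHC montage
#'
#' Paints DAB-brown immunopositive structures on a haematoxylin-like
#' background such that the RGB classifier and the generator are exact duals:
#' every painted pixel lies strictly inside the marker's RGB box and every
#' background pixel strictly outside it. APP-like specks are kept strictly
#' below 100 um^2 and 8-disconnected from all other paint.
#'
#' @param spec an [ihc_scene_spec()].
#' @return list with
#'   \describe{
#'     \item{image}{a [montage_image()] (3x3 tiles).}
#'     \item{truth_mask}{integer matrix: 0 background, 1 pathological
#'       structure, 2 APP speck.}
#'     \item{true_fraction}{painted positive-pixel fraction (all paint).}
#'     \item{true_fraction_pathological}{fraction excluding APP specks — what
#'       size-filtered quantification should recover.}
#'   }
#' @export
make_ihc_montage <- function(spec) {
  stopifnot(inherits(spec, "ihc_scene_spec"))
  withr::with_seed(spec$seed, .make_ihc_montage_impl(spec))
}

.make_ihc_montage_impl <- function(spec) {
  ps <- spec$pixel_size
  h <- w <- 3L * spec$tile_px
  box <- if (spec$marker == "AT8") at8_threshold() else g48_threshold()
  truth <- matrix(0L, h, w)

  target <- spec$target_fraction
  if (!is.na(target) && target > 0.35) {
    stop("target_fraction ", target, " unreachable: painting beyond 0.35 of a ",
         h, "x", w, " px field would merge the scene into confluent paint")
  }
  kinds <- spec$structure_kinds
  if (length(kinds) == 0L && (is.na(target) || target > 0)) {
    kinds <- "plaque"
  }
  total_px <- h * w

  if (!is.na(target)) {
    painted <- 0L
    guard <- 0L
    while (painted / total_px < target) {
      guard <- guard + 1L
      if (guard > 20000L) {
        stop("target_fraction ", target, " not reached after 20000 structures",
             " at tile size ", spec$tile_px, " px")
      }
      idx <- .paint_structure(sample(kinds, 1L), h, w, ps)
      truth[idx] <- 1L
      painted <- sum(truth == 1L)
    }
  } else if (spec$n_structures > 0L) {
    for (i in seq_len(spec$n_structures)) {
      idx <- .paint_structure(kinds[1L + (i - 1L) %% length(kinds)], h, w, ps)
      truth[idx] <- 1L
    }
  }

  # specks last, kept 8-disconnected from everything already painted
  if (spec$n_specks > 0L) {
    placed <- 0L
    guard <- 0L
    while (placed < spec$n_specks) {
      guard <- guard + 1L
      if (guard > 500L * spec$n_specks) {
        stop("could not place ", spec$n_specks,
             " disjoint APP specks on this field")
      }
      idx <- .paint_speck(h, w, ps)
      halo <- .dilate_idx(idx, h, w)
      if (all(truth[halo] == 0L)) {
        truth[idx] <- 2L
        placed <- placed + 1L
      }
    }
  }

  rgb <- array(0L, c(h, w, 3L))
  bg <- which(truth == 0L)
  fg <- which(truth > 0L)
  bgc <- .sample_background(length(bg), box)
  for (ch in 1:3) {
    plane <- matrix(0L, h, w)
    plane[bg] <- bgc[, ch]
    rgb[, , ch] <- plane
  }
  if (length(fg)) {
    fgc <- .sample_inbox(length(fg), box)
    for (ch in 1:3) {
      plane <- rgb[, , ch]
      plane[fg] <- fgc[, ch]
      rgb[, , ch] <- plane
    }
  }

  list(
    image = montage_image(rgb, pixel_size = ps),
    truth_mask = truth,
    true_fraction = sum(truth > 0L) / total_px,
    true_fraction_pathological = sum(truth == 1L) / total_px
  )
}
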
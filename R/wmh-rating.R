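#' Specification of a synthetic white-matter lesion mask
#'
#' Circular lesions of requested diameters placed without contact inside a
#' square field; selected pairs can be joined by a thin "connecting bridge"
#' (well under 3 mm wide) to emulate early-confluent lesion complexes.
#'
#' @param field_mm side length of the square field, mm.
#' @param lesion_diameters numeric vector of lesion diameters, mm (possibly
#'   empty).
#' @param bridges list of length-2 integer vectors: indices of lesion pairs
#'   to connect.
#' @param px_per_mm raster resolution (pixels per mm).
#' @param seed integer seed.
#' @return object of class `lesion_scene_spec`.
#' @export
lesion_scene_spec <- function(field_mm = 100, lesion_diameters = numeric(0),
                              bridges = list(), px_per_mm = 4, seed = 1L) {
  stopifnot(field_mm > 0, px_per_mm > 0)
  if (length(lesion_diameters) && any(lesion_diameters <= 0)) {
    stop("all lesion diameters must be > 0 mm")
  }
  if (length(lesion_diameters) &&
      any(lesion_diameters > field_mm - 4)) {
    stop("lesion does not fit inside the field (need diameter <= field_mm - 4)")
  }
  n <- length(lesion_diameters)
  for (b in bridges) {
    if (length(b) != 2L || any(b < 1) || any(b > n) || b[1] == b[2]) {
      stop("each bridge must name two distinct lesion indices in 1..", n)
    }
  }
  structure(
    list(field_mm = field_mm, lesion_diameters = as.numeric(lesion_diameters),
         bridges = bridges, px_per_mm = px_per_mm, seed = as.integer(seed)),
    class = "lesion_scene_spec"
  )
}

#' Generate a binary lesion mask with known component geometry
#'
#' Non-bridged lesions are kept at least 2 mm apart (so they stay separate
#' 8-connected components); bridged partners are placed 4-6 mm apart and
#' joined by a 0.5 mm-wide line, forming a single component with a thin
#' connection. Overlap that was not requested as a bridge is refused.
#'
#' @param spec a [lesion_scene_spec()].
#' @return object of class `lesion_mask`: list with `mask` (logical matrix),
#'   `mm_per_px`, `centers_mm`, `diameters_mm`, `bridges`.
#' @export
make_lesion_mask <- function(spec) {
  stopifnot(inherits(spec, "lesion_scene_spec"))
  withr::with_seed(spec$seed, .make_lesion_mask_impl(spec))
}

.make_lesion_mask_impl <- function(spec) {
  ppm <- spec$px_per_mm
  side <- max(2L, round(spec$field_mm * ppm))
  n <- length(spec$lesion_diameters)
  mask <- matrix(FALSE, side, side)
  out <- structure(
    list(mask = mask, mm_per_px = 1 / ppm,
         centers_mm = matrix(numeric(0), 0, 2),
         diameters_mm = spec$lesion_diameters, bridges = spec$bridges),
    class = "lesion_mask"
  )
  if (n == 0L) {
    return(out)
  }
  r_mm <- spec$lesion_diameters / 2
  bridged_with <- function(i, j) {
    any(vapply(spec$bridges, function(b) all(sort(b) == sort(c(i, j))),
               logical(1)))
  }
  # anchor of each lesion: first bridge partner with a smaller index, if any
  anchor <- rep(NA_integer_, n)
  for (b in spec$bridges) {
    hi <- max(b)
    lo <- min(b)
    if (is.na(anchor[hi])) anchor[hi] <- lo
  }
  centers <- matrix(NA_real_, n, 2)  # (y, x) in mm
  min_gap <- 2
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(4000L)) {
      if (!is.na(anchor[i]) && !is.na(centers[anchor[i], 1])) {
        gap <- stats::runif(1, 4, 6)
        ang <- stats::runif(1, 0, 2 * pi)
        d <- r_mm[i] + r_mm[anchor[i]] + gap
        cand <- centers[anchor[i], ] + d * c(sin(ang), cos(ang))
      } else {
        cand <- stats::runif(2, r_mm[i] + 1, spec$field_mm - r_mm[i] - 1)
      }
      if (any(cand < r_mm[i] + 1) || any(cand > spec$field_mm - r_mm[i] - 1)) next
      ok <- TRUE
      for (j in seq_len(i - 1L)) {
        dd <- sqrt(sum((cand - centers[j, ])^2))
        need <- if (bridged_with(i, j)) r_mm[i] + r_mm[j] + 3 else
          r_mm[i] + r_mm[j] + min_gap
        if (dd < need) {
          ok <- FALSE
          break
        }
      }
      if (ok) {
        centers[i, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place lesion ", i, " (", spec$lesion_diameters[i],
           " mm) without unrequested overlap; field too crowded")
    }
  }
  for (i in seq_len(n)) {
    mask[disc_indices(side, side, centers[i, 1] * ppm, centers[i, 2] * ppm,
                      r_mm[i] * ppm)] <- TRUE
  }
  # bridges: 0.5 mm-wide line between centres
  for (b in spec$bridges) {
    p1 <- centers[b[1], ] * ppm
    p2 <- centers[b[2], ] * ppm
    len <- sqrt(sum((p2 - p1)^2))
    ts <- seq(0, 1, length.out = max(2L, ceiling(len * 4)))
    w_px <- max(0.6, 0.25 * ppm)  # 0.5 mm diameter
    for (t in ts) {
      p <- p1 + t * (p2 - p1)
      mask[disc_indices(side, side, p[1], p[2], w_px)] <- TRUE
    }
  }
  out$mask <- mask
  out$centers_mm <- centers
  out
}

#' Enumerate lesions in a binary mask
#'
#' Labels 8-connected components, computes each component's maximum caliper
#' (Feret) diameter, and detects bridged lesion complexes by erosion-split: a
#' component is "bridged" when eroding it by half the bridge width
#' (connections locally narrower than `bridge_width_mm` disappear) splits it
#' into two or more lobes whose centroids are at least `lobe_min_sep_mm`
#' apart. Lobe diameters are reported with the erosion loss added back.
#'
#' Reported `diameter_mm` is `(Feret in pixel centres + 1) * mm_per_px`, i.e.
#' including the extent of the boundary pixels, which makes the measure
#' resolution-stable; `feret_px` keeps the raw centre-to-centre value.
#'
#' @param mask logical matrix, or a `lesion_mask`.
#' @param mm_per_px physical pixel size, mm (taken from a `lesion_mask`).
#' @param bridge_width_mm connections locally thinner than this are bridges.
#' @param lobe_min_sep_mm minimum lobe centroid separation for a split to
#'   count as a bridged complex.
#' @return object of class `lesion_census`: data.frame with one row per
#'   component (`component`, `n_px`, `feret_px`, `diameter_mm`, `n_lobes`,
#'   `bridged`) and a `lobe_diameters_mm` list attribute.
#' @export
census_lesions <- function(mask, mm_per_px = NULL, bridge_width_mm = 3,
                           lobe_min_sep_mm = 10) {
  if (inherits(mask, "lesion_mask")) {
    mm_per_px <- mask$mm_per_px
    mask <- mask$mask
  }
  stopifnot(is.matrix(mask), is.numeric(mm_per_px), mm_per_px > 0)
  mode(mask) <- "logical"
  lab <- label_components(mask)
  k <- max(lab)
  empty <- data.frame(component = integer(0), n_px = integer(0),
                      feret_px = numeric(0), diameter_mm = numeric(0),
                      n_lobes = integer(0), bridged = logical(0))
  if (k == 0L) {
    return(structure(empty, lobe_diameters_mm = list(),
                     class = c("lesion_census", "data.frame")))
  }
  h <- nrow(mask)
  res <- vector("list", k)
  lobes <- vector("list", k)
  r_er <- (bridge_width_mm / 2) / mm_per_px
  for (ci in seq_len(k)) {
    idx <- which(lab == ci)
    rows <- ((idx - 1L) %% h) + 1L
    cols <- ((idx - 1L) %/% h) + 1L
    fer <- feret_diameter_px(rows, cols)
    # erosion-split on the component's padded bounding box
    pad <- ceiling(r_er) + 1L
    r0 <- min(rows)
    c0 <- min(cols)
    sub <- matrix(FALSE, diff(range(rows)) + 1L + 2L * pad,
                  diff(range(cols)) + 1L + 2L * pad)
    sub[cbind(rows - r0 + 1L + pad, cols - c0 + 1L + pad)] <- TRUE
    er <- erode_disc(sub, r_er)
    n_lobes <- 0L
    bridged <- FALSE
    lobe_d <- numeric(0)
    if (any(er)) {
      elab <- label_components(er)
      sizes <- tabulate(elab[elab > 0L], nbins = max(elab))
      keep <- which(sizes >= 2L)
      n_lobes <- length(keep)
      if (n_lobes >= 2L) {
        cent <- matrix(NA_real_, n_lobes, 2)
        for (li in seq_along(keep)) {
          lidx <- which(elab == keep[li])
          lr <- ((lidx - 1L) %% nrow(er)) + 1L
          lc <- ((lidx - 1L) %/% nrow(er)) + 1L
          cent[li, ] <- c(mean(lr), mean(lc))
          lobe_d[li] <- (feret_diameter_px(lr, lc) + 1) * mm_per_px +
            bridge_width_mm
        }
        sep <- max(stats::dist(cent)) * mm_per_px
        bridged <- sep >= lobe_min_sep_mm
      }
    }
    res[[ci]] <- data.frame(component = ci, n_px = length(idx), feret_px = fer,
                            diameter_mm = (fer + 1) * mm_per_px,
                            n_lobes = n_lobes, bridged = bridged)
    lobes[[ci]] <- lobe_d
  }
  structure(do.call(rbind, res), lobe_diameters_mm = lobes,
            class = c("lesion_census", "data.frame"))
}

#' ARWMC score for one white-matter region
#'
#' Ordinal 0-3: 0 no lesions; 1 punctate (every component < 10 mm);
#' 2 early-confluent (a component reaching 10-20 mm, or a bridged complex of
#' 10-20 mm lobes, even though the complex as a whole spans more than 20 mm);
#' 3 confluent (a component, or any lobe of one, beyond 20 mm).
#'
#' @param census a `lesion_census` (from [census_lesions()]).
#' @param region optional region label carried into the result.
#' @return object of class `arwmc_score`: list with `region`, `score`.
#' @export
score_region <- function(census, region = NA_character_) {
  stopifnot(inherits(census, "lesion_census"))
  lobes <- attr(census, "lobe_diameters_mm")
  if (nrow(census) == 0L) {
    return(structure(list(region = region, score = 0L), class = "arwmc_score"))
  }
  comp_class <- vapply(seq_len(nrow(census)), function(i) {
    d <- census$diameter_mm[i]
    ld <- lobes[[i]]
    if (census$bridged[i] && length(ld) && any(ld > 20)) {
      3L
    } else if (census$bridged[i] && d > 20) {
      2L  # bridged complex of sub-20 mm lobes: early confluent
    } else if (d > 20) {
      3L
    } else if (d >= 10) {
      2L
    } else {
      1L
    }
  }, integer(1))
  structure(list(region = region, score = max(comp_class)),
            class = "arwmc_score")
}

#' Combine regional ARWMC scores into the reported set and total
#'
#' Parietal and occipital are folded into a single parieto-occipital score
#' (maximum of the two by default); the total is the mean of the frontal,
#' temporal and parieto-occipital scores.
#'
#' @param scores named numeric/integer vector or list with entries `frontal`,
#'   `temporal`, `parietal`, `occipital` (each 0-3).
#' @param parieto_occipital_rule `"max"` (default) or `"mean"`.
#' @return list with `regional` (frontal, temporal, parieto_occipital) and
#'   `total`.
#' @export
combine_scores <- function(scores, parieto_occipital_rule = c("max", "mean")) {
  rule <- match.arg(parieto_occipital_rule)
  scores <- unlist(scores)
  need <- c("frontal", "temporal", "parietal", "occipital")
  absent <- setdiff(need, names(scores))
  if (length(absent)) {
    stop("missing regional scores: ", paste(absent, collapse = ", "))
  }
  if (any(is.na(scores[need])) || any(scores[need] < 0 | scores[need] > 3)) {
    stop("scores must be 0-3 and non-missing")
  }
  po <- if (rule == "max") max(scores["parietal"], scores["occipital"]) else
    mean(c(scores["parietal"], scores["occipital"]))
  regional <- c(frontal = unname(scores["frontal"]),
                temporal = unname(scores["temporal"]),
                parieto_occipital = unname(po))
  list(regional = regional, total = mean(regional))
}
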
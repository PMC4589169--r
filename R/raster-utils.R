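#' Label connected components of a binary mask (8-connectivity)
#'
#' Blob quantification in this package uses 8-connectivity throughout:
#' diagonally touching pixels belong to the same immunoreactive signal or
#' lesion. Labelling is done on the sparse foreground pixel set (edge list +
#' graph components), so cost scales with the stained area, not the raster.
#'
#' @param mask logical matrix (`TRUE` = foreground).
#' @return integer matrix of the same dimension; 0 for background, components
#'   labelled 1..k in no particular order.
#' @export
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  mode(mask) <- "logical"
  h <- nrow(mask)
  w <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, h, w)
  if (length(idx) == 0L) {
    return(lab)
  }
  inmask <- logical(h * w)
  inmask[idx] <- TRUE
  row <- ((idx - 1L) %% h) + 1L
  col <- ((idx - 1L) %/% h) + 1L
  # each undirected edge collected once: look at 4 "previous" neighbours
  offs <- list(c(0L, -1L), c(-1L, 0L), c(-1L, -1L), c(1L, -1L))
  from <- integer(0)
  to <- integer(0)
  for (o in offs) {
    nr <- row + o[1L]
    nc <- col + o[2L]
    ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
    nidx <- (nc - 1L) * h + nr
    ok[ok] <- inmask[nidx[ok]]
    if (any(ok)) {
      from <- c(from, idx[ok])
      to <- c(to, nidx[ok])
    }
  }
  # compact foreground indices to 1..n vertex ids
  vid <- integer(h * w)
  vid[idx] <- seq_along(idx)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(from)) {
    g <- igraph::add_edges(g, rbind(vid[from], vid[to]))
  }
  memb <- igraph::components(g)$membership
  lab[idx] <- as.integer(memb)
  lab
}

#' Maximum caliper (Feret) diameter of a pixel set
#'
#' Returns the largest centre-to-centre distance between any two foreground
#' pixels, in pixel units. Computed on the convex hull so it is exact and
#' cheap even for large blobs. A single pixel has Feret 0.
#'
#' @param rows,cols integer pixel coordinates of one component.
#' @return numeric scalar, pixels.
#' @export
feret_diameter_px <- function(rows, cols) {
  n <- length(rows)
  stopifnot(n == length(cols), n >= 1L)
  if (n == 1L) {
    return(0)
  }
  pts <- cbind(as.numeric(rows), as.numeric(cols))
  if (n > 3L) {
    hull <- grDevices::chull(pts)
    pts <- pts[hull, , drop = FALSE]
  }
  d2 <- stats::dist(pts)
  max(d2)
}

#' Binary erosion by a disc structuring element
#'
#' Pixel survives iff every pixel of the disc of radius `r_px` around it is
#' foreground (pixels outside the image count as background). Implemented as
#' an intersection of shifted masks over the disc offsets; adequate for the
#' small radii used in lesion bridge detection.
#'
#' @param mask logical matrix.
#' @param r_px disc radius in pixels (>= 0; 0 returns the mask unchanged).
#' @return logical matrix.
#' @export
erode_disc <- function(mask, r_px) {
  stopifnot(is.matrix(mask), r_px >= 0)
  mode(mask) <- "logical"
  if (r_px == 0) {
    return(mask)
  }
  r <- ceiling(r_px)
  h <- nrow(mask)
  w <- ncol(mask)
  out <- mask
  for (dr in -r:r) {
    for (dc in -r:r) {
      if (dr * dr + dc * dc > r_px * r_px) next
      if (dr == 0L && dc == 0L) next
      shifted <- matrix(FALSE, h, w)
      src_r <- max(1L, 1L + dr):min(h, h + dr)
      src_c <- max(1L, 1L + dc):min(w, w + dc)
      shifted[src_r - dr, src_c - dc] <- mask[src_r, src_c]
      out <- out & shifted
      if (!any(out)) {
        return(out)
      }
    }
  }
  out
}

#' Rasterise a disc into linear indices of a matrix
#'
#' @param h,w canvas dimensions
#' @param cy,cx centre (rows, cols; may be fractional)
#' @param r radius in pixels
#' @return integer vector of linear (column-major) indices, clipped to canvas
#' @keywords internal
disc_indices <- function(h, w, cy, cx, r) {
  r0 <- ceiling(r)
  rows <- max(1L, floor(cy - r0)):min(h, ceiling(cy + r0))
  cols <- max(1L, floor(cx - r0)):min(w, ceiling(cx + r0))
  if (length(rows) == 0L || length(cols) == 0L) return(integer(0))
  gr <- rep(rows, times = length(cols))
  gc <- rep(cols, each = length(rows))
  keep <- (gr - cy)^2 + (gc - cx)^2 <= r^2
  (gc[keep] - 1L) * h + gr[keep]
}
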
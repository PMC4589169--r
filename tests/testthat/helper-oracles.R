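# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# 8-connected component labelling by breadth-first flood fill
flood_fill_label <- function(mask) {
  h <- nrow(mask)
  w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[1]
      queue <- queue[-1]
      pr <- ((p - 1L) %% h) + 1L
      pc <- ((p - 1L) %/% h) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- pr + dr
        cc <- pc + dc
        if (rr < 1 || rr > h || cc < 1 || cc > w) next
        q <- (cc - 1L) * h + rr
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

# maximum pairwise pixel-centre distance, all pairs (no hull shortcut)
all_pairs_feret <- function(rows, cols) {
  if (length(rows) == 1L) return(0)
  best <- 0
  for (i in seq_along(rows)) {
    d <- sqrt((rows - rows[i])^2 + (cols - cols[i])^2)
    best <- max(best, max(d))
  }
  best
}

# Mann-Whitney U by explicit pair counting with half-credit for ties
all_pairs_u <- function(x, y) {
  u1 <- 0
  for (xi in x) u1 <- u1 + sum(xi > y) + 0.5 * sum(xi == y)
  min(u1, length(x) * length(y) - u1)
}

# closed-form partial correlation of x,y given z from a correlation matrix
closed_form_partial <- function(rxy, rxz, ryz) {
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

# ARWMC rule table applied to a measured census (independent re-statement)
rule_table_score <- function(census) {
  if (nrow(census) == 0L) return(0L)
  lobes <- attr(census, "lobe_diameters_mm")
  cls <- integer(nrow(census))
  for (i in seq_len(nrow(census))) {
    d <- census$diameter_mm[i]
    if (census$bridged[i]) {
      ld <- lobes[[i]]
      cls[i] <- if (any(ld > 20)) 3L else if (d > 20) 2L
        else if (d >= 10) 2L else 1L
    } else {
      cls[i] <- if (d > 20) 3L else if (d >= 10) 2L else 1L
    }
  }
  max(cls)
}

# random sparse logical mask for property tests
random_mask <- function(h, w, p = 0.2) {
  matrix(stats::runif(h * w) < p, h, w)
}

# hand pooled-t from summary stats (plain transcription of the formula)
hand_pooled_t <- function(m1, s1, n1, m2, s2, n2) {
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
}
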
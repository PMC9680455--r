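# Independent oracles used by the unit and acceptance tests. These share no
# code with the package internals: connected regions are found by iterative
# vectorised label propagation, not by the package's C++ flood fill.

# shift a matrix by (dr, dc), padding with `fill`
shift_mat <- function(m, dr, dc, fill) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  rs <- max(1, 1 + dr):min(H, H + dr)
  cs <- max(1, 1 + dc):min(W, W + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

offsets8 <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                  c(0, 1), c(1, -1), c(1, 0), c(1, 1))

# label connected regions of a logical mask (8-connectivity) by propagating
# the minimum index to a fixpoint
propagate_labels <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(seq_len(H * W), H, W)
  lab[!mask] <- NA
  repeat {
    new <- lab
    for (k in seq_len(nrow(offsets8))) {
      s <- shift_mat(lab, offsets8[k, 1], offsets8[k, 2], NA)
      upd <- !is.na(s) & !is.na(new) & s < new
      new[upd] <- s[upd]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  lab
}

# Reference find-maxima: same semantics as the package's find_maxima but
# built from first principles on label propagation. Returns a data frame
# with x, y, value sorted in raster order.
oracle_find_maxima <- function(img, tol) {
  img <- matrix(as.integer(round(img)), nrow(img), ncol(img))
  H <- nrow(img); W <- ncol(img)
  if (H * W <= 1) return(data.frame(x = integer(0), y = integer(0),
                                    value = integer(0)))
  nbr_max <- matrix(-Inf, H, W)
  nbr_min <- matrix(Inf, H, W)
  for (k in seq_len(nrow(offsets8))) {
    s <- shift_mat(img, offsets8[k, 1], offsets8[k, 2], NA)
    nbr_max <- pmax(nbr_max, s, na.rm = TRUE)
    nbr_min <- pmin(nbr_min, s, na.rm = TRUE)
  }
  res <- NULL
  for (v in sort(unique(as.vector(img)), decreasing = TRUE)) {
    plat <- propagate_labels(img == v)
    for (id in unique(plat[!is.na(plat)])) {
      members <- which(!is.na(plat) & plat == id)
      if (max(nbr_max[members]) > v) next   # adjacent higher pixel
      if (min(nbr_min[members]) >= v) next  # no strictly lower neighbour
      # flood region >= v - tol; reject if it contains a higher pixel
      region <- propagate_labels(img >= v - tol)
      comp_ids <- unique(region[members])
      in_comp <- !is.na(region) & region %in% comp_ids
      if (any(img[in_comp] > v)) next
      rows <- (members - 1L) %% H + 1L
      cols <- (members - 1L) %/% H + 1L
      res <- rbind(res, data.frame(x = as.integer(round(mean(cols))),
                                   y = as.integer(round(mean(rows))),
                                   value = v))
    }
  }
  if (is.null(res)) return(data.frame(x = integer(0), y = integer(0),
                                      value = integer(0)))
  res[order(res$y, res$x), , drop = FALSE]
}

expect_same_maxima <- function(img, tol) {
  got <- find_maxima(img, tol)
  want <- oracle_find_maxima(img, tol)
  expect_equal(nrow(got), nrow(want))
  if (nrow(got) > 0) {
    expect_equal(got$x, want$x)
    expect_equal(got$y, want$y)
    expect_equal(got$value, want$value)
  }
}

# standard beam parameter set used across tests: kL ~ 1 at the 8 mm gap
default_beam <- function(E = 1e4, L = 8e-3, r = 4e-4, rho = 1026,
                         kL = 1) {
  I <- pi * r^4 / 4
  P <- kL^2 * E * I / L^2
  beam_parameters(E = E, P = P, r = r, rho = rho, L = L)
}
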
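#' Maximum-intensity z-projection
#'
#' Per-channel, per-pixel maximum across all focal planes of a stack — the
#' standard way of collapsing a live/dead z-series before spot counting.
#'
#' @param stack A [z_stack()].
#' @return Named list of integer matrices, one projection per channel.
#' @export
z_project_max <- function(stack) {
  stopifnot(inherits(stack, "z_stack"))
  a <- stack$intensities
  d <- dim(a)
  if (any(d == 0)) stop("z_project_max: empty stack", call. = FALSE)
  out <- vector("list", d[2])
  names(out) <- stack$channels
  for (ch in seq_len(d[2])) {
    proj <- matrix(a[1, ch, , ], d[3], d[4])
    if (d[1] > 1) {
      for (p in 2:d[1]) proj <- pmax(proj, matrix(a[p, ch, , ], d[3], d[4]))
    }
    storage.mode(proj) <- "integer"
    out[[ch]] <- proj
  }
  out
}

#' ImageJ-style find-maxima spot detection
#'
#' Reimplements the prominence ("noise tolerance") semantics of the ImageJ
#' Find Maxima tool: a candidate local maximum — an 8-connected plateau of
#' equal value with no strictly higher neighbour and at least one strictly
#' lower one — is rejected if a path exists to a strictly higher pixel along
#' which the intensity never drops below `peak - noise_tolerance`. Accepted
#' plateaus are reported as their centroid rounded to the nearest pixel.
#' Edge maxima are not excluded, no smoothing or background subtraction is
#' applied, and ties are resolved by deterministic raster-scan order.
#'
#' @param image Integer matrix of intensities (raw stored scale; tolerance
#'   is applied on that scale, 8-bit by convention).
#' @param noise_tolerance Non-negative prominence threshold (default 20).
#' @return A `maxima_set`: data frame with columns `x` (col), `y` (row),
#'   `value`, ordered by raster scan; attribute `noise_tolerance`.
#' @export
find_maxima <- function(image, noise_tolerance = 20) {
  if (noise_tolerance < 0)
    stop("find_maxima: noise_tolerance must be >= 0", call. = FALSE)
  img <- round(image)
  storage.mode(img) <- "integer"
  H <- nrow(img); W <- ncol(img)
  empty <- data.frame(x = integer(0), y = integer(0), value = integer(0))
  if (H * W == 0 || (H == 1 && W == 1)) {
    return(structure(empty, noise_tolerance = noise_tolerance,
                     class = c("maxima_set", "data.frame")))
  }
  nbr <- neighbour_extrema_cpp(img)
  # plateau components of equal value
  plat <- label_equal_cpp(img)
  vals <- as.vector(img)
  labv <- as.vector(plat)
  # per-plateau aggregates
  peak <- tapply(vals, labv, function(v) v[1])
  max_nbr <- tapply(as.vector(nbr$max), labv, max)
  min_nbr <- tapply(as.vector(nbr$min), labv, min)
  ids <- as.integer(names(peak))
  is_cand <- (max_nbr <= peak) & (min_nbr < peak)
  cand_ids <- ids[is_cand]
  if (length(cand_ids) == 0) {
    return(structure(empty, noise_tolerance = noise_tolerance,
                     class = c("maxima_set", "data.frame")))
  }
  g_min <- min(vals); g_max <- max(vals)
  res_x <- integer(0); res_y <- integer(0); res_v <- integer(0)
  cand_px <- which(labv %in% cand_ids)
  idx_by_lab <- split(cand_px, labv[cand_px])
  for (id in cand_ids) {
    members <- idx_by_lab[[as.character(id)]]
    v <- vals[members[1]]
    floor_val <- v - noise_tolerance
    rejected <- if (floor_val <= g_min) {
      g_max > v  # whole image floodable: any higher pixel suppresses
    } else {
      reaches_higher_cpp(img, members - 1L, floor_val, v)
    }
    if (rejected) next
    rows <- ((members - 1L) %% H) + 1L
    cols <- ((members - 1L) %/% H) + 1L
    res_y <- c(res_y, as.integer(round(mean(rows))))
    res_x <- c(res_x, as.integer(round(mean(cols))))
    res_v <- c(res_v, v)
  }
  ord <- order(res_y, res_x)
  structure(data.frame(x = res_x[ord], y = res_y[ord], value = res_v[ord]),
            noise_tolerance = noise_tolerance,
            class = c("maxima_set", "data.frame"))
}

#' Count live and dead cells in a z-stack
#'
#' Max-projects each channel and counts find-maxima spots: green (Calcein)
#' maxima are live cells, red (EthD) maxima are dead cells. An optional
#' per-plane diagnostic count is available via `per_plane = TRUE`.
#'
#' @param stack A [z_stack()].
#' @param noise_tolerance Prominence threshold (default 20).
#' @param per_plane Also return per-plane spot counts per channel.
#' @return List with `live` and `dead` counts (and `per_plane` matrix when
#'   requested).
#' @export
count_live_dead <- function(stack, noise_tolerance = 20, per_plane = FALSE) {
  stopifnot(inherits(stack, "z_stack"))
  proj <- z_project_max(stack)
  live_ch <- stack$channel_roles$live
  dead_ch <- stack$channel_roles$dead
  res <- list(
    live = nrow(find_maxima(proj[[live_ch]], noise_tolerance)),
    dead = nrow(find_maxima(proj[[dead_ch]], noise_tolerance)))
  if (per_plane) {
    d <- dim(stack$intensities)
    pp <- matrix(0L, d[1], 2, dimnames = list(NULL, c("live", "dead")))
    for (p in seq_len(d[1])) {
      for (role in c("live", "dead")) {
        ch <- match(stack$channel_roles[[role]], stack$channels)
        m <- matrix(stack$intensities[p, ch, , ], d[3], d[4])
        pp[p, role] <- nrow(find_maxima(m, noise_tolerance))
      }
    }
    res$per_plane <- pp
  }
  res
}

#' Viability percentage
#'
#' `100 * live / (live + dead)`; `NA` sentinel when no cells were counted.
#'
#' @param live,dead Non-negative counts.
#' @return Percentage in `[0, 100]`, or `NA_real_`.
#' @export
viability_percent <- function(live, dead) {
  if (any(c(live, dead) < 0))
    stop("viability_percent: counts must be non-negative", call. = FALSE)
  if (live + dead == 0) return(NA_real_)
  100 * live / (live + dead)
}

#' Pooled viability across images
#'
#' Total live cells over total cells across images — the pooled ratio, not
#' the mean of per-image percentages (the two differ when images carry
#' different cell counts).
#'
#' @param results Data frame (or list of lists) with `live` and `dead`
#'   counts per image.
#' @return Pooled percentage, or `NA_real_` if every image is empty.
#' @export
pooled_viability <- function(results) {
  if (is.data.frame(results)) {
    live <- results$live; dead <- results$dead
  } else {
    live <- vapply(results, `[[`, numeric(1), "live")
    dead <- vapply(results, `[[`, numeric(1), "dead")
  }
  if (any(c(live, dead) < 0))
    stop("pooled_viability: counts must be non-negative", call. = FALSE)
  total <- sum(live) + sum(dead)
  if (total == 0) return(NA_real_)
  100 * sum(live) / total
}
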
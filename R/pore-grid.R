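#' Designed grid-scaffold geometry
#'
#' The printed design is a square lattice: `cells_per_side + 1` equally
#' spaced lines in each direction over a `span`-mm edge, so
#' `cells_per_side^2` open pores of analytic area
#' `(pitch - line_width)^2`, `pitch = span / cells_per_side`. The default
#' reproduces the 20 x 20 mm, 11 x 11 = 121-pore design.
#'
#' @param span Design edge length (mm).
#' @param cells_per_side Number of cells along one edge.
#' @param line_width Design filament width (mm).
#' @param calibration Pixels per mm used by imaging and area conversion.
#' @return A `grid_spec` object (with derived `pitch` and `expected_pores`).
#' @export
grid_spec <- function(span = 20, cells_per_side = 11, line_width = 0.4,
                      calibration = 45) {
  if (cells_per_side < 1) stop("grid_spec: cells_per_side must be >= 1",
                               call. = FALSE)
  if (calibration <= 0) stop("grid_spec: calibration must be positive",
                             call. = FALSE)
  if (span <= cells_per_side * line_width)
    stop("grid_spec: span must exceed cells_per_side * line_width",
         call. = FALSE)
  structure(list(span = span, cells_per_side = as.integer(cells_per_side),
                 line_width = line_width, calibration = calibration,
                 pitch = span / cells_per_side,
                 expected_pores = as.integer(cells_per_side)^2),
            class = "grid_spec")
}

#' Segment the pores of a printed grid image
#'
#' Otsu-thresholds the (bright-foreground) grid material, closes small gaps
#' with a 3x3 morphological closing, locates the grid as the largest
#' 8-connected foreground component, and labels the 4-connected background
#' openings that lie strictly inside that component's bounding box;
#' background touching the image border (the outside) is excluded.
#'
#' @param image Integer matrix; grid material brighter than background
#'   (use `invert = TRUE` for dark-on-light images).
#' @param spec A [grid_spec()].
#' @param invert Invert image polarity before thresholding.
#' @return Integer label matrix (0 = not a pore) with attributes `bbox`
#'   (rows `r0, r1`, cols `c0, c1` of the grid) and `n_labels`.
#' @export
segment_pores <- function(image, spec, invert = FALSE) {
  stopifnot(inherits(spec, "grid_spec"))
  img <- round(image)
  storage.mode(img) <- "integer"
  if (invert) img <- max(img) - img
  thr <- otsu_threshold(img)
  fg <- img > thr
  if (!any(fg))
    stop("segment_pores: no grid boundary detectable (empty foreground)",
         call. = FALSE)
  fg <- close_mask_3x3(fg)
  fg_lab <- label_components(fg, 8L)
  sizes <- tabulate(fg_lab[fg_lab > 0])
  grid_mask <- fg_lab == which.max(sizes)
  rows <- range(which(rowSums(grid_mask) > 0))
  cols <- range(which(colSums(grid_mask) > 0))
  if (diff(rows) < 2 || diff(cols) < 2)
    stop("segment_pores: no grid boundary detectable", call. = FALSE)
  bg <- !fg
  bg_lab <- label_components(bg, 4L)
  # drop border-touching background (the outside world)
  border_labels <- unique(c(bg_lab[1, ], bg_lab[nrow(bg_lab), ],
                            bg_lab[, 1], bg_lab[, ncol(bg_lab)]))
  border_labels <- border_labels[border_labels > 0]
  bg_lab[bg_lab %in% border_labels] <- 0L
  # keep only openings inside the grid bounding box
  inside <- matrix(FALSE, nrow(bg_lab), ncol(bg_lab))
  inside[rows[1]:rows[2], cols[1]:cols[2]] <- TRUE
  outside_labels <- unique(bg_lab[!inside & bg_lab > 0])
  bg_lab[bg_lab %in% outside_labels] <- 0L
  # compact label ids
  keep <- sort(unique(bg_lab[bg_lab > 0]))
  if (length(keep)) {
    remap <- integer(max(keep))
    remap[keep] <- seq_along(keep)
    pos <- bg_lab > 0
    bg_lab[pos] <- remap[bg_lab[pos]]
  }
  attr(bg_lab, "bbox") <- c(r0 = rows[1], r1 = rows[2],
                            c0 = cols[1], c1 = cols[2])
  attr(bg_lab, "n_labels") <- length(keep)
  bg_lab
}

#' Match segmented pores to the designed lattice
#'
#' Registers the design to the grid's bounding box (the box spans the outer
#' line edges, i.e. `span + line_width` mm) and classifies every designed
#' cell: `ok` when exactly one pore's centroid falls in it and that pore
#' extends into no other cell; `merged` when its pore spans two or more
#' cells (all spanned cells are marked merged); `missing` otherwise.
#' Openings smaller than `min_area_frac` of the analytic open-cell area are
#' treated as specks and ignored.
#'
#' @param labels Label matrix from [segment_pores()].
#' @param spec A [grid_spec()].
#' @param min_area_frac Minimum pore area as a fraction of the analytic
#'   cell area (default 0.05).
#' @return Data frame of pore records: `cell_row`, `cell_col`, `pore_id`,
#'   `centroid_x_mm`, `centroid_y_mm`, `area_mm2`, `status`.
#' @export
match_pores_to_grid <- function(labels, spec, min_area_frac = 0.05) {
  stopifnot(inherits(spec, "grid_spec"))
  if (spec$calibration <= 0)
    stop("match_pores_to_grid: non-positive calibration", call. = FALSE)
  bbox <- attr(labels, "bbox")
  n <- spec$cells_per_side
  pitch <- spec$pitch
  lw <- spec$line_width
  cell_area_px <- ((pitch - lw) * spec$calibration)^2
  # map pixel centres to lattice mm coordinates (0..span = line centres)
  sx <- (spec$span + lw) / (bbox["c1"] - bbox["c0"] + 1)
  sy <- (spec$span + lw) / (bbox["r1"] - bbox["r0"] + 1)
  px_idx <- which(labels > 0)
  recs <- data.frame(cell_row = rep(seq_len(n), each = n),
                     cell_col = rep(seq_len(n), times = n),
                     pore_id = NA_integer_,
                     centroid_x_mm = NA_real_, centroid_y_mm = NA_real_,
                     area_mm2 = 0, status = "missing",
                     stringsAsFactors = FALSE)
  if (length(px_idx)) {
    H <- nrow(labels)
    lab <- labels[px_idx]
    r <- (px_idx - 1L) %% H + 1L
    cc <- (px_idx - 1L) %/% H + 1L
    x_mm <- (cc - bbox["c0"] + 0.5) * sx - lw / 2
    y_mm <- (r - bbox["r0"] + 0.5) * sy - lw / 2
    cell_c <- pmin(pmax(ceiling(x_mm / pitch), 1L), n)
    cell_r <- pmin(pmax(ceiling(y_mm / pitch), 1L), n)
    areas <- tabulate(lab)
    good <- which(areas >= min_area_frac * cell_area_px)
    for (id in good) {
      sel <- lab == id
      cx <- mean(x_mm[sel]); cy <- mean(y_mm[sel])
      # cells this pore spans: overlap of at least the speck floor
      ov <- table(paste(cell_r[sel], cell_c[sel]))
      spanned <- names(ov)[ov >= min_area_frac * cell_area_px]
      if (length(spanned) == 0)
        spanned <- names(ov)[which.max(ov)]
      span_rc <- do.call(rbind, lapply(strsplit(spanned, " "), as.integer))
      area_mm2 <- areas[id] / spec$calibration^2
      if (nrow(span_rc) >= 2) {
        for (j in seq_len(nrow(span_rc))) {
          k <- (span_rc[j, 1] - 1L) * n + span_rc[j, 2]
          recs$status[k] <- "merged"
          recs$pore_id[k] <- id
          recs$area_mm2[k] <- area_mm2
          recs$centroid_x_mm[k] <- cx
          recs$centroid_y_mm[k] <- cy
        }
      } else {
        # centroid cell
        cr <- min(max(ceiling(cy / pitch), 1L), n)
        ccol <- min(max(ceiling(cx / pitch), 1L), n)
        k <- (cr - 1L) * n + ccol
        if (recs$status[k] == "missing") {
          recs$status[k] <- "ok"
          recs$pore_id[k] <- id
          recs$area_mm2[k] <- area_mm2
          recs$centroid_x_mm[k] <- cx
          recs$centroid_y_mm[k] <- cy
        } else {
          # second centroid in the same cell: ambiguous, mark merged
          recs$status[k] <- "merged"
        }
      }
    }
  }
  recs
}

#' Normalized pore number
#'
#' Percentage of designed pores successfully realised:
#' `100 * n_ok / expected_pores`.
#'
#' @param records Pore records from [match_pores_to_grid()].
#' @param spec A [grid_spec()].
#' @return Percentage in `[0, 100]`.
#' @export
normalized_pore_number <- function(records, spec) {
  stopifnot(inherits(spec, "grid_spec"))
  100 * sum(records$status == "ok") / spec$expected_pores
}

#' Pore-area statistics
#'
#' Mean and sample standard deviation over the `ok` pores only. With no ok
#' pore, the statistics are undefined and returned as an `NA` sentinel
#' rather than an error (the all-spread degenerate print is a legitimate
#' observation).
#'
#' @param records Pore records from [match_pores_to_grid()].
#' @return List with `mean` (mm^2), `sd` (mm^2) and `n_ok`.
#' @export
pore_area_stats <- function(records) {
  a <- records$area_mm2[records$status == "ok"]
  if (length(a) == 0) return(list(mean = NA_real_, sd = NA_real_, n_ok = 0L))
  list(mean = mean(a),
       sd = if (length(a) > 1) stats::sd(a) else 0,
       n_ok = length(a))
}

#' Grid metrics for one image
#'
#' Convenience wrapper running segmentation, lattice matching and the
#' summary statistics.
#'
#' @param image Integer matrix.
#' @param spec A [grid_spec()].
#' @param stage_label One of `after_printing`, `after_crosslinking`,
#'   `after_incubation`.
#' @param invert Passed to [segment_pores()].
#' @return List with `records`, `normalized_pore_number`, `mean_pore_area`,
#'   `sd_pore_area`, `n_ok`, `stage_label`.
#' @export
grid_metrics <- function(image, spec,
                         stage_label = c("after_printing",
                                         "after_crosslinking",
                                         "after_incubation"),
                         invert = FALSE) {
  stage_label <- match.arg(stage_label)
  labels <- segment_pores(image, spec, invert = invert)
  records <- match_pores_to_grid(labels, spec)
  st <- pore_area_stats(records)
  list(records = records,
       normalized_pore_number = normalized_pore_number(records, spec),
       mean_pore_area = st$mean, sd_pore_area = st$sd, n_ok = st$n_ok,
       stage_label = stage_label)
}
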
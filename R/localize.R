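#' Per-row edge counts
#'
#' @param edges An `edge_map` from [detect_edges()] or a logical matrix.
#' @return Integer vector of edge-pixel counts, one per image row.
#' @export
row_edge_profile <- function(edges) {
  E <- if (inherits(edges, "edge_map")) edges$edges else edges
  if (length(E) == 0L) stop("empty edge map")
  as.integer(rowSums(E))
}

#' Initial searching rows from the edge-row profile
#'
#' Looks for sharp rises of the profile (forward difference over a short lag
#' above a threshold; the lag absorbs the few rows over which noise jitter
#' spreads a boundary's edge pixels), groups consecutive rises into areas of
#' interest, keeps areas whose local edge support is wide enough, and
#' returns the first `max_rows` areas from the top of the image.
#'
#' @param profile Integer vector from [row_edge_profile()].
#' @param threshold Rise cutoff; `NULL` uses the adaptive value
#'   `mean + 2 sd` of the lagged forward differences.
#' @param max_rows Maximum number of rows returned (default 3).
#' @param min_support Minimum number of edge pixels in the six rows from the
#'   rise downward (for a single-valued boundary this is the column span it
#'   covers; rejects speckle bursts). Default 0 accepts all.
#' @param min_sep Rises closer than this many rows merge into one area.
#' @param lag Rows over which the forward difference is taken.
#' @return Integer vector of row indices, top to bottom (possibly empty).
#' @export
find_initial_rows <- function(profile, threshold = NULL, max_rows = 3,
                              min_support = 0, min_sep = 4, lag = 3) {
  if (length(profile) < 3) stop("profile too short")
  lag <- min(lag, length(profile) - 1L)
  n <- length(profile)
  d <- profile[(1 + lag):n] - profile[seq_len(n - lag)]
  if (is.null(threshold)) threshold <- mean(d) + 2 * stats::sd(d)
  cand <- which(d > threshold) + 1L  # row where the accumulation starts
  if (length(cand) == 0L) return(integer(0))
  groups <- cumsum(c(TRUE, diff(cand) > min_sep))
  rows <- as.integer(tapply(cand, groups, min))
  np <- length(profile)
  ok <- vapply(split(cand, groups), function(grp) {
    any(vapply(grp, function(r)
      sum(profile[r:min(np, r + 5L)]) >= min_support, logical(1)))
  }, logical(1))
  utils::head(rows[ok], max_rows)
}

#' Label candidate rows as lens limits and cornea
#'
#' The corneal tissue band is the brightest, thickest structure, so the band
#' below its searching row shows the most significant intensity variations
#' (bright plateau against dark background). Candidates are scored by the
#' standard deviation of intensity in a band just below each row and the
#' maximal-score row is labelled as the cornea searching row. Remaining
#' candidates are the lens outer limit (topmost) and, if present, the lens
#' inner limit.
#'
#' @param img Grayscale matrix (intensity image, not edges).
#' @param candidate_rows 1-3 row indices from [find_initial_rows()].
#' @param band_h Height of the scoring band in rows.
#' @return Named list: `cornea`, `scl_outer`, `scl_inner` (row index or `NA`),
#'   plus `scores`.
#' @export
identify_cornea_row <- function(img, candidate_rows, band_h = 15) {
  n <- length(candidate_rows)
  if (n < 1 || n > 3) stop("need 1-3 candidate rows")
  scores <- vapply(candidate_rows, function(r) {
    lo <- min(nrow(img), r + 1L); hi <- min(nrow(img), r + band_h)
    stats::sd(img[lo:hi, ])
  }, numeric(1))
  cornea <- candidate_rows[which.max(scores)]
  rest <- sort(setdiff(candidate_rows, cornea))
  list(cornea = cornea,
       scl_outer = if (length(rest) >= 1) rest[1] else NA_integer_,
       scl_inner = if (length(rest) >= 2) rest[2] else NA_integer_,
       scores = scores)
}

# 5x5 neighbourhood edge counts (including the centre pixel).
.edge_neighbour_counts <- function(E) {
  M <- E * 1
  acc <- matrix(0, nrow(E), ncol(E))
  for (dr in -2:2) for (dc in -2:2) acc <- acc + .shift_mat(M, dr, dc)
  acc
}

#' Trace a layer limit pixel by pixel
#'
#' Grows a curve from a seed edge pixel one column at a time in both
#' directions. Per column, candidate edge pixels inside a vertical window
#' around the running prediction are screened by an artifact criterion
#' (enough edge pixels in the 5x5 neighbourhood and significant nearby
#' intensity), the surviving candidate closest to the theoretical point
#' (least-squares line over the last traced columns) is taken, gaps are
#' crossed by continuing along the current orientation and re-interpolated
#' linearly once the far side is found, and the trace stops at the image
#' border or after too many consecutive unsupported columns.
#'
#' @param edges An `edge_map` or logical matrix.
#' @param img Grayscale matrix used for the intensity-significance check.
#' @param start `c(row, col)` seed; must lie on an edge pixel.
#' @param window_up,window_down Search window above/below the prediction, px.
#' @param max_extrapolation_cols Consecutive unsupported columns tolerated
#'   before the trace terminates (trailing unsupported columns are trimmed).
#' @param orient_window Columns used for the least-squares orientation line.
#' @param min_neighbours Minimum 5x5 edge-neighbour count (criterion 1).
#' @return A [layer_curve()].
#' @export
trace_limit <- function(edges, img, start, window_up = 7, window_down = 7,
                        max_extrapolation_cols = 30, orient_window = 10,
                        min_neighbours = 3) {
  E <- if (inherits(edges, "edge_map")) edges$edges else edges
  r0 <- as.integer(round(start[1])); c0 <- as.integer(round(start[2]))
  if (r0 < 1 || r0 > nrow(E) || c0 < 1 || c0 > ncol(E) || !E[r0, c0])
    stop("start point is not on an edge pixel")
  nbr <- .edge_neighbour_counts(E)
  # significant intensity: local band maximum above the Otsu level of the
  # image (bright structure nearby, not an isolated speckle response)
  thr <- 255 * EBImage::otsu(.as_ebimage(clip255(img)))
  h <- nrow(E); w <- ncol(E)
  localmax <- img
  for (dr in c(-2L, -1L, 1L, 2L))
    localmax <- pmax(localmax, .shift_mat(img, dr, 0))
  valid <- E & (nbr >= min_neighbours) & (localmax >= thr)

  trace_dir <- function(step) {
    rows <- numeric(0); prov <- character(0)
    anchor_row <- r0; anchor_col <- c0  # last supported point
    hist_cols <- c0; hist_rows <- r0
    gap <- 0L
    cc <- c0 + step
    while (cc >= 1L && cc <= w) {
      k <- length(hist_cols)
      use <- max(1L, k - orient_window + 1L):k
      xs <- hist_cols[use]; ys <- hist_rows[use]
      slope <- if (length(xs) >= 2 && stats::var(xs) > 0)
        stats::cov(xs, ys) / stats::var(xs) else 0
      pred <- ys[length(ys)] + slope * (cc - xs[length(xs)])
      lo <- max(1L, floor(pred - window_up))
      hi <- min(h, ceiling(pred + window_down))
      cand <- which(valid[lo:hi, cc]) + lo - 1L
      if (length(cand) > 0) {
        r <- cand[which.min(abs(cand - pred))]
        if (gap > 0L) {
          # re-interpolate the gap linearly between the anchors
          n_new <- length(rows)
          gidx <- (n_new - gap + 1L):n_new
          frac <- seq_len(gap) / (gap + 1L)
          rows[gidx] <- anchor_row + frac * (r - anchor_row)
          prov[gidx] <- "interpolated"
        }
        rows <- c(rows, r); prov <- c(prov, "traced")
        anchor_row <- r; anchor_col <- cc
        hist_cols <- c(hist_cols, cc); hist_rows <- c(hist_rows, r)
        gap <- 0L
      } else {
        rows <- c(rows, pred); prov <- c(prov, "extrapolated")
        hist_cols <- c(hist_cols, cc); hist_rows <- c(hist_rows, pred)
        gap <- gap + 1L
        if (gap > max_extrapolation_cols) break
      }
      cc <- cc + step
    }
    if (gap > 0L && length(rows) >= gap) {  # trim trailing unsupported run
      keep <- seq_len(length(rows) - gap)
      rows <- rows[keep]; prov <- prov[keep]
    }
    list(rows = rows, prov = prov)
  }

  right <- trace_dir(1L)
  left <- trace_dir(-1L)
  nl <- length(left$rows); nr <- length(right$rows)
  cols <- (c0 - nl):(c0 + nr)
  rows <- c(rev(left$rows), r0, right$rows)
  prov <- c(rev(left$prov), "traced", right$prov)
  layer_curve(cols, rows, prov)
}

#' Inner limit of the lens band below a traced outer limit
#'
#' Searches below each outer-limit point for the first sufficiently negative
#' vertical intensity change (the bottom edge of the band). Columns without
#' such a drop reuse the running median band width and are marked
#' `extrapolated`. When an `upper_bound` curve (the cornea) is supplied, the
#' search is confined above it.
#'
#' @param img Grayscale matrix.
#' @param outer The outer-limit [layer_curve()].
#' @param grad_thresh Negative-derivative magnitude cutoff, gray levels/px.
#' @param max_band Deepest search offset below the outer limit, px.
#' @param upper_bound Optional [layer_curve()] capping the search.
#' @param default_width Band width used when no column has a drop.
#' @return A [layer_curve()] with attribute `support_frac`, the fraction of
#'   columns where a genuine intensity drop was found.
#' @export
find_inner_limit <- function(img, outer, grad_thresh = 10, max_band = 30,
                             upper_bound = NULL, default_width = 8) {
  h <- nrow(img)
  n <- length(outer$cols)
  widths <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    col <- outer$cols[i]
    r0 <- as.integer(ceiling(outer$rows[i])) + 1L
    rmax <- min(h, r0 + max_band)
    if (!is.null(upper_bound)) {
      ub <- curve_row_at(upper_bound, col)
      if (is.finite(ub)) rmax <- min(rmax, as.integer(floor(ub)) - 1L)
    }
    if (rmax - r0 < 2L) next
    prof <- img[r0:rmax, col]
    d <- diff(prof)
    hit <- which(d <= -grad_thresh)
    if (length(hit) == 0L) next
    run_end <- hit[1]
    while (run_end < length(d) && d[run_end + 1] <= -grad_thresh)
      run_end <- run_end + 1L
    steep <- hit[1] + which.min(d[hit[1]:run_end]) - 1L
    widths[i] <- (r0 + steep - 0.5) - outer$rows[i]
  }
  support <- mean(!is.na(widths))
  filled <- widths
  if (all(is.na(widths))) {
    filled[] <- default_width
  } else {
    med_all <- stats::median(widths, na.rm = TRUE)
    run <- numeric(0)
    for (i in seq_len(n)) {
      if (!is.na(widths[i])) {
        run <- c(run, widths[i]); if (length(run) > 15) run <- run[-1]
      } else {
        filled[i] <- if (length(run) > 0) stats::median(run) else med_all
      }
    }
  }
  rows <- pmax(outer$rows + pmax(filled, 0), outer$rows)
  structure(layer_curve(outer$cols, rows,
                        ifelse(is.na(widths), "extrapolated", "traced")),
            support_frac = support)
}

#' Bundle of detected layer curves
#'
#' @param scl_outer,cornea [layer_curve()] objects.
#' @param scl_inner [layer_curve()] or `NULL` for two-layer images.
#' @param confidence Continuous distinctness score in `[0, 1]` backing the
#'   two/three-layer call (fraction of shared columns where the inner limit
#'   separates from the cornea by more than the merge distance).
#' @return An object of class `layer_set`.
#' @export
layer_set <- function(scl_outer, scl_inner, cornea, confidence = NA_real_) {
  structure(list(
    scl_outer = scl_outer, scl_inner = scl_inner, cornea = cornea,
    layer_count = if (is.null(scl_inner)) 2L else 3L,
    region_class = if (is.null(scl_inner)) "two_layers" else "three_layers",
    confidence = confidence), class = "layer_set")
}

#' @export
print.layer_set <- function(x, ...) {
  cat(sprintf("<layer_set> %s (%d layers), confidence %.2f\n",
              x$region_class, x$layer_count, x$confidence))
  for (nm in c("scl_outer", "scl_inner", "cornea"))
    if (!is.null(x[[nm]]))
      cat(sprintf("  %-9s cols %d..%d\n", nm,
                  min(x[[nm]]$cols), max(x[[nm]]$cols)))
  invisible(x)
}

# Seed for tracing: edge pixel in rows [r, r+depth] closest to the image
# centre column (ties: closest to r).
.find_start_point <- function(E, r, depth = 10) {
  h <- nrow(E); w <- ncol(E)
  band <- r:min(h, r + depth)
  idx <- which(E[band, , drop = FALSE], arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  score <- abs(idx[, 2] - (w + 1) / 2) * 1000 + (idx[, 1] - 1)
  best <- idx[which.min(score), ]
  c(band[1] + best[1] - 1L, best[2])
}

#' Preliminary localization of the lens limits and the cornea
#'
#' Runs edge detection, initial-row identification, per-layer tracing and the
#' inner-limit search, then classifies the image as showing two or three
#' layers via the distinct-inner-limit test: if the inner limit stays within
#' `merge_dist_px` of the cornea over more than `merge_frac` of the shared
#' columns, the two are considered the same boundary.
#'
#' @param pre An `oct_preprocessed` object (or a raw grayscale matrix, which
#'   is preprocessed first).
#' @param config Pipeline configuration, see [default_config()].
#' @return A [layer_set()].
#' @export
preliminary_localization <- function(pre, config = default_config()) {
  if (!inherits(pre, "oct_preprocessed")) pre <- preprocess(pre, config)
  img <- pre$image
  em <- detect_edges(img, config$canny_low, config$canny_high,
                     config$canny_kernel)
  prof <- row_edge_profile(em)
  # support is judged against the content width: rotation pads the canvas
  # with black corners that carry no layer evidence
  content_w <- sum(colSums(img > 0) > 0)
  rows <- find_initial_rows(prof, config$initial_row_threshold,
                            max_rows = 3,
                            min_support = config$min_support_frac * content_w)
  if (length(rows) == 0L) stop("no layers detected")
  lab <- identify_cornea_row(pre$smooth, rows)
  outer_row <- if (is.na(lab$scl_outer)) lab$cornea else lab$scl_outer

  seed_o <- .find_start_point(em$edges, outer_row)
  if (is.null(seed_o)) stop("no layers detected")
  outer <- trace_limit(em, img, seed_o,
                       config$loc_window_up, config$loc_window_down,
                       config$max_extrapolation_cols)
  cornea <- outer
  if (!is.na(lab$scl_outer)) {
    seed_c <- .find_start_point(em$edges, lab$cornea)
    if (!is.null(seed_c))
      cornea <- trace_limit(em, img, seed_c,
                            config$loc_window_up, config$loc_window_down,
                            config$max_extrapolation_cols)
  }
  inner <- find_inner_limit(img, outer, config$inner_grad_thresh,
                            upper_bound = if (!identical(cornea, outer)) cornea)

  shared <- intersect(inner$cols, cornea$cols)
  if (length(shared) > 0) {
    di <- abs(curve_row_at(inner, shared) - curve_row_at(cornea, shared))
    distinct_frac <- mean(di > config$merge_dist_px)
    # the continuous confidence counts a column as distinct only when the
    # inner limit was actually traced there, not width-fallback filled
    traced <- inner$provenance[match(shared, inner$cols)] == "traced"
    confidence <- mean(di > config$merge_dist_px & traced)
  } else distinct_frac <- confidence <- 0
  support <- attr(inner, "support_frac")
  merged <- distinct_frac < (1 - config$merge_frac) ||
    support < 0.1 || length(rows) < 2L

  # enforce non-crossing ordering on shared columns
  sh_oc <- intersect(outer$cols, cornea$cols)
  if (length(sh_oc) > 0) {
    io <- match(sh_oc, outer$cols); ic <- match(sh_oc, cornea$cols)
    cornea$rows[ic] <- pmax(cornea$rows[ic], outer$rows[io])
  }
  if (!merged) {
    sh <- intersect(inner$cols, cornea$cols)
    ii <- match(sh, inner$cols); ic <- match(sh, cornea$cols)
    inner$rows[ii] <- pmin(inner$rows[ii], cornea$rows[ic])
    sh <- intersect(inner$cols, outer$cols)
    ii <- match(sh, inner$cols); io <- match(sh, outer$cols)
    inner$rows[ii] <- pmax(inner$rows[ii], outer$rows[io])
  }
  layer_set(outer, if (!merged) inner, cornea, confidence = confidence)
}
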
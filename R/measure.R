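#' Measure a branching specimen
#'
#' Full morphometric pipeline for one binary image: Euclidean distance
#' map, Zhang-Suen thinning, feature classification, spur pruning, loop
#' report, skeleton graph with DFS orientation, and the six morphological
#' variables: junction thickness (da), branch thickness (db), terminal
#' thickness (dc), branch length (bl), branch angle (ba) and terminal
#' spacing (bs). Thicknesses are disc *diameters* (twice the distance-map
#' value), i.e. local specimen widths.
#'
#' If the image contains several connected specimens, each component gets
#' its own root and the measurements are pooled.
#'
#' @param binary a [binary_image()] or logical matrix.
#' @param prune prune spurious terminal branches before measuring?
#' @param min_spur minimum spur length in px; with `adaptive_prune` the
#'   threshold grows to the local junction-thickness radius.
#' @param adaptive_prune use the distance map to scale the spur threshold
#'   with the local branch width (default `TRUE`).
#' @param root optional `(row, col)` of the terminal to use as graph root.
#' @param probe,probe_factor branch-angle probe rule, see [branch_angle()].
#' @param on_ring passed to [build_graph()].
#' @param id optional image identifier carried into output tables.
#' @return An object of class `thallus_measurements`: component tables
#'   `da`, `db`, `dc`, `bl`, `ba`, `bs`, the `means` and `medians` of the
#'   six variables (lengths in px), the `loop_report`, the intermediate
#'   `skeleton`, `graph` and `distance_map`, and the `pixel_scale` if the
#'   input carried one (scaled columns are added by [apply_scale()],
#'   called automatically when a scale is present).
#' @export
measure_thallus <- function(binary, prune = TRUE, min_spur = 3,
                            adaptive_prune = TRUE, root = NULL,
                            probe = "direction", probe_factor = 3.5,
                            on_ring = "error", id = "image") {
  if (is.matrix(binary)) binary <- binary_image(binary)
  dm <- distance_map(binary)
  sk <- classify_features(thin_zhang_suen(binary))
  if (prune)
    sk <- prune_spurs(sk, min_length = min_spur,
                      dm = if (adaptive_prune) dm else NULL)
  loops <- detect_loops(sk)
  sk$loop_report <- loops
  g <- build_graph(sk, root = root, on_ring = on_ring)
  g <- traverse_dfs(g)$graph
  da <- junction_thickness(dm, g, skel = sk)
  dc <- terminal_thickness(dm, g)
  db <- branch_thickness(dm, g, da = da)
  bl <- branch_length(g)
  bl$arc_length <- vapply(g$edges, edge_arc_length, numeric(1), g = g)
  ba <- branch_angle(g, dm, db = db, da = da, probe = probe,
                     probe_factor = probe_factor)
  bs <- terminal_spacing(g)
  mn <- function(x) if (length(x)) mean(x) else NA_real_
  md <- function(x) if (length(x)) stats::median(x) else NA_real_
  # boundary-limited db discs (capped by the previous disc, not the
  # specimen edge) are packing artefacts; summaries use the free discs
  db_free <- db$diameter_px[!db$boundary_limited]
  if (!length(db_free)) db_free <- db$diameter_px
  means <- c(da = mn(da$diameter_px), db = mn(db_free),
             dc = mn(dc$diameter_px), bl = mn(bl$arc_length),
             bs = mn(bs$distance_px), ba = mn(ba$angle_deg))
  medians <- c(da = md(da$diameter_px), db = md(db_free),
               dc = md(dc$diameter_px), bl = md(bl$arc_length),
               bs = md(bs$distance_px), ba = md(ba$angle_deg))
  ms <- structure(list(id = id, da = da, db = db, dc = dc, bl = bl,
                       ba = ba, bs = bs, means = means, medians = medians,
                       pixel_scale = binary$pixel_scale,
                       loop_report = loops, skeleton = sk, graph = g,
                       distance_map = dm,
                       provenance = c(binary$provenance,
                                      list(prune = prune, min_spur = min_spur,
                                           adaptive_prune = adaptive_prune,
                                           probe = probe,
                                           probe_factor = probe_factor))),
                  class = "thallus_measurements")
  if (!is.null(binary$pixel_scale)) ms <- apply_scale(ms, binary$pixel_scale)
  ms
}

# arc length of an edge: polyline through rep(v1), path pixels, rep(v2),
# resampled every few pixels. Thinned skeletons staircase (axial step
# pairs instead of diagonals), which inflates the raw pixel-to-pixel sum
# by up to ~25%; summing over a coarser polyline removes the staircase
# while following genuine curvature.
#' @keywords internal
#' @noRd
edge_arc_length <- function(e, g, step = 5L) {
  a <- c(g$vertices$row[e$v1], g$vertices$col[e$v1])
  b <- c(g$vertices$row[e$v2], g$vertices$col[e$v2])
  par <- if (!is.na(e$parent)) e$parent else e$v1
  p <- oriented_path(g, e, par)
  pts <- rbind(if (par == e$v1) a else b, p, if (par == e$v1) b else a)
  keep <- unique(c(seq(1L, nrow(pts), by = step), nrow(pts)))
  pts <- pts[keep, , drop = FALSE]
  sum(sqrt(rowSums((pts[-1L, , drop = FALSE] -
                      pts[-nrow(pts), , drop = FALSE])^2)))
}

#' Apply a pixel-to-physical-unit scale to a measurement set
#'
#' All length-valued measurements (thickness diameters, branch lengths,
#' terminal spacings, and their means/medians) are multiplied by
#' `pixel_scale`; angles are unchanged. Pixel values are retained alongside
#' the scaled columns.
#'
#' @param ms a `thallus_measurements` object.
#' @param pixel_scale physical length per pixel, > 0.
#' @return The measurement set with `*_scaled` columns and `means_scaled` /
#'   `medians_scaled` added.
#' @export
apply_scale <- function(ms, pixel_scale) {
  stopifnot(inherits(ms, "thallus_measurements"))
  if (!is.numeric(pixel_scale) || length(pixel_scale) != 1L ||
      !is.finite(pixel_scale) || pixel_scale <= 0)
    stop("pixel_scale must be a single positive number")
  s <- pixel_scale
  ms$da$diameter_scaled <- ms$da$diameter_px * s
  ms$db$diameter_scaled <- ms$db$diameter_px * s
  ms$dc$diameter_scaled <- ms$dc$diameter_px * s
  ms$bl$pixel_path_length_scaled <- ms$bl$pixel_path_length * s
  ms$bl$chord_length_scaled <- ms$bl$chord_length * s
  ms$bl$arc_length_scaled <- ms$bl$arc_length * s
  ms$bs$distance_scaled <- ms$bs$distance_px * s
  len <- c("da", "db", "dc", "bl", "bs")
  ms$means_scaled <- ms$means
  ms$means_scaled[len] <- ms$means[len] * s
  ms$medians_scaled <- ms$medians
  ms$medians_scaled[len] <- ms$medians[len] * s
  ms$pixel_scale <- s
  ms
}

#' @export
print.thallus_measurements <- function(x, ...) {
  cat(sprintf("<thallus_measurements> '%s'\n", x$id))
  n <- c(da = nrow(x$da), db = nrow(x$db), dc = nrow(x$dc),
         bl = nrow(x$bl), bs = nrow(x$bs), ba = nrow(x$ba))
  cat("  local measurements:",
      paste(names(n), n, sep = "=", collapse = ", "), "\n")
  cat("  means (px / deg):\n")
  print(round(x$means, 2))
  if (!is.null(x$means_scaled)) {
    cat(sprintf("  means (scaled, %g units/px):\n", x$pixel_scale))
    print(signif(x$means_scaled, 4))
  }
  if (x$loop_report$count > 0L)
    cat(sprintf("  WARNING: %d loop(s) detected; see $loop_report\n",
                x$loop_report$count))
  invisible(x)
}

#' @export
summary.thallus_measurements <- function(object, ...) {
  df <- as.data.frame(object)
  agg <- stats::aggregate(value_px ~ variable, df,
                          function(v) c(n = length(v), mean = mean(v),
                                        sd = stats::sd(v),
                                        median = stats::median(v)))
  out <- data.frame(variable = agg$variable, agg$value_px)
  class(out) <- c("summary.thallus_measurements", "data.frame")
  out
}

#' @export
print.summary.thallus_measurements <- function(x, ...) {
  cat("Per-variable summary of local measurements:\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Long-format table of all local measurements
#'
#' One row per local measurement: `image`, `variable` (one of `da`, `db`,
#' `dc`, `bl_pixel`, `bl_chord`, `bl_arc`, `ba`, `bs`), `value_px`,
#' `value_scaled` (NA when no scale is set), pixel location `x`/`y`
#' (column/row), `owner` (vertex or edge id) and `flag`.
#'
#' @param x a `thallus_measurements` object.
#' @param ... unused.
#' @export
as.data.frame.thallus_measurements <- function(x, ...) {
  s <- x$pixel_scale
  sc <- function(v) if (is.null(s)) rep(NA_real_, length(v)) else v * s
  rows <- list(
    data.frame(variable = "da", value_px = x$da$diameter_px,
               x = x$da$col, y = x$da$row, owner = x$da$vertex, flag = ""),
    data.frame(variable = "db", value_px = x$db$diameter_px,
               x = x$db$col, y = x$db$row, owner = x$db$edge,
               flag = ifelse(x$db$boundary_limited, "boundary_limited", "")),
    data.frame(variable = "dc", value_px = x$dc$diameter_px,
               x = x$dc$col, y = x$dc$row, owner = x$dc$vertex, flag = ""),
    data.frame(variable = "bl_pixel", value_px = x$bl$pixel_path_length,
               x = NA, y = NA, owner = x$bl$edge, flag = ""),
    data.frame(variable = "bl_chord", value_px = x$bl$chord_length,
               x = NA, y = NA, owner = x$bl$edge, flag = ""),
    data.frame(variable = "bl_arc", value_px = x$bl$arc_length,
               x = NA, y = NA, owner = x$bl$edge, flag = ""),
    data.frame(variable = "ba", value_px = x$ba$angle_deg,
               x = NA, y = NA, owner = x$ba$junction, flag = ""),
    data.frame(variable = "bs", value_px = x$bs$distance_px,
               x = x$bs$col, y = x$bs$row, owner = x$bs$terminal, flag = "")
  )
  rows <- rows[vapply(rows, nrow, integer(1)) > 0L]
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variable = character(0), value_px = numeric(0), x = numeric(0),
               y = numeric(0), owner = integer(0), flag = character(0))
  df$value_scaled <- if (is.null(s)) NA_real_ else
    ifelse(df$variable %in% c("ba"), df$value_px, df$value_px * s)
  cbind(image = x$id, df)
}

#' Write a measurement overlay PNG
#'
#' Specimen in yellow, skeleton in green, and the measurement discs colour
#' coded: junction thickness red, branch thickness gray, terminal thickness
#' blue; terminal-spacing circles in white.
#'
#' @param ms a `thallus_measurements` object.
#' @param binary the source [binary_image()].
#' @param path output PNG path.
#' @export
write_measurement_overlay <- function(ms, binary, path) {
  m <- binary$mask
  h <- nrow(m); w <- ncol(m)
  img <- array(0, c(h, w, 3L))
  img[, , 1L][m] <- 1; img[, , 2L][m] <- 1; img[, , 3L][m] <- 0.25
  skm <- ms$skeleton$mask
  img[, , 1L][skm] <- 0; img[, , 2L][skm] <- 0.75; img[, , 3L][skm] <- 0
  draw_circle <- function(r0, c0, rad, col) {
    if (rad <= 0) return()
    th <- seq(0, 2 * pi, length.out = max(16L, ceiling(2 * pi * rad)))
    rr <- round(r0 + rad * sin(th)); cc <- round(c0 + rad * cos(th))
    ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    for (ch in 1:3) {
      idx <- cbind(rr[ok], cc[ok], ch)
      img[idx] <<- col[ch]
    }
  }
  for (i in seq_len(nrow(ms$da)))
    draw_circle(ms$da$row[i], ms$da$col[i], ms$da$diameter_px[i] / 2, c(1, 0, 0))
  for (i in seq_len(nrow(ms$db)))
    draw_circle(ms$db$row[i], ms$db$col[i], ms$db$diameter_px[i] / 2,
                c(0.6, 0.6, 0.6))
  for (i in seq_len(nrow(ms$dc)))
    draw_circle(ms$dc$row[i], ms$dc$col[i], ms$dc$diameter_px[i] / 2, c(0, 0.3, 1))
  for (i in seq_len(nrow(ms$bs)))
    draw_circle(ms$bs$row[i], ms$bs$col[i], ms$bs$distance_px[i], c(1, 1, 1))
  png::writePNG(img, path)
  invisible(path)
}
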
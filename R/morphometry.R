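#' Euclidean distance map
#'
#' Exact Euclidean distance transform of the foreground: each foreground
#' pixel carries its shortest distance to any background pixel, 0 on the
#' background. The image border counts as background (the mask is padded by
#' one background pixel before the transform), so an all-foreground image
#' is still well defined.
#'
#' Twice the value at a skeleton pixel is the local width of the specimen
#' there -- the basis of the junction/branch/terminal thickness
#' measurements.
#'
#' @param binary a [binary_image()] or logical matrix.
#' @return numeric matrix of distances in pixels.
#' @export
distance_map <- function(binary) {
  m <- if (inherits(binary, "binary_image")) binary$mask else (binary & TRUE)
  p <- pad_mask(m) * 1
  d <- EBImage::imageData(EBImage::distmap(EBImage::Image(p),
                                           metric = "euclidean"))
  d[2:(nrow(m) + 1L), 2:(ncol(m) + 1L), drop = FALSE]
}

#' Junction thickness (da)
#'
#' One disc per junction vertex with diameter twice the distance-map value
#' at the disc centre: the largest disc about the branching point that
#' stays inside the specimen. By default the centre is the skeleton pixel
#' with the largest distance-map value within one local radius of the
#' junction pixel: raster thinning places the junction pixel near, but not
#' exactly on, the crest of the distance map at the crotch, and the local
#' search removes that displacement; pass `skel = NULL` to measure
#' literally at the junction pixel.
#'
#' @param dm distance map from [distance_map()].
#' @param g a [skeleton_graph].
#' @param skel the classified [skeleton_image()] (enables the crest
#'   search; `NULL` disables it).
#' @return data.frame with `vertex`, `row`, `col` (disc centre),
#'   `diameter_px`.
#' @export
junction_thickness <- function(dm, g, skel = NULL) {
  v <- g$vertices[g$vertices$kind == "junction", ]
  if (!nrow(v))
    return(data.frame(vertex = integer(0), row = integer(0),
                      col = integer(0), diameter_px = numeric(0)))
  rows <- v$row; cols <- v$col
  dia <- 2 * dm[cbind(v$row, v$col)]
  if (!is.null(skel)) {
    sk_px <- which(skel$mask, arr.ind = TRUE)
    for (i in seq_len(nrow(v))) {
      r0 <- dm[v$row[i], v$col[i]]
      d2 <- (sk_px[, 1L] - v$row[i])^2 + (sk_px[, 2L] - v$col[i])^2
      cand <- sk_px[d2 <= (r0 + 1)^2, , drop = FALSE]
      vals <- dm[cand]
      best <- order(-vals, (cand[, 1L] - v$row[i])^2 +
                      (cand[, 2L] - v$col[i])^2,
                    cand[, 1L], cand[, 2L])[1L]
      rows[i] <- cand[best, 1L]; cols[i] <- cand[best, 2L]
      dia[i] <- 2 * vals[best]
    }
  }
  data.frame(vertex = v$id, row = rows, col = cols, diameter_px = dia)
}

#' Terminal thickness (dc)
#'
#' One disc per terminal vertex (root included), centred at the skeleton
#' tip, with diameter twice the distance-map value there.
#'
#' @inheritParams junction_thickness
#' @return data.frame with `vertex`, `row`, `col`, `diameter_px`.
#' @export
terminal_thickness <- function(dm, g) {
  v <- g$vertices[g$vertices$kind == "terminal", ]
  data.frame(vertex = v$id, row = v$row, col = v$col,
             diameter_px = 2 * dm[cbind(v$row, v$col)])
}

#' Branch thickness (db)
#'
#' Walks each branch path away from its parent vertex and places successive
#' non-overlapping discs: starting from the parent's disc (junction
#' thickness at a junction, terminal thickness at a terminal), the next
#' centre is the first path pixel whose background-limited disc no longer
#' overlaps the previous disc, and its diameter is twice
#' `min(EDT, distance to the previous disc's boundary)`. For a constant
#' width branch this spaces centres about one diameter apart and returns
#' the branch width. Placement stops at the end of the path or on entering
#' the terminal-thickness zone of a terminal child. Measurements whose
#' diameter was capped by the previous disc rather than the background are
#' flagged `boundary_limited`.
#'
#' @param dm distance map from [distance_map()].
#' @param g a [skeleton_graph] whose edges carry DFS orientation
#'   (see [traverse_dfs()]); unoriented edges are walked from `v1`.
#' @return data.frame with `edge`, `row`, `col`, `diameter_px`,
#'   `boundary_limited`.
#' @export
branch_thickness <- function(dm, g, da = NULL) {
  out <- list()
  for (e in g$edges) {
    par <- if (!is.na(e$parent)) e$parent else e$v1
    child <- if (e$v1 == par) e$v2 else e$v1
    p <- oriented_path(g, e, par)
    if (!nrow(p)) next
    pc <- c(g$vertices$row[par], g$vertices$col[par])
    cc <- c(g$vertices$row[child], g$vertices$col[child])
    prev_c <- pc
    prev_r <- dm[pc[1L], pc[2L]]
    if (!is.null(da) && par %in% da$vertex) {
      hit <- which(da$vertex == par)[1L]
      prev_c <- c(da$row[hit], da$col[hit])
      prev_r <- da$diameter_px[hit] / 2
    }
    child_r <- if (g$vertices$kind[child] == "terminal")
      dm[cc[1L], cc[2L]] else 0
    for (i in seq_len(nrow(p))) {
      px <- p[i, ]
      if (child_r > 0 &&
          sqrt(sum((px - cc)^2)) <= child_r) break  # terminal zone reached
      gap <- sqrt(sum((px - prev_c)^2)) - prev_r
      r_bg <- dm[px[1L], px[2L]]
      if (r_bg > gap) next                # still overlapping previous disc
      r <- min(r_bg, gap)
      out[[length(out) + 1L]] <- data.frame(
        edge = e$id, row = px[1L], col = px[2L], diameter_px = 2 * r,
        boundary_limited = gap < r_bg)
      prev_c <- px; prev_r <- r
    }
  }
  if (!length(out))
    return(data.frame(edge = integer(0), row = integer(0), col = integer(0),
                      diameter_px = numeric(0), boundary_limited = logical(0)))
  do.call(rbind, out)
}

#' Branch length (bl)
#'
#' Per edge, both the pixel-path length (count of interior path pixels,
#' endpoint vertex pixels excluded) and the chord length (Euclidean
#' distance between the two endpoint vertex coordinates).
#'
#' @param g a [skeleton_graph].
#' @return data.frame with `edge`, `pixel_path_length`, `chord_length`.
#' @export
branch_length <- function(g) {
  if (!length(g$edges))
    return(data.frame(edge = integer(0), pixel_path_length = numeric(0),
                      chord_length = numeric(0)))
  v <- g$vertices
  do.call(rbind, lapply(g$edges, function(e) data.frame(
    edge = e$id,
    pixel_path_length = nrow(e$path),
    chord_length = sqrt((v$row[e$v1] - v$row[e$v2])^2 +
                          (v$col[e$v1] - v$col[e$v2])^2))))
}

#' Branch angle (ba)
#'
#' Per junction, the opening angle between each pair of child branches
#' under the DFS orientation: the angle (in degrees, in `[0, 180]`)
#' between the two vectors originating at the junction along each child
#' path.
#'
#' Probe rules. `"direction"` (default) takes each child's vector as the
#' principal-component direction of the path pixels just beyond the
#' junction disc (a window of about 1.6 junction diameters): thinning
#' retracts the junction pixel into the crotch between the children, so
#' vectors *to* nearby points are biased outward, while fitted directions
#' are free of that origin bias. `"far_db"` uses the vector from the
#' junction pixel to the path pixel at `probe_factor` junction diameters
#' (capped at the path end) -- mostly unbiased for wide openings.
#' `"first_db"` uses the vector to the centre of the first
#' branch-thickness disc on each child, the most literal reading of the
#' disc construction; it overestimates sharp openings.
#'
#' @param g a [skeleton_graph] with DFS orientation (see [traverse_dfs()]).
#' @param dm distance map (needed by both probe rules).
#' @param db branch-thickness table from [branch_thickness()]; only needed
#'   for `probe = "first_db"`.
#' @param da junction-thickness table; sets the local probe distance for
#'   `"far_db"` (falls back to the distance map at the junction pixel).
#' @param probe probe rule, `"far_db"` or `"first_db"`.
#' @param probe_factor multiples of the junction-thickness diameter at
#'   which `"far_db"` probes (default 3.5).
#' @return data.frame with `junction`, `edge1`, `edge2`, `angle_deg`.
#' @export
branch_angle <- function(g, dm, db = NULL, da = NULL,
                         probe = c("direction", "far_db", "first_db"),
                         probe_factor = 3.5) {
  probe <- match.arg(probe)
  out <- list()
  juncs <- g$vertices$id[g$vertices$kind == "junction"]
  for (j in juncs) {
    jc <- c(g$vertices$row[j], g$vertices$col[j])
    da_dia <- if (!is.null(da) && j %in% da$vertex)
      da$diameter_px[which(da$vertex == j)[1L]] else 2 * dm[jc[1L], jc[2L]]
    kids <- Filter(function(e) !is.na(e$parent) && e$parent == j, g$edges)
    if (length(kids) < 2L) {
      if (length(kids) == 1L)
        warning("junction ", j, " has a single child edge; no angle emitted")
      next
    }
    vecs <- lapply(kids, function(e) {
      p <- oriented_path(g, e, j)
      tgt <- NULL
      if (probe == "first_db" && !is.null(db)) {
        hit <- db[db$edge == e$id, ]
        if (nrow(hit)) tgt <- c(hit$row[1L], hit$col[1L])
      }
      if (probe == "direction" && nrow(p) >= 4L) {
        v <- fit_initial_direction(p, jc, da_dia)
        if (!is.null(v)) return(v)
      }
      if (is.null(tgt)) {
        if (nrow(p)) {
          want <- probe_factor * da_dia
          steps <- sqrt(rowSums((p - rbind(jc, p[-nrow(p), , drop = FALSE]))^2))
          arc <- cumsum(steps)
          i <- if (any(arc >= want)) which(arc >= want)[1L] else nrow(p)
          tgt <- p[i, ]
        } else {
          o <- if (e$v1 == j) e$v2 else e$v1
          tgt <- c(g$vertices$row[o], g$vertices$col[o])
        }
      }
      tgt - jc
    })
    ids <- vapply(kids, function(e) e$id, integer(1))
    for (a in seq_along(vecs)) for (b in seq_along(vecs)) {
      if (a >= b) next
      u <- vecs[[a]]; v <- vecs[[b]]
      nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
      if (nu == 0 || nv == 0) next
      cs <- sum(u * v) / (nu * nv)
      out[[length(out) + 1L]] <- data.frame(
        junction = j, edge1 = ids[a], edge2 = ids[b],
        angle_deg = acos(pmin(1, pmax(-1, cs))) * 180 / pi)
    }
  }
  if (!length(out))
    return(data.frame(junction = integer(0), edge1 = integer(0),
                      edge2 = integer(0), angle_deg = numeric(0)))
  do.call(rbind, out)
}

# direction of the initial stretch of a child path, fitted by the first
# principal component of the path pixels with arc distance in
# [0.6, 2.2] junction diameters from the junction (skipping the crotch
# zone where the skeleton bends toward the junction pixel); oriented away
# from the junction. NULL when fewer than 4 pixels fall in the window.
#' @keywords internal
#' @noRd
fit_initial_direction <- function(p, jc, da_dia) {
  steps <- sqrt(rowSums((p - rbind(jc, p[-nrow(p), , drop = FALSE]))^2))
  arc <- cumsum(steps)
  lo <- 0.6 * da_dia
  hi <- lo + max(12, 1.6 * da_dia)
  sel <- arc >= lo & arc <= hi
  if (sum(sel) < 4L) sel <- arc <= hi          # short path: use it all
  if (sum(sel) < 4L) return(NULL)
  pts <- p[sel, , drop = FALSE]
  ctr <- colMeans(pts)
  v <- eigen(stats::cov(pts), symmetric = TRUE)$vectors[, 1L]
  if (sum(v * (ctr - jc)) < 0) v <- -v
  v
}

#' Terminal spacing (bs)
#'
#' For every skeleton tip, the Euclidean distance to its nearest other tip
#' (one value per terminal; symmetric pairs are both retained). With fewer
#' than two terminals an empty table is returned with a warning.
#'
#' @param g a [skeleton_graph].
#' @return data.frame with `terminal`, `row`, `col`, `distance_px`.
#' @export
terminal_spacing <- function(g) {
  v <- g$vertices[g$vertices$kind == "terminal", ]
  if (nrow(v) < 2L) {
    warning("fewer than two terminals; no spacing measurements")
    return(data.frame(terminal = integer(0), row = integer(0),
                      col = integer(0), distance_px = numeric(0)))
  }
  d2 <- outer(v$row, v$row, "-")^2 + outer(v$col, v$col, "-")^2
  diag(d2) <- Inf
  data.frame(terminal = v$id, row = v$row, col = v$col,
             distance_px = sqrt(apply(d2, 1L, min)))
}
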
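#' Skeleton image
#'
#' A single-pixel-wide skeleton raster together with its classified feature
#' pixels. `junctions` holds one representative coordinate per junction
#' (adjacent junction pixels are merged into a cluster, see
#' [classify_features()]); `terminals` holds the skeleton tips.
#'
#' @param mask logical matrix of skeleton pixels.
#' @return An object of class `skeleton_image` with fields `mask`,
#'   `junctions` (n x 2 matrix of row/col), `junction_clusters` (list of
#'   matrices, all member pixels per junction), `terminals` (n x 2 matrix)
#'   and `loop_report` (see [detect_loops()]).
#' @export
skeleton_image <- function(mask) {
  stopifnot(is.matrix(mask))
  structure(list(mask = mask & TRUE,
                 junctions = NULL, junction_clusters = NULL,
                 terminals = NULL, loop_report = NULL),
            class = "skeleton_image")
}

#' @export
print.skeleton_image <- function(x, ...) {
  cat(sprintf("<skeleton_image> %d x %d px, %d skeleton px\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask)))
  if (!is.null(x$junctions))
    cat(sprintf("  %d junctions, %d terminals\n",
                nrow(x$junctions), nrow(x$terminals)))
  if (!is.null(x$loop_report))
    cat(sprintf("  %d loops\n", x$loop_report$count))
  invisible(x)
}

#' Zhang-Suen thinning
#'
#' Reduces a binary object to a single-pixel-wide skeleton by the classic
#' two-subiteration thinning scheme: boundary pixels are deleted in
#' alternating passes (conditions on the 8-neighbourhood: neighbour count in
#' 2..6, exactly one 0-to-1 transition around the pixel, and the directional
#' products that keep north-west resp. south-east boundaries in alternate
#' passes) until a full double pass deletes nothing. Topology (8-connected
#' foreground components and 4-connected holes) is preserved for objects at
#' least 3 px across; degenerate 2 px wide diagonal bars are a known
#' limitation of the scheme itself.
#'
#' @param binary a [binary_image()] or logical matrix.
#' @return A [skeleton_image()] (features not yet classified).
#' @export
thin_zhang_suen <- function(binary) {
  m <- if (inherits(binary, "binary_image")) binary$mask else (binary & TRUE)
  h <- nrow(m); w <- ncol(m)
  if (!any(m)) return(skeleton_image(m))
  p <- pad_mask(m)
  sv <- function(dr, dc) shift_view(p, h, w, dr, dc)
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      cur <- p[2:(h + 1L), 2:(w + 1L)]
      p2 <- sv(-1L, 0L); p3 <- sv(-1L, 1L); p4 <- sv(0L, 1L); p5 <- sv(1L, 1L)
      p6 <- sv(1L, 0L);  p7 <- sv(1L, -1L); p8 <- sv(0L, -1L); p9 <- sv(-1L, -1L)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
           (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      del <- cur & b >= 2L & b <= 6L & a == 1L
      del <- if (pass == 1L) del & !(p2 & p4 & p6) & !(p4 & p6 & p8)
             else            del & !(p2 & p4 & p8) & !(p2 & p6 & p8)
      if (any(del)) {
        changed <- TRUE
        cur[del] <- FALSE
        p[2:(h + 1L), 2:(w + 1L)] <- cur
      }
    }
    if (!changed) break
  }
  skeleton_image(p[2:(h + 1L), 2:(w + 1L)])
}

#' Classify junction and terminal pixels of a skeleton
#'
#' A terminal is a skeleton pixel with exactly one neighbour, a junction
#' pixel one with three or more, both under the package's reduced
#' 8-adjacency (diagonal neighbours that are shortcut by a foreground
#' orthogonal pixel are not counted -- plain 8-adjacency misreads staircase
#' pixels of diagonal runs as junctions). Isolated single-pixel skeletons
#' are classified as terminals. Adjacent junction pixels are merged into one
#' junction whose coordinate is the cluster member nearest the cluster
#' centroid (ties broken lexicographically).
#'
#' @param skel a [skeleton_image()] (or logical matrix).
#' @return The skeleton with `junctions`, `junction_clusters` and
#'   `terminals` filled in.
#' @export
classify_features <- function(skel) {
  if (is.matrix(skel)) skel <- skeleton_image(skel)
  m <- skel$mask
  deg <- reduced_degree(m)
  term <- which(m & (deg <= 1L), arr.ind = TRUE)
  jpix <- m & (deg >= 3L)
  clusters <- list()
  reps <- matrix(integer(0), 0L, 2L)
  if (any(jpix)) {
    lab <- label_components(jpix, connectivity = 8)
    for (k in seq_len(max(lab))) {
      px <- which(lab == k, arr.ind = TRUE)
      ctr <- colMeans(px)
      d2 <- (px[, 1L] - ctr[1L])^2 + (px[, 2L] - ctr[2L])^2
      ord <- order(d2, px[, 1L], px[, 2L])
      clusters[[k]] <- px
      reps <- rbind(reps, px[ord[1L], , drop = FALSE])
    }
  }
  colnames(reps) <- c("row", "col")
  if (nrow(term)) colnames(term) <- c("row", "col")
  skel$junctions <- reps
  skel$junction_clusters <- clusters
  skel$terminals <- term
  skel
}

# walk from a terminal pixel to the first junction-cluster pixel (or the
# far end); used by pruning. Returns list(path = matrix of pixels starting
# at the terminal, end = "junction"|"terminal"|"none", stop_px).
#' @keywords internal
#' @noRd
walk_spur <- function(mask, deg, start) {
  h <- nrow(mask)
  path <- matrix(start, 1L, 2L)
  prev <- c(NA_integer_, NA_integer_)
  cur <- start
  repeat {
    nb <- reduced_neighbors(mask, cur)
    if (!is.na(prev[1L]))
      nb <- nb[!(nb[, 1L] == prev[1L] & nb[, 2L] == prev[2L]), , drop = FALSE]
    if (nrow(nb) == 0L)
      return(list(path = path, end = "terminal", stop_px = NULL))
    if (nrow(nb) > 1L)  # reached a branching point without entering it
      return(list(path = path, end = "junction", stop_px = nb[1L, ]))
    nxt <- nb[1L, ]
    if (deg[nxt[1L], nxt[2L]] >= 3L)
      return(list(path = path, end = "junction", stop_px = nxt))
    prev <- cur; cur <- nxt
    path <- rbind(path, cur)
    if (deg[cur[1L], cur[2L]] <= 1L)
      return(list(path = path, end = "terminal", stop_px = NULL))
  }
}

# reduced-adjacency neighbours of one pixel
#' @keywords internal
#' @noRd
reduced_neighbors <- function(mask, px) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(integer(0), 0L, 2L)
  at <- function(r, c) r >= 1L && r <= h && c >= 1L && c <= w && mask[r, c]
  for (k in seq_len(nrow(NEIGH8))) {
    r <- px[1L] + NEIGH8[k, 1L]; c <- px[2L] + NEIGH8[k, 2L]
    if (!at(r, c)) next
    if (NEIGH8[k, 1L] != 0L && NEIGH8[k, 2L] != 0L) {
      if (at(px[1L] + NEIGH8[k, 1L], px[2L]) || at(px[1L], px[2L] + NEIGH8[k, 2L]))
        next
    }
    out <- rbind(out, c(r, c))
  }
  out
}

#' Prune spurious terminal branches
#'
#' Spurs -- short skeleton branches ending in a terminal, typically created
#' by boundary irregularities during thinning -- are removed when their
#' pixel-path length is below a threshold, and classification is re-run;
#' pruning iterates until no sub-threshold spur remains. A whole component
#' that is a simple terminal-to-terminal path is never removed, and
#' junction-to-junction branches are never touched, so the skeleton is
#' never disconnected.
#'
#' If a distance map is supplied the threshold adapts per spur to
#' `max(min_length, EDT at the parent junction)` -- i.e. half the local
#' junction-thickness disc -- so that crotch artefacts scale with branch
#' width.
#'
#' @param skel a classified [skeleton_image()].
#' @param min_length minimum pixel-path length a terminal branch must have
#'   to survive; 0 is the identity.
#' @param dm optional distance map of the source blob (see [distance_map()]).
#' @return A pruned, re-classified [skeleton_image()].
#' @export
prune_spurs <- function(skel, min_length = 3, dm = NULL) {
  stopifnot(inherits(skel, "skeleton_image"))
  if (is.null(skel$terminals)) skel <- classify_features(skel)
  if (min_length <= 0 && is.null(dm)) return(skel)
  m <- skel$mask
  repeat {
    deg <- reduced_degree(m)
    terms <- which(m & deg == 1L, arr.ind = TRUE)
    removed <- FALSE
    kill <- matrix(integer(0), 0L, 2L)
    for (i in seq_len(nrow(terms))) {
      tpx <- terms[i, ]
      if (!m[tpx[1L], tpx[2L]]) next
      wk <- walk_spur(m, deg, c(tpx[1L], tpx[2L]))
      if (wk$end != "junction") next   # whole-path component: keep
      thr <- min_length
      if (!is.null(dm)) thr <- max(thr, dm[wk$stop_px[1L], wk$stop_px[2L]])
      if (nrow(wk$path) < thr) {
        kill <- rbind(kill, wk$path)
        removed <- TRUE
      }
    }
    if (!removed) break
    m[kill] <- FALSE
  }
  classify_features(skeleton_image(m))
}

#' Detect loops in a skeleton
#'
#' Counts the independent cycles of the skeleton's pixel graph (reduced
#' 8-adjacency): `E - V + C` over edges, vertices and connected components,
#' and reports the pixel coordinates of one fundamental cycle per
#' independent loop (non-tree edge closed through a spanning forest).
#' Loops arise from overlapping branches in the source image; automatic
#' loop breaking is deliberately not attempted -- see [break_loop()] for
#' the explicit, user-directed edit.
#'
#' @param skel a [skeleton_image()] (or logical matrix).
#' @return A list with `count` and `cycles` (list of n x 2 coordinate
#'   matrices).
#' @export
detect_loops <- function(skel) {
  m <- if (inherits(skel, "skeleton_image")) skel$mask else (skel & TRUE)
  h <- nrow(m)
  fg <- which(m)
  if (!length(fg)) return(list(count = 0L, cycles = list()))
  ed <- pixel_edges(m, "reduced")
  g <- igraph::graph_from_edgelist(
    cbind(match(ed[, 1L], fg), match(ed[, 2L], fg)), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
  ncomp <- igraph::components(g)$no
  count <- igraph::ecount(g) - igraph::vcount(g) + ncomp
  cycles <- list()
  if (count > 0L) {
    igraph::E(g)$eid <- seq_len(igraph::ecount(g))
    forest <- igraph::mst(g)
    extra <- setdiff(seq_len(igraph::ecount(g)), igraph::E(forest)$eid)
    all_e <- igraph::as_edgelist(g, names = FALSE)
    for (ei in extra) {
      uv <- all_e[ei, ]
      sp <- suppressWarnings(
        igraph::shortest_paths(forest, from = uv[1L], to = uv[2L])$vpath[[1L]])
      cyc <- fg[as.integer(sp)]
      cycles[[length(cycles) + 1L]] <- lin_to_rc(cyc, h)
    }
  }
  list(count = as.integer(count), cycles = cycles)
}

#' Break a loop by inserting a one-pixel-wide gap in the binary image
#'
#' Carves a narrow background gap across a branch of the *binary* image at
#' a user-chosen location so that re-skeletonization yields separated
#' branches. The cut is specified by two adjacent foreground pixels giving
#' the local branch direction; the gap is the slab of foreground pixels
#' perpendicular to that direction through the first pixel, extended until
#' background on both sides (two pixel rows for diagonal cuts, where a
#' single row would not break 8-connectivity). The foreground component
#' count increases by at most one.
#'
#' @param binary a [binary_image()].
#' @param cut 2 x 2 matrix (or length-4 vector) of two adjacent pixel
#'   coordinates `(row, col)` on the branch to cut.
#' @return The edited [binary_image()].
#' @export
break_loop <- function(binary, cut) {
  stopifnot(inherits(binary, "binary_image"))
  cut <- matrix(as.integer(cut), 2L, 2L, byrow = is.vector(cut))
  m <- binary$mask
  p <- cut[1L, ]; q <- cut[2L, ]
  if (!m[p[1L], p[2L]] || !m[q[1L], q[2L]])
    stop("cut pixels must lie on the foreground")
  v <- q - p
  if (max(abs(v)) != 1L) stop("cut pixels must be 8-adjacent")
  vhat <- v / sqrt(sum(v^2))
  # flood within the slab 0 <= (x - p).vhat < 0.99 from p
  h <- nrow(m); w <- ncol(m)
  inslab <- function(px) {
    d <- sum((px - p) * vhat)
    d >= -1e-9 && d < 0.99
  }
  queue <- list(p)
  gap <- matrix(p, 1L, 2L)
  seen <- matrix(FALSE, h, w)
  seen[p[1L], p[2L]] <- TRUE
  while (length(queue)) {
    cur <- queue[[1L]]; queue <- queue[-1L]
    for (k in seq_len(nrow(NEIGH8))) {
      r <- cur[1L] + NEIGH8[k, 1L]; c <- cur[2L] + NEIGH8[k, 2L]
      if (r < 1L || r > h || c < 1L || c > w) next
      if (seen[r, c] || !m[r, c]) next
      if (!inslab(c(r, c))) next
      seen[r, c] <- TRUE
      queue[[length(queue) + 1L]] <- c(r, c)
      gap <- rbind(gap, c(r, c))
    }
  }
  m[gap] <- FALSE
  prov <- binary$provenance
  prov$loop_cuts <- c(prov$loop_cuts, list(cut))
  binary_image(m, pixel_scale = binary$pixel_scale, provenance = prov)
}

#' Write a feature overlay PNG of a skeleton
#'
#' Foreground in yellow, skeleton in green, junctions light blue, terminals
#' pink and the root terminal white.
#'
#' @param skel a classified [skeleton_image()].
#' @param path output PNG path.
#' @param binary optional source [binary_image()] drawn underneath.
#' @param root optional root terminal coordinate drawn in white.
#' @export
write_skeleton_overlay <- function(skel, path, binary = NULL, root = NULL) {
  m <- skel$mask
  img <- array(0, c(nrow(m), ncol(m), 3L))
  if (!is.null(binary)) {
    fg <- binary$mask
    img[, , 1L][fg] <- 1; img[, , 2L][fg] <- 1; img[, , 3L][fg] <- 0.2
  }
  img[, , 1L][m] <- 0; img[, , 2L][m] <- 0.8; img[, , 3L][m] <- 0
  paint <- function(px, col) {
    for (i in seq_len(nrow(px)))
      img[px[i, 1L], px[i, 2L], ] <<- col
  }
  if (!is.null(skel$junctions) && nrow(skel$junctions))
    paint(skel$junctions, c(0.4, 0.8, 1))
  if (!is.null(skel$terminals) && nrow(skel$terminals))
    paint(skel$terminals, c(1, 0.4, 0.7))
  if (!is.null(root)) paint(matrix(root, 1L), c(1, 1, 1))
  png::writePNG(img, path)
  invisible(path)
}
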
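#' Specification of a synthetic branching thallus
#'
#' Parameters of the recursive generator in [generate_thallus()]. Branches
#' are tapered capsules (stroked segments with round caps): generation 0 is
#' the main axis, each internal branch spawns two children at the sibling
#' angle. Widths taper across generations from `width_junction` at the base
#' through `width_branch` mid-depth to `width_terminal` at the tips, so the
#' junction > branch > terminal thickness ordering of real pinnate thalli
#' holds by construction; set the three equal for constant-width fixtures.
#'
#' @param depth branching generations (0 = a single bar).
#' @param branch_length base branch length in px.
#' @param length_decay multiplicative length decay per generation.
#' @param width_junction,width_branch,width_terminal tapering profile in
#'   px; must satisfy `width_junction >= width_branch >= width_terminal > 0`.
#' @param branch_angle sibling opening angle between the two children of a
#'   junction, in degrees, in (0, 180).
#' @param orientation direction of the main axis in degrees (90 = straight
#'   up the canvas). The default, 60, tilts the specimen off the
#'   pixel axes the way a real specimen lies on a slide at an arbitrary
#'   orientation; exactly axis- or diagonal-aligned strokes are degenerate
#'   rasters for any thinning scheme (the published two-subiteration
#'   deletion conditions erode perfect 45-degree strokes of even width).
#' @param jitter positional noise amplitude in px (uniform displacement of
#'   branch endpoints; the recorded ground truth is the realized, jittered
#'   geometry).
#' @param overlap add a crossing bar between the first junction's two
#'   subtrees, creating a loop (for loop-handling fixtures).
#' @param seed RNG seed; generation is deterministic given the spec.
#' @return An object of class `thallus_spec`.
#' @export
thallus_spec <- function(depth = 2, branch_length = 60, length_decay = 0.85,
                         width_junction = 15, width_branch = 11,
                         width_terminal = 7, branch_angle = 90,
                         orientation = 60, jitter = 0, overlap = FALSE,
                         seed = 1) {
  stopifnot(depth >= 0, branch_length > 0, length_decay > 0,
            width_junction >= width_branch,
            width_branch >= width_terminal, width_terminal > 0,
            branch_angle > 0, branch_angle < 180, jitter >= 0)
  structure(list(depth = as.integer(depth), branch_length = branch_length,
                 length_decay = length_decay,
                 width_junction = width_junction,
                 width_branch = width_branch,
                 width_terminal = width_terminal,
                 branch_angle = branch_angle, orientation = orientation,
                 jitter = jitter,
                 overlap = isTRUE(overlap), seed = as.integer(seed)),
            class = "thallus_spec")
}

# station widths: piecewise linear junction -> branch -> terminal over
# generations 0..depth+1
#' @keywords internal
#' @noRd
station_widths <- function(spec) {
  n <- spec$depth + 1L
  st <- numeric(n + 1L)
  if (n == 1L) {
    st <- c(spec$width_junction, spec$width_terminal)
  } else {
    mid <- ceiling(n / 2)
    st[1:(mid + 1L)] <- seq(spec$width_junction, spec$width_branch,
                            length.out = mid + 1L)
    st[(mid + 1L):(n + 1L)] <- seq(spec$width_branch, spec$width_terminal,
                                   length.out = n - mid + 1L)
  }
  st
}

# crotch geometry at a symmetric junction of three strokes of width w:
# parent entering along +x, children leaving at +/- theta/2 from +x
# (theta in degrees). The background near the junction consists of three
# convex wedges, each bounded by the w/2-offset lines of two adjacent
# strokes; the analytic distance-to-background of a point is the minimum
# of its distances to those wedges, and the expected junction-thickness
# disc is its maximum over the parent/bisector axis (where thinning puts
# the junction pixel). Computed numerically from the exact continuous
# geometry -- no rasterization involved.
#' @keywords internal
#' @noRd
crotch_geometry <- function(w, theta) {
  th <- theta * pi / 180
  dirs <- cbind(c(cos(th / 2), sin(th / 2)),     # child 1
                c(cos(-th / 2), sin(-th / 2)),   # child 2
                c(-1, 0))                        # parent (points backwards)
  # background wedge between adjacent rays u, v: points at >= w/2 from
  # both centrelines, i.e. the intersection of two half-planes whose
  # boundary lines are the offset stroke sides; convex, so the distance
  # from an interior point is the min distance to its two boundary rays
  wedge_dist <- function(p, u, v) {
    # inner normals (pointing from the wedge towards the strokes)
    nu <- c(-u[2L], u[1L]); if (sum(nu * v) < 0) nu <- -nu
    nv <- c(-v[2L], v[1L]); if (sum(nv * u) < 0) nv <- -nv
    # wedge corner: on both w/2 offset lines, gap side
    corner <- solve(rbind(nu, nv), c(w / 2, w / 2))
    du <- sum(nu * (p - corner)); dv <- sum(nv * (p - corner))
    if (du >= 0 && dv >= 0) return(0)   # inside the wedge
    ray_dist <- function(dirray) {
      t <- sum((p - corner) * dirray)
      q <- corner + max(0, t) * dirray
      sqrt(sum((p - q)^2))
    }
    min(ray_dist(u), ray_dist(v))
  }
  edt <- function(p) min(wedge_dist(p, dirs[, 1L], dirs[, 2L]),
                         wedge_dist(p, dirs[, 1L], dirs[, 3L]),
                         wedge_dist(p, dirs[, 2L], dirs[, 3L]))
  ts <- seq(-0.2 * w, 1.5 * w, by = 0.02 * w)
  vals <- vapply(ts, function(t) edt(c(t, 0)), numeric(1))
  i <- which.max(vals)
  list(edt_max = vals[i], offset = ts[i])
}

# discrete thinning ends a skeleton about 1-2.5 px short of a round cap
# centre, growing with cap width (characterized on rendered bars across
# widths 5-25 px and orientations)
#' @keywords internal
#' @noRd
cap_retraction <- function(w) pmin(2.5, 0.5 + w / 10)

#' Generate a synthetic branching thallus with exact ground truth
#'
#' Recursively renders tapered, round-capped branches into a binary raster
#' and records the realized geometry: per-branch centreline, width profile,
#' length and the expected skeleton arc length (corrected for the crotch
#' offset by which thinning retracts each junction); per-junction position,
#' realized sibling angle and the analytic junction-thickness ground truth
#' `2w / (1 + sin(theta/2))` (the largest inscribed disc at the crotch);
#' per-tip coordinates, terminal thickness and nearest-tip spacing.
#'
#' @param spec a [thallus_spec()].
#' @param pixel_scale optional scale carried into the binary image.
#' @return list with `image` (a [binary_image()]) and `truth` (lists
#'   `branches`, `junctions`, `tips`, plus `cut` when `overlap = TRUE`:
#'   a 2 x 2 pixel pair usable with [break_loop()]).
#' @export
generate_thallus <- function(spec, pixel_scale = NULL) {
  stopifnot(inherits(spec, "thallus_spec"))
  rng_state <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(rng_state)) assign(".Random.seed", rng_state, .GlobalEnv))
  set.seed(spec$seed)

  stw <- station_widths(spec)
  segs <- list()
  junctions <- list()
  tips <- list()
  branches <- list()
  # grow in continuous (x up, y right) = (-row, col) coordinates from origin
  grow <- function(a, dir_deg, gen, parent_theta) {
    L <- spec$branch_length * spec$length_decay^gen
    th <- dir_deg * pi / 180
    b <- a + L * c(cos(th), sin(th))
    if (spec$jitter > 0)
      b <- b + stats::runif(2, -spec$jitter, spec$jitter)
    wa <- stw[gen + 1L]; wb <- stw[gen + 2L]
    segs[[length(segs) + 1L]] <<- list(a = a, b = b, wa = wa, wb = wb)
    bid <- length(branches) + 1L
    branches[[bid]] <<- list(id = bid, gen = gen, a = a, b = b,
                             wa = wa, wb = wb,
                             length = sqrt(sum((b - a)^2)),
                             dir_deg = atan2(b[2] - a[2], b[1] - a[1]) * 180 / pi)
    if (gen < spec$depth) {
      half <- spec$branch_angle / 2
      jit <- if (spec$jitter > 0) stats::runif(2, -spec$jitter, spec$jitter) else c(0, 0)
      d1 <- branches[[bid]]$dir_deg - half + jit[1L]
      d2 <- branches[[bid]]$dir_deg + half + jit[2L]
      theta_real <- d2 - d1
      cg <- crotch_geometry(wb, theta_real)
      junctions[[length(junctions) + 1L]] <<- list(
        pos = b, parent_branch = bid, width = wb,
        sibling_angle = theta_real, da_true = 2 * cg$edt_max,
        offset = cg$offset, parent_dir = branches[[bid]]$dir_deg)
      k1 <- grow(b, d1, gen + 1L, theta_real)
      k2 <- grow(b, d2, gen + 1L, theta_real)
      branches[[bid]]$children <<- c(k1, k2)
    } else {
      tips[[length(tips) + 1L]] <<- list(pos = b, branch = bid, dc_true = wb)
    }
    bid
  }
  grow(c(0, 0), spec$orientation - 90, 0L, NA_real_)
  # the base of the main axis is also a tip of the skeleton
  tips[[length(tips) + 1L]] <- list(pos = c(0, 0), branch = 1L,
                                    dc_true = stw[1L], base = TRUE)

  # the recorded tip truth is the expected *skeleton* tip: the cap centre
  # pulled back by the thinning cap retraction
  for (i in seq_along(tips)) {
    b <- branches[[tips[[i]]$branch]]
    dirv <- (b$b - b$a) / sqrt(sum((b$b - b$a)^2))
    if (isTRUE(tips[[i]]$base)) dirv <- -dirv   # base cap points backwards
    tips[[i]]$pos_geom <- tips[[i]]$pos
    tips[[i]]$pos <- tips[[i]]$pos - cap_retraction(tips[[i]]$dc_true) * dirv
  }

  cut <- NULL
  if (spec$overlap && length(junctions)) {
    j <- junctions[[1L]]
    kids <- branches[[j$parent_branch]]$children
    m1 <- (branches[[kids[1L]]]$a + branches[[kids[1L]]]$b) / 2
    m2 <- (branches[[kids[2L]]]$a + branches[[kids[2L]]]$b) / 2
    segs[[length(segs) + 1L]] <- list(a = m1, b = m2,
                                      wa = spec$width_terminal,
                                      wb = spec$width_terminal)
    cut_mid <- (m1 + m2) / 2
    cut_dir <- (m2 - m1) / sqrt(sum((m2 - m1)^2))
    cut <- rbind(cut_mid, cut_mid + cut_dir)  # continuous, converted below
  }

  # --- rasterize ---------------------------------------------------------
  allpts <- do.call(rbind, lapply(segs, function(s) rbind(s$a, s$b)))
  margin <- max(stw) + 4
  xmin <- min(allpts[, 1L]) - margin; xmax <- max(allpts[, 1L]) + margin
  ymin <- min(allpts[, 2L]) - margin; ymax <- max(allpts[, 2L]) + margin
  h <- ceiling(xmax - xmin) + 1L; w <- ceiling(ymax - ymin) + 1L
  # continuous (x, y) -> pixel (row, col): row = xmax - x, col = y - ymin
  to_px <- function(p) c(xmax - p[1L] + 1, p[2L] - ymin + 1)
  rr <- matrix(rep(seq_len(h), w), h, w)
  cc <- matrix(rep(seq_len(w), each = h), h, w)
  xs <- xmax - rr + 1; ys <- cc + ymin - 1
  m <- matrix(FALSE, h, w)
  for (s in segs) {
    ab <- s$b - s$a; L2 <- sum(ab^2)
    t <- if (L2 == 0) 0 else
      pmin(1, pmax(0, ((xs - s$a[1L]) * ab[1L] + (ys - s$a[2L]) * ab[2L]) / L2))
    dx <- xs - (s$a[1L] + t * ab[1L]); dy <- ys - (s$a[2L] + t * ab[2L])
    wd <- s$wa + t * (s$wb - s$wa)
    m <- m | (dx * dx + dy * dy <= (wd / 2)^2)
  }

  # --- ground-truth tables in pixel coordinates --------------------------
  jdf <- if (length(junctions)) do.call(rbind, lapply(junctions, function(j) {
    px <- to_px(j$pos)
    data.frame(row = px[1L], col = px[2L], width = j$width,
               sibling_angle = j$sibling_angle, da_true = j$da_true,
               offset = j$offset, parent_branch = j$parent_branch)
  })) else data.frame()
  tdf <- do.call(rbind, lapply(tips, function(tp) {
    px <- to_px(tp$pos); pg <- to_px(tp$pos_geom)
    data.frame(row = px[1L], col = px[2L],
               row_geom = pg[1L], col_geom = pg[2L], branch = tp$branch,
               dc_true = tp$dc_true)
  }))
  if (nrow(tdf) >= 2L) {
    d2 <- outer(tdf$row, tdf$row, "-")^2 + outer(tdf$col, tdf$col, "-")^2
    diag(d2) <- Inf
    tdf$bs_true <- sqrt(apply(d2, 1L, min))
  }
  # expected skeleton arc length per branch: geometric length, extended by
  # the crotch offset at an internal end (thinning retracts the junction
  # into the crotch), shortened by the projected crotch offset at the
  # start and by the cap retraction at terminal/base ends
  joff <- function(bid) {
    hit <- which(vapply(junctions, function(j) j$parent_branch == bid, logical(1)))
    if (length(hit)) junctions[[hit[1L]]]$offset
    else -cap_retraction(branches[[bid]]$wb)
  }
  parent_of <- integer(length(branches))
  for (b in branches) if (!is.null(b$children)) parent_of[b$children] <- b$id
  bdf <- do.call(rbind, lapply(branches, function(b) {
    start_corr <- if (b$gen == 0L) cap_retraction(b$wa) else 0
    if (b$gen > 0L) {
      pj <- junctions[[which(vapply(junctions, function(j)
        j$parent_branch == parent_of[b$id], logical(1)))[1L]]]
      start_corr <- pj$offset * cos(pj$sibling_angle / 2 * pi / 180)
    }
    apx <- to_px(b$a); bpx <- to_px(b$b)
    data.frame(id = b$id, gen = b$gen,
               row_a = apx[1L], col_a = apx[2L],
               row_b = bpx[1L], col_b = bpx[2L],
               width_a = b$wa, width_b = b$wb, length = b$length,
               skeleton_length_true = b$length + joff(b$id) - start_corr)
  }))

  if (!is.null(cut)) {
    p1 <- round(to_px(cut[1L, ])); p2 <- round(to_px(cut[2L, ]))
    if (all(p1 == p2)) p2 <- p1 + c(0L, 1L)
    p2 <- p1 + sign(p2 - p1) * pmin(abs(p2 - p1), 1L)
    cut <- rbind(p1, p2)
  }

  list(image = binary_image(m, pixel_scale = pixel_scale,
                            provenance = list(generator = "thallus_spec",
                                              seed = spec$seed)),
       truth = list(branches = bdf, junctions = jdf, tips = tdf, cut = cut,
                    spec = spec))
}

#' Default per-group distribution parameters for the six variables
#'
#' Group means and standard deviations (in mm and degrees) representative
#' of the four taxonomic groups of pinnate liverwort thalli the pipeline
#' is designed around; used by [generate_group_tables()] to simulate
#' measurement tables at realistic magnitudes. The ordering junction >
#' branch > terminal thickness holds in every group.
#'
#' @return A list with one element per group, each holding `n`, `mean` and
#'   `sd` vectors over `da`, `db`, `dc`, `bl`, `bs`, `ba`.
#' @export
example_group_params <- function() {
  v <- c("da", "db", "dc", "bl", "bs", "ba")
  g <- function(n, mean, sd)
    list(n = n, mean = stats::setNames(mean, v), sd = stats::setNames(sd, v))
  list(
    amazonica_AF = g(37, c(0.40, 0.28, 0.18, 1.03, 0.99, 119.02),
                     c(0.09, 0.07, 0.05, 0.25, 0.31, 15.94)),
    amazonica_SA = g(26, c(0.49, 0.34, 0.22, 1.31, 1.33, 118.88),
                     c(0.14, 0.08, 0.07, 0.35, 0.30, 18.02)),
    compacta     = g(25, c(0.31, 0.22, 0.15, 1.47, 1.33, 128.19),
                     c(0.05, 0.04, 0.03, 0.46, 0.43, 14.74)),
    obtusa       = g(50, c(0.67, 0.45, 0.29, 1.28, 1.18, 112.69),
                     c(0.06, 0.11, 0.07, 0.28, 0.31, 14.74))
  )
}

#' Simulate a per-specimen measurement table
#'
#' Draws independent normal values per variable and group at the stated
#' means and standard deviations (morphological means of this kind pass
#' normality checks on real material, so Gaussian sampling is the natural
#' emulation); optionally draws correlated variables through a common
#' correlation matrix.
#'
#' @param group_params list as returned by [example_group_params()]: per
#'   group, `n`, named `mean` and `sd` vectors.
#' @param seed RNG seed.
#' @param correlation optional p x p correlation matrix applied within
#'   every group (default: independent draws).
#' @return data.frame with a `group` factor and one column per variable.
#' @export
generate_group_tables <- function(group_params = example_group_params(),
                                  seed = 1, correlation = NULL) {
  rng_state <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(rng_state)) assign(".Random.seed", rng_state, .GlobalEnv))
  set.seed(seed)
  rows <- list()
  for (gname in names(group_params)) {
    gp <- group_params[[gname]]
    stopifnot(all(gp$sd > 0) || gp$n == 0)
    p <- length(gp$mean)
    if (gp$n == 0) next
    z <- matrix(stats::rnorm(gp$n * p), gp$n, p)
    if (!is.null(correlation)) {
      stopifnot(nrow(correlation) == p)
      z <- z %*% chol(correlation)
    }
    x <- sweep(sweep(z, 2L, gp$sd, "*"), 2L, gp$mean, "+")
    colnames(x) <- names(gp$mean)
    rows[[gname]] <- data.frame(group = gname, x)
  }
  if (!length(rows)) {
    nm <- names(group_params[[1L]]$mean)
    out <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(nm)), nm))
    return(cbind(data.frame(group = character(0)), out))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$group <- factor(out$group, levels = names(group_params))
  out
}
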
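# Independent oracle implementations used across the test files. These are
# deliberately written in the most literal (slow) style so that they share
# no code path with the package internals they check.

# Reference Zhang-Suen thinning: per-pixel double loop, conditions written
# out directly from the published deletion rules.
naive_zhang_suen <- function(mask) {
  m <- mask & TRUE
  h <- nrow(m); w <- ncol(m)
  at <- function(r, c) r >= 1 && r <= h && c >= 1 && c <= w && m[r, c]
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      kill <- NULL
      for (i in seq_len(h)) for (j in seq_len(w)) {
        if (!m[i, j]) next
        p2 <- at(i - 1, j); p3 <- at(i - 1, j + 1); p4 <- at(i, j + 1)
        p5 <- at(i + 1, j + 1); p6 <- at(i + 1, j); p7 <- at(i + 1, j - 1)
        p8 <- at(i, j - 1); p9 <- at(i - 1, j - 1)
        seqv <- c(p2, p3, p4, p5, p6, p7, p8, p9, p2)
        b <- sum(seqv[1:8])
        a <- sum(!seqv[1:8] & seqv[2:9])
        if (b < 2 || b > 6 || a != 1) next
        ok <- if (pass == 1)
          !(p2 && p4 && p6) && !(p4 && p6 && p8)
        else
          !(p2 && p4 && p8) && !(p2 && p6 && p8)
        if (ok) kill <- rbind(kill, c(i, j))
      }
      if (!is.null(kill)) {
        changed <- TRUE
        m[kill] <- FALSE
      }
    }
    if (!changed) break
  }
  m
}

# Brute-force Euclidean distance transform: min over all background pixels
# (image border counts as background).
brute_edt <- function(mask) {
  p <- matrix(FALSE, nrow(mask) + 2L, ncol(mask) + 2L)
  p[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  bg <- which(!p, arr.ind = TRUE)
  out <- matrix(0, nrow(mask), ncol(mask))
  fg <- which(mask, arr.ind = TRUE)
  for (i in seq_len(nrow(fg))) {
    r <- fg[i, 1L] + 1L; c <- fg[i, 2L] + 1L
    out[fg[i, 1L], fg[i, 2L]] <-
      sqrt(min((bg[, 1L] - r)^2 + (bg[, 2L] - c)^2))
  }
  out
}

# BFS connected-component count, independent of igraph.
count_components_bfs <- function(mask, conn = 8) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w); k <- 0L
  offs <- if (conn == 4) list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1)) else
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (!mask[i, j] || lab[i, j] > 0L) next
    k <- k + 1L
    queue <- list(c(i, j)); lab[i, j] <- k
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      for (o in offs) {
        r <- p[1L] + o[1L]; c <- p[2L] + o[2L]
        if (r >= 1 && r <= h && c >= 1 && c <= w &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- k
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  k
}

# 4-connected holes (background components not touching the border).
count_holes_bfs <- function(mask) {
  p <- matrix(FALSE, nrow(mask) + 2L, ncol(mask) + 2L)
  p[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  count_components_bfs(!p, conn = 4) - 1L
}

# Random blob: union of discs (radius >= 3) and rectangles (sides >= 4),
# the kind of compact shape thinning is designed for.
random_shape_mask <- function(size = 64) {
  rr <- matrix(rep(seq_len(size), size), size)
  cc <- t(rr)
  m <- matrix(FALSE, size, size)
  for (k in seq_len(sample(3:6, 1))) {
    r0 <- sample(8:(size - 8), 1); c0 <- sample(8:(size - 8), 1)
    rad <- sample(3:8, 1)
    m <- m | ((rr - r0)^2 + (cc - c0)^2 <= rad^2)
  }
  for (k in seq_len(sample(1:3, 1))) {
    r0 <- sample(seq_len(size - 12), 1); c0 <- sample(seq_len(size - 12), 1)
    m[r0:(r0 + sample(3:12, 1)), c0:(c0 + sample(3:12, 1))] <- TRUE
  }
  m
}

# Measure a generated thallus rooted at the terminal nearest its true base
# (the trunk base tip is recorded last in the truth tips table).
measure_rooted <- function(gt, ...) {
  base <- unlist(gt$truth$tips[nrow(gt$truth$tips), c("row", "col")])
  sk <- classify_features(thin_zhang_suen(gt$image))
  sk <- prune_spurs(sk, 3, distance_map(gt$image))
  tr <- sk$terminals
  rt <- tr[which.min((tr[, 1L] - base[1L])^2 + (tr[, 2L] - base[2L])^2), ]
  suppressWarnings(measure_thallus(gt$image, root = rt, ...))
}

# Recursive depth-first traversal oracle with the same child ordering rule
# as the package (initial direction angle, ties by edge id).
recursive_dfs_oracle <- function(g) {
  visited_v <- logical(nrow(g$vertices))
  visited_e <- logical(length(g$edges))
  vorder <- integer(0); eorder <- integer(0)
  ang_of <- function(e, v) {
    vc <- c(g$vertices$row[v], g$vertices$col[v])
    p <- e$path
    if (nrow(p)) {
      d1 <- max(abs(p[1L, ] - vc)); d2 <- max(abs(p[nrow(p), ] - vc))
      tgt <- if (d1 <= d2) p[1L, ] else p[nrow(p), ]
    } else {
      o <- if (e$v1 == v) e$v2 else e$v1
      tgt <- c(g$vertices$row[o], g$vertices$col[o])
    }
    atan2(tgt[2L] - vc[2L], -(tgt[1L] - vc[1L]))
  }
  recurse <- function(v) {
    visited_v[v] <<- TRUE
    vorder <<- c(vorder, v)
    repeat {
      eids <- vapply(g$edges, function(e)
        if ((e$v1 == v || e$v2 == v) && !visited_e[e$id]) e$id else NA_integer_,
        integer(1))
      eids <- eids[!is.na(eids)]
      if (!length(eids)) break
      angs <- vapply(eids, function(ei) ang_of(g$edges[[ei]], v), numeric(1))
      ei <- eids[order(angs, eids)][1L]
      visited_e[ei] <<- TRUE
      eorder <<- c(eorder, ei)
      e <- g$edges[[ei]]
      nxt <- if (e$v1 == v) e$v2 else e$v1
      if (!visited_v[nxt]) recurse(nxt)
    }
  }
  roots <- g$vertices$id[g$vertices$is_root]
  roots <- c(g$root[!is.na(g$root)], setdiff(roots, g$root))
  for (r in roots) if (!visited_v[r]) recurse(r)
  list(vertex_order = vorder, edge_order = eorder)
}

# small hand-built skeleton rasters
skel_line <- function(len = 20) {
  m <- matrix(FALSE, 5, len + 4)
  m[3, 3:(len + 2)] <- TRUE
  m
}
skel_y <- function(arm = 6) {
  n <- 2 * arm + 5
  m <- matrix(FALSE, n, n)
  mid <- arm + 3
  m[mid:(n - 2), mid] <- TRUE            # trunk down
  for (k in 1:arm) {
    m[mid - k, mid - k] <- TRUE          # arm up-left
    m[mid - k, mid + k] <- TRUE          # arm up-right
  }
  m
}
skel_cross <- function(arm = 5) {
  n <- 2 * arm + 5
  m <- matrix(FALSE, n, n)
  mid <- arm + 3
  m[(mid - arm):(mid + arm), mid] <- TRUE
  m[mid, (mid - arm):(mid + arm)] <- TRUE
  m
}
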
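# Internal pixel-adjacency helpers shared by the skeleton and graph layers.
#
# All rasters are logical matrices indexed [row, col] (origin top-left,
# 1-based inside R). Two adjacency notions are used:
#  * plain 8-connectivity, for connected components of blobs and skeletons;
#  * "reduced" 8-adjacency on skeletons, where a diagonal neighbour is
#    ignored whenever one of the two shared orthogonal pixels is itself
#    foreground. Thinned skeletons contain staircase runs in which plain
#    8-degree overcounts (an interior pixel of a diagonal staircase has
#    three 8-neighbours); the reduced adjacency restores degree 2 there and
#    removes the spurious 3-cycles that would corrupt cycle counting.

#' @keywords internal
#' @noRd
pad_mask <- function(m, fill = FALSE) {
  out <- matrix(fill, nrow(m) + 2L, ncol(m) + 2L)
  out[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
  out
}

# shifted view of a padded matrix: value of the (dr,dc) neighbour per pixel
#' @keywords internal
#' @noRd
shift_view <- function(padded, h, w, dr, dc) {
  padded[(2L + dr):(h + 1L + dr), (2L + dc):(w + 1L + dc), drop = FALSE]
}

# the 8 neighbourhood offsets, clockwise from north
NEIGH8 <- cbind(
  dr = c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L),
  dc = c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
)

#' Reduced-adjacency degree of every skeleton pixel
#' @keywords internal
#' @noRd
reduced_degree <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  p <- pad_mask(mask)
  sv <- function(dr, dc) shift_view(p, h, w, dr, dc)
  n  <- sv(-1L, 0L); s  <- sv(1L, 0L); e <- sv(0L, 1L); wv <- sv(0L, -1L)
  ne <- sv(-1L, 1L); se <- sv(1L, 1L); sw <- sv(1L, -1L); nw <- sv(-1L, -1L)
  deg <- n + s + e + wv +
    (ne & !(n | e)) + (se & !(s | e)) + (sw & !(s | wv)) + (nw & !(n | wv))
  deg[!mask] <- 0L
  deg
}

#' Plain 8-connectivity degree
#' @keywords internal
#' @noRd
degree8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  p <- pad_mask(mask)
  deg <- matrix(0L, h, w)
  for (k in seq_len(nrow(NEIGH8)))
    deg <- deg + shift_view(p, h, w, NEIGH8[k, 1L], NEIGH8[k, 2L])
  deg[!mask] <- 0L
  deg
}

# Edge list (pairs of linear pixel indices) of the adjacency graph of the
# foreground of `mask`. connectivity: 4, 8 or "reduced". Each undirected
# pair is listed once.
#' @keywords internal
#' @noRd
pixel_edges <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  idx <- matrix(seq_len(h * w), h, w)
  offs <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))  # S, E, SE, NE
  if (identical(connectivity, 4)) offs <- offs[1:2]
  reduced <- identical(connectivity, "reduced")
  p <- pad_mask(mask)
  from <- integer(0); to <- integer(0)
  for (o in offs) {
    nb <- shift_view(p, h, w, o[1L], o[2L])
    ok <- mask & nb
    if (reduced && (o[1L] != 0L && o[2L] != 0L)) {
      # drop diagonal links covered by an orthogonal pixel
      shared1 <- shift_view(p, h, w, o[1L], 0L)
      shared2 <- shift_view(p, h, w, 0L, o[2L])
      ok <- ok & !(shared1 | shared2)
    }
    wok <- which(ok)
    if (length(wok)) {
      rr <- ((wok - 1L) %% h) + 1L
      cc <- ((wok - 1L) %/% h) + 1L
      from <- c(from, wok)
      to <- c(to, idx[cbind(rr + o[1L], cc + o[2L])])
    }
  }
  cbind(from, to)
}

# Connected-component labels of the foreground. Returns an integer matrix
# (0 on background). Components are relabelled 1..k in order of their
# smallest linear index so labelling is deterministic.
#' @keywords internal
#' @noRd
label_components <- function(mask, connectivity = 8) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  fg <- which(mask)
  if (!length(fg)) return(lab)
  ed <- pixel_edges(mask, connectivity)
  g <- igraph::graph_from_edgelist(
    cbind(match(ed[, 1L], fg), match(ed[, 2L], fg)), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  first <- tapply(seq_along(fg), comp, function(i) min(fg[i]))
  relab <- match(comp, as.integer(names(sort(first))))
  lab[fg] <- relab
  lab
}

#' Number of connected components
#' @keywords internal
#' @noRd
n_components <- function(mask, connectivity = 8) {
  if (!any(mask)) return(0L)
  max(label_components(mask, connectivity))
}

# number of holes: 4-connected background components fully inside minus none;
# the image border is considered connected to the outside, so pad first.
#' @keywords internal
#' @noRd
n_holes <- function(mask) {
  bg <- !pad_mask(mask)
  n_components(bg, connectivity = 4) - 1L
}

#' @keywords internal
#' @noRd
which_rc <- function(mask) {
  which(mask, arr.ind = TRUE)
}

#' @keywords internal
#' @noRd
rc_to_lin <- function(rc, h) (rc[, 2L] - 1L) * h + rc[, 1L]

#' @keywords internal
#' @noRd
lin_to_rc <- function(lin, h) cbind(row = ((lin - 1L) %% h) + 1L,
                                    col = ((lin - 1L) %/% h) + 1L)
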
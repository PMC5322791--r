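#' Skeleton graph
#'
#' Formal graph G = (V, E) of a classified skeleton: vertices are junctions
#' and terminals, edges are the branch paths between them, carried
#' pixel-by-pixel. Junction vertices own their whole merged pixel cluster
#' (so that edge paths stay pairwise disjoint) but expose a single
#' representative coordinate; every skeleton pixel belongs to exactly one
#' vertex or one edge path.
#'
#' @name skeleton_graph
#' @return `build_graph()` returns an object of class `skeleton_graph`:
#'   \describe{
#'     \item{vertices}{data.frame with `id`, `row`, `col`, `kind`
#'       (`"junction"`/`"terminal"`), `component`, `is_root`.}
#'     \item{vertex_pixels}{list of n x 2 matrices, all pixels per vertex.}
#'     \item{edges}{list of `list(id, v1, v2, path, parent, closes_cycle)`;
#'       `path` is an ordered n x 2 matrix of interior pixels (may be
#'       empty), `parent` is filled by [traverse_dfs()].}
#'     \item{root}{vertex id of the designated root terminal (largest
#'       component); every component also has its own root flagged in
#'       `vertices$is_root`.}
#'   }
NULL

#' Build the skeleton graph
#'
#' Vertex pixels (junction clusters and terminals) are removed from the
#' skeleton; the remaining pixels fall apart into chains under the reduced
#' 8-adjacency of the full skeleton, and each chain becomes one edge whose
#' ordered pixel path is recorded. Directly adjacent vertex pairs yield
#' edges with empty paths. If `root` is not given, the terminal with the
#' smallest `(row, col)` in lexicographic order is chosen per connected
#' component; the overall root is the root of the largest component.
#'
#' @param skel a classified [skeleton_image()].
#' @param root optional `(row, col)` of a terminal to use as root.
#' @param on_ring what to do with components that have no terminal (pure
#'   rings): `"error"` (default) or `"drop"` them with a warning.
#' @return A [skeleton_graph] object.
#' @export
build_graph <- function(skel, root = NULL, on_ring = c("error", "drop")) {
  on_ring <- match.arg(on_ring)
  if (is.matrix(skel)) skel <- skeleton_image(skel)
  if (is.null(skel$terminals)) skel <- classify_features(skel)
  m <- skel$mask
  h <- nrow(m); w <- ncol(m)
  if (!any(m)) stop("empty skeleton")
  comp_lab <- label_components(m, connectivity = 8)

  # --- vertices -----------------------------------------------------------
  vkind <- character(0); vrow <- integer(0); vcol <- integer(0)
  vpix <- list()
  for (k in seq_along(skel$junction_clusters)) {
    vkind <- c(vkind, "junction")
    vrow <- c(vrow, skel$junctions[k, 1L]); vcol <- c(vcol, skel$junctions[k, 2L])
    vpix[[length(vpix) + 1L]] <- skel$junction_clusters[[k]]
  }
  for (k in seq_len(nrow(skel$terminals))) {
    vkind <- c(vkind, "terminal")
    vrow <- c(vrow, skel$terminals[k, 1L]); vcol <- c(vcol, skel$terminals[k, 2L])
    vpix[[length(vpix) + 1L]] <- skel$terminals[k, , drop = FALSE]
  }
  nv <- length(vkind)
  vmap <- matrix(0L, h, w)
  for (i in seq_len(nv)) vmap[vpix[[i]]] <- i

  # --- adjacency of the full skeleton, split by pixel role ----------------
  # all edges under reduced adjacency *of the full mask*: diagonal links
  # shortcut by any foreground orthogonal pixel (vertex or chain) are
  # dropped, so distinct branches that touch diagonally across a junction
  # cluster are not merged.
  ed <- pixel_edges(m, "reduced")
  role1 <- vmap[ed[, 1L]]; role2 <- vmap[ed[, 2L]]
  cc_ed <- ed[role1 == 0L & role2 == 0L, , drop = FALSE]   # chain-chain
  nn_ed <- ed[role1 != 0L & role2 != 0L & role1 != role2, , drop = FALSE]
  cn_ed <- ed[xor(role1 == 0L, role2 == 0L), , drop = FALSE] # chain-node

  chain_lin <- which(m & vmap == 0L)
  edges <- list()
  add_edge <- function(v1, v2, path) {
    edges[[length(edges) + 1L]] <<- list(
      id = length(edges) + 1L, v1 = v1, v2 = v2,
      path = path, parent = NA_integer_, closes_cycle = FALSE)
  }

  if (length(chain_lin)) {
    # neighbour lists within chains
    ci <- match(cc_ed[, 1L], chain_lin); cj <- match(cc_ed[, 2L], chain_lin)
    nbr <- vector("list", length(chain_lin))
    for (i in seq_along(ci)) {
      nbr[[ci[i]]] <- c(nbr[[ci[i]]], cj[i])
      nbr[[cj[i]]] <- c(nbr[[cj[i]]], ci[i])
    }
    # vertices attached to each chain pixel
    att <- vector("list", length(chain_lin))
    if (nrow(cn_ed)) {
      cpx <- ifelse(vmap[cn_ed[, 1L]] == 0L, cn_ed[, 1L], cn_ed[, 2L])
      npx <- ifelse(vmap[cn_ed[, 1L]] == 0L, cn_ed[, 2L], cn_ed[, 1L])
      idx <- match(cpx, chain_lin)
      for (i in seq_along(idx))
        att[[idx[i]]] <- unique(c(att[[idx[i]]], vmap[npx[i]]))
    }
    # chain components
    gch <- igraph::graph_from_edgelist(cbind(ci, cj), directed = FALSE)
    gch <- igraph::add_vertices(gch,
                                max(0L, length(chain_lin) - igraph::vcount(gch)))
    memb <- igraph::components(gch)$membership
    # deterministic order: by smallest linear pixel index per chain
    first <- tapply(seq_along(chain_lin), memb, function(i) min(chain_lin[i]))
    for (cid in as.integer(names(sort(first)))) {
      members <- which(memb == cid)
      degs <- lengths(nbr[members])
      endpts <- members[degs <= 1L]
      if (!length(endpts)) {
        # closed chain: ring through at most one vertex, or floating ring
        vs <- unique(unlist(att[members]))
        if (length(vs)) {
          # cycle re-entering a vertex cluster: record as a self-loop edge
          start <- members[order(chain_lin[members])][1L]
          path <- walk_chain(start, nbr, members)
          add_edge(vs[1L], vs[1L], lin_to_path(chain_lin[path], h))
          next
        }
        if (on_ring == "error")
          stop("skeleton component without terminals (closed ring); ",
               "inspect detect_loops() and cut it with break_loop()")
        next
      }
      # order endpoints lexicographically on (row, col) for determinism
      eprc <- lin_to_rc(chain_lin[endpts], h)
      endpts <- endpts[order(eprc[, 1L], eprc[, 2L])]
      start <- endpts[1L]
      path <- walk_chain(start, nbr, members)
      e1 <- path[1L]; e2 <- path[length(path)]
      va <- att[[e1]]; vb <- att[[e2]]
      if (!length(va) && !length(vb)) {
        if (on_ring == "error")
          stop("skeleton chain not attached to any vertex; ",
               "inspect detect_loops()")
        next
      }
      if (!length(va)) va <- vb
      if (!length(vb)) vb <- va
      if (length(path) == 1L && length(va) >= 2L) {
        v1 <- va[1L]; v2 <- setdiff(va, v1)[1L]
      } else {
        v1 <- va[1L]
        v2 <- if (length(setdiff(vb, v1))) setdiff(vb, v1)[1L] else vb[1L]
      }
      add_edge(v1, v2, lin_to_path(chain_lin[path], h))
    }
  }
  # --- direct vertex-vertex adjacency ------------------------------------
  if (nrow(nn_ed)) {
    ids1 <- vmap[nn_ed[, 1L]]; ids2 <- vmap[nn_ed[, 2L]]
    prs <- unique(cbind(pmin(ids1, ids2), pmax(ids1, ids2)))
    for (i in seq_len(nrow(prs)))
      add_edge(prs[i, 1L], prs[i, 2L],
               matrix(integer(0), 0L, 2L,
                      dimnames = list(NULL, c("row", "col"))))
  }

  vdf <- data.frame(id = seq_len(nv), row = vrow, col = vcol,
                    kind = vkind,
                    component = comp_lab[cbind(vrow, vcol)],
                    is_root = FALSE)
  # --- roots --------------------------------------------------------------
  if (!is.null(root)) {
    root <- as.integer(root)
    hit <- which(vdf$kind == "terminal" & vdf$row == root[1L] &
                   vdf$col == root[2L])
    if (!length(hit)) stop("root must be a terminal coordinate")
    vdf$is_root[hit[1L]] <- TRUE
  }
  for (cp in sort(unique(vdf$component))) {
    if (any(vdf$is_root[vdf$component == cp])) next
    terms <- vdf[vdf$kind == "terminal" & vdf$component == cp, ]
    if (!nrow(terms)) {
      if (on_ring == "error")
        stop("skeleton component without terminals (closed ring); ",
             "inspect detect_loops() and cut it with break_loop()")
      warning("dropping ring component ", cp, " (no terminal for a root)")
      next
    }
    pick <- terms$id[order(terms$row, terms$col)][1L]
    vdf$is_root[vdf$id == pick] <- TRUE
  }
  # overall root: root of the largest component (ties: smallest label)
  root_id <- NA_integer_
  if (any(vdf$is_root)) {
    sizes <- table(factor(comp_lab[comp_lab > 0L]))
    rts <- vdf[vdf$is_root, ]
    rts <- rts[order(-as.integer(sizes[as.character(rts$component)]),
                     rts$component), ]
    root_id <- rts$id[1L]
  }
  structure(list(vertices = vdf, vertex_pixels = vpix, edges = edges,
                 root = root_id, dims = c(h, w)),
            class = "skeleton_graph")
}

# walk an open or closed chain from `start` through neighbour lists,
# returning member indices in path order
#' @keywords internal
#' @noRd
walk_chain <- function(start, nbr, members) {
  path <- start
  prev <- NA_integer_; cur <- start
  repeat {
    nxt <- setdiff(nbr[[cur]], c(prev, path[1L]))
    if (!length(nxt)) {
      # allow closed chains to terminate next to the start
      break
    }
    prev <- cur; cur <- nxt[1L]
    path <- c(path, cur)
    if (length(path) >= length(members)) break
  }
  path
}

#' @keywords internal
#' @noRd
lin_to_path <- function(lin, h) {
  p <- lin_to_rc(lin, h)
  colnames(p) <- c("row", "col")
  p
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph> %d vertices (%d junctions, %d terminals), %d edges, %d component(s)\n",
              nrow(x$vertices), sum(x$vertices$kind == "junction"),
              sum(x$vertices$kind == "terminal"), length(x$edges),
              length(unique(x$vertices$component))))
  if (!is.na(x$root))
    cat(sprintf("  root: vertex %d at (%d, %d)\n", x$root,
                x$vertices$row[x$root], x$vertices$col[x$root]))
  invisible(x)
}

# initial direction angle of an edge leaving vertex v (radians; y axis up,
# i.e. decreasing row)
#' @keywords internal
#' @noRd
edge_initial_angle <- function(g, e, v) {
  vc <- c(g$vertices$row[v], g$vertices$col[v])
  p <- oriented_path(g, e, v)
  tgt <- if (nrow(p)) p[1L, ] else {
    o <- if (e$v1 == v) e$v2 else e$v1
    c(g$vertices$row[o], g$vertices$col[o])
  }
  atan2(tgt[2L] - vc[2L], -(tgt[1L] - vc[1L]))
}

# edge path ordered so that it starts at the end nearest vertex v's pixels
#' @keywords internal
#' @noRd
oriented_path <- function(g, e, v) {
  p <- e$path
  if (!nrow(p)) return(p)
  vp <- g$vertex_pixels[[v]]
  dist_to <- function(px) min(pmax(abs(vp[, 1L] - px[1L]),
                                   abs(vp[, 2L] - px[2L])))
  if (dist_to(p[1L, ]) <= dist_to(p[nrow(p), ])) p
  else p[nrow(p):1L, , drop = FALSE]
}

#' Depth-first traversal of a skeleton graph
#'
#' Starting from the root terminal of each component, visits every vertex
#' and edge exactly once. Children at each vertex are explored in the order
#' of their edges' initial direction angle (ties by edge id), which makes
#' the traversal deterministic. Each visited edge is assigned its parent
#' vertex (the endpoint it was entered from) -- the orientation used by the
#' branch-angle measurement. Edges that would close a cycle are visited
#' once, flagged, and reported with a warning pointing at the loop report.
#'
#' @param g a [skeleton_graph] object.
#' @return A list with `vertex_order`, `edge_order` (ids in visit order)
#'   and `graph`, the input graph with `parent` and `closes_cycle` set on
#'   its edges.
#' @export
traverse_dfs <- function(g) {
  stopifnot(inherits(g, "skeleton_graph"))
  nv <- nrow(g$vertices)
  inc <- vector("list", nv)
  for (e in g$edges) {
    inc[[e$v1]] <- c(inc[[e$v1]], e$id)
    if (e$v2 != e$v1) inc[[e$v2]] <- c(inc[[e$v2]], e$id)
  }
  visited_v <- logical(nv)
  visited_e <- logical(length(g$edges))
  vertex_order <- integer(0)
  edge_order <- integer(0)
  any_cycle <- FALSE
  roots <- g$vertices$id[g$vertices$is_root]
  roots <- c(g$root[!is.na(g$root)], setdiff(roots, g$root))
  visit <- function(v) {
    stack <- list(v)
    visited_v[v] <<- TRUE
    vertex_order <<- c(vertex_order, v)
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      eids <- inc[[cur]]
      eids <- eids[!visited_e[eids]]
      if (!length(eids)) { stack[[length(stack)]] <- NULL; next }
      ang <- vapply(eids, function(ei) edge_initial_angle(g, g$edges[[ei]], cur),
                    numeric(1))
      ei <- eids[order(ang, eids)][1L]
      visited_e[ei] <<- TRUE
      e <- g$edges[[ei]]
      g$edges[[ei]]$parent <<- cur
      edge_order <<- c(edge_order, ei)
      nxt <- if (e$v1 == cur) e$v2 else e$v1
      if (visited_v[nxt]) {
        g$edges[[ei]]$closes_cycle <<- TRUE
        any_cycle <<- TRUE
      } else {
        visited_v[nxt] <<- TRUE
        vertex_order <<- c(vertex_order, nxt)
        stack[[length(stack) + 1L]] <- nxt
      }
    }
  }
  for (r in roots) if (!visited_v[r]) visit(r)
  if (any_cycle)
    warning("skeleton graph contains cycles; see detect_loops() for their locations")
  list(vertex_order = vertex_order, edge_order = edge_order, graph = g)
}

#' Serialize a skeleton graph to JSON
#'
#' Coordinates are written 0-based `(row, col)` with origin at the top-left
#' pixel, as documented in the file's `coordinate_system` field.
#'
#' @param g a [skeleton_graph] object.
#' @param path output JSON path.
#' @export
write_graph_json <- function(g, path) {
  v <- g$vertices
  obj <- list(
    coordinate_system = "0-based (row, col), origin top-left",
    vertices = data.frame(id = v$id, row = v$row - 1L, col = v$col - 1L,
                          kind = v$kind, is_root = v$is_root),
    edges = lapply(g$edges, function(e) list(
      id = e$id, v1 = e$v1, v2 = e$v2,
      path = if (nrow(e$path)) unname(e$path - 1L) else matrix(0L, 0L, 2L)))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
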
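# Skeletonization wrapper and centerline graph machinery.

new_centerline_graph <- function(nodes, edges, voxel_um) {
  structure(list(nodes = nodes, edges = edges, voxel_um = voxel_um),
            class = "centerline_graph")
}

#' @export
print.centerline_graph <- function(x, ...) {
  labs <- vapply(x$edges, function(e)
    if (is.null(e$label) || is.na(e$label)) "<NA>" else e$label, character(1))
  cat(sprintf("<centerline_graph> %d nodes, %d edges (%s)\n",
              nrow(x$nodes), length(x$edges),
              paste(unique(labs), collapse = ", ")))
  invisible(x)
}

#' Per-edge summary of a centerline graph
#'
#' @param x a `centerline_graph`.
#' @param ... unused.
#' @return data.frame with one row per edge: label, endpoints, arclength.
#' @export
as.data.frame.centerline_graph <- function(x, ...) {
  data.frame(
    edge = seq_along(x$edges),
    label = vapply(x$edges, function(e) e$label %||% NA_character_,
                   character(1)),
    from = vapply(x$edges, function(e) e$from, numeric(1)),
    to = vapply(x$edges, function(e) e$to, numeric(1)),
    n_points = vapply(x$edges, function(e) nrow(e$points), numeric(1)),
    arclength_mm = vapply(x$edges, function(e) e$arclength_mm, numeric(1)))
}

edge_degrees <- function(graph) {
  deg <- setNames(rep(0, nrow(graph$nodes)), graph$nodes$id)
  for (e in graph$edges) {
    deg[as.character(e$from)] <- deg[as.character(e$from)] + 1
    deg[as.character(e$to)] <- deg[as.character(e$to)] + 1
  }
  deg
}

refresh_degrees <- function(graph) {
  deg <- edge_degrees(graph)
  graph$nodes$degree <- as.numeric(deg[as.character(graph$nodes$id)])
  graph
}

# ground-truth graph straight from phantom primitives; a primitive is split
# wherever another primitive's endpoint lies on its centerline (branch
# origins become junction nodes)
graph_from_primitives <- function(spec) {
  prims <- spec$primitives
  if (!length(prims))
    return(new_centerline_graph(
      data.frame(id = integer(), x = numeric(), y = numeric(),
                 z = numeric(), degree = numeric()),
      list(), spec$voxel_um))
  ends <- do.call(rbind, lapply(prims, function(p)
    p$points[c(1, nrow(p$points)), , drop = FALSE]))
  key <- apply(round(ends, 6), 1, paste, collapse = "/")
  upts <- ends[!duplicated(key), , drop = FALSE]
  node_id_of <- function(q) match(paste(round(q, 6), collapse = "/"),
                                  apply(round(upts, 6), 1, paste,
                                        collapse = "/"))
  tol <- 1e-6
  pieces <- list()
  for (p in prims) {
    P <- p$points; R <- p$radius_um
    n <- nrow(P)
    # locate interior touch points of other endpoints: (segment, t)
    splits <- list()
    for (k in seq_len(nrow(upts))) {
      q <- upts[k, ]
      if (sum((q - P[1, ])^2) < tol^2 || sum((q - P[n, ])^2) < tol^2) next
      best <- NULL
      for (s in seq_len(n - 1)) {
        v <- P[s + 1, ] - P[s, ]
        vv <- sum(v^2)
        t <- if (vv > 0) sum((q - P[s, ]) * v) / vv else 0
        t <- min(max(t, 0), 1)
        d2 <- sum((q - P[s, ] - t * v)^2)
        if (is.null(best) || d2 < best$d2) best <- list(d2 = d2, s = s, t = t)
      }
      if (best$d2 < tol^2)
        splits[[length(splits) + 1L]] <- c(k = k, s = best$s, t = best$t)
    }
    if (!length(splits)) {
      pieces[[length(pieces) + 1L]] <-
        list(points = P, radius_um = R, label = p$label,
             from = node_id_of(P[1, ]), to = node_id_of(P[n, ]))
      next
    }
    sp <- do.call(rbind, splits)
    sp <- sp[order(sp[, "s"], sp[, "t"]), , drop = FALSE]
    cur_pts <- P[1, , drop = FALSE]; cur_rad <- R[1]
    cur_from <- node_id_of(P[1, ])
    si <- 1L
    for (s in seq_len(n - 1)) {
      while (si <= nrow(sp) && sp[si, "s"] == s) {
        t <- sp[si, "t"]
        q <- P[s, ] + t * (P[s + 1, ] - P[s, ])
        rq <- R[s] + t * (R[s + 1] - R[s])
        if (sum((q - cur_pts[nrow(cur_pts), ])^2) > tol^2) {
          cur_pts <- rbind(cur_pts, q); cur_rad <- c(cur_rad, rq)
        }
        nid <- node_id_of(upts[sp[si, "k"], ])
        pieces[[length(pieces) + 1L]] <-
          list(points = cur_pts, radius_um = cur_rad, label = p$label,
               from = cur_from, to = nid)
        cur_pts <- matrix(q, 1); cur_rad <- rq; cur_from <- nid
        si <- si + 1L
      }
      if (sum((P[s + 1, ] - cur_pts[nrow(cur_pts), ])^2) > tol^2) {
        cur_pts <- rbind(cur_pts, P[s + 1, ]); cur_rad <- c(cur_rad, R[s + 1])
      }
    }
    pieces[[length(pieces) + 1L]] <-
      list(points = cur_pts, radius_um = cur_rad, label = p$label,
           from = cur_from, to = node_id_of(P[n, ]))
  }
  nodes <- data.frame(id = seq_len(nrow(upts)), x = upts[, 1], y = upts[, 2],
                      z = upts[, 3], degree = 0)
  edges <- lapply(seq_along(pieces), function(i) {
    pc <- pieces[[i]]
    list(id = i, from = pc$from, to = pc$to, points = pc$points,
         label = pc$label, radius_um = pc$radius_um,
         arclength_mm = polyline_arclength(pc$points))
  })
  refresh_degrees(new_centerline_graph(nodes, edges, spec$voxel_um))
}

#' Topology-preserving 3D skeletonization
#'
#' Thins a binary vessel mask to a one-voxel-thick centerline skeleton by
#' sequential deletion of simple points over six directional subcycles,
#' preserving 26-connectivity components, loops and cavities of the
#' foreground. The skeleton is always a subset of the mask, and the
#' operation is idempotent.
#'
#' @param mask a logical [ct_volume()].
#' @return A logical [ct_volume()] skeleton.
#' @export
skeletonize <- function(mask) {
  assert_volume(mask)
  dm <- dim(mask$data)
  fg <- as.logical(mask$data)
  if (!any(fg)) {
    message("skeletonize: empty mask; returning empty skeleton")
    return(ct_volume(array(FALSE, dm), mask$voxel_um, mask$origin_mm))
  }
  sk <- cpp_skeletonize(fg, dm)
  ct_volume(array(sk, dim = dm), mask$voxel_um, mask$origin_mm)
}

#' Build a centerline graph from a skeleton
#'
#' Skeleton voxels with a number of 26-neighbors different from two become
#' nodes (adjacent node voxels are condensed into a single node at their
#' centroid); maximal chains of degree-2 voxels between nodes become edges
#' with world-coordinate (mm) polylines. A connected component that is a
#' pure cycle (every voxel has exactly two neighbors) receives one
#' artificial node at its lexicographically smallest voxel and becomes a
#' self-edge.
#'
#' @param skeleton a one-voxel-thick logical [ct_volume()] (from
#'   [skeletonize()]).
#' @return A `centerline_graph` with nodes (id, world mm, degree) and edges
#'   (polyline, arclength, label slot).
#' @export
build_graph <- function(skeleton) {
  assert_volume(skeleton)
  dm <- dim(skeleton$data)
  fg <- skeleton$data > 0
  idx <- which(fg)
  if (!length(idx))
    return(new_centerline_graph(
      data.frame(id = integer(), x = numeric(), y = numeric(),
                 z = numeric(), degree = numeric()),
      list(), skeleton$voxel_um))
  n <- length(idx)
  coord <- arrayInd(idx, dm)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  adj <- matrix(NA_integer_, nrow = n, ncol = 26)
  for (k in seq_len(26)) {
    nc <- sweep(coord, 2, offs[k, ], "+")
    ok <- nc[, 1] >= 1 & nc[, 1] <= dm[1] & nc[, 2] >= 1 & nc[, 2] <= dm[2] &
      nc[, 3] >= 1 & nc[, 3] <= dm[3]
    nidx <- rep(NA_integer_, n)
    nidx[ok] <- nc[ok, 1] + dm[1] * (nc[ok, 2] - 1) +
      dm[1] * dm[2] * (nc[ok, 3] - 1)
    adj[, k] <- match(nidx, idx)
  }
  deg <- rowSums(!is.na(adj))
  nbrs <- function(i) adj[i, !is.na(adj[i, ])]

  # connected components (for pure-cycle detection)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    stack <- s; comp[s] <- cur
    while (length(stack)) {
      i <- stack[length(stack)]; stack <- stack[-length(stack)]
      nb <- nbrs(i)
      new <- nb[comp[nb] == 0L]
      comp[new] <- cur
      stack <- c(stack, new)
    }
  }

  is_node <- deg != 2
  # pure cycles: designate the lexicographically smallest voxel as a node
  for (cc in seq_len(cur)) {
    rows <- which(comp == cc)
    if (!any(is_node[rows])) {
      o <- rows[order(coord[rows, 1], coord[rows, 2], coord[rows, 3])[1]]
      is_node[o] <- TRUE
    }
  }

  # condense 26-connected clusters of node voxels into single graph nodes
  cluster <- integer(n)  # 0 = chain voxel
  ncl <- 0L
  for (s in which(is_node)) {
    if (cluster[s]) next
    ncl <- ncl + 1L
    stack <- s; cluster[s] <- ncl
    while (length(stack)) {
      i <- stack[length(stack)]; stack <- stack[-length(stack)]
      nb <- nbrs(i)
      new <- nb[is_node[nb] & cluster[nb] == 0L]
      cluster[new] <- ncl
      stack <- c(stack, new)
    }
  }
  vol_stub <- list(voxel_um = skeleton$voxel_um, origin_mm = skeleton$origin_mm)
  class(vol_stub) <- "ct_volume"
  world <- vox_to_world(vol_stub, coord)
  nodes <- data.frame(id = seq_len(ncl), x = NA_real_, y = NA_real_,
                      z = NA_real_, degree = 0)
  for (cc in seq_len(ncl)) {
    rows <- which(cluster == cc)
    nodes[cc, c("x", "y", "z")] <- colMeans(world[rows, , drop = FALSE])
  }

  edges <- list()
  visited <- rep(FALSE, n)  # consumed chain voxels
  add_edge <- function(from, to, rows) {
    edges[[length(edges) + 1L]] <<- list(
      id = length(edges) + 1L, from = from, to = to,
      points = world[rows, , drop = FALSE], label = NA_character_,
      radius_um = NULL,
      arclength_mm = polyline_arclength(world[rows, , drop = FALSE]))
  }
  for (a in which(is_node)) {
    for (b in nbrs(a)) {
      if (is_node[b] || visited[b]) next
      path <- c(a, b)
      visited[b] <- TRUE
      prev <- a; curv <- b
      repeat {
        nb <- nbrs(curv)
        nxt <- nb[nb != prev]
        if (!length(nxt)) break               # dangling chain end (shouldn't
        nxt <- nxt[1]                         # happen in a thin skeleton)
        path <- c(path, nxt)
        if (is_node[nxt]) break
        if (visited[nxt]) break
        visited[nxt] <- TRUE
        prev <- curv; curv <- nxt
      }
      tail_row <- path[length(path)]
      to <- if (is_node[tail_row]) cluster[tail_row] else cluster[a]
      add_edge(cluster[a], to, path)
    }
  }
  g <- new_centerline_graph(nodes, edges, skeleton$voxel_um)
  refresh_degrees(g)
}

#' Prune short terminal spurs from a centerline graph
#'
#' Iteratively removes terminal edges (one endpoint of degree 1) shorter
#' than `min_length_mm`, then merges the resulting degree-2 pass-through
#' nodes. Edges participating in cycles (self-edges, or edges whose both
#' endpoints stay connected) are never removed. Idempotent at its fixed
#' point.
#'
#' @param graph a `centerline_graph`.
#' @param min_length_mm spurs strictly shorter than this are removed;
#'   default 3 voxels.
#' @return The pruned `centerline_graph`.
#' @export
prune_spurs <- function(graph, min_length_mm = 3 * graph$voxel_um / 1000) {
  stopifnot(inherits(graph, "centerline_graph"))
  if (min_length_mm < 0) stop("min_length_mm must be >= 0")
  repeat {
    deg <- edge_degrees(graph)
    drop <- vapply(graph$edges, function(e) {
      e$from != e$to && e$arclength_mm < min_length_mm &&
        (deg[as.character(e$from)] == 1 || deg[as.character(e$to)] == 1)
    }, logical(1))
    if (!any(drop)) break
    graph$edges <- graph$edges[!drop]
    graph <- merge_pass_nodes(graph)
  }
  graph <- merge_pass_nodes(graph)
  # drop isolated nodes left behind
  used <- unique(unlist(lapply(graph$edges, function(e) c(e$from, e$to))))
  graph$nodes <- graph$nodes[graph$nodes$id %in% used |
                               graph$nodes$degree == 0, , drop = FALSE]
  refresh_degrees(graph)
}

# merge degree-2 nodes joining two distinct edges into a single edge
merge_pass_nodes <- function(graph) {
  repeat {
    deg <- edge_degrees(graph)
    merged <- FALSE
    for (nid in graph$nodes$id) {
      if (is.na(deg[as.character(nid)]) || deg[as.character(nid)] != 2) next
      inc <- which(vapply(graph$edges, function(e)
        e$from == nid || e$to == nid, logical(1)))
      if (length(inc) != 2) next  # single edge touching twice = self loop
      e1 <- graph$edges[[inc[1]]]; e2 <- graph$edges[[inc[2]]]
      if (e1$from == e1$to || e2$from == e2$to) next
      # orient e1 to end at nid, e2 to start at nid
      if (e1$from == nid) {
        e1$points <- e1$points[rev(seq_len(nrow(e1$points))), , drop = FALSE]
        if (!is.null(e1$radius_um)) e1$radius_um <- rev(e1$radius_um)
        e1$from <- e1$to
      }
      if (e2$to == nid) {
        e2$points <- e2$points[rev(seq_len(nrow(e2$points))), , drop = FALSE]
        if (!is.null(e2$radius_um)) e2$radius_um <- rev(e2$radius_um)
        e2$to <- e2$from
      }
      lab <- if (identical(e1$label, e2$label)) e1$label else NA_character_
      rad <- if (!is.null(e1$radius_um) && !is.null(e2$radius_um))
        c(e1$radius_um, e2$radius_um[-1]) else NULL
      new_edge <- list(id = e1$id, from = e1$from, to = e2$to,
                       points = rbind(e1$points, e2$points[-1, , drop = FALSE]),
                       label = lab, radius_um = rad, arclength_mm = NA)
      new_edge$arclength_mm <- polyline_arclength(new_edge$points)
      graph$edges[[inc[1]]] <- new_edge
      graph$edges <- graph$edges[-inc[2]]
      graph$nodes <- graph$nodes[graph$nodes$id != nid, , drop = FALSE]
      merged <- TRUE
      break
    }
    if (!merged) break
  }
  for (i in seq_along(graph$edges)) graph$edges[[i]]$id <- i
  refresh_degrees(graph)
}

#' Transfer ground-truth labels onto a detected graph
#'
#' Each detected polyline point is assigned the nearest ground-truth
#' segment; edges are split at label-run boundaries and each resulting
#' sub-edge inherits its run's label if the mean closest-point distance to
#' that truth segment is below `max_dist_vox` voxels, otherwise
#' `"unassigned"`.
#'
#' @param graph detected `centerline_graph` (world mm).
#' @param truth ground-truth `centerline_graph` (e.g. from [rasterize()]).
#' @param max_dist_vox matching gate in voxels (default 2).
#' @return The labeled (possibly split) `centerline_graph`.
#' @export
match_labels <- function(graph, truth, max_dist_vox = 2) {
  stopifnot(inherits(graph, "centerline_graph"))
  thr <- max_dist_vox * graph$voxel_um / 1000
  if (!inherits(truth, "centerline_graph") || !length(truth$edges)) {
    for (i in seq_along(graph$edges)) graph$edges[[i]]$label <- "unassigned"
    return(graph)
  }
  tlabs <- vapply(truth$edges, function(e) e$label %||% "truth", character(1))
  new_edges <- list()
  next_node <- max(graph$nodes$id, 0) + 1L
  extra_nodes <- list()
  for (e in graph$edges) {
    P <- e$points
    D <- vapply(truth$edges, function(te)
      cpp_points_polyline_dist(P, te$points), numeric(nrow(P)))
    D <- matrix(D, nrow = nrow(P))
    ptlab <- max.col(-D)             # argmin per row
    ptdist <- D[cbind(seq_len(nrow(P)), ptlab)]
    r <- rle(ptlab)
    # absorb runs shorter than 3 points into their longer neighbor
    while (length(r$lengths) > 1 && min(r$lengths) < 3) {
      i <- which.min(r$lengths)
      j <- if (i == 1) 2 else if (i == length(r$lengths)) i - 1 else
        if (r$lengths[i - 1] >= r$lengths[i + 1]) i - 1 else i + 1
      r$values[i] <- r$values[j]
      r <- rle(inverse.rle(r))
    }
    bounds <- cumsum(r$lengths)
    prev_node <- e$from
    for (si in seq_along(r$values)) {
      i0 <- if (si == 1) 1 else bounds[si - 1]  # share the boundary point
      i1 <- bounds[si]
      if (i1 - i0 < 1) next
      rows <- i0:i1
      lab <- tlabs[r$values[si]]
      if (mean(ptdist[rows]) >= thr) lab <- "unassigned"
      to_node <- if (si == length(r$values)) e$to else {
        nd <- next_node; next_node <- next_node + 1L
        extra_nodes[[length(extra_nodes) + 1L]] <-
          data.frame(id = nd, x = P[i1, 1], y = P[i1, 2], z = P[i1, 3],
                     degree = 2)
        nd
      }
      new_edges[[length(new_edges) + 1L]] <- list(
        id = length(new_edges) + 1L, from = prev_node, to = to_node,
        points = P[rows, , drop = FALSE], label = lab, radius_um = NULL,
        arclength_mm = polyline_arclength(P[rows, , drop = FALSE]))
      prev_node <- to_node
    }
  }
  nodes <- rbind(graph$nodes, do.call(rbind, extra_nodes))
  refresh_degrees(new_centerline_graph(nodes, new_edges, graph$voxel_um))
}

#' Export a centerline graph to JSON or SWC-like CSV
#'
#' @param graph a `centerline_graph`.
#' @param path destination (`.json` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_graph <- function(graph, path) {
  stopifnot(inherits(graph, "centerline_graph"))
  if (grepl("\\.json$", tolower(path))) {
    obj <- list(
      voxel_um = graph$voxel_um,
      nodes = graph$nodes,
      edges = lapply(graph$edges, function(e) list(
        id = e$id, from = e$from, to = e$to, label = e$label,
        arclength_mm = e$arclength_mm,
        points = unname(apply(e$points, 1, as.numeric, simplify = FALSE)),
        radius_um = e$radius_um)))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", null = "null")
  } else if (grepl("\\.csv$", tolower(path))) {
    rows <- do.call(rbind, lapply(graph$edges, function(e) {
      data.frame(edge = e$id, label = e$label %||% NA_character_,
                 x_mm = e$points[, 1], y_mm = e$points[, 2],
                 z_mm = e$points[, 3],
                 radius_um = if (is.null(e$radius_um)) NA_real_ else
                   e$radius_um)
    }))
    write.csv(rows, path, row.names = FALSE)
  } else stop("unsupported graph export format: ", path)
  invisible(path)
}

#' Number of independent cycles in a centerline graph
#'
#' Cyclomatic number `E - N + C` (edges minus nodes plus connected
#' components).
#'
#' @param graph a `centerline_graph`.
#' @return Integer cycle count.
#' @export
graph_cycle_count <- function(graph) {
  n <- nrow(graph$nodes)
  m <- length(graph$edges)
  if (!n) return(0L)
  # count connected components over nodes
  ids <- graph$nodes$id
  parent <- setNames(ids, ids)
  find <- function(i) {
    while (parent[[as.character(i)]] != i) i <- parent[[as.character(i)]]
    i
  }
  for (e in graph$edges) {
    a <- find(e$from); b <- find(e$to)
    if (a != b) parent[[as.character(a)]] <- b
  }
  comps <- length(unique(vapply(ids, find, numeric(1))))
  as.integer(m - n + comps)
}
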
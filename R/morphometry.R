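# Quantitative vessel metrics: ROI HU statistics, contrast-to-noise SNR,
# radial chord diameters, arc:chord tortuosity, Menger middle curvature,
# Circle-of-Willis width, branch counts, visibility scoring.

#' ROI statistics (mean and SD of HU)
#'
#' Spherical region of interest: statistics over all voxels whose centers
#' lie within `radius_mm` of `center_mm`.
#'
#' @param volume a [ct_volume()].
#' @param center_mm ROI center (world mm).
#' @param radius_mm ROI radius (mm).
#' @param label optional tag.
#' @return An `roi_stats` object: `mean_hu`, `sd_hu`, `n_voxels`,
#'   `roi_label`.
#' @export
roi_stats <- function(volume, center_mm, radius_mm, label = "") {
  assert_volume(volume)
  dm <- dim(volume$data)
  h <- voxel_mm(volume)
  lo <- (center_mm - radius_mm - volume$origin_mm) / h + 1
  hi <- (center_mm + radius_mm - volume$origin_mm) / h + 1
  if (any(lo < 0.5) || any(hi > dm + 0.5))
    stop("ROI extends outside the volume")
  rng <- lapply(1:3, function(j)
    max(1L, floor(lo[j])):min(dm[j], ceiling(hi[j])))
  ijk <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  w <- vox_to_world(volume, ijk)
  inside <- rowSums(sweep(w, 2, center_mm, "-")^2) <= radius_mm^2
  if (!any(inside)) stop("ROI contains no voxel centers")
  vals <- volume$data[ijk[inside, , drop = FALSE]]
  structure(list(mean_hu = mean(vals),
                 sd_hu = if (length(vals) > 1) sd(vals) else 0,
                 n_voxels = sum(inside), roi_label = label),
            class = "roi_stats")
}

#' Signal-to-noise ratio of a vessel ROI
#'
#' Contrast-to-noise convention: (vessel mean - background mean) divided by
#' the background SD (parenchyma ROI SDs are used as noise levels). Set
#' `subtract_background = FALSE` for the raw mean/SD variant.
#'
#' @param vessel,background [roi_stats()] objects.
#' @param subtract_background subtract the background mean (default TRUE)?
#' @return Dimensionless SNR.
#' @export
snr <- function(vessel, background, subtract_background = TRUE) {
  stopifnot(inherits(vessel, "roi_stats"), inherits(background, "roi_stats"))
  if (background$sd_hu <= 0)
    stop("undefined SNR: background ROI has zero standard deviation")
  num <- vessel$mean_hu - if (subtract_background) background$mean_hu else 0
  num / background$sd_hu
}

#' Radial chord lengths through a vessel cross-section
#'
#' Casts `n_rays` ray-pairs uniformly spaced in angle within the plane
#' orthogonal to `tangent` at `point_mm` and measures the full chord (both
#' directions) to the mask boundary, located sub-voxel at the trilinear 0.5
#' level.
#'
#' @param mask a logical [ct_volume()].
#' @param point_mm point on/near the centerline (must be inside the mask).
#' @param tangent local centerline direction (any non-zero 3-vector).
#' @param n_rays number of ray-pairs (default 90, i.e. 2 degree steps).
#' @param step_vox marching step in voxels.
#' @param max_mm maximum search radius per direction.
#' @return Numeric vector of chord lengths (um); NA where the ray never
#'   exits within `max_mm`.
#' @export
radial_lengths <- function(mask, point_mm, tangent, n_rays = 90,
                           step_vox = 0.1, max_mm = 1) {
  assert_volume(mask)
  h <- voxel_mm(mask)
  v0 <- cpp_trilinear(as.numeric(mask$data), dim(mask$data), h,
                      mask$origin_mm, matrix(point_mm, ncol = 3))
  if (v0 < 0.5) stop("invalid point: not inside the mask foreground")
  ch <- cpp_radial_chords(as.numeric(mask$data), dim(mask$data), h,
                          mask$origin_mm, as.numeric(point_mm),
                          as.numeric(tangent), as.integer(n_rays),
                          step_vox * h, max_mm)
  ch * 1000
}

# tangents by central differences on a 5-point moving-average smoothed
# polyline
polyline_tangents <- function(points) {
  n <- nrow(points)
  sm <- points
  if (n >= 5) {
    for (j in 1:3) {
      x <- points[, j]
      sm[, j] <- (c(x[1], x[1], x[1:(n - 2)]) + c(x[1], x[1:(n - 1)]) + x +
                    c(x[2:n], x[n]) + c(x[3:n], x[n], x[n])) / 5
    }
  }
  tg <- matrix(0, n, 3)
  tg[1, ] <- sm[2, ] - sm[1, ]
  tg[n, ] <- sm[n, ] - sm[n - 1, ]
  if (n > 2) tg[2:(n - 1), ] <- sm[3:n, , drop = FALSE] -
      sm[1:(n - 2), , drop = FALSE]
  tg / pmax(sqrt(rowSums(tg^2)), 1e-12)
}

#' Vessel segment diameter (median of minimal chords)
#'
#' At each interior centerline point the local diameter is the minimum over
#' ray directions of the full chord through the mask; the segment diameter
#' is the median of these minima. Points within `exclude_vox` voxels of the
#' segment ends (branch nodes) are excluded.
#'
#' @param segment a graph edge (list with `points`) or an n x 3 matrix of
#'   centerline points (mm).
#' @param mask a logical [ct_volume()].
#' @param n_rays ray-pairs per point.
#' @param exclude_vox end exclusion zone (voxels).
#' @return Diameter in um.
#' @export
segment_diameter <- function(segment, mask, n_rays = 90, exclude_vox = 2) {
  assert_volume(mask)
  P <- if (is.list(segment)) segment$points else segment
  if (nrow(P) < 5)
    stop("insufficient length: segment needs >= 5 centerline points")
  s <- cum_arclength(P)
  total <- s[length(s)]
  margin <- exclude_vox * voxel_mm(mask)
  keep <- which(s >= margin & s <= total - margin)
  if (length(keep) < 1)
    stop("insufficient length: all points fall within the end exclusion zone")
  tg <- polyline_tangents(P)
  h <- voxel_mm(mask)
  dm <- dim(mask$data)
  v <- as.numeric(mask$data)
  dia <- rep(NA_real_, length(keep))
  for (i in seq_along(keep)) {
    r <- keep[i]
    v0 <- cpp_trilinear(v, dm, h, mask$origin_mm,
                        matrix(P[r, ], ncol = 3))
    if (v0 < 0.5) next  # centerline point off the mask (noise): skip
    ch <- cpp_radial_chords(v, dm, h, mask$origin_mm, P[r, ], tg[r, ],
                            as.integer(n_rays), 0.1 * h, 1.0)
    if (all(is.na(ch))) next
    dia[i] <- min(ch, na.rm = TRUE) * 1000
  }
  if (all(is.na(dia)))
    stop("insufficient length: no usable centerline points inside the mask")
  median(dia, na.rm = TRUE)
}

#' Arc:chord (tortuosity) ratio
#'
#' Polyline arclength divided by the Euclidean distance between its
#' endpoints; exactly 1 for a straight vessel, > 1 otherwise.
#'
#' @param segment a graph edge or an n x 3 point matrix (mm).
#' @return Dimensionless ratio >= 1.
#' @export
arc_chord_ratio <- function(segment) {
  P <- if (is.list(segment)) segment$points else segment
  if (nrow(P) < 2) stop("need >= 2 points")
  chord <- sqrt(sum((P[nrow(P), ] - P[1, ])^2))
  if (chord == 0)
    stop("undefined ratio: coincident endpoints (closed loop)")
  polyline_arclength(P) / chord
}

#' Middle (Menger) curvature of a segment
#'
#' Takes the arclength midpoint and the two points `half_window_mm` along
#' the centerline on either side, and returns the Menger curvature (inverse
#' circumradius) of these three points; 0 for collinear points.
#'
#' @param segment a graph edge or point matrix (mm).
#' @param half_window_mm half window (mm), default 0.25.
#' @return Curvature in 1/mm.
#' @export
middle_curvature <- function(segment, half_window_mm = 0.25) {
  P <- if (is.list(segment)) segment$points else segment
  s <- cum_arclength(P)
  total <- s[length(s)]
  if (total <= 2 * half_window_mm)
    stop("insufficient length: segment arclength must exceed the window")
  interp <- function(t) vapply(1:3, function(j) approx(s, P[, j], t)$y,
                               numeric(1))
  m <- total / 2
  a <- interp(m - half_window_mm); b <- interp(m); cc <- interp(m + half_window_mm)
  ab <- b - a; bc <- cc - b; ac <- cc - a
  cr <- c(ab[2] * ac[3] - ab[3] * ac[2],
          ab[3] * ac[1] - ab[1] * ac[3],
          ab[1] * ac[2] - ab[2] * ac[1])
  area2 <- sqrt(sum(cr^2))  # 2 * triangle area
  den <- sqrt(sum(ab^2)) * sqrt(sum(bc^2)) * sqrt(sum(ac^2))
  if (den == 0) return(0)
  2 * area2 / den  # 4 * area / (|ab| |bc| |ac|)
}

#' Circle-of-Willis width from a labeled centerline graph
#'
#' Establishes the anterior-posterior axis through the anterior origin node
#' (the junction of the two anterior arcs; by analogy, the intersection of
#' the internal carotids and the azygos pericallosal artery) and measures,
#' at matched axis positions, the distance between the left and right
#' lateral ring segments orthogonal to that axis. The width is the maximum
#' over axis positions.
#'
#' @param graph a labeled `centerline_graph` (see [match_labels()]).
#' @param left_label,right_label labels of the lateral ring segments.
#' @param anterior_labels,posterior_labels labels whose junctions define the
#'   axis; the posterior junction is optional (falls back to the ring
#'   centroid direction).
#' @param n_samples number of axis positions sampled.
#' @return Width in mm.
#' @export
cow_width <- function(graph, left_label = "ica_left",
                      right_label = "ica_right",
                      anterior_labels = c("anterior_left", "anterior_right"),
                      posterior_labels = c("posterior_left",
                                           "posterior_right"),
                      n_samples = 200) {
  stopifnot(inherits(graph, "centerline_graph"))
  lab_of <- function(e) e$label %||% NA_character_
  pts_for <- function(lab) {
    sel <- vapply(graph$edges, function(e) isTRUE(lab_of(e) %in% lab),
                  logical(1))
    if (!any(sel)) return(NULL)
    do.call(rbind, lapply(graph$edges[sel], `[[`, "points"))
  }
  L <- pts_for(left_label); R <- pts_for(right_label)
  if (is.null(L) || is.null(R))
    stop("missing structure: no edges labeled '", left_label, "' / '",
         right_label, "'")
  junction <- function(two_labs) {
    hit <- lapply(two_labs, function(lb)
      unlist(lapply(graph$edges, function(e)
        if (isTRUE(lab_of(e) == lb)) c(e$from, e$to) else NULL)))
    cand <- intersect(hit[[1]], hit[[2]])
    if (length(cand)) {
      nd <- graph$nodes[graph$nodes$id == cand[1], ]
      return(c(nd$x, nd$y, nd$z))
    }
    # fallback: midpoint of the closest endpoint pair between the two
    # labeled edge sets (the junction node may be fragmented by spurs)
    ends_of <- function(lb) {
      sel <- Filter(function(e) isTRUE(lab_of(e) == lb), graph$edges)
      if (!length(sel)) return(NULL)
      do.call(rbind, lapply(sel, function(e)
        e$points[c(1, nrow(e$points)), , drop = FALSE]))
    }
    A <- ends_of(two_labs[1]); B <- ends_of(two_labs[2])
    if (is.null(A) || is.null(B)) return(NULL)
    d2 <- outer(seq_len(nrow(A)), seq_len(nrow(B)), Vectorize(function(i, j)
      sum((A[i, ] - B[j, ])^2)))
    ij <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
    (A[ij[1], ] + B[ij[2], ]) / 2
  }
  origin <- junction(anterior_labels)
  if (is.null(origin))
    stop("missing structure: anterior origin junction (labels ",
         paste(anterior_labels, collapse = " & "), ") not found")
  post <- junction(posterior_labels)
  axis <- if (!is.null(post)) post - origin else
    colMeans(rbind(L, R)) - origin
  nv <- sqrt(sum(axis^2))
  if (nv == 0) stop("degenerate anterior-posterior axis")
  axis <- axis / nv
  proj <- function(P) {
    t <- as.numeric(sweep(P, 2, origin, "-") %*% axis)
    o <- order(t)
    list(t = t[o], P = P[o, , drop = FALSE])
  }
  pl <- proj(L); pr <- proj(R)
  t0 <- max(min(pl$t), min(pr$t))
  t1 <- min(max(pl$t), max(pr$t))
  if (t1 <= t0)
    stop("missing structure: lateral segments do not overlap along the axis")
  tt <- seq(t0, t1, length.out = n_samples)
  at <- function(p, tt) vapply(1:3, function(j)
    approx(p$t, p$P[, j], xout = tt, ties = mean)$y, numeric(length(tt)))
  XL <- at(pl, tt); XR <- at(pr, tt)
  W <- XR - XL
  Wax <- W %*% axis
  Wperp <- W - outer(as.numeric(Wax), axis)
  max(sqrt(rowSums(Wperp^2)))
}

#' Count branches along a parent vessel within an arclength window
#'
#' Counts, over all branch-point nodes (degree >= 3) lying on the parent
#' centerline within `window_mm` of the parent origin, the number of
#' non-parent edges leaving them (the pontine-artery counting rule: branches
#' originating from the first 3.0 mm of basilar artery).
#'
#' @param graph a labeled `centerline_graph`.
#' @param parent_label label of the parent vessel.
#' @param window_mm arclength window from the parent origin.
#' @param origin_mm optional world position identifying the parent origin
#'   end; defaults to the parent endpoint with the lexicographically
#'   smallest coordinates.
#' @return Integer branch count.
#' @export
count_branches <- function(graph, parent_label, window_mm = 3,
                           origin_mm = NULL) {
  stopifnot(inherits(graph, "centerline_graph"))
  is_parent <- vapply(graph$edges, function(e)
    isTRUE((e$label %||% NA_character_) == parent_label), logical(1))
  if (!any(is_parent))
    stop("missing structure: no edges labeled '", parent_label, "'")
  pedges <- graph$edges[is_parent]
  # order parent edges into a chain
  ends <- unlist(lapply(pedges, function(e) c(e$from, e$to)))
  tab <- table(ends)
  endpoints <- as.numeric(names(tab)[tab == 1])
  if (length(endpoints) < 1)
    stop("parent vessel forms a closed loop; no origin defined")
  node_xyz <- function(id) {
    nd <- graph$nodes[graph$nodes$id == id, ]
    c(nd$x, nd$y, nd$z)
  }
  start <- if (!is.null(origin_mm)) {
    d <- vapply(endpoints, function(id)
      sum((node_xyz(id) - origin_mm)^2), numeric(1))
    endpoints[which.min(d)]
  } else {
    xyz <- t(vapply(endpoints, node_xyz, numeric(3)))
    endpoints[order(xyz[, 1], xyz[, 2], xyz[, 3])[1]]
  }
  # walk the chain accumulating arclength at nodes
  s_at <- setNames(0, as.character(start))
  cur <- start
  used <- rep(FALSE, length(pedges))
  repeat {
    nxt_i <- which(!used & vapply(pedges, function(e)
      e$from == cur || e$to == cur, logical(1)))
    if (!length(nxt_i)) break
    i <- nxt_i[1]
    used[i] <- TRUE
    e <- pedges[[i]]
    other <- if (e$from == cur) e$to else e$from
    s_at[as.character(other)] <- s_at[as.character(cur)] + e$arclength_mm
    cur <- other
  }
  deg <- edge_degrees(graph)
  count <- 0L
  for (nid in names(s_at)) {
    if (s_at[nid] > window_mm + 1e-9) next
    if (is.na(deg[nid]) || deg[nid] < 3) next
    inc <- vapply(graph$edges, function(e) {
      k <- 0L
      if (as.character(e$from) == nid) k <- k + 1L
      if (as.character(e$to) == nid) k <- k + 1L
      if (isTRUE((e$label %||% NA_character_) == parent_label)) k <- 0L
      k
    }, integer(1))
    count <- count + sum(inc)
  }
  as.integer(count)
}

#' CNR-based visibility score (0-3)
#'
#' Samples the volume along the true centerline (one sample per voxel of
#' arclength), computes the mean contrast-to-noise ratio against the
#' background ROI, and maps it to the 4-point visibility scale:
#' CNR < 1 -> 0 (absent), \[1, 3) -> 1 (weak), \[3, 6) -> 2 (good), and 6
#' or more -> 3 (very good). The thresholds are package calibration constants;
#' only orderings across protocols are meaningful.
#'
#' @param volume a [ct_volume()] of HU.
#' @param truth_segment a graph edge or point matrix (mm).
#' @param background a [roi_stats()] of nearby parenchyma.
#' @param thresholds the three CNR cut points.
#' @return Integer score in 0..3, with attribute `"cnr"`.
#' @export
visibility_score <- function(volume, truth_segment, background,
                             thresholds = c(1, 3, 6)) {
  assert_volume(volume)
  stopifnot(inherits(background, "roi_stats"))
  if (background$sd_hu <= 0)
    stop("undefined score: background ROI has zero standard deviation")
  P <- if (is.list(truth_segment)) truth_segment$points else truth_segment
  s <- cum_arclength(P)
  m <- max(2L, ceiling(s[length(s)] / voxel_mm(volume)) + 1L)
  Q <- resample_polyline(P, m)
  vals <- cpp_trilinear(as.numeric(volume$data), dim(volume$data),
                        voxel_mm(volume), volume$origin_mm, Q)
  cnr <- (mean(vals) - background$mean_hu) / background$sd_hu
  score <- as.integer(findInterval(cnr, thresholds))
  attr(score, "cnr") <- cnr
  score
}

#' Full morphometry report for one labeled network
#'
#' Applies the per-segment metrics (diameter, arc:chord ratio, middle
#' curvature, optional visibility) to every labeled edge and assembles the
#' network-level metrics (Circle-of-Willis width where the ring labels are
#' present; branch count where a parent label is given).
#'
#' @param graph labeled `centerline_graph`.
#' @param mask segmentation mask [ct_volume()] (for diameters), or `NULL`.
#' @param volume HU [ct_volume()] (for visibility), or `NULL`.
#' @param background [roi_stats()] for visibility, or `NULL`.
#' @param parent_label,window_mm branch-count settings, or `NULL` to skip.
#' @param stenosis_flag_ratio flag segments whose minimum/median local
#'   diameter ratio falls below this value.
#' @return List with data.frames `segments` and `network`.
#' @export
morphometry_report <- function(graph, mask = NULL, volume = NULL,
                               background = NULL, parent_label = NULL,
                               window_mm = 3, stenosis_flag_ratio = 0.7) {
  stopifnot(inherits(graph, "centerline_graph"))
  rows <- lapply(graph$edges, function(e) {
    lab <- e$label %||% NA_character_
    dia <- if (!is.null(mask))
      tryCatch(segment_diameter(e, mask), error = function(err) NA_real_)
    else NA_real_
    acr <- tryCatch(arc_chord_ratio(e), error = function(err) NA_real_)
    mc <- tryCatch(middle_curvature(e), error = function(err) NA_real_)
    vis <- if (!is.null(volume) && !is.null(background))
      tryCatch(as.integer(visibility_score(volume, e, background)),
               error = function(err) NA_integer_)
    else NA_integer_
    data.frame(label = lab, arclength_mm = e$arclength_mm,
               diameter_um = dia, arc_chord_ratio = acr,
               middle_curvature_per_mm = mc, visibility = vis)
  })
  segments <- do.call(rbind, rows)
  width <- tryCatch(cow_width(graph), error = function(err) NA_real_)
  bc <- if (!is.null(parent_label))
    tryCatch(count_branches(graph, parent_label, window_mm),
             error = function(err) NA_integer_)
  else NA_integer_
  list(segments = segments,
       network = data.frame(cow_width_mm = width, branch_count = bc))
}
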
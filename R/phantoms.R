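#' Vessel primitive: a centerline tube with a radius profile
#'
#' Ground-truth carrier for synthetic vessels: an ordered 3D polyline in
#' world coordinates (mm) with a per-point radius (um). Focal stenoses are
#' localized dips in the radius profile.
#'
#' @param label unique name tag.
#' @param points n x 3 matrix of centerline points (mm), n >= 2.
#' @param radius_um per-point radius (um), length n or 1.
#' @return A `vessel_primitive`.
#' @export
vessel_primitive <- function(label, points, radius_um) {
  points <- matrix(as.numeric(points), ncol = 3)
  n <- nrow(points)
  if (n < 2) stop("invalid geometry: a vessel primitive needs >= 2 points")
  radius_um <- rep_len(as.numeric(radius_um), n)
  if (any(radius_um <= 0)) stop("radii must be positive")
  steps <- sqrt(rowSums((points[-1, , drop = FALSE] -
                         points[-n, , drop = FALSE])^2))
  if (any(steps == 0)) stop("invalid geometry: coincident consecutive points")
  if (max(steps) > 0.5 * min(radius_um) / 1000 + 1e-12)
    stop("point spacing exceeds half the minimum radius; resample the ",
         "centerline more finely")
  structure(list(label = as.character(label), points = points,
                 radius_um = radius_um),
            class = "vessel_primitive")
}

polyline_arclength <- function(points) {
  n <- nrow(points)
  if (n < 2) return(0)
  sum(sqrt(rowSums((points[-1, , drop = FALSE] -
                    points[-n, , drop = FALSE])^2)))
}

# cumulative arclength (length n, starting at 0)
cum_arclength <- function(points) {
  n <- nrow(points)
  c(0, cumsum(sqrt(rowSums((points[-1, , drop = FALSE] -
                            points[-n, , drop = FALSE])^2))))
}

# resample a polyline (and optional per-point values) to m points uniform in
# arclength
resample_polyline <- function(points, m, values = NULL) {
  s <- cum_arclength(points)
  t <- seq(0, s[length(s)], length.out = m)
  out <- vapply(1:3, function(j) approx(s, points[, j], xout = t)$y,
                numeric(m))
  out <- matrix(out, ncol = 3)
  if (is.null(values)) return(out)
  list(points = out, values = approx(s, values, xout = t)$y)
}

#' Straight tube primitive
#'
#' @param start,end endpoints (mm); must differ.
#' @param radius_um constant tube radius (um).
#' @param n_points number of centerline points; default fine enough to meet
#'   the spacing invariant (spacing <= radius / 2.5).
#' @param label name tag.
#' @return A [vessel_primitive()] whose centerline arc:chord ratio is 1.
#' @export
make_tube <- function(start, end, radius_um, n_points = NULL,
                      label = "tube") {
  start <- as.numeric(start); end <- as.numeric(end)
  len <- sqrt(sum((end - start)^2))
  if (len == 0) stop("invalid geometry: coincident endpoints")
  if (is.null(n_points))
    n_points <- max(2L, ceiling(len / (0.4 * radius_um / 1000)) + 1L)
  if (n_points < 2) stop("invalid geometry: need n_points >= 2")
  t <- seq(0, 1, length.out = n_points)
  pts <- cbind(start[1] + t * (end[1] - start[1]),
               start[2] + t * (end[2] - start[2]),
               start[3] + t * (end[3] - start[3]))
  vessel_primitive(label, pts, radius_um)
}

#' Circular-arc primitive
#'
#' Analytic curvature fixture: the centerline is a circular arc of radius
#' `radius_mm`, so its true curvature is `1 / radius_mm` everywhere and its
#' arc:chord ratio is `span / (2 sin(span / 2))`.
#'
#' @param center arc center (mm).
#' @param radius_mm arc radius (mm).
#' @param angular_span arc span (radians), in (0, 2 pi].
#' @param tube_radius_um tube radius (um).
#' @param n_points number of points; default meets the spacing invariant.
#' @param start_angle starting angle (radians) in the arc plane.
#' @param label name tag.
#' @return A [vessel_primitive()].
#' @export
make_arc <- function(center, radius_mm, angular_span, tube_radius_um,
                     n_points = NULL, start_angle = 0, label = "arc") {
  if (radius_mm <= 0) stop("invalid geometry: arc radius must be positive")
  if (!(angular_span > 0 && angular_span <= 2 * pi + 1e-12))
    stop("invalid geometry: angular span must be in (0, 2*pi]")
  len <- radius_mm * angular_span
  if (is.null(n_points))
    n_points <- max(3L, ceiling(len / (0.4 * tube_radius_um / 1000)) + 1L)
  th <- start_angle + seq(0, angular_span, length.out = n_points)
  pts <- cbind(center[1] + radius_mm * cos(th),
               center[2] + radius_mm * sin(th),
               rep(center[3], n_points))
  vessel_primitive(label, pts, tube_radius_um)
}

#' Trunk with side branches inside an arclength window
#'
#' Emulates the pontine-artery counting setup: a straight basilar-like trunk
#' with `branch_count` thin side branches whose origins lie strictly inside
#' the first `window_mm` of trunk arclength (plus optional branches beyond
#' the window). Origins are evenly spaced with a small seeded jitter, so the
#' layout is deterministic given `seed`.
#'
#' @param trunk_length_mm trunk length (mm).
#' @param trunk_radius_um trunk radius (um).
#' @param branch_count number of in-window branches.
#' @param branch_radius_um branch radius (um).
#' @param window_mm counting window measured from the trunk origin.
#' @param branch_length_mm branch length (mm).
#' @param extra_branches branches placed beyond the window (for testing the
#'   window bookkeeping).
#' @param seed jitter seed.
#' @param trunk_label,branch_prefix labels.
#' @return List of [vessel_primitive()]s; the trunk runs from the origin
#'   `(0, 0, 0)` along +y.
#' @export
make_branching_trunk <- function(trunk_length_mm = 3.5, trunk_radius_um = 120,
                                 branch_count = 7, branch_radius_um = 40,
                                 window_mm = 3.0, branch_length_mm = 0.8,
                                 extra_branches = 0, seed = 1,
                                 trunk_label = "basilar",
                                 branch_prefix = "pontine") {
  if (branch_count < 0) stop("branch_count must be >= 0")
  if (window_mm > trunk_length_mm)
    stop("window_mm must not exceed trunk_length_mm")
  trunk <- make_tube(c(0, 0, 0), c(0, trunk_length_mm, 0), trunk_radius_um,
                     label = trunk_label)
  origins <- numeric(0)
  if (branch_count > 0) {
    base <- window_mm * (seq_len(branch_count) - 0.5) / branch_count
    gap <- window_mm / branch_count
    jit <- with_seed(seed, runif(branch_count, -0.25 * gap, 0.25 * gap))
    origins <- base + jit
  }
  if (extra_branches > 0) {
    span <- trunk_length_mm - window_mm
    extra <- window_mm + span * (seq_len(extra_branches) - 0.5) /
      extra_branches
    origins <- c(origins, extra)
  }
  if (length(origins) > 1) {
    if (min(diff(sort(origins))) < 2 * branch_radius_um / 1000)
      stop("invalid geometry: branch origins closer than twice the branch ",
           "radius")
  }
  golden <- 2.399963229728653
  branches <- lapply(seq_along(origins), function(k) {
    phi <- k * golden
    d <- c(cos(phi), 0, sin(phi))
    p0 <- c(0, origins[k], 0)
    make_tube(p0, p0 + d * branch_length_mm, branch_radius_um,
              label = sprintf("%s_%02d", branch_prefix, k))
  })
  c(list(trunk), branches)
}

#' Phantom specification
#'
#' A set of vessel primitives plus the voxel grid they will be rendered
#' into. If `volume_shape`/`origin_mm` are omitted they are derived from the
#' primitive bounding box plus `margin_mm`.
#'
#' @param primitives list of [vessel_primitive()] with unique labels.
#' @param voxel_um isotropic voxel size (um).
#' @param volume_shape integer length-3 voxel counts, or `NULL` to fit.
#' @param origin_mm world position (mm) of the first voxel center, or `NULL`.
#' @param parenchyma_hu,skull_hu compartment HU defaults carried as metadata.
#' @param skull_shell optional list(center, semiaxes_mm, thickness_mm)
#'   describing an ellipsoidal skull shell.
#' @param margin_mm padding around the primitive bounding box when fitting.
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(primitives, voxel_um = 19, volume_shape = NULL,
                         origin_mm = NULL, parenchyma_hu = 73,
                         skull_hu = 1800, skull_shell = NULL,
                         margin_mm = 0.25) {
  stopifnot(is.list(primitives), length(primitives) >= 0)
  labs <- vapply(primitives, function(p) p$label, character(1))
  if (anyDuplicated(labs)) stop("primitive labels must be unique")
  h <- voxel_um / 1000
  if (length(primitives)) {
    allpts <- do.call(rbind, lapply(primitives, `[[`, "points"))
    rmax <- max(vapply(primitives, function(p) max(p$radius_um), numeric(1)))
    lo <- apply(allpts, 2, min) - rmax / 1000 - margin_mm
    hi <- apply(allpts, 2, max) + rmax / 1000 + margin_mm
  } else {
    lo <- c(0, 0, 0); hi <- c(1, 1, 1) * h * 15
  }
  if (is.null(origin_mm)) origin_mm <- lo
  if (is.null(volume_shape))
    volume_shape <- pmax(2L, as.integer(ceiling((hi - origin_mm) / h)) + 1L)
  volume_shape <- as.integer(volume_shape)
  # every primitive (inflated by its radius) must fit inside the grid
  upper <- origin_mm + (volume_shape - 1) * h
  for (p in primitives) {
    pad <- max(p$radius_um) / 1000
    if (any(sweep(p$points, 2, origin_mm + pad - h / 2, "-") < -1e-9) ||
        any(sweep(p$points, 2, upper - pad + h / 2, "-") > 1e-9))
      stop("primitive '", p$label, "' does not fit inside the volume bounds")
  }
  structure(list(primitives = primitives, voxel_um = voxel_um,
                 volume_shape = volume_shape, origin_mm = origin_mm,
                 parenchyma_hu = parenchyma_hu, skull_hu = skull_hu,
                 skull_shell = skull_shell),
            class = "phantom_spec")
}

#' Circle-of-Willis ring phantom
#'
#' A planar closed ring of six labeled arcs (anterior left/right, lateral
#' internal-carotid analogs left/right, posterior left/right) plus two
#' afferent trunks (an azygos-pericallosal analog at the anterior junction
#' and a basilar analog at the posterior junction). The ring is an ellipse
#' whose lateral extremal separation -- the ground-truth Circle-of-Willis
#' width -- equals `width_mm` exactly, also after straightening (lateral
#' extent is rescaled to preserve the width). Anatomical fidelity is not
#' attempted; only the measured quantities (width, tortuosity, stenosis) are
#' faithful.
#'
#' @param width_mm ground-truth ring width (mm); the wild-type default is
#'   2.82 mm.
#' @param ap_ratio anterior-posterior semi-axis as a multiple of the lateral
#'   semi-axis.
#' @param ring_radius_um tube radius of the ring arcs (um).
#' @param trunk_radius_um tube radius of the two trunks (um).
#' @param trunk_length_mm length of the afferent trunks (mm).
#' @param straightening 0 = curved (typical tortuosity), 1 = fully straight
#'   arcs; each arc is blended toward its chord.
#' @param stenosis_labels labels of ring segments that receive a focal
#'   stenosis (radius dip), or `NULL`.
#' @param stenosis_severity fractional radius reduction at the dip center,
#'   in \[0, 1).
#' @param stenosis_extent affected fraction of segment arclength.
#' @param voxel_um,margin_mm,parenchyma_hu,skull_hu passed to
#'   [phantom_spec()].
#' @return A [phantom_spec()] with attribute `"truth_width_mm"`.
#' @export
make_cow_phantom <- function(width_mm = 2.82, ap_ratio = 1.15,
                             ring_radius_um = 80, trunk_radius_um = 95,
                             trunk_length_mm = 0.7, straightening = 0,
                             stenosis_labels = NULL, stenosis_severity = 0.5,
                             stenosis_extent = 0.1, voxel_um = 19,
                             margin_mm = 0.25, parenchyma_hu = 73,
                             skull_hu = 1800) {
  if (width_mm <= 0) stop("invalid geometry: width must be positive")
  a <- width_mm / 2
  if (a <= 2 * ring_radius_um / 1000)
    stop("invalid geometry: width too small for the ring tube radius")
  if (!(straightening >= 0 && straightening <= 1))
    stop("straightening factor must be in [0, 1]")
  if (!(stenosis_severity >= 0 && stenosis_severity < 1))
    stop("stenosis severity must be in [0, 1)")
  b <- a * ap_ratio
  segs <- list(
    anterior_right  = c(0, 1) * pi / 4,
    ica_right       = c(1, 3) * pi / 4,
    posterior_right = c(3, 4) * pi / 4,
    posterior_left  = -c(4, 3) * pi / 4,
    ica_left        = -c(3, 1) * pi / 4,
    anterior_left   = -c(1, 0) * pi / 4)
  spacing <- 0.4 * ring_radius_um / 1000
  ring <- lapply(names(segs), function(lab) {
    th0 <- segs[[lab]][1]; th1 <- segs[[lab]][2]
    sp <- spacing
    if (lab %in% stenosis_labels) sp <- sp * (1 - stenosis_severity)
    len <- 0.5 * (a + b) * abs(th1 - th0)  # generous estimate
    m <- max(8L, ceiling(len / sp) + 1L)
    th <- seq(th0, th1, length.out = m)
    pts <- cbind(a * sin(th), b * cos(th), 0)
    if (straightening > 0) {
      t <- seq(0, 1, length.out = m)
      chord <- outer(1 - t, pts[1, ]) + outer(t, pts[m, ])
      pts <- (1 - straightening) * pts + straightening * chord
    }
    list(label = lab, points = pts, radius_um = rep(ring_radius_um, m))
  })
  names(ring) <- names(segs)
  # restore the lateral extremal separation after straightening
  latx <- max(abs(c(ring$ica_right$points[, 1], ring$ica_left$points[, 1])))
  if (latx > 0 && abs(latx - a) > 1e-12) {
    k <- a / latx
    ring <- lapply(ring, function(rg) { rg$points[, 1] <- rg$points[, 1] * k; rg })
  }
  # focal stenoses
  if (!is.null(stenosis_labels)) {
    for (lab in stenosis_labels) {
      if (!lab %in% names(ring)) stop("unknown ring segment label: ", lab)
      rg <- ring[[lab]]
      s <- cum_arclength(rg$points)
      u <- s / s[length(s)]
      dip <- 1 - stenosis_severity * exp(-((u - 0.5) / (stenosis_extent / 2))^2)
      ring[[lab]]$radius_um <- rg$radius_um * dip
    }
  }
  prims <- lapply(ring, function(rg)
    vessel_primitive(rg$label, rg$points, rg$radius_um))
  ant <- c(0, b, 0); post <- c(0, -b, 0)
  prims <- c(prims, list(
    make_tube(ant, ant + c(0, trunk_length_mm, 0), trunk_radius_um,
              label = "azygos_pericallosal"),
    make_tube(post, post - c(0, trunk_length_mm, 0), trunk_radius_um,
              label = "basilar")))
  spec <- phantom_spec(unname(prims), voxel_um = voxel_um,
                       margin_mm = margin_mm, parenchyma_hu = parenchyma_hu,
                       skull_hu = skull_hu)
  attr(spec, "truth_width_mm") <- width_mm
  spec
}

#' Rasterize a phantom into a binary mask plus ground-truth graph
#'
#' A voxel is foreground iff at least 50% of its `supersample^3` sample
#' points fall inside any vessel tube (partial-volume rule). The returned
#' ground-truth [centerline graph][build_graph()] carries the exact
#' world-space centerlines and radii of the primitives.
#'
#' @param spec a [phantom_spec()].
#' @param supersample samples per axis per voxel (1..4; default 3).
#' @return List with elements `mask` (logical [ct_volume()]) and `truth`
#'   (a `centerline_graph`).
#' @export
rasterize <- function(spec, supersample = 3) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (supersample < 1) stop("supersample must be >= 1")
  h <- spec$voxel_um / 1000
  if (supersample == 1) {
    rmin <- suppressWarnings(min(vapply(spec$primitives,
                                        function(p) min(p$radius_um),
                                        numeric(1))))
    if (is.finite(rmin) && 2 * rmin < spec$voxel_um)
      warning("vessels thinner than one voxel at supersample 1 may ",
              "disappear (sub-resolution)")
  }
  prims <- lapply(spec$primitives, function(p)
    list(points = p$points, radius_mm = p$radius_um / 1000))
  m <- cpp_rasterize(prims, spec$volume_shape, h, spec$origin_mm,
                     as.integer(supersample))
  mask <- ct_volume(array(m, dim = spec$volume_shape), spec$voxel_um,
                    spec$origin_mm)
  list(mask = mask, truth = graph_from_primitives(spec))
}

#' Render a phantom into a noisy HU volume
#'
#' Builds the compartment HU map (vessel HU from the contrast model inside
#' the rasterized vessels, parenchyma elsewhere, optional ellipsoidal skull
#' shell with air outside), blurs it with a Gaussian PSF and adds Gaussian
#' noise with the protocol's [noise_sigma()]. Deterministic given `seed`.
#'
#' @param spec a [phantom_spec()].
#' @param contrast a [contrast_model()].
#' @param protocol an [acquisition_protocol()]; its `voxel_um` overrides the
#'   spec's voxel size if they differ.
#' @param seed RNG seed for the noise field.
#' @param mask optional precomputed rasterized mask (skips rasterization).
#' @param supersample passed to [rasterize()].
#' @param psf_fwhm_vox PSF full width at half maximum in voxels (default 1.5,
#'   near-voxel-limited resolution); 0 disables blurring.
#' @param sigma_ref reference noise SD (HU), see [noise_sigma()].
#' @param air_hu HU outside the skull shell.
#' @param ring_artifact add a concentric ring artifact (additive radial
#'   sinusoid about the z axis)?
#' @param ring_amp_hu,ring_period_vox ring artifact amplitude and period.
#' @return A [ct_volume()] of HU values.
#' @export
render_ct <- function(spec, contrast, protocol, seed = NULL, mask = NULL,
                      supersample = 3, psf_fwhm_vox = 1.5, sigma_ref = 60,
                      air_hu = -1000, ring_artifact = FALSE,
                      ring_amp_hu = 30, ring_period_vox = 8) {
  if (missing(contrast) || !inherits(contrast, "contrast_model"))
    stop("config error: `contrast` must be a contrast_model")
  if (missing(protocol) || !inherits(protocol, "acquisition_protocol"))
    stop("config error: `protocol` must be an acquisition_protocol")
  if (!is.null(spec) && !is.null(protocol$voxel_um) &&
      inherits(spec, "phantom_spec") &&
      abs(protocol$voxel_um - spec$voxel_um) > 1e-9)
    spec$voxel_um <- protocol$voxel_um
  if (is.null(mask)) mask <- rasterize(spec, supersample)$mask
  assert_volume(mask)
  dm <- dim(mask$data)
  hu <- array(contrast$background_hu, dim = dm)
  if (inherits(spec, "phantom_spec") && !is.null(spec$skull_shell)) {
    sh <- spec$skull_shell
    ijk <- as.matrix(expand.grid(seq_len(dm[1]), seq_len(dm[2]),
                                 seq_len(dm[3])))
    w <- vox_to_world(mask, ijk)
    rr <- sqrt(((w[, 1] - sh$center[1]) / sh$semiaxes_mm[1])^2 +
               ((w[, 2] - sh$center[2]) / sh$semiaxes_mm[2])^2 +
               ((w[, 3] - sh$center[3]) / sh$semiaxes_mm[3])^2)
    th <- sh$thickness_mm / mean(sh$semiaxes_mm)
    hu[rr > 1 + th] <- air_hu
    hu[rr >= 1 & rr <= 1 + th] <- contrast$skull_hu
  }
  hu[mask$data] <- vessel_hu(contrast)
  if (psf_fwhm_vox > 0) {
    k <- gaussian_kernel(psf_fwhm_vox / (2 * sqrt(2 * log(2))), order = 0)
    v <- as.numeric(hu)
    for (ax in 0:2) v <- cpp_conv3_axis(v, dm, k, ax)
    hu <- array(v, dim = dm)
  }
  sig <- if (sigma_ref > 0) noise_sigma(protocol, sigma_ref) else 0
  if (sig > 0)
    hu <- hu + array(with_seed(seed, rnorm(prod(dm), 0, sig)), dim = dm)
  if (ring_artifact) {
    cx <- (dm[1] + 1) / 2; cy <- (dm[2] + 1) / 2
    r2 <- outer(seq_len(dm[1]) - cx, seq_len(dm[2]) - cy,
                function(x, y) sqrt(x^2 + y^2))
    hu <- hu + array(rep(ring_amp_hu * sin(2 * pi * r2 / ring_period_vox),
                         dm[3]), dim = dm)
  }
  ct_volume(hu, mask$voxel_um, mask$origin_mm)
}

#' Cohort parameters
#'
#' Generative parameters of one experimental group of Circle-of-Willis
#' phantoms. Defaults reproduce the wild-type group (width 2.82 +/- 0.19 mm,
#' n = 7); the knock-out analog is `cohort_params("ko", 6, 2.56, 0.08)` and
#' the heterozygous analog `cohort_params("het", 9, 2.74, 0.23)`.
#'
#' @param group group label.
#' @param n_subjects number of subjects (>= 1).
#' @param cow_width_mean_mm,cow_width_sd_mm Normal parameters of the
#'   ground-truth width (truncated positive).
#' @param straightening straightening factor passed to [make_cow_phantom()].
#' @param stenosis_prob per-subject probability of one focal stenosis.
#' @param stenosis_severity fractional radius reduction, in \[0, 1).
#' @param seed master seed of the group.
#' @return A `cohort_params` object.
#' @export
cohort_params <- function(group = "wt", n_subjects = 7,
                          cow_width_mean_mm = 2.82, cow_width_sd_mm = 0.19,
                          straightening = 0, stenosis_prob = 0,
                          stenosis_severity = 0.5, seed = 1) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (cow_width_sd_mm < 0) stop("cow_width_sd_mm must be >= 0")
  if (!(stenosis_severity >= 0 && stenosis_severity < 1))
    stop("stenosis severity must be in [0, 1)")
  structure(list(group = group, n_subjects = as.integer(n_subjects),
                 cow_width_mean_mm = cow_width_mean_mm,
                 cow_width_sd_mm = cow_width_sd_mm,
                 straightening = straightening,
                 stenosis_prob = stenosis_prob,
                 stenosis_severity = stenosis_severity, seed = seed),
            class = "cohort_params")
}

#' Generate a cohort of Circle-of-Willis phantoms
#'
#' Draws each subject's ground-truth width from
#' `Normal(cow_width_mean_mm, cow_width_sd_mm)` truncated positive, builds
#' the phantom, and (optionally) renders the noisy HU volume. Fully
#' reproducible: the same `params$seed` yields bit-identical ground truth
#' and volumes.
#'
#' @param params a [cohort_params()].
#' @param contrast,protocol passed to [render_ct()] when `render = TRUE`;
#'   defaults are the high-dose (2.2 g I/kg, 50 kVp) high-res protocol.
#' @param render render noisy HU volumes (`TRUE`) or return phantom specs
#'   only (`FALSE`, cheap; geometry-level studies).
#' @param voxel_um voxel size of the phantom grid.
#' @param ... further arguments to [make_cow_phantom()].
#' @return List of subjects, each a list with elements `id`, `group`,
#'   `spec`, `truth_width_mm`, `stenosed`, `seed` and (if rendered)
#'   `volume`.
#' @export
make_cohort <- function(params, contrast = NULL, protocol = NULL,
                        render = TRUE, voxel_um = 19, ...) {
  stopifnot(inherits(params, "cohort_params"))
  n <- params$n_subjects
  draws <- with_seed(params$seed, {
    widths <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        w <- rnorm(1, params$cow_width_mean_mm, params$cow_width_sd_mm)
        if (w > 0) break
      }
      widths[i] <- w
    }
    list(widths = widths,
         sten = runif(n) < params$stenosis_prob,
         seeds = sample.int(.Machine$integer.max - 1L, n))
  })
  if (render) {
    if (is.null(contrast)) contrast <- contrast_model(2.2, kvp = 50)
    if (is.null(protocol)) protocol <- acquisition_protocol(voxel_um = voxel_um)
  }
  lapply(seq_len(n), function(i) {
    sten_lab <- if (draws$sten[i]) "ica_left" else NULL
    spec <- make_cow_phantom(width_mm = draws$widths[i],
                             straightening = params$straightening,
                             stenosis_labels = sten_lab,
                             stenosis_severity = params$stenosis_severity,
                             voxel_um = voxel_um, ...)
    subj <- list(id = sprintf("%s_%02d", params$group, i),
                 group = params$group, spec = spec,
                 truth_width_mm = draws$widths[i],
                 stenosed = draws$sten[i], seed = draws$seeds[i])
    if (render)
      subj$volume <- render_ct(spec, contrast, protocol,
                               seed = draws$seeds[i])
    subj
  })
}
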
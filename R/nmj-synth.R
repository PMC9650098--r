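#' Shape and imaging parameters for a synthetic NMJ stack
#'
#' Targets and acquisition settings for [render_nmj_stack()].  Geometry is
#' specified in physical units; the renderer works at `pixel_size` um/px so
#' results are pixel-size independent to first order.  The rendered field
#' defaults to 256 x 256 px (a single-NMJ crop, rather than a full
#' 1200 x 1200 acquisition field) with a z-stack of `n_slices` at
#' `z_step` um.
#'
#' @param target_endplate_csa Target projected endplate area, um^2.
#' @param target_apposition Target percent of endplate area covered by the
#'   pre-synaptic terminal, `[0, 100]`.
#' @param target_relative_planar_area Target endplate area as a percent of
#'   its axis-aligned bounding rectangle, `(0, 100]`.
#' @param branch_count Number of curvilinear branches of the endplate
#'   "pretzel" (>= 1); one closed loop plus `branch_count - 1` arms.
#' @param branch_width Nominal branch width, um (initial guess only; realised
#'   width follows from the area target).
#' @param fiber_diameter Diameter of the underlying muscle fibre, um
#'   (metadata used for fibre-type classification, not rendered).
#' @param pixel_size In-plane pixel size, um/px.
#' @param z_step Z-step between slices, um.
#' @param n_slices Number of z-slices (1-50; typical projections use 6-12).
#' @param canvas Field size in pixels (square).
#' @param psf_sigma Gaussian point-spread sigma, um (in-plane).
#' @param amplitude Peak signal intensity above background, arbitrary units.
#' @param background Background intensity level.
#' @param noise_sd Gaussian noise SD on intensities.
#' @param fringe_fraction Fraction of the terminal lying outside the endplate
#'   (pre-synaptic fringe), so apposition (normalised to the post-synaptic
#'   area) differs from overlap normalised to the pre-synaptic area.
#' @param seed Seed for the stack's randomness; `NULL` leaves the RNG alone.
#' @return An object of class `nmj_shape_params`.
#' @export
nmj_shape_params <- function(target_endplate_csa = 417,
                             target_apposition = 60.7,
                             target_relative_planar_area = 48.7,
                             branch_count = 4,
                             branch_width = 1.5,
                             fiber_diameter = 40,
                             pixel_size = 0.176,
                             z_step = 2,
                             n_slices = 8,
                             canvas = 256,
                             psf_sigma = 0.15,
                             amplitude = 150,
                             background = 20,
                             noise_sd = 7.5,
                             fringe_fraction = 0.05,
                             seed = NULL) {
  stopifnot_scalar_pos(target_endplate_csa, "target_endplate_csa")
  if (target_apposition < 0 || target_apposition > 100) {
    abort("`target_apposition` must lie in [0, 100].")
  }
  if (target_relative_planar_area <= 0 || target_relative_planar_area > 100) {
    abort("`target_relative_planar_area` must lie in (0, 100].")
  }
  if (branch_count < 1) abort("`branch_count` must be >= 1.")
  if (n_slices < 1 || n_slices > 50) abort("`n_slices` must lie in [1, 50].")
  stopifnot_scalar_pos(pixel_size, "pixel_size")
  stopifnot_scalar_pos(z_step, "z_step")
  stopifnot_scalar_pos(fiber_diameter, "fiber_diameter")
  if (fringe_fraction < 0 || fringe_fraction >= 1) {
    abort("`fringe_fraction` must lie in [0, 1).")
  }
  structure(
    list(target_endplate_csa = target_endplate_csa,
         target_apposition = target_apposition,
         target_relative_planar_area = target_relative_planar_area,
         branch_count = branch_count, branch_width = branch_width,
         fiber_diameter = fiber_diameter,
         pixel_size = pixel_size, z_step = z_step, n_slices = n_slices,
         canvas = canvas, psf_sigma = psf_sigma, amplitude = amplitude,
         background = background, noise_sd = noise_sd,
         fringe_fraction = fringe_fraction, seed = seed),
    class = "nmj_shape_params"
  )
}

# smooth scalar field on an ny x nx grid: coarse white noise, bilinear upsample
smooth_field <- function(ny, nx, scale = 10) {
  cy <- max(2L, ceiling(ny / scale))
  cx <- max(2L, ceiling(nx / scale))
  coarse <- matrix(rnorm(cy * cx), cy, cx)
  fine <- EBImage::resize(coarse, w = ny, h = nx)
  matrix(as.numeric(fine), ny, nx)
}

# random curvilinear skeleton ("pretzel"): a wobbly closed loop plus arms
# leaving from the loop, in unit coordinates spanning [0,1] x [0,1]
nmj_skeleton <- function(branch_count) {
  phi <- seq(0, 2 * pi, length.out = 500)
  a <- rnorm(2, 0, 0.06)
  ps <- runif(2, 0, 2 * pi)
  r <- 1 + a[1] * sin(2 * phi + ps[1]) + a[2] * sin(3 * phi + ps[2])
  rot <- runif(1, 0, pi)
  ax <- runif(1, 0.38, 0.5)
  ay <- runif(1, 0.28, 0.4)
  lx <- r * ax * cos(phi)
  ly <- r * ay * sin(phi)
  x <- 0.5 + lx * cos(rot) - ly * sin(rot)
  y <- 0.5 + lx * sin(rot) + ly * cos(rot)
  pts <- cbind(x, y)
  for (b in seq_len(max(0, branch_count - 1))) {
    i0 <- sample(length(phi), 1)
    p0 <- pts[i0, ]
    side <- sample(4, 1)
    p2 <- switch(side,
                 c(runif(1), 0), c(runif(1), 1),
                 c(0, runif(1)), c(1, runif(1)))
    pc <- (p0 + p2) / 2 + rnorm(2, 0, 0.12)
    s <- seq(0, 1, length.out = 200)
    bx <- (1 - s)^2 * p0[1] + 2 * s * (1 - s) * pc[1] + s^2 * p2[1]
    by <- (1 - s)^2 * p0[2] + 2 * s * (1 - s) * pc[2] + s^2 * p2[2]
    pts <- rbind(pts, cbind(bx, by))
  }
  pts[, 1] <- (pts[, 1] - min(pts[, 1])) / diff(range(pts[, 1]))
  pts[, 2] <- (pts[, 2] - min(pts[, 2])) / diff(range(pts[, 2]))
  pts
}

#' Render a synthetic two-channel NMJ z-stack with ground truth
#'
#' Builds a post-synaptic endplate mask as a union of smoothed curvilinear
#' branches, iteratively rescaled so the projected area matches
#' `target_endplate_csa` (within 2%) and the bounding-rectangle fill ratio
#' matches `target_relative_planar_area` (within 3 points); constructs the
#' pre-synaptic terminal as a spatially coherent subset of the endplate
#' covering `target_apposition` percent of its pixels plus a small
#' non-overlapping fringe; distributes both masks across z-slices with a
#' smooth depth field; and renders intensities with a Gaussian PSF,
#' background and noise.  Ground truth is recorded from the pre-blur masks.
#'
#' @param params An [nmj_shape_params()].
#' @return A list with `stack` (class `nmj_stack`: integer intensity volumes
#'   `post` and `pre` of dim canvas x canvas x n_slices, plus calibration
#'   metadata) and `truth` (class `nmj_ground_truth`: true binary projection
#'   masks, true endplate/terminal CSA in um^2, true apposition and relative
#'   planar area in percent, fibre diameter, and the intended fibre-type
#'   class from [classify_fiber_type()]).
#' @export
render_nmj_stack <- function(params = nmj_shape_params()) {
  stopifnot(inherits(params, "nmj_shape_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  p <- params$pixel_size
  nc <- params$canvas
  area_px <- round(params$target_endplate_csa / p^2)
  if (area_px < 10) abort("Target endplate area is below the pixel resolution.")

  pts <- nmj_skeleton(params$branch_count)

  bbox_px <- area_px / (params$target_relative_planar_area / 100)
  aspect <- runif(1, 1.05, 1.35)
  w_est <- max(2, params$branch_width / (2 * p))
  sk_w <- sqrt(bbox_px * aspect) - 2 * w_est
  sk_h <- bbox_px / sqrt(bbox_px * aspect) - 2 * w_est
  if (max(sk_w, sk_h) > nc - 8) {
    abort(sprintf(
      "Requested geometry (bbox %.0f px) does not fit the %d-px canvas.",
      sqrt(bbox_px * aspect), nc))
  }

  mask <- NULL
  achieved <- NULL
  for (iter in 1:12) {
    ox <- (nc - sk_w) / 2
    oy <- (nc - sk_h) / 2
    ix <- pmin(nc, pmax(1, round(ox + pts[, 1] * sk_w)))
    iy <- pmin(nc, pmax(1, round(oy + pts[, 2] * sk_h)))
    bg <- matrix(1, nc, nc)
    bg[cbind(ix, iy)] <- 0
    d <- matrix(as.numeric(EBImage::distmap(bg)), nc, nc)
    thr <- sort(d, partial = area_px)[area_px]
    mask <- d <= thr
    rows <- range(which(rowSums(mask) > 0))
    cols <- range(which(colSums(mask) > 0))
    bw <- diff(rows) + 1
    bh <- diff(cols) + 1
    area_a <- sum(mask)
    rpa_a <- 100 * area_a / (bw * bh)
    achieved <- list(area = area_a, rpa = rpa_a)
    if (abs(rpa_a - params$target_relative_planar_area) < 1 &&
        abs(area_a - area_px) / area_px < 0.02) break
    bbox_des <- area_a / (params$target_relative_planar_area / 100)
    bw_des <- sqrt(bbox_des * bw / bh)
    bh_des <- bbox_des / bw_des
    sk_w <- min(nc - 8, sk_w * bw_des / bw)
    sk_h <- min(nc - 8, sk_h * bh_des / bh)
  }
  if (abs(achieved$area - area_px) / area_px > 0.02 ||
      abs(achieved$rpa - params$target_relative_planar_area) > 3) {
    abort(sprintf(
      "Geometry targets unreachable: achieved area %.0f um^2 / fill %.1f%% vs requested %.0f um^2 / %.1f%%.",
      achieved$area * p^2, achieved$rpa,
      params$target_endplate_csa, params$target_relative_planar_area))
  }

  post_mask <- mask
  n_post <- sum(post_mask)

  # pre-synaptic terminal: coherent subset of the endplate + external fringe
  field <- smooth_field(nc, nc)
  k <- round(params$target_apposition / 100 * n_post)
  pre_mask <- matrix(FALSE, nc, nc)
  if (k > 0) {
    in_post <- which(post_mask)
    sel <- in_post[order(field[in_post], decreasing = TRUE)[seq_len(k)]]
    pre_mask[sel] <- TRUE
  }
  if (params$fringe_fraction > 0 && k > 0) {
    brush <- EBImage::makeBrush(7, shape = "disc")
    dil <- matrix(as.numeric(EBImage::dilate(post_mask * 1, brush)), nc, nc) > 0
    band <- which(dil & !post_mask)
    m_f <- min(length(band),
               round(params$fringe_fraction / (1 - params$fringe_fraction) * k))
    if (m_f > 0) {
      sel_f <- band[order(field[band], decreasing = TRUE)[seq_len(m_f)]]
      pre_mask[sel_f] <- TRUE
    }
  }

  truth <- structure(
    list(
      post_mask = post_mask,
      pre_mask = pre_mask,
      endplate_csa = n_post * p^2,
      terminal_csa = sum(pre_mask) * p^2,
      apposition = if (n_post > 0) 100 * sum(pre_mask & post_mask) / n_post else NA_real_,
      orthogonal_area = achieved$area / (achieved$rpa / 100) * p^2,
      relative_planar_area = achieved$rpa,
      fiber_diameter = params$fiber_diameter,
      intended_class = classify_fiber_type(n_post * p^2, params$fiber_diameter)
    ),
    class = "nmj_ground_truth"
  )

  # depth field: both channels share one smooth z-profile
  ns <- params$n_slices
  zf <- smooth_field(nc, nc, scale = 16)
  zc <- if (ns > 1) {
    1 + (ns - 1) * (rank(zf) - 0.5) / length(zf)
  } else {
    matrix(1, nc, nc)
  }
  zc <- matrix(zc, nc, nc)

  render_channel <- function(mask) {
    vol <- array(0, dim = c(nc, nc, ns))
    sig_px <- params$psf_sigma / p
    for (s in seq_len(ns)) {
      w <- exp(-(s - zc)^2 / (2 * 0.9^2))
      slice <- params$amplitude * (mask * w)
      if (sig_px > 0.2) {
        slice <- matrix(as.numeric(EBImage::gblur(slice, sigma = sig_px)), nc, nc)
      }
      slice <- slice + params$background + rnorm(nc * nc, sd = params$noise_sd)
      vol[, , s] <- round(pmax(0, slice))
    }
    vol
  }

  stack <- structure(
    list(
      post = render_channel(post_mask),
      pre = render_channel(pre_mask),
      pixel_size = p,
      z_step = params$z_step,
      channels = c("BTX", "SYN"),
      meta = list(fiber_diameter = params$fiber_diameter,
                  seed = params$seed,
                  params = params)
    ),
    class = "nmj_stack"
  )
  list(stack = stack, truth = truth)
}

#' @export
print.nmj_stack <- function(x, ...) {
  d <- dim(x$post)
  cat(sprintf(
    "<nmj_stack> %d x %d px x %d slices x 2 channels (%s), %.3f um/px, z-step %g um\n",
    d[1], d[2], d[3], paste(x$channels, collapse = "/"), x$pixel_size, x$z_step))
  invisible(x)
}

#' @export
print.nmj_ground_truth <- function(x, ...) {
  cat(sprintf(
    "<nmj_ground_truth> endplate %.0f um^2, terminal %.0f um^2, apposition %.1f%%, fill %.1f%%, fibre %.0f um (%s)\n",
    x$endplate_csa, x$terminal_csa, x$apposition, x$relative_planar_area,
    x$fiber_diameter, x$intended_class))
  invisible(x)
}

#' Per-class parameter distributions for synthetic NMJ cohorts
#'
#' Default distributions emulating the two morphological classes of
#' diaphragm NMJs: small endplates on small-diameter fibres (type I/IIa,
#' endplate CSA about 280 um^2, apposition about 60%) and large endplates on
#' large fibres (type IIx/IIb, about 500 um^2, apposition about 56%).
#' Draws are truncated-normal; type I/IIa ranges keep all draws below the
#' 500-um^2 / 50-um classification boundaries, while the type IIx/IIb ranges
#' straddle them so a fraction of drawn NMJs fails the joint size criteria
#' and is flagged "excluded", as in real cohorts.
#'
#' @return Named list of per-class distribution parameter lists.
#' @export
nmj_class_defaults <- function() {
  list(
    I_IIa = list(csa_mean = 280, csa_sd = 50, csa_range = c(150, 490),
                 rpa_mean = 45, rpa_sd = 4,
                 appos_mean = 60.7, appos_sd = 5,
                 diam_mean = 38, diam_sd = 5, diam_range = c(25, 49.5)),
    IIx_IIb = list(csa_mean = 500, csa_sd = 60, csa_range = c(260, 750),
                   rpa_mean = 50, rpa_sd = 4,
                   appos_mean = 56.4, appos_sd = 5,
                   diam_mean = 55, diam_sd = 5, diam_range = c(40, 70))
  )
}

#' Generate a synthetic NMJ cohort
#'
#' Draws per-NMJ geometry targets from the per-class distributions and
#' renders each stack with [render_nmj_stack()].  Deterministic given `seed`;
#' each stack's own seed is derived from it.
#'
#' @param n_per_class NMJs per class per animal.
#' @param n_animals Number of animals.
#' @param class_params Per-class distribution list (see
#'   [nmj_class_defaults()]).
#' @param seed Integer master seed.
#' @param ... Further arguments passed to [nmj_shape_params()] (e.g.
#'   `canvas`, `n_slices`, `noise_sd`).
#' @return A tibble with one row per NMJ: `animal_id`, `drawn_class`,
#'   `intended_class` (after applying the joint size criteria to the drawn
#'   geometry), `fiber_diameter`, the drawn targets, and list-columns
#'   `stack` and `truth`.
#' @export
generate_nmj_cohort <- function(n_per_class = 5, n_animals = 4,
                                class_params = nmj_class_defaults(),
                                seed = 1, ...) {
  if (n_per_class < 1 || n_animals < 1) {
    abort("`n_per_class` and `n_animals` must be >= 1.")
  }
  set.seed(seed)
  rtrunc <- function(n, mean, sd, range) {
    pmin(range[2], pmax(range[1], rnorm(n, mean, sd)))
  }
  draws <- purrr::imap(class_params, function(cp, cls) {
    n <- n_per_class * n_animals
    tibble(
      animal_id = rep(sprintf("R%02d", seq_len(n_animals)), each = n_per_class),
      drawn_class = cls,
      target_csa = rtrunc(n, cp$csa_mean, cp$csa_sd, cp$csa_range),
      target_rpa = rtrunc(n, cp$rpa_mean, cp$rpa_sd, c(30, 70)),
      target_appos = rtrunc(n, cp$appos_mean, cp$appos_sd, c(20, 90)),
      fiber_diameter = rtrunc(n, cp$diam_mean, cp$diam_sd, cp$diam_range)
    )
  }) %>% bind_rows()
  draws$stack_seed <- (seed + 7907L * seq_len(nrow(draws))) %% .Machine$integer.max

  dots <- list(...)
  rendered <- purrr::map(seq_len(nrow(draws)), function(i) {
    args <- dots
    # grow the rendered field when a large, low-fill endplate needs the room
    p_px <- args$pixel_size %||% 0.176
    need <- ceiling(sqrt((draws$target_csa[i] / p_px^2) /
                           (draws$target_rpa[i] / 100) * 1.4)) + 24
    args$canvas <- max(args$canvas %||% 256, need)
    args$target_endplate_csa <- draws$target_csa[i]
    args$target_apposition <- draws$target_appos[i]
    args$target_relative_planar_area <- draws$target_rpa[i]
    args$fiber_diameter <- draws$fiber_diameter[i]
    args$seed <- draws$stack_seed[i]
    render_nmj_stack(do.call(nmj_shape_params, args))
  })
  draws %>%
    mutate(
      intended_class = purrr::map_chr(rendered, ~ as.character(.x$truth$intended_class)),
      stack = purrr::map(rendered, "stack"),
      truth = purrr::map(rendered, "truth")
    )
}
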
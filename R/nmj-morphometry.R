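#' Maximum-intensity projection of a two-channel NMJ stack
#'
#' Projects each channel over a slice range.  By default the range is chosen
#' automatically per channel: a slice is included when its bright tail
#' (99.9th percentile) clearly exceeds the background estimate (the channel
#' median), i.e. is above both twice the background and the background plus
#' five robust noise SDs.  Slices of pure background are thereby excluded
#' from the projection, emulating how only the z-slices containing the NMJ
#' (typically 6-12) enter the projection image.
#'
#' @param stack An `nmj_stack`.
#' @param slices Optional integer vector of slices to project (both
#'   channels); `NULL` selects automatically.
#' @return An object of class `nmj_projection`: list with matrices `post`
#'   and `pre`, `pixel_size`, and `slices` (the per-channel slice indices
#'   used).
#' @export
project_stack <- function(stack, slices = NULL) {
  stopifnot(inherits(stack, "nmj_stack"))
  ns <- dim(stack$post)[3]
  if (!is.null(slices)) {
    slices <- as.integer(slices)
    if (length(slices) == 0 || any(slices < 1 | slices > ns)) {
      abort("`slices` must be a non-empty set of valid slice indices.")
    }
    sel <- list(post = slices, pre = slices)
  } else {
    auto <- function(vol) {
      bg <- median(vol)
      noise <- stats::mad(vol)
      bright <- apply(vol, 3, quantile, probs = 0.999)
      which(bright > pmax(2 * bg, bg + 5 * noise))
    }
    sel <- list(post = auto(stack$post), pre = auto(stack$pre))
    if (length(sel$post) == 0 && length(sel$pre) == 0) {
      abort("No signal slices found in either channel.")
    }
    # fall back to the partner channel's range if one channel is empty
    if (length(sel$post) == 0) sel$post <- sel$pre
    if (length(sel$pre) == 0) sel$pre <- sel$post
  }
  mip <- function(vol, s) {
    if (length(s) == 1) return(vol[, , s])
    apply(vol[, , s, drop = FALSE], c(1, 2), max)
  }
  structure(
    list(post = mip(stack$post, sel$post), pre = mip(stack$pre, sel$pre),
         pixel_size = stack$pixel_size, slices = sel),
    class = "nmj_projection"
  )
}

#' Threshold a projected channel into a binary mask
#'
#' @param image Intensity matrix (one projected channel).
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param value Threshold intensity for `method = "fixed"`.
#' @return A logical mask with attributes `method` and `threshold` (the
#'   absolute intensity threshold applied), so the choice is logged with the
#'   result.
#' @export
threshold_channel <- function(image, method = c("otsu", "fixed"), value = NULL) {
  method <- match.arg(method)
  if (method == "otsu") {
    rng <- range(image)
    if (diff(rng) == 0) abort("Cannot Otsu-threshold a constant image.")
    norm <- (image - rng[1]) / diff(rng)
    thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1), levels = 256)
    thr_abs <- rng[1] + thr * diff(rng)
  } else {
    if (is.null(value)) abort("`value` is required for method = \"fixed\".")
    thr_abs <- value
  }
  mask <- image > thr_abs
  attr(mask, "method") <- method
  attr(mask, "threshold") <- as.numeric(thr_abs)
  mask
}

#' Clean a binary mask
#'
#' Removes speckle objects smaller than `min_area` um^2 and optionally keeps
#' only the largest connected component.  Applied after thresholding to
#' suppress noise-driven specks before area measurement.
#'
#' @param mask Logical matrix.
#' @param pixel_size Pixel size, um/px.
#' @param min_area Minimum object area to keep, um^2.
#' @param keep_largest Keep only the largest connected component.
#' @return A logical mask.
#' @export
clean_mask <- function(mask, pixel_size, min_area = 2, keep_largest = FALSE) {
  if (!any(mask)) return(mask)
  lab <- EBImage::bwlabel(mask * 1)
  sizes <- table(lab[lab > 0])
  keep <- as.integer(names(sizes)[sizes * pixel_size^2 >= min_area])
  if (keep_largest && length(keep) > 1) {
    keep <- as.integer(names(sizes)[which.max(sizes)])
  }
  out <- matrix(as.numeric(lab) %in% keep, nrow(mask), ncol(mask))
  out
}

#' Pre/post-synaptic apposition
#'
#' Percent of the post-synaptic endplate area co-localised with the
#' pre-synaptic terminal: `100 * |pre AND post| / |post|`.  The denominator
#' is the endplate (post) area, so terminal signal outside the endplate does
#' not enter the statistic.
#'
#' @param pre_mask,post_mask Logical masks of the projected terminal and
#'   endplate.
#' @return Apposition in percent.
#' @export
compute_apposition <- function(pre_mask, post_mask) {
  if (!any(post_mask)) abort("Post-synaptic mask is empty.")
  100 * sum(pre_mask & post_mask) / sum(post_mask)
}

#' Projected area, orthogonal area and relative planar area of a mask
#'
#' `csa` is the pixel count times the pixel area; `orthogonal_area` is the
#' area of the axis-aligned bounding rectangle of the mask (the rectangular
#' xy boundaries of an endplate); `relative_planar_area = 100 * csa /
#' orthogonal_area` measures how much of its own bounding rectangle the
#' shape fills - a planar complexity index.
#'
#' @param mask Logical matrix.
#' @param pixel_size Pixel size, um/px.
#' @return A one-row tibble with `csa`, `orthogonal_area` (um^2) and
#'   `relative_planar_area` (percent).
#' @export
compute_areas <- function(mask, pixel_size) {
  stopifnot_scalar_pos(pixel_size, "pixel_size")
  if (!any(mask)) abort("Mask is empty.")
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  csa <- sum(mask) * pixel_size^2
  orth <- (diff(rows) + 1) * (diff(cols) + 1) * pixel_size^2
  tibble(csa = csa, orthogonal_area = orth,
         relative_planar_area = 100 * csa / orth)
}

#' Classify an NMJ's fibre type from size criteria
#'
#' Joint morphological criteria: endplate planar area < 500 um^2 on a fibre
#' of diameter < 50 um is classed type I/IIa; area > 500 um^2 on a fibre
#' > 50 um is classed type IIx/IIb.  NMJs that do not meet both criteria of
#' either class (including exact boundary values) are flagged `excluded`;
#' excluded NMJs are kept for overall per-animal estimates but dropped from
#' type-specific analyses.
#'
#' @param endplate_planar_area Endplate planar area(s), um^2.
#' @param fiber_diameter Fibre diameter(s), um.
#' @return Factor with levels `I_IIa`, `IIx_IIb`, `excluded` (vectorised).
#' @examples
#' classify_fiber_type(c(400, 600, 600), c(40, 60, 40))
#' @export
classify_fiber_type <- function(endplate_planar_area, fiber_diameter) {
  if (any(endplate_planar_area <= 0) || any(fiber_diameter <= 0)) {
    abort("Areas and diameters must be positive.")
  }
  cls <- dplyr::case_when(
    endplate_planar_area < 500 & fiber_diameter < 50 ~ "I_IIa",
    endplate_planar_area > 500 & fiber_diameter > 50 ~ "IIx_IIb",
    TRUE ~ "excluded"
  )
  factor(cls, levels = c("I_IIa", "IIx_IIb", "excluded"))
}

#' Measure a single NMJ stack
#'
#' Full morphometry chain for one two-channel stack: projection,
#' per-channel thresholding, mask cleanup, endplate and terminal areas,
#' apposition, and fibre-type classification.
#'
#' @param stack An `nmj_stack`.
#' @param fiber_diameter Fibre diameter, um; defaults to the stack metadata.
#'   (Fibre diameter is supplied metadata; measuring it from images is out
#'   of scope.)
#' @param method,value Thresholding method and fixed value, see
#'   [threshold_channel()].
#' @param min_area,keep_largest Mask cleanup, see [clean_mask()].
#' @param slices Optional projection slice range.
#' @return A one-row tibble: `apposition`, `endplate_csa`, `terminal_csa`,
#'   `orthogonal_area`, `relative_planar_area`, `fiber_diameter`,
#'   `fiber_type_class`, `n_projected_slices`, `threshold_post`,
#'   `threshold_pre`, `threshold_method`.
#' @export
measure_nmj <- function(stack, fiber_diameter = NULL,
                        method = c("otsu", "fixed"), value = NULL,
                        min_area = 2, keep_largest = TRUE, slices = NULL) {
  method <- match.arg(method)
  fiber_diameter <- fiber_diameter %||% stack$meta$fiber_diameter
  proj <- project_stack(stack, slices = slices)
  post_m <- threshold_channel(proj$post, method, value)
  pre_m <- threshold_channel(proj$pre, method, value)
  post_c <- clean_mask(post_m, proj$pixel_size, min_area, keep_largest)
  pre_c <- clean_mask(pre_m, proj$pixel_size, min_area, keep_largest = FALSE)
  post_a <- compute_areas(post_c, proj$pixel_size)
  pre_a <- compute_areas(pre_c, proj$pixel_size)
  tibble(
    apposition = compute_apposition(pre_c, post_c),
    endplate_csa = post_a$csa,
    terminal_csa = pre_a$csa,
    orthogonal_area = post_a$orthogonal_area,
    relative_planar_area = post_a$relative_planar_area,
    fiber_diameter = fiber_diameter,
    fiber_type_class = classify_fiber_type(post_a$csa, fiber_diameter),
    n_projected_slices = length(proj$slices$post),
    threshold_post = attr(post_m, "threshold"),
    threshold_pre = attr(pre_m, "threshold"),
    threshold_method = method
  )
}

#' Analyze a cohort of NMJ stacks
#'
#' Measures every stack and aggregates to per-animal means: type-specific
#' means over classified NMJs, and overall per-animal means that retain
#' excluded NMJs (excluded NMJs are flagged, not dropped, for animal-level
#' estimates).
#'
#' @param cohort A data frame with columns `animal_id` and `stack`
#'   (list-column of `nmj_stack`), e.g. from [generate_nmj_cohort()];
#'   optional `fiber_diameter` overrides stack metadata.
#' @param ... Passed to [measure_nmj()].
#' @return A list of tibbles: `per_nmj` (one row per NMJ), `per_animal_class`
#'   (type-specific per-animal means) and `per_animal` (overall per-animal
#'   means including excluded NMJs).
#' @export
analyze_nmj_cohort <- function(cohort, ...) {
  if (!all(c("animal_id", "stack") %in% names(cohort)) || nrow(cohort) < 1) {
    abort("`cohort` needs at least one row and columns `animal_id` and `stack`.")
  }
  per_nmj <- purrr::map(seq_len(nrow(cohort)), function(i) {
    fd <- if ("fiber_diameter" %in% names(cohort)) cohort$fiber_diameter[i] else NULL
    measure_nmj(cohort$stack[[i]], fiber_diameter = fd, ...) %>%
      mutate(animal_id = cohort$animal_id[i], nmj = i, .before = 1)
  }) %>% bind_rows()

  metrics <- c("apposition", "endplate_csa", "terminal_csa",
               "relative_planar_area")
  per_animal_class <- per_nmj %>%
    filter(.data$fiber_type_class != "excluded") %>%
    group_by(.data$animal_id, .data$fiber_type_class) %>%
    summarise(dplyr::across(dplyr::all_of(metrics), mean),
              n_nmj = dplyr::n(), .groups = "drop")
  per_animal <- per_nmj %>%
    group_by(.data$animal_id) %>%
    summarise(dplyr::across(dplyr::all_of(metrics), mean),
              n_nmj = dplyr::n(),
              n_excluded = sum(.data$fiber_type_class == "excluded"),
              .groups = "drop")
  list(per_nmj = per_nmj, per_animal_class = per_animal_class,
       per_animal = per_animal)
}
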
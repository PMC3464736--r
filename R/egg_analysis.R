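#' Estimate the single-egg area
#'
#' Components whose eccentricity falls strictly inside the window
#' `(e1, e2)` are taken as single-egg candidates (a lone egg is an elongated
#' ellipse; piles of overlapping eggs are more circular, dirt specks are
#' irregular). The estimate `S` is the mode of the candidate areas. Because
#' areas are near-continuous, the mode is computed over geometric bins of
#' relative width 10%: candidate areas are binned by
#' `floor(log(area / min_area) / log(1.1))`, the most populous bin wins
#' (ties toward the smaller-area bin), and the median area inside the winning
#' bin is returned.
#'
#' @param cs a [label_components()] result.
#' @param params an [egg_params()] object.
#' @return object of class `"egg_size_estimate"`: list with `s` (estimated
#'   area, pixels), `n_candidates`, `candidate_areas`.
#' @export
estimate_egg_size <- function(cs, params = egg_params()) {
  st <- cs$stats
  cand <- st$area[st$eccentricity > params$e1 & st$eccentricity < params$e2]
  if (length(cand) == 0L)
    stop(errorCondition(
      sprintf(paste("no single-egg candidates: no component has eccentricity",
                    "in (%.3f, %.3f); widen the eccentricity window"),
              params$e1, params$e2),
      class = c("ovocount_no_candidates", "error")))
  bin <- floor(log(cand / min(cand)) / log(1.1))
  counts <- table(bin)
  best <- as.numeric(names(counts)[which.max(counts)])  # first max = smallest bin
  s <- stats::median(cand[bin == best])
  structure(list(s = s, n_candidates = length(cand),
                 candidate_areas = as.numeric(cand)),
            class = "egg_size_estimate")
}

#' Per-pixel chroma map
#'
#' Chroma is the spread between the largest and smallest channel,
#' `C = max(R, G, B) - min(R, G, B)`: 0 for achromatic (gray) pixels, large
#' for saturated colors such as the yellow-brown halos surrounding debris.
#'
#' @param img RGB image (`H x W x 3` in `[0, 1]`).
#' @return `H x W` numeric matrix of chroma in `[0, 1]`.
#' @export
chroma_map <- function(img) {
  img <- as_rgb_array(img)
  ch <- pmax(img[, , 1L], img[, , 2L], img[, , 3L]) -
    pmin(img[, , 1L], img[, , 2L], img[, , 3L])
  dim(ch) <- dim(img)[1:2]
  ch
}

#' Flag debris components by their chromatic surroundings
#'
#' A component is debris when at least `X = chroma_min_pixels` pixels with
#' chroma above `C_E = chroma_cutoff` lie within Chebyshev distance
#' `debris_radius` (the radius r) of any of its pixels (component pixels
#' included) —
#' the yellow-brown halo that dried organic debris leaves on the paper.
#'
#' @param cs a [label_components()] result.
#' @param chroma chroma matrix from [chroma_map()], same shape as the mask.
#' @param params an [egg_params()] object.
#' @return logical vector, one flag per component (label order).
#' @export
debris_flags <- function(cs, chroma, params = egg_params()) {
  if (!identical(dim(chroma), as.integer(cs$shape)) &&
      !identical(dim(chroma), cs$shape))
    stop("debris_flags: chroma map shape differs from the mask", call. = FALSE)
  st <- cs$stats
  if (nrow(st) == 0L) return(logical(0L))
  r <- params$debris_radius
  chromatic <- chroma > params$chroma_cutoff
  H <- cs$shape[1L]; W <- cs$shape[2L]
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "box")
  vapply(seq_len(nrow(st)), function(i) {
    r0 <- max(1L, st$min_row[i] - r); r1 <- min(H, st$max_row[i] + r)
    c0 <- max(1L, st$min_col[i] - r); c1 <- min(W, st$max_col[i] + r)
    sub <- cs$labels[r0:r1, c0:c1] == st$label[i]
    near <- EBImage::dilate(EBImage::Image(sub * 1), brush) > 0
    sum(chromatic[r0:r1, c0:c1] & near) >= params$chroma_min_pixels
  }, logical(1L))
}

#' Debris test for a single component
#'
#' Convenience wrapper around [debris_flags()] for one labeled component.
#'
#' @param cs a [label_components()] result.
#' @param label component id.
#' @param chroma chroma matrix from [chroma_map()].
#' @param params an [egg_params()] object.
#' @return `TRUE` if the component is debris.
#' @export
is_debris <- function(cs, label, chroma, params = egg_params()) {
  flags <- debris_flags(cs, chroma, params)
  st_label <- cs$stats$label
  if (!label %in% st_label) stop("is_debris: no such label", call. = FALSE)
  flags[match(label, st_label)]
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Number of eggs in an object by area division
#'
#' An object of area `A` holds `round(A / S)` eggs when `A <= 2 S`, and
#' `round(A * C / S)` otherwise, where `S` is the estimated single-egg area
#' and `C < 1` is the accumulative ratio discounting the shadowed overlap
#' regions that enlarge a pile's silhouette. Rounding is half-away-from-zero.
#' A surviving (non-debris, non-noise) object holds at least one egg, so the
#' result is floored at 1.
#'
#' @param area object area(s), pixels (vectorized).
#' @param s estimated single-egg area, `>= 1`.
#' @param c_ratio accumulative ratio in `(0, 1)`.
#' @return integer egg count(s), `>= 1`.
#' @export
count_eggs_in_object <- function(area, s, c_ratio = 0.9) {
  stopifnot(s >= 1, c_ratio > 0, c_ratio < 1)
  n <- ifelse(area <= 2 * s,
              round_half_away(area / s),
              round_half_away(area * c_ratio / s))
  as.integer(pmax(n, 1))
}

#' Identify sub-half-egg noise components
#'
#' Components smaller than half the estimated egg size are noise — typically
#' thresholding residue on the paper's grid lines — and contribute zero eggs.
#' The rule is strict: area exactly `S / 2` is kept.
#'
#' @param areas component areas (pixels).
#' @param s estimated single-egg area.
#' @return logical vector, `TRUE` = noise (area `< s / 2`).
#' @export
is_noise <- function(areas, s) {
  stopifnot(s >= 1)
  areas < s / 2
}

#' Remove noise components from a component set
#'
#' Drops every component with area strictly below `s / 2` and relabels the
#' survivors compactly in their original order.
#'
#' @param cs a [label_components()] result.
#' @param s estimated single-egg area.
#' @return a `component_set` containing only components with area `>= s / 2`.
#' @export
remove_noise <- function(cs, s) {
  drop <- cs$stats$label[is_noise(cs$stats$area, s)]
  if (length(drop) == 0L) return(cs)
  labels <- cs$labels
  labels[labels %in% drop] <- 0L
  keep <- sort(setdiff(unique(as.vector(labels)), 0L))
  remap <- integer(max(c(keep, 0L)))
  remap[keep] <- seq_along(keep)
  labels[labels > 0L] <- remap[labels[labels > 0L]]
  structure(list(labels = labels, stats = component_stats(labels),
                 shape = cs$shape),
            class = "component_set")
}

#' Count the eggs in a filter-paper photograph
#'
#' Runs the full pipeline: luminance conversion, capped entropic threshold,
#' binarization, 8-connected component extraction, single-egg size
#' estimation from the eccentricity window, chroma-based debris rejection
#' (on the original color image), sub-half-egg noise removal, and per-object
#' egg counts by area division. Deterministic for fixed inputs.
#'
#' A uniform (e.g. blank paper) image admits no threshold; the result is
#' then empty (zero eggs, no records) and a classed warning
#' (`ovocount_degenerate_image`) is raised.
#'
#' @param img RGB image (`H x W x 3` array in `[0, 1]`), or an `H x W`
#'   luminance matrix (treated as achromatic).
#' @param params an [egg_params()] object.
#' @return object of class `"egg_analysis"`: list with
#'   \describe{
#'     \item{records}{data frame, one row per extracted component: `label`,
#'       `area`, `eccentricity`, `classification` (one of `single_egg`,
#'       `pile`, `debris`, `noise`), `egg_count`, and bounding box columns}
#'     \item{total_eggs}{sum of `egg_count`}
#'     \item{threshold}{the [entropic_threshold()] result (or `NULL` when
#'       degenerate)}
#'     \item{egg_size}{the [estimate_egg_size()] result (or `NULL`)}
#'     \item{params}{the parameters used}
#'   }
#' @export
analyze_image <- function(img, params = egg_params()) {
  img <- as_rgb_array(img)
  validate_params(params)
  gray <- to_grayscale(img, params$luminance_weights)

  th <- tryCatch(entropic_threshold(intensity_histogram(gray), params$t_cap),
                 ovocount_degenerate_image = function(e) e)
  if (inherits(th, "ovocount_degenerate_image")) {
    warning(warningCondition(conditionMessage(th),
                             class = "ovocount_degenerate_image"))
    return(empty_analysis(params))
  }

  mask <- binarize(gray, th$t_auto)
  cs <- label_components(mask)
  if (nrow(cs$stats) == 0L) return(empty_analysis(params, threshold = th))

  size <- estimate_egg_size(cs, params)
  debris <- debris_flags(cs, chroma_map(img), params)
  noise <- !debris & is_noise(cs$stats$area, size$s)

  st <- cs$stats
  cls <- ifelse(debris, "debris",
                ifelse(noise, "noise",
                       ifelse(st$eccentricity > params$e1 &
                                st$eccentricity < params$e2,
                              "single_egg", "pile")))
  counted <- !debris & !noise
  n <- integer(nrow(st))
  n[counted] <- count_eggs_in_object(st$area[counted], size$s,
                                     params$accumulative_ratio)
  records <- data.frame(label = st$label, area = st$area,
                        eccentricity = st$eccentricity,
                        classification = cls, egg_count = n,
                        min_row = st$min_row, min_col = st$min_col,
                        max_row = st$max_row, max_col = st$max_col,
                        row.names = NULL)
  structure(list(records = records, total_eggs = sum(n), threshold = th,
                 egg_size = size, params = params),
            class = "egg_analysis")
}

empty_analysis <- function(params, threshold = NULL) {
  structure(list(
    records = data.frame(label = integer(), area = integer(),
                         eccentricity = numeric(), classification = character(),
                         egg_count = integer(), min_row = integer(),
                         min_col = integer(), max_row = integer(),
                         max_col = integer()),
    total_eggs = 0L, threshold = threshold, egg_size = NULL, params = params),
    class = "egg_analysis")
}

#' @export
print.egg_analysis <- function(x, ...) {
  cat("Egg batch analysis\n")
  if (!is.null(x$threshold))
    cat(sprintf("  threshold: %d (cap %d)\n", x$threshold$t_auto,
                x$threshold$t_cap))
  if (!is.null(x$egg_size))
    cat(sprintf("  single-egg area S: %.1f px (%d candidates)\n",
                x$egg_size$s, x$egg_size$n_candidates))
  tab <- table(factor(x$records$classification,
                      levels = c("single_egg", "pile", "debris", "noise")))
  cat(sprintf("  objects: %d single, %d pile, %d debris, %d noise\n",
              tab[["single_egg"]], tab[["pile"]], tab[["debris"]],
              tab[["noise"]]))
  cat(sprintf("  total eggs: %d\n", x$total_eggs))
  invisible(x)
}
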
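#' Label 8-connected foreground components
#'
#' Partitions the foreground of a binary mask into connected components under
#' 8-adjacency (pixels touching by edge or corner belong to the same object).
#' Labels are assigned in raster-scan order of first encounter, so the result
#' is deterministic. Border-touching components are kept.
#'
#' @param mask `H x W` logical matrix, `TRUE` = foreground.
#' @return object of class `"component_set"`: list with
#'   \describe{
#'     \item{labels}{`H x W` integer matrix, 0 = background, `1..n` = component id}
#'     \item{stats}{data frame of per-component descriptors, one row per
#'       component, ordered by label: `label`, `area`, centroid
#'       (`cbar_row`, `cbar_col`), central moments `mu20` (row), `mu02`
#'       (column), `mu11`, `eccentricity`, and bounding box
#'       `min_row`, `min_col`, `max_row`, `max_col` (1-based, inclusive)}
#'     \item{shape}{`c(H, W)`}
#'   }
#' @export
label_components <- function(mask) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("label_components: 'mask' must be a logical matrix", call. = FALSE)
  labels <- .label8_cpp(mask)
  structure(list(labels = labels, stats = component_stats(labels),
                 shape = dim(mask)),
            class = "component_set")
}

component_stats <- function(labels) {
  idx <- which(labels > 0L)
  empty <- data.frame(label = integer(), area = integer(),
                      cbar_row = numeric(), cbar_col = numeric(),
                      mu20 = numeric(), mu02 = numeric(), mu11 = numeric(),
                      eccentricity = numeric(),
                      min_row = integer(), min_col = integer(),
                      max_row = integer(), max_col = integer())
  if (length(idx) == 0L) return(empty)
  lab <- labels[idx]
  rc <- arrayInd(idx, dim(labels))
  u <- rc[, 1L]; v <- rc[, 2L]
  n <- max(lab)
  area <- tabulate(lab, nbins = n)
  su <- rowsum(u, lab, reorder = TRUE)[, 1L]
  sv <- rowsum(v, lab, reorder = TRUE)[, 1L]
  ubar <- su / area; vbar <- sv / area
  du <- u - ubar[lab]; dv <- v - vbar[lab]
  mu20 <- rowsum(du * du, lab, reorder = TRUE)[, 1L]
  mu02 <- rowsum(dv * dv, lab, reorder = TRUE)[, 1L]
  mu11 <- rowsum(du * dv, lab, reorder = TRUE)[, 1L]
  bb <- vapply(split(seq_along(lab), lab), function(i)
    c(min(u[i]), min(v[i]), max(u[i]), max(v[i])), integer(4L))
  data.frame(label = seq_len(n), area = area,
             cbar_row = ubar, cbar_col = vbar,
             mu20 = mu20, mu02 = mu02, mu11 = mu11,
             eccentricity = moment_eccentricity(mu20, mu02, mu11),
             min_row = bb[1L, ], min_col = bb[2L, ],
             max_row = bb[3L, ], max_col = bb[4L, ],
             row.names = NULL)
}

#' Central moments of a pixel set
#'
#' Second-order central moments about the pixel centroid:
#' `mu_mn = sum over pixels (u - ubar)^m (v - vbar)^n`, with `u` the row and
#' `v` the column coordinate. Raw (non-normalized) sums; eccentricity depends
#' only on their ratios, so normalization by area is immaterial.
#'
#' @param pixels two-column matrix of (row, col) pixel coordinates.
#' @return named numeric vector `c(mu20, mu02, mu11)` (pixel^2 units).
#' @export
central_moments <- function(pixels) {
  pixels <- as.matrix(pixels)
  stopifnot(ncol(pixels) == 2L, nrow(pixels) >= 1L)
  du <- pixels[, 1L] - mean(pixels[, 1L])
  dv <- pixels[, 2L] - mean(pixels[, 2L])
  c(mu20 = sum(du * du), mu02 = sum(dv * dv), mu11 = sum(du * dv))
}

#' Eccentricity from second central moments
#'
#' The eigenvalues of the second-moment (covariance) matrix are
#' `lambda = (mu20 + mu02)/2 +- sqrt(4 mu11^2 + (mu20 - mu02)^2)/2`;
#' eccentricity is `e = sqrt(1 - lambda_min/lambda_max)`, in `[0, 1]`:
#' 0 for a disk, approaching 1 for a line segment (for a filled ellipse with
#' semi-axes `a >= b`, `e = sqrt(1 - (b/a)^2)`, the focal-distance to
#' major-axis ratio). Degenerate cases: a single pixel (both eigenvalues 0)
#' has `e = 0`; a 1-pixel-thick straight segment (`lambda_min = 0`,
#' `lambda_max > 0`) has `e = 1`.
#'
#' @param mu20,mu02,mu11 central moments (vectorized).
#' @return eccentricity value(s) in `[0, 1]`.
#' @export
moment_eccentricity <- function(mu20, mu02, mu11) {
  s <- mu20 + mu02
  d <- sqrt(4 * mu11^2 + (mu20 - mu02)^2)
  l1 <- (s - d) / 2
  l2 <- (s + d) / 2
  e <- ifelse(l2 <= 0, 0, sqrt(pmax(0, 1 - l1 / pmax(l2, .Machine$double.xmin))))
  unname(pmin(pmax(e, 0), 1))
}

#' Pixel coordinates of one component
#'
#' @param cs a [label_components()] result.
#' @param label component id.
#' @return two-column integer matrix of (row, col), 1-based.
#' @export
component_pixels <- function(cs, label) {
  idx <- which(cs$labels == label)
  rc <- arrayInd(idx, cs$shape)
  colnames(rc) <- c("row", "col")
  rc
}
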
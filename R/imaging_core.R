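#' Construct an RGB image from an array
#'
#' Images are stored as plain `H x W x 3` numeric arrays with channel
#' intensities in `[0, 1]`, row index = image row. This constructor only
#' validates and tags the array; all pipeline functions accept the bare array
#' as well.
#'
#' @param pixels numeric array, `H x W x 3`, values in `[0, 1]`.
#' @return the validated array, classed `"rgb_image"`.
#' @export
rgb_image <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3L] != 3L)
    stop("rgb_image: 'pixels' must be an H x W x 3 array", call. = FALSE)
  if (dim(pixels)[1L] < 1L || dim(pixels)[2L] < 1L)
    stop("rgb_image: image must have at least one pixel", call. = FALSE)
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1)
    stop("rgb_image: intensities must lie in [0, 1]", call. = FALSE)
  structure(pixels, class = c("rgb_image", class(pixels)))
}

as_rgb_array <- function(img) {
  # Accepts an rgb_image, a bare HxWx3 array, or an HxW luminance matrix
  # (replicated to three identical channels, i.e. chroma 0).
  if (is.matrix(img)) {
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  }
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3L] != 3L)
    stop("expected an H x W x 3 RGB array or an H x W luminance matrix",
         call. = FALSE)
  unclass(img)
}

#' Default luminance weights
#'
#' Rec. 601 luma coefficients for the red, green and blue channels. They sum
#' to one, so a pure gray pixel keeps its intensity.
#' @export
LUMINANCE_WEIGHTS <- c(r = 0.299, g = 0.587, b = 0.114)

#' Convert a color image to luminance
#'
#' Luminance is the weighted sum of the three channels,
#' `I = w_r R + w_g G + w_b B`, clipped to `[0, 1]`.
#'
#' @param img RGB image (`H x W x 3` array in `[0, 1]`); an `H x W` matrix is
#'   accepted and returned unchanged (already luminance).
#' @param weights non-negative length-3 vector of channel weights.
#' @return `H x W` numeric matrix of luminance in `[0, 1]`.
#' @export
to_grayscale <- function(img, weights = LUMINANCE_WEIGHTS) {
  if (is.matrix(img)) return(pmin(pmax(img, 0), 1))
  img <- as_rgb_array(img)
  stopifnot(length(weights) == 3L, all(weights >= 0))
  g <- img[, , 1L] * weights[1L] + img[, , 2L] * weights[2L] +
    img[, , 3L] * weights[3L]
  g <- pmin(pmax(g, 0), 1)
  dim(g) <- dim(img)[1:2]
  g
}

#' Quantize luminance to 8-bit levels
#'
#' Maps `[0, 1]` to integer levels `{0, ..., 255}` by `floor(I * 255 + 0.5)`.
#' Thresholds throughout the package are expressed on this 8-bit scale.
#'
#' @param gray numeric matrix (or vector) of luminance in `[0, 1]`.
#' @return integer matrix/vector of levels in `0..255`.
#' @export
quantize255 <- function(gray) {
  q <- floor(gray * 255 + 0.5)
  storage.mode(q) <- "integer"
  q
}

#' Intensity histogram of a luminance image
#'
#' @param gray `H x W` luminance matrix in `[0, 1]`.
#' @return object of class `"intensity_histogram"`: a list with `probs`
#'   (256-bin probability vector over levels 0..255, sums to 1), `cum`
#'   (cumulative probabilities `P(T)`), and `n` (pixel count).
#' @export
intensity_histogram <- function(gray) {
  if (length(gray) == 0L)
    stop("intensity_histogram: empty image", call. = FALSE)
  lev <- quantize255(gray)
  counts <- tabulate(as.integer(lev) + 1L, nbins = 256L)
  probs <- counts / sum(counts)
  structure(list(probs = probs, cum = cumsum(probs), n = sum(counts)),
            class = "intensity_histogram")
}

yen_criterion <- function(probs, cum, T) {
  # C_B(T) + C_F(T): entropic-correlation criterion for splitting the
  # histogram at level T (background = levels 0..T, foreground = T+1..255).
  PT <- cum[T + 1L]  # cum is indexed by level+1
  if (PT <= 0 || PT >= 1) return(NA_real_)
  pb <- probs[seq_len(T + 1L)]
  pf <- probs[(T + 2L):256L]
  cb <- -log(sum((pb / PT)^2))
  cf <- -log(sum((pf / (1 - PT))^2))
  cb + cf
}

#' Automatic capped entropic threshold
#'
#' Selects the threshold maximizing the entropic-correlation criterion
#' `C_B(T) + C_F(T)` with
#' `C_B(T) = -log sum_{g<=T} (p(g)/P(T))^2` and
#' `C_F(T) = -log sum_{g>T} (p(g)/(1-P(T)))^2`,
#' searching only `T` in `1..(t_cap - 1)`. The cap `t_cap` keeps the
#' threshold below flash-overexposed highlights; useful values lie around
#' 160-180 on the 8-bit scale. Levels with `P(T)` equal to 0 or 1 are
#' inadmissible (they put all mass in one class); ties break toward the
#' smallest `T`.
#'
#' @param hist an [intensity_histogram()].
#' @param t_cap integer cap on the threshold, in `1..255`.
#' @return object of class `"threshold_result"`: list with integer `t_auto`,
#'   `t_cap`, and `criterion_curve` (named numeric over the searched range,
#'   `NA` at inadmissible `T`).
#' @export
entropic_threshold <- function(hist, t_cap = 170L) {
  stopifnot(inherits(hist, "intensity_histogram"))
  t_cap <- as.integer(t_cap)
  if (t_cap < 1L || t_cap > 255L)
    stop("entropic_threshold: t_cap must be in 1..255", call. = FALSE)
  Ts <- seq_len(max(t_cap - 1L, 0L))
  curve <- vapply(Ts, function(T) yen_criterion(hist$probs, hist$cum, T),
                  numeric(1L))
  names(curve) <- Ts
  if (length(curve) == 0L || all(is.na(curve)))
    stop(errorCondition(
      paste("degenerate image: no threshold below the cap separates two",
            "intensity classes"),
      class = c("ovocount_degenerate_image", "error")))
  t_auto <- Ts[which.max(curve)]  # which.max skips NA, first max wins
  structure(list(t_auto = as.integer(t_auto), t_cap = t_cap,
                 criterion_curve = curve),
            class = "threshold_result")
}

#' Binarize a luminance image at a threshold
#'
#' Foreground (`TRUE`) marks dark object pixels: those whose quantized level
#' is strictly below `t`. This is the complement of the background map; all
#' downstream stages operate on dark objects (eggs, debris, noise) against
#' the near-white paper.
#'
#' @param gray `H x W` luminance matrix in `[0, 1]`.
#' @param t threshold on the 8-bit scale; `0` yields no foreground, `256`
#'   marks every pixel foreground.
#' @return `H x W` logical matrix, `TRUE` = foreground.
#' @export
binarize <- function(gray, t) {
  t <- as.numeric(t)
  stopifnot(length(t) == 1L, t >= 0, t <= 256)
  m <- quantize255(gray) < t
  dim(m) <- dim(gray)
  m
}
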
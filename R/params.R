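#' Analysis parameters
#'
#' Bundles every tunable of the counting pipeline with its default.
#'
#' @param e1,e2 eccentricity window bounds (dimensionless, `0 <= e1 < e2 <= 1`).
#'   Components with `e1 < e < e2` are the single-egg candidates used to
#'   estimate the egg size; the interval 0.95-0.99 captures the elongated
#'   shape of a single egg while excluding the more circular piles.
#' @param t_cap cap on the automatic threshold (8-bit level, default 170, the
#'   midpoint of the useful 160-180 range); keeps flash-overexposed
#'   highlights out of the foreground.
#' @param chroma_cutoff chroma level `C_E` above which a pixel counts as
#'   chromatic (channels in `[0, 1]`; default 0.15). The yellow-brown halo
#'   around debris is chromatic; eggs and paper are nearly achromatic.
#' @param chroma_min_pixels minimum number `X` of chromatic pixels near a
#'   component for it to be flagged as debris (default 10).
#' @param debris_radius neighborhood radius `r` in pixels (Chebyshev
#'   distance) within which chromatic pixels are counted (default 5).
#' @param accumulative_ratio pile-area shrinkage factor `C` in `(0, 1)`
#'   (default 0.9), compensating the shadowed overlap regions that inflate a
#'   pile's apparent area before division by the egg size.
#' @param luminance_weights RGB-to-luminance weights (default Rec. 601).
#' @return a classed list of validated parameters.
#' @export
egg_params <- function(e1 = 0.95, e2 = 0.99, t_cap = 170L,
                       chroma_cutoff = 0.15, chroma_min_pixels = 10L,
                       debris_radius = 5L, accumulative_ratio = 0.9,
                       luminance_weights = LUMINANCE_WEIGHTS) {
  p <- list(e1 = as.numeric(e1), e2 = as.numeric(e2),
            t_cap = as.integer(t_cap),
            chroma_cutoff = as.numeric(chroma_cutoff),
            chroma_min_pixels = as.integer(chroma_min_pixels),
            debris_radius = as.integer(debris_radius),
            accumulative_ratio = as.numeric(accumulative_ratio),
            luminance_weights = as.numeric(luminance_weights))
  validate_params(p)
  structure(p, class = "egg_params")
}

validate_params <- function(p) {
  stopifnot(
    "e1/e2 must satisfy 0 <= e1 < e2 <= 1" =
      p$e1 >= 0 && p$e1 < p$e2 && p$e2 <= 1,
    "t_cap must be in 1..255" = p$t_cap >= 1L && p$t_cap <= 255L,
    "chroma_cutoff must be in [0, 1]" =
      p$chroma_cutoff >= 0 && p$chroma_cutoff <= 1,
    "chroma_min_pixels must be >= 1" = p$chroma_min_pixels >= 1L,
    "debris_radius must be >= 1" = p$debris_radius >= 1L,
    "accumulative_ratio must be in (0, 1)" =
      p$accumulative_ratio > 0 && p$accumulative_ratio < 1,
    "luminance_weights must be 3 non-negative values" =
      length(p$luminance_weights) == 3L && all(p$luminance_weights >= 0)
  )
  invisible(p)
}

#' Write parameters to a flat key-value config file
#'
#' TOML-style `key = value` lines; vectors are comma-separated.
#'
#' @param params an [egg_params()] object.
#' @param path output file path.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "egg_params"))
  fmt <- function(v) {
    if (length(v) > 1L) paste0("[", paste(format(v, digits = 15), collapse = ", "), "]")
    else format(v, digits = 15)
  }
  lines <- vapply(names(params), function(k) paste(k, "=", fmt(params[[k]])),
                  character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read parameters from a flat key-value config file
#'
#' @param path config file written by [write_params()] (or by hand); unknown
#'   keys are an error, missing keys keep their defaults.
#' @return an [egg_params()] object.
#' @export
read_params <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  args <- list()
  for (p in kv) {
    if (length(p) < 2L) stop("read_params: malformed line: ", p[[1L]], call. = FALSE)
    key <- trimws(p[[1L]])
    val <- trimws(paste(p[-1L], collapse = "="))
    val <- gsub("^\\[|\\]$", "", val)
    args[[key]] <- as.numeric(trimws(strsplit(val, ",", fixed = TRUE)[[1L]]))
  }
  unknown <- setdiff(names(args), names(formals(egg_params)))
  if (length(unknown))
    stop("read_params: unknown keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(egg_params, args)
}

#' @export
print.egg_params <- function(x, ...) {
  cat("Egg-counting parameters:\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-18s %s\n", k, paste(format(v), collapse = ", ")))
  }
  invisible(x)
}
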
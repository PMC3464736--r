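#' Read an image file as an RGB array
#'
#' Reads PNG/JPEG/TIFF via EBImage. Intensities are clipped to `[0, 1]`
#' (16-bit inputs arrive already rescaled). A grayscale file is replicated
#' to three identical channels, i.e. treated as already-converted luminance.
#'
#' @param path image file path.
#' @return `H x W x 3` numeric array in `[0, 1]`.
#' @export
read_egg_image <- function(path) {
  if (!file.exists(path)) stop("read_egg_image: no such file: ", path, call. = FALSE)
  im <- EBImage::readImage(path)
  d <- dim(im)
  a <- as.array(im)
  if (length(d) == 2L) {
    a <- aperm(array(a, dim = c(d[1L], d[2L], 1L)), c(2L, 1L, 3L))[, , c(1L, 1L, 1L)]
  } else {
    if (d[3L] > 3L) a <- a[, , 1:3, drop = FALSE]  # drop alpha
    if (d[3L] == 1L) a <- a[, , c(1L, 1L, 1L), drop = FALSE]
    a <- aperm(a, c(2L, 1L, 3L))
  }
  dim(a) <- c(dim(a)[1L], dim(a)[2L], 3L)
  pmin(pmax(a, 0), 1)
}

#' Write an RGB array to an image file
#'
#' @param img `H x W x 3` array in `[0, 1]` (or `H x W` matrix).
#' @param path output path; format from the extension (png/jpeg/tiff).
#' @export
write_egg_image <- function(img, path) {
  img <- as_rgb_array(img)
  EBImage::writeImage(EBImage::Image(aperm(img, c(2L, 1L, 3L)),
                                     colormode = "Color"), path)
  invisible(path)
}

# 5x3 bitmap digit glyphs for overlay labels
.digit_font <- lapply(c(
  "111101101101111", "010110010010111", "111001111100111", "111001111001111",
  "101101111001001", "111100111001111", "111100111101111", "111001001001001",
  "111101111101111", "111101111001111"),
  function(s) matrix(as.integer(strsplit(s, "")[[1]]) == 1L, 5L, 3L, byrow = TRUE))

stamp_text <- function(text, row, col, scale = 2L) {
  # returns (row, col) pixel coords of the rendered string (digits only)
  digs <- strsplit(text, "")[[1]]
  out <- NULL
  x <- col
  for (d in digs) {
    g <- .digit_font[[as.integer(d) + 1L]]
    base <- which(g, arr.ind = TRUE) - 1L
    px <- do.call(rbind, lapply(seq_len(nrow(base)), function(i) {
      rr <- base[i, 1L] * scale + seq_len(scale) - 1L + row
      cc <- base[i, 2L] * scale + seq_len(scale) - 1L + x
      cbind(rep(rr, times = scale), rep(cc, each = scale))
    }))
    out <- rbind(out, px)
    x <- x + 4L * scale
  }
  out
}

.class_colors <- list(single_egg = c(0.1, 0.75, 0.1), pile = c(0.15, 0.35, 0.9),
                      debris = c(0.9, 0.15, 0.15), noise = c(0.55, 0.55, 0.55))

#' Write an annotated overlay image
#'
#' Draws each object's bounding box tinted by class (green = single egg,
#' blue = pile, red = debris, gray = noise), prints its egg count beside
#' it, and prints the total egg count in the top-left corner. Output is a
#' deterministic PNG: no timestamps are embedded.
#'
#' @param img the analyzed RGB image (`H x W x 3` in `[0, 1]`).
#' @param result the [analyze_image()] result for `img`.
#' @param path output PNG path.
#' @export
write_overlay <- function(img, result, path) {
  img <- as_rgb_array(img)
  stopifnot(inherits(result, "egg_analysis"))
  H <- dim(img)[1L]; W <- dim(img)[2L]
  rec <- result$records
  paint <- function(pix, col3) {
    pix <- pix[pix[, 1L] >= 1L & pix[, 1L] <= H &
                 pix[, 2L] >= 1L & pix[, 2L] <= W, , drop = FALSE]
    if (nrow(pix) == 0L) return(invisible())
    i <- (pix[, 2L] - 1L) * H + pix[, 1L]
    for (ch in 1:3) img[i + (ch - 1L) * H * W] <<- col3[ch]
  }
  for (i in seq_len(nrow(rec))) {
    r0 <- max(1L, rec$min_row[i] - 2L); r1 <- min(H, rec$max_row[i] + 2L)
    c0 <- max(1L, rec$min_col[i] - 2L); c1 <- min(W, rec$max_col[i] + 2L)
    box <- rbind(cbind(r0, c0:c1), cbind(r1, c0:c1),
                 cbind(r0:r1, c0), cbind(r0:r1, c1))
    col3 <- .class_colors[[rec$classification[i]]]
    paint(box, col3)
    if (rec$egg_count[i] > 0L)
      paint(stamp_text(as.character(rec$egg_count[i]), r0, c1 + 3L,
                       scale = 1L), col3)
  }
  paint(stamp_text(as.character(result$total_eggs), 4L, 4L, scale = 3L),
        c(0.85, 0.1, 0.1))
  write_egg_image(img, path)
}

#' Write per-object results to CSV
#'
#' One row per extracted object (`row_type = "object"`) with its image id,
#' label, class, area, eccentricity and egg count, followed by one summary
#' row per image (`row_type = "summary"`) carrying the total. Stable column
#' order; round-trips losslessly through [utils::read.csv()].
#'
#' @param results a single [analyze_image()] result or a named list of them
#'   (names = image identifiers).
#' @param path output CSV path.
#' @return the data frame written, invisibly.
#' @export
write_report_csv <- function(results, path) {
  if (inherits(results, "egg_analysis")) results <- list(image = results)
  if (is.null(names(results))) names(results) <- paste0("image", seq_along(results))
  rows <- lapply(names(results), function(nm) {
    res <- results[[nm]]
    rec <- res$records
    obj <- data.frame(image = rep(nm, nrow(rec)), row_type = rep("object", nrow(rec)),
                      label = rec$label, classification = rec$classification,
                      area = rec$area, eccentricity = rec$eccentricity,
                      egg_count = rec$egg_count)
    summ <- data.frame(image = nm, row_type = "summary", label = NA_integer_,
                       classification = NA_character_, area = NA_integer_,
                       eccentricity = NA_real_, egg_count = res$total_eggs)
    rbind(obj, summ)
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Batch-process a set of images
#'
#' Runs [analyze_image()] on every path, independently: a failure on one
#' image is recorded in its report row and does not abort the batch. Writes
#' `report.csv` (one row per image), a per-object `objects.csv`, and, when
#' `overlays = TRUE`, an annotated `<name>_overlay.png` per image, all under
#' `out_dir`.
#'
#' @param paths character vector of image files.
#' @param params an [egg_params()] object.
#' @param out_dir output directory (created if missing); `NULL` writes no
#'   files.
#' @param overlays write annotated overlay PNGs?
#' @return object of class `"run_report"`: data frame with one row per
#'   image (`path`, `status`, `total_eggs`, `t_auto`, `egg_size_s`, object
#'   counts by class, `elapsed_s`, `message`), with the parameter set and
#'   package version as attributes. Attribute `n_failed` counts hard
#'   failures.
#' @export
run_batch <- function(paths, params = egg_params(), out_dir = NULL,
                      overlays = !is.null(out_dir)) {
  validate_params(params)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  results <- list()
  rows <- lapply(paths, function(p) {
    t0 <- proc.time()[["elapsed"]]
    msg <- ""
    res <- tryCatch({
      img <- read_egg_image(p)
      withCallingHandlers(
        analyze_image(img, params),
        warning = function(w) {
          msg <<- conditionMessage(w)
          invokeRestart("muffleWarning")
        })
    }, error = function(e) e)
    elapsed <- proc.time()[["elapsed"]] - t0
    nm <- sub("\\.[^.]+$", "", basename(p))
    if (inherits(res, "error")) {
      return(data.frame(path = p, status = "error", total_eggs = NA_integer_,
                        t_auto = NA_integer_, egg_size_s = NA_real_,
                        n_single = NA_integer_, n_pile = NA_integer_,
                        n_debris = NA_integer_, n_noise = NA_integer_,
                        elapsed_s = elapsed, message = conditionMessage(res)))
    }
    results[[nm]] <<- res
    if (!is.null(out_dir) && overlays)
      write_overlay(read_egg_image(p), res,
                    file.path(out_dir, paste0(nm, "_overlay.png")))
    tab <- table(factor(res$records$classification,
                        levels = c("single_egg", "pile", "debris", "noise")))
    data.frame(path = p,
               status = if (nzchar(msg)) "warning" else "ok",
               total_eggs = res$total_eggs,
               t_auto = if (is.null(res$threshold)) NA_integer_ else res$threshold$t_auto,
               egg_size_s = if (is.null(res$egg_size)) NA_real_ else res$egg_size$s,
               n_single = as.integer(tab[["single_egg"]]),
               n_pile = as.integer(tab[["pile"]]),
               n_debris = as.integer(tab[["debris"]]),
               n_noise = as.integer(tab[["noise"]]),
               elapsed_s = elapsed, message = msg)
  })
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(path = character(), status = character(),
               total_eggs = integer(), t_auto = integer(),
               egg_size_s = numeric(), n_single = integer(),
               n_pile = integer(), n_debris = integer(), n_noise = integer(),
               elapsed_s = numeric(), message = character())
  attr(report, "params") <- params
  attr(report, "version") <- as.character(utils::packageVersion("ovocount"))
  attr(report, "n_failed") <- sum(report$status == "error")
  class(report) <- c("run_report", class(report))
  if (!is.null(out_dir)) {
    utils::write.csv(report, file.path(out_dir, "report.csv"), row.names = FALSE)
    if (length(results))
      write_report_csv(results, file.path(out_dir, "objects.csv"))
    write_params(params, file.path(out_dir, "params.toml"))
  }
  report
}
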
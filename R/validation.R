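#' Standard validation scene suite
#'
#' Twenty synthetic scenes spanning the conditions an egg-laying experiment
#' produces: totals from 20 to 700 eggs per roughly 1-megapixel image, up to
#' 30% of eggs in piles of 2-3, faint grid lines, noise speckles, and 0-3
#' debris blobs per scene. Used to quantify end-to-end counting accuracy.
#'
#' @param base_seed seed of the first scene; scene `i` uses `base_seed + i - 1`.
#' @param n_scenes number of scenes.
#' @return list of [scene_spec()] objects; each carries attributes
#'   `target_eggs` (intended total) via its pile sizes and singles count.
#' @export
validation_suite <- function(base_seed = 101L, n_scenes = 20L) {
  totals <- round(seq(20, 700, length.out = n_scenes))
  pile_frac <- rep(c(0, 0.1, 0.2, 0.3), length.out = n_scenes)
  n_debris <- rep(0:3, length.out = n_scenes)
  lapply(seq_len(n_scenes), function(i) {
    npe <- round(totals[i] * pile_frac[i])
    sizes <- rep_len(2:3, max(ceiling(npe / 2), 1L))
    sizes <- sizes[cumsum(sizes) <= npe]
    scene_spec(image_shape = c(1024L, 1024L),
               n_single_eggs = totals[i] - sum(sizes),
               n_piles = length(sizes),
               pile_sizes = if (length(sizes)) sizes else NULL,
               n_debris = n_debris[i],
               seed = base_seed + i - 1L)
  })
}
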
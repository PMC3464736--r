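make_cs <- function(areas, eccs) {
  # minimal component_set stand-in for size-estimation tests
  structure(list(labels = NULL,
                 stats = data.frame(label = seq_along(areas), area = areas,
                                    eccentricity = eccs),
                 shape = c(100L, 100L)),
            class = "component_set")
}

test_that("egg size is the binned mode of candidate areas", {
  cs <- make_cs(c(100, 100, 102, 250), rep(0.97, 4))
  est <- estimate_egg_size(cs, egg_params())
  expect_equal(est$s, 100)
  expect_equal(est$n_candidates, 4L)

  expect_equal(estimate_egg_size(make_cs(80, 0.96), egg_params())$s, 80)

  # candidates outside the eccentricity window are ignored
  cs2 <- make_cs(c(100, 101, 500, 500, 500), c(0.97, 0.97, 0.5, 0.5, 0.5))
  expect_equal(estimate_egg_size(cs2, egg_params())$s, 100.5)

  # tie between two bins: the smaller-area bin wins
  cs3 <- make_cs(c(100, 100, 200, 200), rep(0.96, 4))
  expect_equal(estimate_egg_size(cs3, egg_params())$s, 100)

  expect_error(estimate_egg_size(make_cs(100, 0.5), egg_params()),
               class = "ovocount_no_candidates")
})

test_that("chroma is the max minus min channel spread", {
  px <- function(r, g, b) array(c(r, g, b), dim = c(1, 1, 3))
  expect_equal(chroma_map(px(0.3, 0.3, 0.3))[1, 1], 0)
  expect_equal(chroma_map(px(1, 0, 0))[1, 1], 1)
  expect_equal(chroma_map(px(0.6, 0.4, 0.2))[1, 1], 0.4)
})

test_that("debris detection needs enough chromatic pixels in the neighborhood", {
  # dark blob at rows/cols 10..13 on a gray image
  img <- array(0.9, dim = c(30, 30, 3))
  img[10:13, 10:13, ] <- 0.1
  mask <- binarize(to_grayscale(img), 100)
  cs <- label_components(mask)
  p <- egg_params()

  expect_false(is_debris(cs, 1L, chroma_map(img), p))  # fully achromatic

  # paint a brown ring just outside the blob: chroma 0.4 > C_E
  img2 <- img
  img2[8:15, 8, 1] <- 0.8; img2[8:15, 8, 2] <- 0.6; img2[8:15, 8, 3] <- 0.4
  img2[8:15, 15, 1] <- 0.8; img2[8:15, 15, 2] <- 0.6; img2[8:15, 15, 3] <- 0.4
  expect_true(is_debris(cs, 1L, chroma_map(img2), p))

  # halo farther than r: not seen
  img3 <- img
  img3[1:30, 25, 1] <- 0.8; img3[1:30, 25, 2] <- 0.6; img3[1:30, 25, 3] <- 0.4
  expect_false(is_debris(cs, 1L, chroma_map(img3), p))
})

test_that("debris flagging is monotone in the cutoff and the pixel minimum", {
  set.seed(77)
  sc <- generate_scene(scene_spec(image_shape = c(400L, 400L),
                                  n_single_eggs = 8L, n_piles = 0L,
                                  n_debris = 3L, noise_speck_count = 0L,
                                  grid_spacing = 0L, seed = 19))
  res0 <- analyze_image(sc$image)
  mask <- binarize(to_grayscale(sc$image), res0$threshold$t_auto)
  cs <- label_components(mask)
  ch <- chroma_map(sc$image)
  n_flagged <- function(ce, x) sum(debris_flags(cs, ch,
    egg_params(chroma_cutoff = ce, chroma_min_pixels = x)))
  expect_true(all(diff(vapply(c(0.05, 0.15, 0.25, 0.35),
                              function(ce) n_flagged(ce, 10L),
                              numeric(1))) <= 0))
  expect_true(all(diff(vapply(c(1L, 10L, 100L, 1000L),
                              function(x) n_flagged(0.15, x),
                              numeric(1))) <= 0))
})

test_that("egg counts divide area by the estimated size with the pile discount", {
  S <- 200
  expect_identical(count_eggs_in_object(S, S), 1L)
  expect_identical(count_eggs_in_object(2 * S, S), 2L)          # branch boundary
  expect_identical(count_eggs_in_object(4 * S, S, 0.9), 4L)     # round(3.6)
  expect_identical(count_eggs_in_object(0.5 * S, S), 1L)        # floor at one egg
  expect_identical(count_eggs_in_object(0.3 * S, S), 1L)
  # rounding is half-away-from-zero: 2.5 eggs -> 3
  expect_identical(count_eggs_in_object(2.5 * S / 0.9, S, 0.9), 3L)
  # monotone in area within each branch
  a1 <- seq(0.5 * S, 2 * S, by = 10)
  a2 <- seq(2 * S + 1, 8 * S, by = 10)
  expect_true(all(diff(count_eggs_in_object(a1, S)) >= 0))
  expect_true(all(diff(count_eggs_in_object(a2, S)) >= 0))
})

test_that("noise rule removes components below half an egg, boundary kept", {
  S <- 100
  expect_true(is_noise(0.4 * S, S))
  expect_false(is_noise(0.6 * S, S))
  expect_false(is_noise(S / 2, S))   # "smaller than half" is strict

  m <- matrix(FALSE, 40, 40)
  m[2:21, 2:11] <- TRUE     # area 200
  m[30, 30:34] <- TRUE      # area 5 (below S/2 for S = 200)
  cs <- label_components(m)
  kept <- remove_noise(cs, 200)
  expect_equal(nrow(kept$stats), 1L)
  expect_equal(kept$stats$area, 200L)
  expect_equal(sum(kept$labels > 0L), 200L)
})

test_that("full pipeline: conservation, classification consistency, determinism", {
  sc <- generate_scene(scene_spec(image_shape = c(640L, 640L),
                                  n_single_eggs = 20L, n_piles = 2L,
                                  n_debris = 1L, seed = 5))
  res <- analyze_image(sc$image)
  rec <- res$records
  expect_equal(res$total_eggs, sum(rec$egg_count))
  expect_true(all(rec$egg_count[rec$classification %in% c("debris", "noise")] == 0L))
  expect_true(all(rec$egg_count[rec$classification == "single_egg"] >= 1L))
  # every extracted component appears exactly once
  mask <- binarize(to_grayscale(sc$image), res$threshold$t_auto)
  expect_equal(nrow(rec), nrow(label_components(mask)$stats))
  expect_identical(sort(rec$label), seq_len(nrow(rec)))

  res2 <- analyze_image(sc$image)
  expect_identical(serialize(res, NULL), serialize(res2, NULL))
})

test_that("a uniform image yields an empty result with a degenerate-image warning", {
  blank <- array(0.95, dim = c(64, 64, 3))
  expect_warning(res <- analyze_image(blank),
                 class = "ovocount_degenerate_image")
  expect_equal(res$total_eggs, 0L)
  expect_equal(nrow(res$records), 0L)
})
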
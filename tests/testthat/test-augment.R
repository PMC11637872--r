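make_img <- function(boxes, H = 64, W = 64, seed = 1, id = "a") {
  set.seed(seed)
  annotated_image(array(runif(H * W * 3), c(H, W, 3)), boxes, id)
}

test_that("splitting remaps fully contained boxes to half-frame coordinates", {
  img <- make_img(bbox(0L, 0.2, 0.5, 0.2, 0.3))
  hs <- split_image(img)
  expect_equal(nrow(hs[[1]]$boxes), 1L)
  expect_equal(hs[[1]]$boxes$cx, 0.4)   # cx' = cx * W / (W/2)
  expect_equal(hs[[1]]$boxes$w, 0.4)
  expect_equal(hs[[1]]$boxes$cy, 0.5)
  expect_equal(nrow(hs[[2]]$boxes), 0L)
})

test_that("a box straddling the cut is kept on both sides above the keep fraction", {
  img <- make_img(bbox(1L, 0.5, 0.5, 0.25, 0.25))
  hs <- split_image(img, clip_keep_fraction = 0.2)
  expect_equal(nrow(hs[[1]]$boxes), 1L)
  expect_equal(nrow(hs[[2]]$boxes), 1L)
  # retained fraction exactly 0.5 per side; clipped widths match
  expect_equal(hs[[1]]$boxes$w, 0.25, tolerance = 1e-9)
  # a sliver below the keep fraction is dropped from the far side
  img2 <- make_img(bbox(1L, 0.4, 0.5, 0.25, 0.25))
  hs2 <- split_image(img2, clip_keep_fraction = 0.2)
  expect_equal(nrow(hs2[[1]]$boxes), 1L)
  expect_equal(nrow(hs2[[2]]$boxes), 0L)
})

test_that("halves concatenate back to the source exactly and recombine inverts split", {
  img <- make_img(bbox(c(0L, 1L), c(0.3, 0.8), c(0.3, 0.6), c(0.2, 0.2),
                       c(0.2, 0.2)), seed = 3)
  hs <- split_image(img)
  rec <- recombine_halves(hs[[1]], hs[[2]])
  expect_identical(rec$pixels, img$pixels)
  expect_equal(rec$boxes[order(rec$boxes$cx), ],
               img$boxes[order(img$boxes$cx), ], ignore_attr = TRUE)
  # horizontal orientation too
  ht <- split_image(img, orientation = "horizontal")
  rec2 <- recombine_halves(ht[[1]], ht[[2]])
  expect_identical(rec2$pixels, img$pixels)
})

test_that("a right-slot box at cx 0.4 lands at 0.7 in the combined frame", {
  img <- make_img(bbox(0L, 0.2, 0.5, 0.2, 0.2))   # left half box at cx 0.4
  hs <- split_image(img)
  other <- make_img(empty_boxes(), seed = 9, id = "b")
  ho <- split_image(other)
  # put the box-carrying half in the right slot: cx' = 0.5 + 0.4/2 = 0.7
  rec <- recombine_halves(ho[[1]], hs[[1]])
  expect_equal(rec$boxes$cx, 0.7)
  # box-free halves recombine to an empty list
  expect_equal(nrow(recombine_halves(ho[[1]], ho[[2]])$boxes), 0L)
  # height mismatch errors
  short <- structure(list(pixels = other$pixels[1:32, 1:32, , drop = FALSE],
                          boxes = empty_boxes(),
                          origin = list(source = "b", side = "left"),
                          orientation = "vertical"), class = "image_half")
  expect_error(recombine_halves(hs[[1]], short), "shape error")
})

test_that("a pair yields exactly the four mixed-source recombinations", {
  A <- make_img(bbox(0L, 0.2, 0.3, 0.2, 0.2), seed = 1, id = "A")
  B <- make_img(bbox(1L, 0.8, 0.7, 0.2, 0.2), seed = 2, id = "B")
  outs <- split_recombine_pair(A, B)
  expect_length(outs, 4L)
  for (o in outs) {
    expect_false(identical(o$pixels, A$pixels))
    expect_false(identical(o$pixels, B$pixels))
    expect_equal(dim(o$pixels), dim(A$pixels))
  }
  # each half used exactly twice: box totals double the split survivors
  nA <- sum(vapply(split_image(A), function(h) nrow(h$boxes), integer(1)))
  nB <- sum(vapply(split_image(B), function(h) nrow(h$boxes), integer(1)))
  expect_equal(sum(vapply(outs, function(o) nrow(o$boxes), integer(1))),
               2L * (nA + nB))
  expect_error(split_recombine_pair(A, A), "distinctness")
})

test_that("geometric ops move pixels and boxes together, exactly", {
  img <- make_img(bbox(0L, 0.2, 0.5, 0.1, 0.3), seed = 4)
  mir <- geometric_augment(img, "mirror")
  expect_equal(mir$boxes$cx, 0.8)
  expect_equal(mir$boxes$cy, 0.5)
  expect_identical(geometric_augment(mir, "mirror")$pixels, img$pixels)
  expect_equal(geometric_augment(mir, "mirror")$boxes$cx, 0.2)
  rot <- geometric_augment(img, "rotate", list(angle = 90))
  expect_equal(unlist(rot$boxes[1, c("cx", "cy", "w", "h")]),
               c(cx = 0.5, cy = 0.2, w = 0.3, h = 0.1))
  # four quarter turns are the identity
  r4 <- Reduce(function(im, .) geometric_augment(im, "rotate", list(angle = 90)),
               1:4, accumulate = FALSE, init = img)
  expect_identical(r4$pixels, img$pixels)
  expect_error(geometric_augment(img, "rotate", list(angle = 45)), "parameter")
  # translation clips: a box pushed fully outside disappears
  img2 <- make_img(bbox(0L, 0.9, 0.5, 0.1, 0.2))
  tr <- geometric_augment(img2, "translate", list(dx = 0.5, dy = 0))
  expect_equal(nrow(tr$boxes), 0L)
})

test_that("boxes track the pixel transform: the labeled region carries the same pixels", {
  # paint a distinctive patch, transform, and check the patch sits inside
  # the transformed box exactly where the label says
  px <- array(0.5, c(64, 64, 3))
  px[29:36, 13:20, 1] <- 1  # rows 29-36, cols 13-20
  b <- bbox(0L, cx = 16 / 64, cy = 32 / 64, w = 8 / 64, h = 8 / 64)
  img <- annotated_image(px, b, "patch")
  for (tf in list(function(i) geometric_augment(i, "mirror"),
                  function(i) geometric_augment(i, "rotate", list(angle = 90)),
                  function(i) geometric_augment(i, "rotate", list(angle = 270)),
                  function(i) geometric_augment(i, "translate",
                                                list(dx = 0.25, dy = -0.125)))) {
    out <- tf(img)
    bb <- out$boxes[1, ]
    r <- (round(bb$cy * 64 - bb$h * 32) + 1):round(bb$cy * 64 + bb$h * 32)
    c2 <- (round(bb$cx * 64 - bb$w * 32) + 1):round(bb$cx * 64 + bb$w * 32)
    expect_true(all(out$pixels[r, c2, 1] == 1))
    expect_equal(sum(out$pixels[, , 1] == 1), 64)  # patch intact elsewhere
  }
  # and through split/recombine of the two halves in swapped order
  hs <- split_image(img)
  rec <- recombine_halves(hs[[2]], hs[[1]])
  bb <- rec$boxes[1, ]
  r <- (round(bb$cy * 64 - bb$h * 32) + 1):round(bb$cy * 64 + bb$h * 32)
  c2 <- (round(bb$cx * 64 - bb$w * 32) + 1):round(bb$cx * 64 + bb$w * 32)
  expect_true(all(rec$pixels[r, c2, 1] == 1))
})

test_that("balancing reaches the target ratio and is deterministic", {
  dir <- withr::local_tempdir()
  sp <- tiny_spec(image_size = c(64L, 64L), class_weights = c(0.85, 0.15),
                  cells_per_image = c(1L, 2L), blur_sigma = c(0, 0))
  idx <- generate_dataset(sp, 30, dir)
  expect_lt(idx$class_counts[2] / idx$class_counts[1], 0.5)
  pol <- augmentation_policy(balance_ratio = 0.5, budget = 80L, seed = 3L)
  out1 <- file.path(dir, "aug1")
  aug <- balance_dataset(idx, pol, out_dir = out1)
  expect_gte(aug$class_counts[2], 0.5 * aug$class_counts[1])
  expect_equal(aug$status, "ok")
  # determinism: same seed, same file set and counts
  out2 <- file.path(dir, "aug2")
  aug2 <- balance_dataset(idx, pol, out_dir = out2)
  expect_equal(aug2$class_counts, aug$class_counts)
  expect_equal(basename(aug2$files$image), basename(aug$files$image))
  # already balanced input is returned unchanged
  expect_identical(balance_dataset(aug, pol), aug)
  # starved budget reports a warning status instead of erroring
  aug3 <- balance_dataset(idx, augmentation_policy(balance_ratio = 0.9,
                                                   budget = 1L, seed = 3L),
                          out_dir = file.path(dir, "aug3"))
  expect_match(aug3$status, "warning")
})
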
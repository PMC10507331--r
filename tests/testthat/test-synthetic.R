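# Synthetic smear generator, preprocessing ops and COCO round-trips.

test_that("generator respects counts, determinism and overlap guarantees", {
  # no cells -> empty annotations
  s0 <- generate_smear(smear_spec(width = 64, n_wbc = 0, n_rbc = 3, seed = 1))
  expect_length(s0$annotations, 0)
  expect_equal(dim(s0$image), c(64, 64, 3))
  expect_true(all(s0$image >= 0 & s0$image <= 1))

  # same seed -> identical image and masks
  sp <- smear_spec(width = 96, n_wbc = 3, n_rbc = 8, seed = 42)
  a <- generate_smear(sp); b <- generate_smear(sp)
  expect_identical(a$image, b$image)
  expect_identical(lapply(a$annotations, `[[`, "mask"),
                   lapply(b$annotations, `[[`, "mask"))

  # requested adhesion: some pair intersects by >= min_overlap of the smaller
  sp2 <- smear_spec(width = 96, n_wbc = 2, n_rbc = 0, overlap_prob = 1,
                    min_overlap = 0.2, seed = 7)
  s2 <- generate_smear(sp2)
  m1 <- s2$annotations[[1]]$mask; m2 <- s2$annotations[[2]]$mask
  frac <- sum(m1 & m2) / min(sum(m1), sum(m2))
  expect_gte(frac, 0.2)

  # annotation invariants: area == pixel count, bbox is the tight bound
  for (a in s2$annotations) {
    expect_equal(a$area, sum(a$mask))
    expect_equal(a$bbox, mask_to_bbox(a$mask))
  }

  # impossible packing errors out
  expect_error(generate_smear(smear_spec(width = 40, n_wbc = 30, seed = 1)),
               "could not place")
})

test_that("sliding-window origins and tile counts follow the edge-anchored rule", {
  img512 <- array(0.5, c(512, 512, 3))
  t1 <- sliding_window_crop(img512, NULL, 512L, 256L)
  expect_length(t1, 1)

  img <- array(0.5, c(512, 1024, 3))
  t3 <- sliding_window_crop(img, NULL, 512L, 256L)
  expect_length(t3, 3)
  expect_equal(sort(vapply(t3, function(t) t$offset[1], numeric(1))),
               c(0, 256, 512))

  # the full-frame case: 2592 x 1944 -> 10 x 7 = 70 tiles
  expect_equal(wbcseg:::window_origins(2592L, 512L, 256L),
               c(seq(0L, 2048L, 256L), 2080L))
  expect_equal(wbcseg:::window_origins(1944L, 512L, 256L),
               c(seq(0L, 1280L, 256L), 1432L))
  expect_equal(length(wbcseg:::window_origins(2592L, 512L, 256L)) *
                 length(wbcseg:::window_origins(1944L, 512L, 256L)), 70)

  # too-small image: one zero-padded tile with a warning
  expect_warning(tp <- sliding_window_crop(array(0.5, c(100, 80, 3)), NULL,
                                           512L, 256L), "zero-padded")
  expect_length(tp, 1)
  expect_equal(dim(tp[[1]]$image), c(512, 512, 3))
})

test_that("tile-boundary instances survive above the keep fraction and masks are conserved", {
  img <- array(0.8, c(600, 600, 3))
  mk_int <- matrix(0L, 600, 600); mk_int[100:160, 100:160] <- 1L  # interior
  mk_edge <- matrix(0L, 600, 600); mk_edge[480:560, 480:560] <- 1L
  anns <- list(list(mask = mk_int, bbox = mask_to_bbox(mk_int),
                    area = sum(mk_int), category = "wbc"),
               list(mask = mk_edge, bbox = mask_to_bbox(mk_edge),
                    area = sum(mk_edge), category = "wbc"))
  tiles <- sliding_window_crop(img, anns, 512L, 256L)
  expect_length(tiles, 4)  # origins {0, 88} x {0, 88}
  # interior instance fully contained in tile 1: pixel count conserved
  t1 <- tiles[[1]]
  expect_equal(sum(t1$annotations[[1]]$mask), sum(mk_int))
  # tiles where the edge instance is fully interior keep its full area
  full_copies <- vapply(tiles, function(t)
    any(vapply(t$annotations, function(a) a$area == sum(mk_edge), logical(1))),
    logical(1))
  expect_true(any(full_copies))
})

test_that("pad_to_square zero-pads bottom/right only", {
  img <- array(runif(640 * 480 * 3), c(480, 640, 3))
  p <- pad_to_square(img)
  expect_equal(dim(p), c(640, 640, 3))
  expect_equal(p[1:480, , ], img[, , ])
  expect_true(all(p[481:640, , ] == 0))

  sq <- array(runif(27), c(3, 3, 3))
  expect_identical(pad_to_square(sq), sq)

  toy <- matrix(1, 3, 5)
  pt <- pad_to_square(toy)
  expect_equal(dim(pt), c(5, 5))
  expect_true(all(pt[4:5, ] == 0))
  expect_true(all(pt[1:3, ] == 1))
})

test_that("dataset split is a deterministic partition with cumulative-floor sizes", {
  sp <- split_dataset(678L, c(7, 1, 2), seed = 4)
  expect_equal(lengths(sp), c(train = 474, val = 68, test = 136))
  expect_equal(sort(unname(unlist(sp))), 1:678)

  sp10 <- split_dataset(10L, c(7, 1, 2), seed = 4)
  expect_equal(lengths(sp10), c(train = 7, val = 1, test = 2))
  expect_length(intersect(sp10$train, sp10$test), 0)

  expect_identical(split_dataset(50L, seed = 9), split_dataset(50L, seed = 9))
  expect_error(split_dataset(2L, c(7, 1, 2)), "fewer items")
})

test_that("COCO JSON round-trips RLE masks bit-identically", {
  set.seed(80)
  smears <- lapply(1:3, function(i)
    generate_smear(smear_spec(width = 48, n_wbc = 2, n_rbc = 3, seed = 500 + i)))
  coco <- as_coco(smears)
  path <- tempfile(fileext = ".json")
  write_coco(coco, path)
  back <- read_coco(path)
  expect_length(back$annotations, length(coco$annotations))
  for (i in seq_along(coco$annotations)) {
    orig_mask <- rle_decode(coco$annotations[[i]]$segmentation)
    rt_mask <- rle_decode(back$annotations[[i]]$segmentation)
    expect_identical(rt_mask, orig_mask)
    expect_equal(back$annotations[[i]]$bbox, coco$annotations[[i]]$bbox)
  }
  unlink(path)

  # RLE basics: empty, full, checker
  for (m in list(matrix(0L, 3, 4), matrix(1L, 3, 4),
                 matrix(c(1L, 0L), 4, 4), random_mask(c(7, 5), 11, seed = 3))) {
    expect_identical(rle_decode(rle_encode(m)), m + 0L)
  }
  expect_equal(rle_encode(matrix(1L, 2, 2))$counts[1], 0L)
})

test_that("a written dataset directory loads back with consistent geometry", {
  dir <- file.path(tempdir(), "wbc_synth_test")
  unlink(dir, recursive = TRUE)
  synth_dataset(2, smear_spec(width = 48, n_wbc = 1, n_rbc = 2), seed = 31,
                dir = dir)
  expect_true(file.exists(file.path(dir, "annotations.json")))
  loaded <- wbcseg:::read_dataset_dir(dir)
  expect_length(loaded, 2)
  expect_equal(dim(loaded[[1]]$image), c(48, 48, 3))
  # mask and image agree spatially
  expect_equal(dim(loaded[[1]]$annotations[[1]]$mask), c(48, 48))
  unlink(dir, recursive = TRUE)
})
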
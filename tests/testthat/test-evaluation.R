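# Mask IoU, matching, average precision and the reference-evaluator oracle.

test_that("mask IoU counts pixels", {
  a <- matrix(0L, 4, 4); a[1:2, 1:2] <- 1L
  expect_equal(mask_iou(a, a), 1)
  b <- matrix(0L, 4, 4); b[3:4, 3:4] <- 1L
  expect_equal(mask_iou(a, b), 0)
  cc <- matrix(0L, 4, 4); cc[2:3, 1:2] <- 1L   # |A|=|B|=4, overlap 2
  expect_equal(mask_iou(a, cc), 2 / 6)
  expect_equal(mask_iou(matrix(0L, 2, 2), matrix(0L, 2, 2)), 0)
  expect_error(mask_iou(a, matrix(0L, 3, 3)), "shapes differ")
})

test_that("greedy matching yields the textbook TP/FP/FN counts", {
  gt <- matrix(0L, 8, 8); gt[2:5, 2:5] <- 1L
  m <- match_predictions(list(gt), 0.9, list(gt), 0.5)
  expect_equal(sum(m$tp), 1)
  expect_equal(m$fn, 0)
  # precision = recall = 1
  expect_equal(sum(m$tp) / length(m$tp), 1)

  # two detections on one gt: TP = 1, FP = 1
  m2 <- match_predictions(list(gt, gt), c(0.9, 0.8), list(gt), 0.5)
  expect_equal(sum(m2$tp), 1)
  expect_equal(sum(!m2$tp), 1)

  # random 3 dets / 2 gts equals the reference-loop matching
  set.seed(70)
  for (rep in 1:10) {
    gts <- list(random_mask(c(12, 12), 30), random_mask(c(12, 12), 30))
    dets <- lapply(1:3, function(i) random_mask(c(12, 12), 30))
    sc <- runif(3)
    got <- match_predictions(dets, sc, gts, 0.3)
    # independent re-derivation
    ord <- order(sc, decreasing = TRUE)
    used <- c(FALSE, FALSE); tp_ref <- logical(3)
    for (d in ord) {
      ious <- vapply(seq_along(gts), function(j)
        if (used[j]) -1 else sum(dets[[d]] & gts[[j]]) / sum(dets[[d]] | gts[[j]]),
        numeric(1))
      j <- which.max(ious)
      if (ious[j] >= 0.3) { used[j] <- TRUE; tp_ref[which(ord == d)] <- TRUE }
    }
    expect_equal(got$tp, tp_ref)
  }
})

test_that("average precision reproduces hand-computed PR areas", {
  gt <- matrix(0L, 8, 8); gt[2:5, 2:5] <- 1L
  bad <- matrix(0L, 8, 8); bad[7:8, 7:8] <- 1L

  # perfect detector -> AP = 1
  expect_equal(average_precision(list(list(masks = list(gt), scores = 1)),
                                 list(list(gt)), 0.5), 1)

  # 1 gt, 2 dets, TP ranked second: precision 1/2 at recall 1 -> AP = 0.5
  # (101-point interpolation: p(0)=0.5 envelope too)
  ap <- average_precision(
    list(list(masks = list(bad, gt), scores = c(0.9, 0.8))),
    list(list(gt)), 0.5)
  expect_equal(ap, 0.5, tolerance = 1e-9)

  # zero gts & zero dets -> NaN with warning
  expect_warning(
    v <- average_precision(list(list(masks = list(), scores = numeric(0))),
                           list(list())), "undefined")
  expect_true(is.nan(v))
})

test_that("AP is non-increasing in the IoU threshold and duplicates never raise it", {
  set.seed(71)
  mk_blob <- function(cx, cy, r, hw = c(24, 24)) {
    m <- matrix(0L, hw[1], hw[2])
    for (y in 1:hw[1]) for (x in 1:hw[2])
      if ((x - cx)^2 + (y - cy)^2 < r^2) m[y, x] <- 1L
    m
  }
  gts <- list(list(mk_blob(8, 8, 5), mk_blob(17, 17, 4)))
  dets <- list(mk_blob(8, 9, 5), mk_blob(18, 17, 4), mk_blob(5, 20, 3))
  preds <- list(list(masks = dets, scores = c(0.9, 0.8, 0.3)))
  aps <- vapply(seq(0.5, 0.95, 0.05), function(t)
    average_precision(preds, gts, t), numeric(1))
  expect_true(all(diff(aps) <= 1e-12))

  # duplicating a TP cannot raise AP
  ap1 <- average_precision(preds, gts, 0.5)
  preds_dup <- list(list(masks = c(dets, dets[1]), scores = c(0.9, 0.8, 0.3, 0.85)))
  ap2 <- average_precision(preds_dup, gts, 0.5)
  expect_lte(ap2, ap1 + 1e-12)
})

test_that("evaluator agrees with the reference protocol implementation", {
  set.seed(72)
  # randomized predictions on synthetic images
  smears <- lapply(1:6, function(i)
    generate_smear(smear_spec(width = 64, n_wbc = 2, n_rbc = 4, seed = 100 + i)))
  gts <- lapply(smears, function(s) lapply(s$annotations, function(a) a$mask))
  preds <- lapply(smears, function(s) {
    masks <- list(); scores <- numeric(0)
    for (a in s$annotations) {
      if (runif(1) < 0.8) {  # jittered true mask
        m <- a$mask
        if (runif(1) < 0.5) m <- rbind(m[-1, ], 0L)   # shift down
        masks <- c(masks, list(m)); scores <- c(scores, runif(1, 0.5, 1))
      }
      if (runif(1) < 0.4) {  # random false positive
        masks <- c(masks, list(random_mask(dim(a$mask), 80)))
        scores <- c(scores, runif(1, 0, 0.6))
      }
    }
    list(masks = masks, scores = scores)
  })
  for (thr in c(0.5, 0.75, 0.9)) {
    expect_equal(average_precision(preds, gts, thr),
                 ref_coco_ap(preds, gts, thr), tolerance = 1e-10)
  }
  ev <- evaluate_detections(preds, gts)
  expect_true(ev$AP <= ev$AP50 + 1e-9)
  expect_true(ev$AP75 <= ev$AP50 + 1e-9)
  expect_true(ev$AP >= 0 && ev$AP50 <= 100)
})

test_that("results JSON round-trips through the file evaluator", {
  set.seed(73)
  smears <- lapply(1:2, function(i)
    generate_smear(smear_spec(width = 48, n_wbc = 1, n_rbc = 2, seed = 300 + i)))
  coco <- as_coco(smears)
  gt_path <- tempfile(fileext = ".json")
  write_coco(coco, gt_path)
  dets <- lapply(smears, function(s)
    list(masks = lapply(s$annotations, function(a) a$mask),
         scores = rep(0.9, length(s$annotations)),
         boxes = matrix(rep(c(1, 1, 10, 10), length(s$annotations)),
                        ncol = 4, byrow = TRUE)))
  pred_path <- tempfile(fileext = ".json")
  write_results_json(dets, c(1L, 2L), pred_path)
  ev <- evaluate_coco_files(gt_path, pred_path)
  expect_equal(ev$AP50, 100, tolerance = 1e-9)
  expect_equal(ev$AP, 100, tolerance = 1e-9)
  unlink(c(gt_path, pred_path))
})
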
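# Cell and inclusion segmentation and the mask combination.

test_that("background-only and degenerate fields yield empty cell masks", {
  noise <- withr::with_seed(1L, matrix(rnorm(256^2, 100, 20), 256, 256))
  expect_identical(objectCount(segmentCells(noise)), 0L)
  expect_identical(objectCount(segmentCells(matrix(5, 64, 64))), 0L)
  expect_error(segmentCells(matrix(c(1, NA), 2, 2)), "non-finite")
})

test_that("well-separated cells are recovered with IoU >= 0.7", {
  fx <- generateField(cleanSpec(nCells = 2L, seed = 6L,
                                countLaw = countLaw("categorical",
                                                    prevalence = 0,
                                                    counts = 1L, probs = 1)))
  mask <- segmentCells(getChannel(fx$field, "aggregate"))
  expect_identical(objectCount(mask), 2L)
  tc <- groundTruthCells(fx$truth)
  lab <- maskLabels(mask)
  for (i in seq_len(2)) {
    cl <- tc[i, ]
    # planted ellipse mask
    DR <- outer(seq_len(nrow(lab)) - cl$center_row, rep(1, ncol(lab)))
    DC <- outer(rep(1, nrow(lab)), seq_len(ncol(lab)) - cl$center_col)
    u <- (DR * cos(cl$theta) + DC * sin(cl$theta)) / cl$axis_a
    v <- (-DR * sin(cl$theta) + DC * cos(cl$theta)) / cl$axis_b
    planted <- (u^2 + v^2) <= 1
    k <- lab[round(cl$center_row), round(cl$center_col)]
    expect_gt(k, 0L)
    got <- lab == k
    iou <- sum(planted & got) / sum(planted | got)
    expect_gte(iou, 0.7)
  }
})

test_that("touching cells are split by the distance-transform watershed", {
  # two disks with centres 1.5 radii apart: overlapping binary component
  img <- matrix(100, 128, 128)
  img[diskMask(128, 128, c(64, 50), 14)] <- 400
  img[diskMask(128, 128, c(64, 71), 14)] <- 400
  mask <- segmentCells(img, minAreaPx = 100, maxAreaPx = 5000)
  expect_identical(objectCount(mask), 2L)
})

test_that("segmentation is invariant to positive intensity scaling", {
  fx <- generateField(smallSpec(seed = 8L))
  img <- getChannel(fx$field, "aggregate")
  m1 <- segmentCells(img)
  m2 <- segmentCells(img * 3.7)
  expect_identical(maskLabels(m1), maskLabels(m2))
  spot <- subtractBackground(img, 7)
  i1 <- segmentInclusions(spot, m1)
  i2 <- segmentInclusions(spot * 3.7, m2)
  expect_identical(maskLabels(i1), maskLabels(i2))
})

test_that("planted inclusions are recovered per cell and filters apply", {
  # one big cell, three well-separated spots
  img <- spotImage(128, 128, 100, centers = matrix(
    c(50, 50, 50, 80, 80, 64), 3, byrow = TRUE), amp = 600, sigma = 1.2)
  img[diskMask(128, 128, c(64, 64), 40)] <-
    img[diskMask(128, 128, c(64, 64), 40)] + 300
  cells <- segmentCells(img, minAreaPx = 200, maxAreaPx = 10000)
  expect_identical(objectCount(cells), 1L)
  spot <- subtractBackground(img, 7)
  ibs <- segmentInclusions(spot, cells)
  expect_identical(objectCount(ibs), 3L)
  # a cell with no planted IBs has no inclusion labels
  img0 <- matrix(100, 128, 128)
  img0[diskMask(128, 128, c(64, 64), 20)] <- 400
  cells0 <- segmentCells(img0)
  ibs0 <- segmentInclusions(subtractBackground(img0, 7), cells0)
  expect_identical(objectCount(ibs0), 0L)
  # min-area filter: a candidate smaller than minAreaPx is absent
  ibsBig <- segmentInclusions(spot, cells, minAreaPx = 1000)
  expect_identical(objectCount(ibsBig), 0L)
  expect_error(segmentInclusions(spot[1:64, ], cells), "shapes differ")
})

test_that("mask combination assigns owners and conserves inclusion labels", {
  cellLab <- matrix(0L, 64, 64)
  cellLab[10:30, 10:30] <- 1L
  cellLab[40:60, 10:30] <- 2L
  cells <- labeledMask(cellLab, "cell")
  ibLab <- matrix(0L, 64, 64)
  ibLab[15:17, 15:17] <- 1L          # fully inside cell 1
  ibLab[45:47, 15:17] <- 2L          # fully inside cell 2
  ibLab[2:4, 50:52] <- 3L            # fully on background
  ibs <- labeledMask(ibLab, "inclusion")
  asg <- assignInclusions(cells, ibs)
  expect_identical(asg$inclusions$owner, c(1L, 2L, 0L))
  expect_identical(asg$counts$ib_count, c(1L, 1L))
  # conservation: owned + unassigned = total labels
  expect_identical(sum(asg$counts$ib_count) +
                     sum(asg$inclusions$owner == 0L),
                   objectCount(ibs))
  expect_error(assignInclusions(cells, cells), "inclusion mask")
})

test_that("boundary-straddling inclusions break ties to the smaller cell label", {
  cellLab <- matrix(0L, 32, 32)
  cellLab[1:16, 1:32] <- 2L
  cellLab[17:32, 1:32] <- 1L
  cells <- labeledMask(cellLab, "cell")
  ibLab <- matrix(0L, 32, 32)
  ibLab[15:18, 5:6] <- 1L            # 2 px in each cell (relabeled order)
  ibs <- labeledMask(ibLab, "inclusion")
  asg <- assignInclusions(cells, ibs)
  expect_identical(asg$inclusions$owner, 1L)
})

test_that("per-cell count recovery on a default-SNR field meets the accuracy bar", {
  fx <- generateField(fieldSpec(seed = 42L))
  res <- analyzeField(fx$field)
  mc <- matchCounts(fx$truth, res)
  expect_gt(nrow(mc), 140)
  expect_gte(mean(mc$measured == mc$planted), 0.9)
  expect_gte(cor(mc$measured, mc$planted), 0.95)
})

test_that("segmentation is deterministic on identical input", {
  fx <- generateField(smallSpec(seed = 4L))
  img <- getChannel(fx$field, "aggregate")
  expect_identical(maskLabels(segmentCells(img)),
                   maskLabels(segmentCells(img)))
})
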
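test_that("phantom generation is deterministic given the seed", {
  spec <- tinyCancerSpec(seed = 5L)
  a <- generatePhantom(spec)
  b <- generatePhantom(spec)
  expect_identical(a$stack@voxels, b$stack@voxels)
  expect_identical(a$truth@cancerMask, b$truth@cancerMask)
  expect_identical(a$truth@tileLabels, b$truth@tileLabels)
})

test_that("empty noiseless phantom is constant background with no cancer", {
  spec <- phantomSpec(stackGeometry(256L, 256L), ducts = 0L, adipose = 0L,
                      collagen = 0L, immune = 0L, noiseSd = 0,
                      backgroundLevel = 80, seed = 1L)
  ph <- generatePhantom(spec)
  expect_identical(unique(as.vector(ph$stack@voxels)), 80L)
  expect_true(all(ph$truth@tileLabels == "no_cancer"))
})

test_that("normal phantoms carry no cancer truth", {
  ph <- generatePhantom(tinyNormalSpec())
  expect_false(any(ph$truth@cancerMask))
  expect_true(all(ph$truth@tileLabels == "no_cancer"))
  expect_error(phantomSpec(tissueClass = "normal", dcis = 1L),
               "zero DCIS/invasive")
})

test_that("cancer-mask pixels lie inside DCIS or invasive structures", {
  ph <- generatePhantom(tinyCancerSpec(seed = 9L))
  codes <- ph$truth@structureMask[ph$truth@cancerMask]
  expect_true(all(codes %in% c(4L, 5L)))
  expect_gt(sum(ph$truth@cancerMask), 0)
})

test_that("tile truth follows the coverage rule", {
  ph <- generatePhantom(tinyCancerSpec(seed = 3L))
  cov <- tileCoverage(ph$truth@cancerMask, 128L)
  lab <- as.vector(t(ph$truth@tileLabels))
  expect_identical(lab == "cancer", cov > 0.05)
})

test_that("SHG dominates channel 1 on collagen relative to epithelium", {
  spec <- phantomSpec(stackGeometry(512L, 512L), tissueClass = "normal",
                      ducts = 2L, adipose = 0L, collagen = 3L, immune = 0L,
                      noiseSd = 0, seed = 4L)
  ph <- generatePhantom(spec)
  ch1 <- ph$stack@voxels[, , 1, 1]
  sm <- ph$truth@structureMask
  expect_gt(mean(ch1[sm == 3L]), mean(ch1[sm == 1L]))
})

test_that("normal ducts show edge puncta that DCIS ducts lack", {
  ## mean channel-2 intensity in the thin shell just outside the duct
  ## radius: bright dot-like puncta for normal ducts, background for DCIS
  shellMean <- function(ph, structure) {
    pl <- ph$truth@placements
    pl <- pl[pl$structure == structure, ][1, ]
    H <- nrow(ph$truth@cancerMask)
    Y <- matrix(seq_len(H), H, H)
    X <- t(Y)
    d <- sqrt((Y - pl$cy)^2 + (X - pl$cx)^2)
    shell <- d > pl$r + 1 & d < pl$r + 6
    mean(ph$stack@voxels[, , 2, 1][shell])
  }
  normal <- generatePhantom(phantomSpec(stackGeometry(384L, 384L),
                                        tissueClass = "normal", ducts = 1L,
                                        adipose = 0L, collagen = 0L,
                                        immune = 0L, noiseSd = 0, seed = 8L))
  dcis <- generatePhantom(phantomSpec(stackGeometry(384L, 384L),
                                      tissueClass = "cancer", ducts = 0L,
                                      adipose = 0L, collagen = 0L,
                                      immune = 0L, dcis = 1L, invasive = 0L,
                                      noiseSd = 0, seed = 8L))
  expect_gt(shellMean(normal, "duct"), 1.5 * shellMean(dcis, "dcis"))
})

test_that("impossible placements raise a placement error", {
  spec <- phantomSpec(stackGeometry(256L, 256L), ducts = 80L, adipose = 0L,
                      collagen = 0L, immune = 0L, seed = 1L)
  expect_error(generatePhantom(spec), "placement error")
})

test_that("cohorts are patient-disjoint with correct layout", {
  coh <- generateCohort(4L, 3L, 0.5, seed = 2L,
                        geometry = stackGeometry(256L, 256L))
  man <- coh$manifest
  expect_identical(nrow(man), 12L)
  byGroup <- split(man$patient_id, man$group)
  expect_length(intersect(byGroup$A, byGroup$B), 0L)
  expect_setequal(unique(man$group), c("A", "B"))
  ## both tissue types in both groups
  expect_setequal(unique(man$tissue_label[man$group == "A"]),
                  c("normal", "cancerous"))
  expect_error(generateCohort(4L, 2L, 1.5), "cancerFraction")
  expect_error(generateCohort(1L, 2L, 0.5), "nPatients")
})

test_that("cancer-free cohorts have no cancer tiles anywhere", {
  coh <- generateCohort(2L, 2L, 0, seed = 3L,
                        geometry = stackGeometry(256L, 256L))
  for (i in seq_len(nrow(coh$manifest))) {
    ph <- cohortImage(coh, i)
    expect_true(all(ph$truth@tileLabels == "no_cancer"))
  }
})

test_that("stacks round-trip through TIFF with JSON sidecar", {
  ph <- generatePhantom(phantomSpec(stackGeometry(128L, 128L, nPlanes = 2L),
                                    ducts = 0L, adipose = 1L, collagen = 1L,
                                    immune = 0L, seed = 6L))
  f <- tempfile(fileext = ".tif")
  writeStackTIFF(ph$stack, f)
  back <- readStackTIFF(f)
  expect_identical(back@voxels, ph$stack@voxels)
  expect_identical(back@imageId, ph$stack@imageId)
  expect_identical(back@geometry@zStepUm, ph$stack@geometry@zStepUm)
  unlink(c(f, paste0(f, ".json")))
})
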
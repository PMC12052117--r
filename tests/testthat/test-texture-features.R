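test_that("quantization uses uniform bins with clipping at the ends", {
  img <- matrix(c(0, 20, 21, 42, 2099, 2100, 5000, -5), 2, 4)
  lv <- quantize(img, c(0, 2100), 100)
  expect_identical(as.vector(lv), c(1L, 1L, 2L, 3L, 100L, 100L, 100L, 1L))
  expect_true(all(quantize(matrix(7, 3, 3), c(0, 2100), 100) == 1L))
  expect_error(quantize(img, c(0, 2100), 1), ">= 2")
})

test_that("GLCM matches hand-enumerated and degenerate cases", {
  # constant image: a single nonzero entry equal to 1 after normalization
  lv <- matrix(1L, 4, 4)
  P <- compute_glcm(lv, 0, 1, num_levels = 3)
  expect_equal(P[1, 1], 1)
  expect_equal(sum(P), 1)
  # 2x2 image with columns (1,1) and (2,2): two horizontal pairs
  lv2 <- matrix(c(1L, 1L, 2L, 2L), 2, 2)
  P2 <- compute_glcm(lv2, 0, 1, num_levels = 2)
  expect_equal(P2, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  # symmetric GLCM equals its transpose
  set.seed(2)
  lvr <- matrix(sample(1:5, 64, replace = TRUE), 8, 8)
  for (dir in c(0, 45, 90, 135)) {
    Ps <- compute_glcm(lvr, dir, 2, num_levels = 5)
    expect_equal(Ps, t(Ps))
    expect_equal(sum(Ps), 1)
  }
  expect_warning(P0 <- compute_glcm(matrix(1L, 2, 2), 0, 5, num_levels = 2),
                 "exceeds")
  expect_equal(sum(P0), 0)
})

test_that("GLCM and GLRLM match the naive enumeration oracle exactly", {
  set.seed(42)
  for (rep in 1:8) {
    L <- sample(3:6, 1)
    lv <- matrix(sample(seq_len(L), 64, replace = TRUE), 8, 8)
    for (dir in c(0, 45, 90, 135)) {
      off <- sample(1:3, 1)
      expect_identical(
        compute_glcm(lv, dir, off, L, normalize = FALSE),
        naive_glcm(lv, dir, off, L, normalize = FALSE)
      )
      expect_identical(compute_glrlm(lv, dir, L), naive_glrlm(lv, dir, L))
    }
  }
})

test_that("GLCM features match direct evaluation on small matrices", {
  # constant image -> single-entry distribution
  f <- glcm_features(compute_glcm(matrix(1L, 4, 4), 0, 1, num_levels = 4))
  expect_equal(unname(f["Energy"]), 1)
  expect_equal(unname(f["Entropy"]), 0)
  expect_equal(unname(f["Contrast"]), 0)
  expect_equal(unname(f["MaxProbability"]), 1)
  expect_equal(unname(f["Correlation"]), 0) # degenerate by convention
  # 2x2 diagonal GLCM
  f2 <- glcm_features(matrix(c(0.5, 0, 0, 0.5), 2, 2))
  expect_equal(unname(f2["Energy"]), 0.5)
  expect_equal(unname(f2["Contrast"]), 0)
  expect_equal(unname(f2["Entropy"]), log(2))
  # bounds on random GLCMs; non-normalized input is normalized with warning
  set.seed(3)
  for (rep in 1:5) {
    lv <- matrix(sample(1:6, 100, replace = TRUE), 10, 10)
    P <- compute_glcm(lv, 45, 1, num_levels = 6)
    f <- glcm_features(P)
    expect_true(all(is.finite(f)))
    expect_gt(f["Energy"], 0)
    expect_lte(f["Energy"], 1)
    expect_gte(f["Entropy"], 0)
  }
  expect_warning(glcm_features(matrix(c(2, 0, 0, 2), 2, 2)), "normaliz")
})

test_that("GLRLM run counting and features match their definitions", {
  # single constant row: one run of full length
  R <- compute_glrlm(matrix(2L, 1, 5), 0, num_levels = 3)
  expect_equal(sum(R), 1)
  expect_equal(R[2, 5], 1)
  # hand run-length encoding
  R2 <- compute_glrlm(matrix(c(1L, 1L, 2L, 2L, 2L), 1, 5), 0, num_levels = 2)
  expect_equal(R2[1, 2], 1)
  expect_equal(R2[2, 3], 1)
  expect_equal(sum(R2), 2)
  # conservation: sum over runs of j * count = pixels scanned
  set.seed(4)
  lv <- matrix(sample(1:4, 56, replace = TRUE), 7, 8)
  for (dir in c(0, 45, 90, 135)) {
    R3 <- compute_glrlm(lv, dir, num_levels = 4)
    expect_equal(sum(sweep(R3, 2, seq_len(ncol(R3)), `*`)), 56)
  }
  # single run of length N
  N <- 5
  fr <- glrlm_features(compute_glrlm(matrix(1L, 1, N), 0, 2), n_pixels = N)
  expect_equal(unname(fr["ShortRunEmphasis"]), 1 / N^2)
  expect_equal(unname(fr["LongRunEmphasis"]), N^2)
  expect_equal(unname(fr["RunPercentage"]), 1 / N)
  # all runs length 1
  alt <- matrix(rep(c(1L, 2L), 8), 4, 4)
  fa <- glrlm_features(compute_glrlm(alt, 90, 2), n_pixels = 16)
  expect_equal(unname(fa["ShortRunEmphasis"]), 1)
  expect_equal(unname(fa["RunPercentage"]), 1)
  # one gray level: GrayLevelNonuniformity = number of runs
  mono <- compute_glrlm(matrix(1L, 4, 6), 0, 3)
  expect_equal(unname(glrlm_features(mono, 24)["GrayLevelNonuniformity"]),
               sum(mono))
  expect_error(glrlm_features(matrix(0, 2, 2), 4), "empty")
})

test_that("feature enumeration yields 22 columns for a single GLCM variant", {
  coh <- test_cohort(n = 1, seed = 21, hw = 16, slices = 2)
  cfg <- texture_config(glcm_directions = 0, glcm_offsets = 1,
                        glrlm_directions = 0, direction_average = FALSE)
  row <- extract_features(coh[[1]], cfg)
  expect_identical(sum(grepl("GLCM", names(row))), 22L)
  expect_identical(sum(grepl("GLRLM", names(row))), 11L)
})

test_that("a mask makes features invariant to added background slices", {
  coh <- test_cohort(n = 1, seed = 23, hw = 16, slices = 2)
  vol <- coh[[1]]
  cfg <- texture_config(glcm_directions = c(0, 90), glcm_offsets = 1,
                        num_levels = 16)
  mask <- array(TRUE, dim = dim(vol))
  base <- extract_features(vol, cfg, mask = mask)
  # append two all-background slices, masked out
  padded <- vol
  for (nm in names(padded$sequences)) {
    a <- padded$sequences[[nm]]
    pad <- array(0, c(2, dim(a)[2], dim(a)[3]))
    padded$sequences[[nm]] <- array(c(aperm(a, c(2, 3, 1)),
                                      aperm(pad, c(2, 3, 1))),
                                    dim = c(dim(a)[2], dim(a)[3], 4))
    padded$sequences[[nm]] <- aperm(padded$sequences[[nm]], c(3, 1, 2))
  }
  mask2 <- array(c(rep(TRUE, 2 * 16 * 16), rep(FALSE, 2 * 16 * 16)),
                 dim = c(16, 16, 4))
  mask2 <- aperm(mask2, c(3, 1, 2))
  expect_equal(extract_features(padded, cfg, mask = mask2), base)
  # requesting an absent sequence is rejected by name
  expect_error(extract_features(vol, cfg, sequences = c("T2", "DWI")), "DWI")
})
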
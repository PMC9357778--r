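test_that("quantization bins linearly and matches brute-force assignment", {
  expect_true(all(unclass(quantize(gray_image(matrix(9L, 4, 4)), 8)) == 0))
  img <- gray_image(matrix(0:255, 16, 16))
  q <- quantize(img, 8)
  expect_equal(unclass(q)[unclass(img) == 255], 7L)
  # brute-force bin assignment
  m <- unclass(img)
  want <- pmin(floor((m - min(m)) / (max(m) - min(m)) * 8), 7)
  expect_equal(as.vector(unclass(q)), as.vector(want))
  expect_error(quantize(img, 1), "levels")
})

test_that("GLCM matches the naive pair-enumeration oracle", {
  # constant image: single diagonal entry 1
  cst <- gray_image(matrix(3L, 5, 5), 8L)
  P <- compute_glcm(cst, c(0, 1), 8)
  expect_equal(P[4, 4], 1)
  expect_equal(sum(P), 1)

  # checkerboard, offset (0,1): every horizontal pair differs
  cb <- gray_image(outer(1:6, 1:6, function(i, j) (i + j) %% 2L), 2L)
  Pcb <- compute_glcm(cb, c(0, 1), 2)
  expect_equal(Pcb[1, 2], 0.5)
  expect_equal(Pcb[2, 1], 0.5)
  expect_equal(Pcb[1, 1] + Pcb[2, 2], 0)

  set.seed(7)
  for (i in 1:5) {
    img <- random_gray(8, 8, 4)
    for (sym in c(TRUE, FALSE)) {
      got <- compute_glcm(img, c(1, 1), 4, symmetric = sym, normalize = TRUE)
      want <- naive_glcm(unclass(img), c(1, 1), 4, symmetric = sym)
      expect_equal(unclass(got), want, ignore_attr = TRUE, tolerance = 1e-12)
    }
  }
  expect_error(compute_glcm(random_gray(4, 4, 4), c(0, 4), 4), "offset")
})

test_that("Haralick features match the loop oracle and the worked constants", {
  cst <- compute_glcm(gray_image(matrix(3L, 5, 5), 8L), c(0, 1), 8)
  f <- haralick_features(cst)
  expect_equal(f[["contrast"]], 0)
  expect_equal(f[["energy"]], 1)
  expect_equal(f[["homogeneity"]], 1)
  expect_equal(f[["entropy"]], 0)
  expect_equal(f[["correlation"]], 0)  # zero marginal SD convention

  set.seed(13)
  for (i in 1:10) {
    P <- matrix(runif(16), 4, 4)
    P <- P / sum(P)
    expect_equal(haralick_features(P), naive_haralick(P), tolerance = 1e-10)
  }
  expect_error(haralick_features(matrix(1, 2, 2)), "normalized")
})

test_that("plane splitting follows the first-half convention and symmetry", {
  img <- random_gray(4, 4, 8)
  h <- split_planes(img)
  expect_equal(dim(unclass(h$top)), c(2, 4))
  expect_equal(dim(unclass(h$left)), c(4, 2))
  expect_equal(rbind(unclass(h$top), unclass(h$bottom)), unclass(img),
               ignore_attr = TRUE)

  odd <- random_gray(5, 5, 8)
  ho <- split_planes(odd)
  expect_equal(nrow(unclass(ho$top)), 3L)
  expect_equal(nrow(unclass(ho$bottom)), 2L)

  # mirror-symmetric image: left and right half features agree
  m <- unclass(random_gray(6, 3, 4))
  sym <- gray_image(cbind(m, m[, 3:1]), 4L)
  hs <- split_planes(sym)
  fl <- haralick_features(compute_glcm(hs$left, c(1, 0), 4))
  fr <- haralick_features(compute_glcm(hs$right, c(1, 0), 4))
  expect_equal(fl, fr, tolerance = 1e-12)
})

test_that("feature vector has the documented layout and composes from parts", {
  set.seed(3)
  img <- random_gray(16, 16, 256)
  v <- extract_feature_vector(img)
  expect_length(v, 120L)
  expect_identical(v, extract_feature_vector(img))

  # whole-image block equals direct glcm + features on the quantized image
  q <- quantize(img, 8, range = c(0, 255))
  direct <- haralick_features(compute_glcm(q, c(0, 1), 8))
  expect_equal(unname(v[1:6]), unname(direct), tolerance = 1e-12)

  # transpose invariance of symmetric GLCM features with transposed offset
  f1 <- haralick_features(compute_glcm(q, c(0, 1), 8))
  f2 <- haralick_features(compute_glcm(gray_image(t(unclass(q)), 8L), c(1, 0), 8))
  expect_equal(f1, f2, tolerance = 1e-12)
})
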
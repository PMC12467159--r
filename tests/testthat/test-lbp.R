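test_that("circular sampling hits axis neighbours exactly and matches a
           bilinear oracle off-grid", {
  img <- toy_image(9)
  cfg4 <- lbp_config(p = 4, r = 1)
  centre <- c(5, 5)
  g <- sample_neighbourhood(img, centre, cfg4)
  # g0 right, then the remaining axis neighbours (top, left, bottom under
  # the (-r sin, r cos) convention)
  expect_equal(g, c(img[5, 6], img[4, 5], img[5, 4], img[6, 5]))

  # constant image: interpolation of constants is the constant
  cfg8 <- lbp_config(8, 1)
  expect_equal(sample_neighbourhood(matrix(7, 5, 5), c(3, 3), cfg8),
               rep(7, 8))

  # p=8 r=1 diagonals against the hand-written bilinear formula
  img3 <- matrix(c(0, 0, 0, 0, 0, 100, 0, 100, 100), 3, 3, byrow = TRUE)
  g8 <- sample_neighbourhood(img3, c(2, 2), cfg8)
  s <- sqrt(2) / 2
  expect_equal(g8[2], oracle_bilinear(img3, 2 - s, 2 + s))  # n=1 up-right
  expect_equal(g8[4], oracle_bilinear(img3, 2 - s, 2 - s))
  expect_equal(g8[6], oracle_bilinear(img3, 2 + s, 2 - s))
  expect_equal(g8[8], oracle_bilinear(img3, 2 + s, 2 + s))

  expect_error(sample_neighbourhood(img, c(1, 5), cfg8), "border")
})

test_that("elementary LBP codes: ties give bit 1; codes are a bijection", {
  expect_equal(lbp_code(5, rep(5, 8)), 255)    # x >= 0 on ties
  expect_equal(lbp_code(10, c(20, 0, 0, 0, 0, 0, 0, 0)), 1)
  expect_equal(lbp_code(10, c(0, 0, 0, 20, 0, 0, 0, 0)), 8)
  # all sign patterns enumerate to distinct codes 0..255
  codes <- vapply(0:255, function(k) {
    g <- ifelse(oracle_bits(k, 8) == 1, 1, -1)   # neighbours above/below 0
    lbp_code(0, g)
  }, numeric(1))
  expect_equal(sort(codes), 0:255)
})

test_that("ror_min matches brute-force rotation over the full 8-bit space", {
  rm <- ror_min(0:255, 8)
  for (code in 0:255) {
    rots <- oracle_rotations(code, 8)
    expect_equal(rm$min_code[code + 1], min(rots))
    expect_equal(rm$steps[code + 1], which.min(rots) - 1)
  }
  # rotation-invariant patterns
  expect_equal(ror_min(0, 8)$steps, 0)
  expect_equal(ror_min(255, 8)$min_code, 255)
  expect_equal(ror_min(255, 8)$steps, 0)
})

test_that("uniformity and riu2 match the enumeration oracle for p in {4,8}", {
  for (p in c(4, 8)) {
    codes <- 0:(2^p - 1)
    expect_equal(uniformity(codes, p),
                 vapply(codes, oracle_uniformity, numeric(1), p = p))
    expect_equal(riu2_code(codes, p),
                 vapply(codes, oracle_riu2, numeric(1), p = p))
  }
  # label space: exactly p+2 labels, p(p-1)+2 uniform codes
  for (p in c(4, 8, 12)) {
    lab <- riu2_code(0:(2^p - 1), p)
    expect_equal(sort(unique(lab)), 0:(p + 1))
    expect_equal(sum(lab <= p), p * (p - 1) + 2)
  }
})

test_that("dense code maps: margins, constant image, riu2 equals
           generic + per-pixel post-processing", {
  cfg <- lbp_config(8, 2)
  img <- toy_image(10)
  cm <- dense_code_map(img, cfg, "generic")
  expect_equal(dim(cm$codes), c(6, 6))       # margin ceiling(r) = 2

  const <- dense_code_map(matrix(50, 8, 8), lbp_config(8, 1), "riu2")
  expect_true(all(const$codes == 8))          # all-ones uniform pattern

  # generic map post-processed per pixel equals the riu2 map
  riu <- dense_code_map(img, cfg, "riu2")
  expect_equal(riu$codes,
               matrix(riu2_code(as.vector(cm$codes), 8),
                      nrow(cm$codes), ncol(cm$codes)))
  expect_error(dense_code_map(matrix(1, 4, 4), cfg), "too small")

  # fractional-radius samples agree with per-centre sampling
  cfg3 <- lbp_config(12, 1.5)
  cm3 <- dense_code_map(img, cfg3, "generic")
  ctr <- c(5, 5)
  g <- sample_neighbourhood(img, ctr, cfg3)
  expect_equal(cm3$codes[ctr[1] - 2, ctr[2] - 2],
               lbp_code(img[ctr[1], ctr[2]], g))
})

test_that("histograms conserve mass and respect bin counts", {
  img <- toy_image(12)
  cm <- dense_code_map(img, lbp_config(8, 1), "riu2")
  h <- lbp_histogram(cm, normalize = FALSE)
  expect_length(h$bins, 10)                        # p + 2
  expect_equal(sum(h$bins), prod(dim(cm$codes)))   # conservation
  hn <- lbp_histogram(cm)
  expect_equal(sum(hn$bins), 1, tolerance = 1e-12)

  g <- dense_code_map(img, lbp_config(4, 1), "generic")
  expect_length(lbp_histogram(g)$bins, 16)         # 2^p
})

test_that("code maps are invariant to illumination offset and monotone
           grey transforms", {
  img <- toy_image(14)
  cfg <- lbp_config(8, 1)
  for (variant in c("generic", "riu2")) {
    base <- dense_code_map(img, cfg, variant)$codes
    expect_identical(dense_code_map(img + 37, cfg, variant)$codes, base)
    expect_identical(dense_code_map(2 * img + 3, cfg, variant)$codes,
                     base)
  }
  # nonlinear monotone maps are exactly invariant when all samples are
  # grid pixels (p = 4, r = 1); interpolation breaks this in general
  cfg4 <- lbp_config(4, 1)
  base4 <- dense_code_map(img, cfg4, "generic")$codes
  expect_identical(dense_code_map((img / 255)^1.7 * 512 + 3, cfg4,
                                  "generic")$codes, base4)
})

test_that("90-degree rotation preserves the riu2 histogram but not
           necessarily the generic one", {
  img <- toy_image(16)
  cfg <- lbp_config(8, 1)
  rot <- t(img)[, nrow(img):1]                      # rotate 90 degrees
  h0 <- lbp_histogram(dense_code_map(img, cfg, "riu2"))$bins
  h1 <- lbp_histogram(dense_code_map(rot, cfg, "riu2"))$bins
  expect_equal(h1, h0, tolerance = 1e-12)
  g0 <- lbp_histogram(dense_code_map(img, cfg, "generic"))$bins
  g1 <- lbp_histogram(dense_code_map(rot, cfg, "generic"))$bins
  expect_false(isTRUE(all.equal(g0, g1)))
})

test_that("tiny fixtures carry their hand-derived riu2 maps", {
  fx <- tiny_fixture("constant")
  cm <- dense_code_map(fx$pixels, lbp_config(8, 1), "riu2")
  expect_true(all(cm$codes == fx$expected_riu2))

  cb <- tiny_fixture("checkerboard")
  cmc <- dense_code_map(cb$pixels, lbp_config(8, 1), "riu2")
  dark <- cb$pixels[2:7, 2:7] == 100
  expect_true(all(cmc$codes[dark] == cb$expected_riu2[["dark"]]))
  expect_true(all(cmc$codes[!dark] == cb$expected_riu2[["bright"]]))

  # step edge: codes on the edge columns are uniform (u <= 2)
  se <- tiny_fixture("step_edge")
  gm <- dense_code_map(se$pixels, lbp_config(8, 1), "generic")$codes
  edge_cols <- c(3, 4)   # interior columns flanking the step at col 4/5
  u <- uniformity(as.vector(gm[, edge_cols]), 8)
  expect_true(all(u <= 2))
})
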
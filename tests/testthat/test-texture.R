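test_that("quantization bins the 0-255 range into 1..Ng", {
  expect_identical(as.vector(quantize_image(matrix(0, 1, 1), ng = 9)), 1L)
  expect_identical(as.vector(quantize_image(matrix(255, 1, 1), ng = 9)),
                   9L)
  expect_identical(as.vector(quantize_image(matrix(c(10, 200), 1, 2),
                                            ng = 2)), c(1L, 2L))
  # hand bin arithmetic: floor(100 / (256/9)) + 1
  expect_equal(as.vector(quantize_image(matrix(100, 1, 1), ng = 9)),
               floor(100 / (256 / 9)) + 1)
  # off-mask pixels become NA; empty mask errors
  m <- matrix(c(1L, 0L), 1, 2)
  q <- quantize_image(matrix(c(10, 200), 1, 2), mask = m, ng = 4)
  expect_true(is.na(q[1, 2]) && !is.na(q[1, 1]))
  expect_error(quantize_image(matrix(1, 2, 2), mask = matrix(0L, 2, 2)),
               "empty mask")
})

test_that("GLCM handles constant regions and the 1x4 strip example", {
  cfg2 <- glcm_config(ng = 2)
  # constant in-mask region: single diagonal entry
  p <- glcm(quantize_image(matrix(200, 3, 3), ng = 2), cfg2)
  expect_equal(p[2, 2], 1)
  expect_equal(sum(p), 1)

  # strip with levels 1,2,1,2: only (1,2)/(2,1) pairs
  q <- matrix(c(1L, 2L, 1L, 2L), 1, 4)
  p2 <- glcm(q, cfg2)
  expect_equal(p2, matrix(c(0, 0.5, 0.5, 0), 2, 2),
               ignore_attr = TRUE)

  expect_error(glcm(matrix(NA_integer_, 2, 2), cfg2), "no valid")
})

test_that("GLCM matches the naive pair-counting oracle", {
  set.seed(31)
  for (rep in 1:10) {
    ng <- sample(3:9, 1)
    q <- matrix(sample(1:ng, 64, TRUE), 8, 8)
    if (rep > 5) q[sample(64, 10)] <- NA  # masked holes
    for (sym in c(TRUE, FALSE)) {
      off <- sample(list(c(0L, 1L), c(1L, 0L), c(1L, 1L)), 1)[[1]]
      cfg <- glcm_config(ng = ng, offset = off, symmetric = sym)
      skip_ok <- tryCatch({
        p <- glcm(q, cfg)
        expect_equal(p, oracle_glcm(q, ng, off, sym),
                     ignore_attr = TRUE, tolerance = 1e-12)
        TRUE
      }, error = function(e) grepl("no valid", conditionMessage(e)))
      expect_true(isTRUE(skip_ok))
    }
  }
})

test_that("marginal distributions and entropies satisfy their identities", {
  set.seed(17)
  p <- random_prob_matrix(6)    # symmetric by construction
  m <- glcm_marginals(p)
  expect_equal(sum(m$px), 1, tolerance = 1e-9)
  expect_equal(sum(m$py), 1, tolerance = 1e-9)
  expect_equal(sum(m$p_xplusy), 1, tolerance = 1e-9)
  expect_equal(sum(m$p_xminusy), 1, tolerance = 1e-9)
  # symmetry: px = py, HX = HY, mu_x = mu_y, var_x = var_y
  expect_equal(m$px, m$py)
  expect_equal(m$HX, m$HY)
  expect_equal(m$mu_x, m$mu_y)
  expect_equal(m$var_x, m$var_y)

  # single-entry matrix p(k,k) = 1
  ng <- 5; k <- 3
  p1 <- matrix(0, ng, ng); p1[k, k] <- 1
  m1 <- glcm_marginals(p1)
  expect_equal(m1$HXY, 0, tolerance = 1e-9)
  expect_equal(m1$p_xminusy[1], 1)             # k = 0
  expect_equal(m1$p_xplusy[2 * k - 1], 1)      # k = 2k (support 2..2Ng)

  # uniform 2x2: HX = HY = 1 bit, HXY = 2 bits
  mu <- glcm_marginals(matrix(0.25, 2, 2))
  expect_equal(mu$HX, 1, tolerance = 1e-9)
  expect_equal(mu$HY, 1, tolerance = 1e-9)
  expect_equal(mu$HXY, 2, tolerance = 1e-9)
})

test_that("trait panel limits: one-hot and uniform 2x2 matrices", {
  ng <- 4
  p <- matrix(0, ng, ng); p[2, 2] <- 1
  fv <- glcm_features(p)
  expect_equal(fv[["energ"]], 1)
  expect_equal(fv[["entro"]], 0, tolerance = 1e-9)
  expect_equal(fv[["contr"]], 0)
  expect_equal(fv[["dissi"]], 0)
  expect_equal(fv[["maxpr"]], 1)
  expect_equal(fv[["homom"]], 1)

  u <- matrix(0.25, 2, 2)
  fu <- glcm_features(u)
  expect_equal(fu[["contr"]], 0.5)     # 4-term hand sum
  expect_equal(fu[["energ"]], 0.25)    # 4 x 0.0625
})

test_that("optimized features equal the naive double-loop oracle", {
  set.seed(77)
  for (rep in 1:20) {
    p <- random_prob_matrix(5)
    fv <- glcm_features(p)
    expect_equal(fv, oracle_features(p), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("trait panel invariants hold on random matrices", {
  set.seed(41)
  for (rep in 1:25) {
    p <- random_prob_matrix(sample(2:9, 1))
    fv <- glcm_features(p)
    expect_length(fv, 23)
    expect_identical(names(fv), glcm_trait_names)
    expect_lte(fv[["energ"]], fv[["maxpr"]] + 1e-12)
    expect_lte(fv[["maxpr"]], 1)
    expect_gte(fv[["entro"]], 0)
    expect_gte(fv[["contr"]], 0)
    expect_gte(fv[["dissi"]], 0)
    expect_equal(fv[["homop"]], fv[["homom1"]])
  }
})

test_that("the square-rooted inf2h variant lies in [0, 1]", {
  set.seed(53)
  cfg <- glcm_config(corrections = list(inf2h_sqrt = TRUE))
  for (rep in 1:20) {
    fv <- glcm_features(random_prob_matrix(5), cfg)
    expect_gte(fv[["inf2h"]], 0)
    expect_lte(fv[["inf2h"]], 1)
  }
})

test_that("degenerate one-level region flags the correlation traits", {
  p <- matrix(0, 3, 3); p[1, 1] <- 1
  fv <- glcm_features(p)
  expect_true(is.nan(fv[["corrm"]]))
  expect_true(is.nan(fv[["corrp"]]))
  expect_true(isTRUE(attr(fv, "degenerate_correlation")))
})

test_that("feature tables have the contracted shape and round-trip CSV", {
  scenes <- make_timeline(5, "control", seed = 2, frame = c(96, 72))
  imgs <- lapply(scenes, function(sc)
    list(image = sc$image, mask = sc$canopy_mask, condition = "control"))
  imgs <- c(imgs, imgs[1])            # duplicate listed twice
  tab <- extract_feature_table(imgs)
  expect_equal(nrow(tab), 6)
  expect_true(all(glcm_trait_names %in% names(tab)))
  expect_equal(unname(unlist(tab[1, glcm_trait_names])),
               unname(unlist(tab[6, glcm_trait_names])))

  fp <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab, fp, row.names = FALSE)
  back <- utils::read.csv(fp)
  expect_equal(as.matrix(back[glcm_trait_names]),
               as.matrix(tab[glcm_trait_names]), tolerance = 1e-12)

  # degenerate images are skipped with a reason, not fatal
  bad <- list(list(image = matrix(0, 4, 4),
                   mask = matrix(0L, 4, 4), condition = "control"))
  tab2 <- extract_feature_table(c(imgs[1], bad))
  expect_equal(nrow(tab2), 1)
  expect_length(attr(tab2, "skipped"), 1)
})
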
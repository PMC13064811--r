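test_that("surface/total ratio recovers the generating fraction", {
  st <- generate_surface_total_image(surface_fraction = 0.4, seed = 3)
  r <- surface_total_ratio(st$surface, st$total, st$cell_mask)
  expect_equal(r, 0.4, tolerance = 0.05)
  # identity and zero-surface cases
  expect_equal(surface_total_ratio(st$total, st$total, st$cell_mask), 1,
               tolerance = 1e-8)
  zero <- matrix(0, nrow(st$total), ncol(st$total))
  expect_equal(surface_total_ratio(zero, st$total, st$cell_mask,
                                   background_subtract = FALSE), 0)
  expect_error(surface_total_ratio(st$surface, st$total,
                                   st$cell_mask & FALSE), "empty")
})

test_that("colocalization ratio recovers the generating enrichment", {
  img <- generate_two_channel_image(inside_outside_ratio = 3, seed = 4)
  r <- colocalization_ratio(img$signal, img$marker_mask, img$cell_mask)
  expect_equal(r, 3, tolerance = 0.04)
  uni <- generate_two_channel_image(inside_outside_ratio = 1, seed = 5)
  expect_equal(colocalization_ratio(uni$signal, uni$marker_mask,
                                    uni$cell_mask), 1, tolerance = 0.03)
  # degenerate: all signal inside the marker region
  conc <- img$signal
  conc[img$cell_mask & !img$marker_mask] <- 0
  expect_error(colocalization_ratio(conc, img$marker_mask, img$cell_mask,
                                    background_subtract = FALSE),
               "undefined ratio")
})

test_that("ratio metrics are gain- and background-invariant", {
  img <- generate_two_channel_image(seed = 6)
  r0 <- colocalization_ratio(img$signal, img$marker_mask, img$cell_mask)
  expect_equal(colocalization_ratio(img$signal * 7, img$marker_mask,
                                    img$cell_mask), r0, tolerance = 1e-10)
  expect_equal(colocalization_ratio(img$signal + 50, img$marker_mask,
                                    img$cell_mask), r0, tolerance = 0.02)
  st <- generate_surface_total_image(seed = 7)
  s0 <- surface_total_ratio(st$surface, st$total, st$cell_mask)
  expect_equal(surface_total_ratio(st$surface * 3, st$total * 3,
                                   st$cell_mask), s0, tolerance = 1e-10)
  expect_equal(surface_total_ratio(st$surface + 30, st$total + 30,
                                   st$cell_mask), s0, tolerance = 0.02)
})

test_that("marker mask thresholding finds the enriched blob", {
  img <- generate_two_channel_image(seed = 8)
  mm <- marker_mask_from_channel(img$marker, img$cell_mask, k = 2)
  # recovered mask overlaps the true blob almost perfectly
  jaccard <- sum(mm & img$marker_mask) / sum(mm | img$marker_mask)
  expect_gt(jaccard, 0.9)
})

test_that("spine classification reproduces the morphology rules", {
  expect_identical(classify_spine(0.40, 0.30, TRUE, FALSE)$class, "mushroom")
  expect_identical(classify_spine(0.40, NA, TRUE, TRUE)$class, "stubby")
  expect_identical(classify_spine(NA, NA, FALSE, TRUE)$class, "filopodia")
  expect_identical(classify_spine(0.30, 0.25, TRUE, FALSE)$class, "thin")
  # boundary: large head but sub-threshold head/neck ratio -> thin + flag
  low <- classify_spine(0.40, 0.38, TRUE, FALSE)
  expect_identical(low$class, "thin")
  expect_identical(low$flag, "low_head_neck_ratio")
  # exact thresholds are inclusive
  expect_identical(classify_spine(0.35, 0.35 / 1.1, TRUE, FALSE)$class,
                   "mushroom")
  expect_error(classify_spine(0.4, NA, FALSE, TRUE), "inconsistent")
})

test_that("spine classes partition any valid input and percentages sum to
           100", {
  set.seed(31)
  n <- 200
  has_head <- stats::runif(n) > 0.2
  head <- ifelse(has_head, stats::runif(n, 0.1, 0.8), NA)
  has_neck <- has_head & stats::runif(n) > 0.3
  neck <- ifelse(has_neck, stats::runif(n, 0.1, 0.6), NA)
  spines <- data.frame(head_um = head, neck_um = neck, has_head = has_head,
                       attached = !has_neck,
                       condition = sample(c("wt", "mut"), n, TRUE))
  cl <- classify_spines(spines)
  expect_true(all(cl$class %in% c("mushroom", "stubby", "thin", "filopodia")))
  expect_false(anyNA(cl$class))
  tab <- spine_type_table(cl)
  expect_equal(rowSums(tab[, c("mushroom", "stubby", "thin", "filopodia")]),
               rep(100, nrow(tab)), tolerance = 1e-10)
})
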
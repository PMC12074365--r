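test_that("Gabor banks are reproducible, finite, zero-mean and orientation-symmetric", {
  b1 <- build_gabor_bank(10, seed = 3)
  b2 <- build_gabor_bank(10, seed = 3)
  expect_identical(lapply(b1, `[[`, "kernel"), lapply(b2, `[[`, "kernel"))
  for (f in b1) {
    expect_true(all(is.finite(f$kernel)))
    expect_gt(stats::sd(f$kernel), 0)          # non-constant
    expect_lt(abs(mean(f$kernel)), 1e-12)      # zero-mean convention
  }
  # a filter rotated by 180 degrees responds identically on any pattern
  f0 <- gabor_kernel(2, 0.2, pi / 5)
  f180 <- gabor_kernel(2, 0.2, pi / 5 + pi)
  grating <- outer(1:32, 1:32, function(i, j) sin(0.4 * i + 0.2 * j))
  expect_equal(apply_gabor(grating, f0), apply_gabor(grating, f180),
               tolerance = 1e-10)
})

make_flair_only_phantom <- function(seed) {
  generate_phantom(phantom_spec(shape = c(32L, 32L),
                                contrast = c(flair = 0.4, t1c = 0,
                                             t1 = 0, t2 = 0),
                                rim_factor = c(flair = 1, t1c = 0,
                                               t1 = 0, t2 = 0),
                                noise_sd = 0.02, seed = seed))
}

test_that("filter selection keeps two representatives per cluster and tracks the informative modality", {
  phs <- lapply(1:2, make_flair_only_phantom)
  bank <- build_gabor_bank(24, seed = 5)
  sel <- select_filters(bank, lapply(phs, `[[`, "image"),
                        lapply(phs, `[[`, "lesion_mask"), k = 6, seed = 9)
  expect_lte(length(sel), 12L)
  expect_gte(length(sel), 6L)
  expect_true(all(vapply(sel, `[[`, "", "selection_basis") %in%
                    c("discriminative", "variance")))
  # only FLAIR carries lesion contrast -> every filter is assigned to it
  expect_true(all(vapply(sel, `[[`, "", "assigned_modality") == "flair"))
  sel2 <- select_filters(bank, lapply(phs, `[[`, "image"),
                         lapply(phs, `[[`, "lesion_mask"), k = 6, seed = 9)
  expect_identical(lapply(sel, `[[`, "kernel"),
                   lapply(sel2, `[[`, "kernel"))
  expect_error(select_filters(bank, lapply(phs, `[[`, "image"),
                              lapply(phs, `[[`, "lesion_mask"), k = 20))
})

test_that("voxel descriptors behave on constant regions, outliers and the identity channel", {
  ch <- array(0.5, dim = c(16, 16))
  ch[8, 8] <- 0.9                     # single-voxel outlier
  img <- multimodal_image(ch, ch, ch, ch, normalize = FALSE)
  vd <- voxel_descriptors(img, gaussian_window = 5, median_window = 3)
  expect_identical(vd$raw_flair, img$channels$flair)  # identity channel
  # far from the outlier the image is constant: zero local sd
  expect_equal(vd$gsd_flair[2, 2], 0, tolerance = 1e-12)
  # the median filter suppresses the outlier at its location
  expect_equal(vd$med_flair[8, 8], 0.5)
  # sorting oracle for a median window elsewhere
  patch <- as.vector(img$channels$flair[3:5, 3:5])
  expect_equal(vd$med_flair[4, 4], sort(patch)[5])
  expect_error(voxel_descriptors(img, gaussian_window = 33), "exceeds")
})

test_that("box-counting fractal dimension recovers analytic shapes and is shift-stable", {
  sq <- array(FALSE, dim = c(256, 256)); sq[1:256, 1:256] <- TRUE
  expect_equal(as.numeric(fractal_dimension(sq)), 2.0, tolerance = 0.15)
  ln <- array(FALSE, dim = c(256, 256)); ln[128, 1:256] <- TRUE
  expect_equal(as.numeric(fractal_dimension(ln)), 1.0, tolerance = 0.15)
  # translation changes the estimate only marginally
  blob <- array(FALSE, dim = c(300, 300)); blob[40:120, 60:140] <- TRUE
  shifted <- array(FALSE, dim = c(300, 300)); shifted[43:123, 65:145] <- TRUE
  expect_lt(abs(as.numeric(fractal_dimension(blob)) -
                as.numeric(fractal_dimension(shifted))), 0.05)
  one <- array(FALSE, dim = c(8, 8)); one[3, 3] <- TRUE
  expect_warning(fd <- fractal_dimension(one), "single")
  expect_equal(as.numeric(fd), 0)
})

test_that("cluster descriptors capture shape and intensity statistics", {
  # disk vs thin ellipse eccentricity via the moment-based estimate
  n <- 60
  co <- expand.grid(x = 1:n, y = 1:n)
  lab <- array(0L, dim = c(n, n))
  lab[(co$x - 16)^2 + (co$y - 30)^2 <= 10^2] <- 1L            # disk
  lab[((co$x - 45) / 13)^2 + ((co$y - 30) / 3)^2 <= 1] <- 2L  # thin ellipse
  ch <- array(0.5, dim = c(n, n))
  img <- multimodal_image(ch, ch, ch, ch, normalize = FALSE)
  cd <- cluster_descriptors(lab, img)
  expect_lt(cd["1", "eccentricity"], 0.2)     # disk: near-isotropic
  expect_gt(cd["2", "eccentricity"], 0.85)    # thin ellipse
  expect_true(all(is.finite(cd)))
  expect_true(all(cd[, "density"] > 0 & cd[, "density"] <= 1))
  # constant intensity: mean equals the value, sd is 0
  expect_equal(unname(cd[, "mean_flair"]), c(0.5, 0.5))
  expect_equal(unname(cd[, "sd_flair"]), c(0, 0))
  # single-element cluster
  lab1 <- array(0L, dim = c(8, 8)); lab1[4, 4] <- 1L
  img8 <- multimodal_image(array(0.3, c(8, 8)), array(0.3, c(8, 8)),
                           array(0.3, c(8, 8)), array(0.3, c(8, 8)),
                           normalize = FALSE)
  cd1 <- suppressWarnings(cluster_descriptors(lab1, img8))
  expect_equal(unname(cd1[1, "size"]), 1)
  expect_equal(unname(cd1[1, "sd_flair"]), 0)
})

test_that("cluster intensity means lie within the member value range", {
  ph <- tiny_phantom(61)
  seg <- mdpso_segment(ph$image, pso = small_pso(2, S = 12, N = 4,
                                                 dmin = 1, dmax = 2))
  cd <- cluster_descriptors(seg, ph$image)
  for (k in rownames(cd)) {
    members <- ph$image$channels$flair[seg$labels == as.integer(k)]
    expect_gte(cd[k, "mean_flair"], min(members) - 1e-12)
    expect_lte(cd[k, "mean_flair"], max(members) + 1e-12)
  }
})

test_that("assembled feature tables share cluster blocks and support the GF-only ablation", {
  ph <- tiny_phantom(71)
  seg <- mdpso_segment(ph$image, pso = small_pso(3, S = 12, N = 4,
                                                 dmin = 1, dmax = 2))
  bank <- build_gabor_bank(12, seed = 4)
  sel <- select_filters(bank, list(ph$image), list(ph$lesion_mask),
                        k = 3, seed = 4)
  idx <- which(!ph$image$background)[1:50]
  ft <- assemble_features(ph$image, seg, sel, index = idx)
  sch <- attr(ft, "schema")
  expect_identical(ncol(ft), length(sch$columns))
  expect_identical(ncol(ft), sch$n_voxel + sch$n_gabor + sch$n_cluster)
  # two elements of the same cluster share the whole cluster block
  labs <- seg$labels[idx]
  same <- which(labs == labs[1])
  cl_cols <- grep("^cl_", names(ft))
  expect_equal(unlist(ft[same[1], cl_cols]), unlist(ft[same[2], cl_cols]))
  # GF-only ablation drops exactly the cluster block
  ft0 <- assemble_features(ph$image, NULL, sel, index = idx,
                           include_cluster = FALSE)
  expect_identical(names(ft0), setdiff(names(ft), names(ft)[cl_cols]))
  expect_identical(attr(ft0, "schema")$n_cluster, 0L)
})
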
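test_that("the attribute transform has its closed-form values and is strictly increasing", {
  expect_equal(intensity_transform(0), 0)
  expect_equal(intensity_transform(1), exp(1) - 1, tolerance = 1e-12)
  xs <- sort(runif(50, 0, 3))
  expect_true(all(diff(intensity_transform(xs)) > 0))
  expect_error(intensity_transform(-0.1))
})

test_that("element distance reduces to single-term closed forms and matches the oracle", {
  cfg <- distance_config(alpha = rep(1, 6), weight = rep(1, 6), s_dim = 2)
  p <- runif(6)
  expect_equal(element_distance(p, p, cfg), 0)
  q <- p; q[3] <- p[3] + 1
  expect_equal(element_distance(p, q, cfg), exp(1) - 1, tolerance = 1e-12)
  expect_error(element_distance(p[1:5], q, cfg))
  set.seed(11)
  for (i in 1:50) {
    a <- runif(6, 0.2, 3); w <- runif(6, 0, 2)
    cfg <- distance_config(alpha = a, weight = c(rep(w[1], 2), w[3:6]),
                           s_dim = 2)
    x <- runif(6); y <- runif(6)
    expect_equal(element_distance(x, y, cfg),
                 oracle_distance(x, y, cfg$alpha, cfg$weight),
                 tolerance = 1e-12)
  }
})

test_that("assignment matches exhaustive search and breaks ties to the lowest index", {
  set.seed(21)
  for (i in 1:10) {
    E <- matrix(runif(8 * 8 * 4), 64, 4)  # 2 spatial + 2 channels
    C <- matrix(runif(3 * 4), 3, 4)
    a <- runif(4, 0.3, 2); w <- runif(4, 0.1, 2)
    cfg <- distance_config(alpha = a, weight = c(rep(w[1], 2), w[3:4]),
                           s_dim = 2)
    got <- assign_elements(E, C, cfg)
    exp_ <- oracle_assign(E, C, cfg$alpha, cfg$weight)
    expect_identical(got$labels, exp_$labels)
    expect_equal(got$A_i, exp_$A_i)
    expect_equal(got$e_i, exp_$e_i, tolerance = 1e-12)
    expect_equal(sum(got$A_i), nrow(E))
  }
  # tie-break: centroids 2 and 5 identical and nearest -> label 2
  E <- matrix(c(0.5, 0.5, 0.5), 1, 3)
  C <- rbind(c(9, 9, 9), c(0.5, 0.5, 0.5), c(8, 8, 8), c(7, 7, 7),
             c(0.5, 0.5, 0.5))
  cfg2 <- distance_config(alpha = rep(1, 3), weight = rep(1, 3), s_dim = 2)
  expect_identical(assign_elements(E, C, cfg2)$labels, 2L)
  # single centroid: everything in cluster 1, e_1 is the distance total
  got1 <- assign_elements(E, C[2, , drop = FALSE], cfg2)
  expect_identical(got1$labels, 1L)
  expect_equal(got1$e_i, 0)
})

test_that("the balance-seeking fitness reproduces the hand-worked example", {
  stats <- structure(list(labels = c(1L, 1L, 2L, 2L), A_i = c(2, 2),
                          e_i = c(1, 3), A = 4), class = "cluster_stats")
  expect_equal(cluster_fitness(stats, 1), (1 / 4) * (1 / 2 + 9 / 2))
  expect_equal(cluster_fitness(stats, 1), 1.25)
  # zero error everywhere -> zero fitness
  stats0 <- structure(list(A_i = c(2, 2), e_i = c(0, 0), A = 4),
                      class = "cluster_stats")
  expect_equal(cluster_fitness(stats0, 3), 0)
  expect_error(cluster_fitness(structure(list(A_i = 1, e_i = 0, A = 0),
                                         class = "cluster_stats"), 1))
})

test_that("splitting a cluster into identical halves changes fitness only by the d-prefactor", {
  # one cluster (A=2n, e=2e) versus two equal halves (A=n, e=e each):
  # sum e_i^2/A_i is invariant, so fitness scales exactly by d2/d1
  n <- 7; e <- 2.31
  one <- structure(list(A_i = 2 * n, e_i = 2 * e, A = 2 * n),
                   class = "cluster_stats")
  two <- structure(list(A_i = c(n, n), e_i = c(e, e), A = 2 * n),
                   class = "cluster_stats")
  f1 <- cluster_fitness(one, 1)
  f2 <- cluster_fitness(two, 2)
  expect_equal(f2 / f1, 2 / 1)
})

test_that("empty clusters are repaired by reseeding at the worst-fit element", {
  set.seed(3)
  E <- matrix(runif(40 * 6), 40, 6)
  cfg <- default_distance_config(2)
  # second centroid far outside the data: guaranteed empty before repair
  cs <- structure(list(d_index = 1L, count = 2L,
                       centroids = rbind(E[1, ], rep(100, 6))),
                  class = "centroid_set")
  raw <- assign_elements(E, cs, cfg)
  expect_true(any(raw$A_i == 0))
  ev <- evaluate_centroids(E, cs, cfg)
  expect_true(all(ev$stats$A_i > 0))
  expect_true(is.finite(ev$fitness))
  expect_equal(sum(ev$stats$A_i), nrow(E))
})

test_that("centroid initialization samples real intensity tuples inside the unit domain", {
  ph <- tiny_phantom(5)
  set.seed(42)
  cs <- initialize_centroids(ph$image, d = 3)
  expect_identical(cs$count, 6L)
  expect_true(all(cs$centroids[, 1:2] >= 0 & cs$centroids[, 1:2] <= 1))
  # every intensity 4-tuple occurs somewhere in the image
  chans <- ph$image$channels
  tuples <- cbind(as.vector(chans$flair), as.vector(chans$t1c),
                  as.vector(chans$t1), as.vector(chans$t2))
  for (r in seq_len(cs$count)) {
    hit <- which(abs(tuples[, 1] - cs$centroids[r, 3]) < 1e-12)
    expect_true(any(apply(abs(tuples[hit, , drop = FALSE] -
      matrix(cs$centroids[r, 3:6], length(hit), 4, byrow = TRUE)), 1,
      max) < 1e-12))
  }
  set.seed(42)
  cs2 <- initialize_centroids(ph$image, d = 3)
  expect_identical(cs$centroids, cs2$centroids)
  expect_error(initialize_centroids(
    multimodal_image(array(0, c(4, 4)), array(0, c(4, 4)),
                     array(0, c(4, 4)), array(0, c(4, 4)),
                     normalize = FALSE), d = 2), "background")
})

test_that("segmentation separates well-contrasted blobs and is seed-reproducible", {
  ph <- tiny_phantom(13, noise = 0.03)
  seg1 <- mdpso_segment(ph$image, pso = small_pso(99, S = 24, N = 8,
                                                  dmin = 1, dmax = 3))
  seg2 <- mdpso_segment(ph$image, pso = small_pso(99, S = 24, N = 8,
                                                  dmin = 1, dmax = 3))
  expect_identical(seg1$labels, seg2$labels)
  expect_identical(seg1$d, seg2$d)
  expect_gte(asa_dice(seg1$labels, ph$lesion_labels), 0.90)
  # optimizer contract: the returned fitness never exceeds any initial
  # particle evaluation
  init_fit <- seg1$opt$trace$fitness[seg1$opt$trace$iteration == -1L]
  expect_true(seg1$fitness <= min(init_fit, na.rm = TRUE) + 1e-12)
  # labels form a partition of the non-background domain
  expect_true(all(seg1$labels[ph$image$background] == 0L))
  expect_true(all(seg1$labels[!ph$image$background] > 0L))
})

test_that("superpixel-mode segmentation weights clusters by superpixel size", {
  ph <- tiny_phantom(29, shape = c(24L, 24L))
  sp <- slic_superpixels(ph$image, k = 30)
  seg <- mdpso_segment(ph$image, pso = small_pso(7, S = 12, N = 5,
                                                 dmin = 1, dmax = 3),
                       elements = "superpixel", superpixels = sp)
  expect_equal(sum(seg$stats$A_i), sum(!ph$image$background))
  expect_true(all(seg$labels[!ph$image$background] > 0))
})
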
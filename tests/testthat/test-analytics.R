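test_that("person_item_distances matches hand values", {
  xi <- matrix(c(0, 0), 1, 2)
  zeta <- rbind(c(3, 4), c(0, 1))
  expect_equal(unname(person_item_distances(xi, zeta)),
               matrix(c(5, 1), 1, 2))
  expect_equal(unname(person_item_distances(matrix(0, 3, 2),
                                            matrix(0, 2, 2))),
               matrix(0, 3, 2))
  expect_error(person_item_distances(matrix(0, 2, 2), matrix(0, 2, 3)))
})

test_that("item_distance_matrix is symmetric with zero diagonal", {
  z <- rbind(c(0, 0), c(0, 2))
  D <- item_distance_matrix(z)
  expect_equal(unname(D), matrix(c(0, 2, 2, 0), 2, 2))
  # two tight, far-apart blobs give block structure
  set.seed(31)
  z2 <- rbind(matrix(rnorm(10, 0, 0.05), 5, 2),
              matrix(rnorm(10, 10, 0.05), 5, 2))
  D2 <- item_distance_matrix(z2)
  within <- c(D2[1:5, 1:5][upper.tri(diag(5))],
              D2[6:10, 6:10][upper.tri(diag(5))])
  between <- as.vector(D2[1:5, 6:10])
  expect_lt(max(within), min(between))
})

test_that("cluster_centers: means, singletons, label handling", {
  z <- rbind(c(0, 0), c(2, 2), c(5, -1))
  cc <- cluster_centers(z, c("a", "a", "b"))
  expect_equal(unname(cc["a", ]), c(1, 1))
  expect_equal(unname(cc["b", ]), c(5, -1))
})

test_that("inter-cluster distances reproduce the worked example", {
  tab <- inter_cluster_distance_table(ref_centers)
  expect_equal(tab$distances["c1", "c2"], 0.673, tolerance = 0.001)
  expect_equal(tab$distances["c1", "c4"], 2.116, tolerance = 0.005)
  expect_equal(tab$distances["c6", "c7"], 1.370, tolerance = 0.005)
  expect_true(isSymmetric(tab$distances))
  expect_equal(unname(diag(tab$distances)), rep(0, 7))
  expect_equal(unname(tab$mean_to_others),
               unname(rowSums(tab$distances) / 6))
})

test_that("person_cluster_distances: worked example and contracts", {
  # centroid method against the printed person/center pair
  pcd <- person_cluster_distances(ref_persons[, c("x1", "x2")],
                                  ref_centers,
                                  labels = rownames(ref_centers),
                                  method = "centroid")
  expect_equal(unname(pcd$distances[1, "c7"]), 3.749, tolerance = 0.005)
  expect_equal(pcd$farthest[1], "c7")
  # one-item clusters: both methods coincide
  z <- rbind(c(0, 0), c(1, 1), c(-2, 0.5))
  xi <- rbind(c(0.2, 0.3), c(-1, 2))
  a <- person_cluster_distances(xi, z, c("u", "v", "w"), "per-item-mean")
  b <- person_cluster_distances(xi, z, c("u", "v", "w"), "centroid")
  expect_equal(a$distances, b$distances)
  # per-item-mean equals the mean of member-item distances
  lab <- c("g", "g", "h")
  m <- person_cluster_distances(xi, z, lab, "per-item-mean")
  D <- person_item_distances(xi, z)
  expect_equal(unname(m$distances[, "g"]), unname(rowMeans(D[, 1:2])))
  # farthest ties go to the lowest cluster index
  zt <- rbind(c(1, 0), c(-1, 0))
  t2 <- person_cluster_distances(matrix(c(0, 0), 1, 2), zt, c("1", "2"))
  expect_equal(t2$farthest, "1")
})

test_that("person_mean_distance is the row mean", {
  expect_equal(person_mean_distance(matrix(c(5, 1), 1, 2)), 3)
  expect_equal(person_mean_distance(matrix(2, 3, 4)), rep(2, 3))
})

test_that("perceived_difficulty intervals", {
  D <- matrix(c(1, 2, 3, 1, 1, 1), 3, 2)
  # lambda = 0: degenerate at b
  p0 <- perceived_difficulty(c(0.4, -0.2), 0, D)
  expect_equal(p0$table$min, p0$table$max)
  expect_equal(p0$table$mean_effect, c(0.4, -0.2))
  # b = 0, lambda = 1, distances {1,2,3}
  p1 <- perceived_difficulty(c(0, 0), 1, D)
  expect_equal(p1$table$mean_effect[1], -2)
  expect_equal(p1$table$min[1], -3)
  expect_equal(p1$table$max[1], -1)
  expect_error(perceived_difficulty(c(0, 0), -1, D))
})

test_that("covariate_overlay summarizes groups and correlations", {
  xi <- rbind(c(0, 1), c(0, 3))
  rownames(xi) <- c("a", "b")
  zeta <- matrix(0, 2, 2)  # both items at origin -> distances 1 and 3
  cov <- data.frame(person = c("a", "b"), group = c("g1", "g2"))
  ov <- covariate_overlay(xi, zeta, cov, "group")
  expect_equal(ov$summary$type, "categorical")
  g <- ov$summary$groups
  expect_equal(g$mean[g$value == "g1"], 1)
  expect_equal(g$mean[g$value == "g2"], 3)
  # continuous covariate equal to the mean distance -> correlation 1
  set.seed(32)
  xi2 <- matrix(rnorm(20), 10, 2)
  rownames(xi2) <- paste0("p", 1:10)
  md <- person_mean_distance(person_item_distances(xi2, zeta))
  cov2 <- data.frame(person = paste0("p", 1:10), score = md)
  ov2 <- covariate_overlay(xi2, zeta, cov2, "score")
  expect_equal(ov2$summary$type, "continuous")
  expect_equal(ov2$summary$correlation, 1)
  # unmatched persons are dropped and counted
  expect_message(
    ov3 <- covariate_overlay(xi, zeta, cov[1, , drop = FALSE], "group"),
    "dropped")
  expect_equal(ov3$n_dropped, 1L)
  expect_error(covariate_overlay(xi, zeta, cov, "missing_column"))
})

test_that("item_clusters separates far blobs", {
  set.seed(33)
  z <- rbind(matrix(rnorm(12, 0, 0.1), 6, 2),
             matrix(rnorm(12, 8, 0.1), 6, 2))
  cl <- item_clusters(z, 2)
  expect_equal(length(unique(cl[1:6])), 1L)
  expect_equal(length(unique(cl[7:12])), 1L)
  expect_true(cl[1] != cl[7])
  # accepts a precomputed distance matrix too
  cl2 <- item_clusters(item_distance_matrix(z), 2)
  expect_equal(cl, cl2)
})

test_that("feedback_report ranks items by distance, farthest first", {
  set.seed(34)
  n <- 4L; P <- 3L; I <- 4L
  xi <- array(rep(matrix(rnorm(P * 2), P, 2), n), c(P, 2, n))
  zeta <- array(rep(matrix(rnorm(I * 2), I, 2), n), c(I, 2, n))
  fit <- fake_fit(matrix(rnorm(n * P), n, P), matrix(0, n, I),
                  rep(1, n), rep(0, n), xi = xi, zeta = zeta)
  fit$response$values <- matrix(c(1L, 0L), P, I)
  al <- align_posterior(fit)
  fr <- feedback_report(fit, al, "p2", labels = c("a", "a", "b", "b"))
  D <- person_item_distances(al$xi, al$zeta)
  expect_equal(fr$items$item_id,
               paste0("i", order(D[2, ], decreasing = TRUE)))
  expect_equal(fr$items$distance, sort(D[2, ], decreasing = TRUE),
               ignore_attr = TRUE)
  expect_equal(fr$theta_hat, unname(theta_hat(fit)["p2"]))
  expect_equal(nrow(fr$clusters), 2L)
  expect_equal(fr$clusters$cluster[1], fr$farthest_cluster,
               ignore_attr = TRUE)
  expect_error(feedback_report(fit, al, "nobody"), "unknown")
})

test_that("cluster ranking matches a descending sort of the distance row", {
  pcd <- person_cluster_distances(ref_persons[, c("x1", "x2")], ref_centers,
                                  rownames(ref_centers), "centroid")
  for (p in 1:4) {
    expect_equal(order(pcd$distances[p, ], decreasing = TRUE),
                 order(ref_person_cluster[p, ], decreasing = TRUE))
  }
})
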
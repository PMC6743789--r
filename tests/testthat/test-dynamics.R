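test_that("fraction_of_max divides rows by their maximum", {
  m <- tiny_signal(list(a = c(2, 4, 8, 4, 2, 1),
                        b = c(3, 3, 3, 3, 3, 3),
                        z = c(0, 0, 0, 0, 0, 0)))
  fom <- fraction_of_max(m)
  expect_equal(unname(fom["a", ]), c(0.25, 0.5, 1, 0.5, 0.25, 0.125))
  expect_equal(unname(fom["b", ]), rep(1, 6))
  expect_equal(unname(fom["z", ]), rep(0, 6))
  expect_equal(unname(attr(fom, "all_zero")), c(FALSE, FALSE, TRUE))
})

test_that("static/dynamic calls follow the pairwise fold rule", {
  m <- tiny_signal(list(s = c(10, 10, 12, 11, 10, 10),
                        d = c(5, 5, 5, 12, 5, 5),
                        k = c(7, 7, 7, 7, 7, 7)))
  calls <- classify_static_dynamic(m, 2, 0.1)
  expect_equal(calls$label, c("static", "dynamic", "static"))
  expect_equal(calls$max_pairwise_fold[1], 12.1 / 10.1)
  expect_equal(calls$max_pairwise_fold[2], 12.1 / 5.1)
  expect_error(classify_static_dynamic(m, 1, 0.1), "fold_threshold")
  expect_error(classify_static_dynamic(m[, 1, drop = FALSE]), "2 stages")
})

test_that("static/dynamic matches the all-pairs brute-force oracle", {
  set.seed(11)
  m <- matrix(rlnorm(200 * 6, 1, 1), 200, 6,
              dimnames = list(sprintf("r%03d", 1:200), stage6()))
  for (pc in c(0, 0.1, 1)) {
    calls <- classify_static_dynamic(m, 2, pc)
    expect_equal(calls$label, unname(oracle_static_dynamic(m, 2, pc)))
  }
  # partition property and threshold monotonicity
  n_dyn <- function(fold) {
    sum(classify_static_dynamic(m, fold, 0.1)$label == "dynamic")
  }
  counts <- vapply(c(1.5, 2, 3, 5), n_dyn, 0)
  expect_true(all(diff(counts) <= 0))
  calls <- classify_static_dynamic(m, 2, 0.1)
  expect_equal(sum(calls$label == "static") + sum(calls$label == "dynamic"),
               nrow(m))
})

test_that("stage transitions label opening/closing/flat per adjacent pair", {
  m <- tiny_signal(list(a = c(1, 5, 1, 5, 8, 1)))
  tr <- stage_transitions(m, 2, 0)
  expect_equal(unname(tr["a", ]),
               c("opening", "closing", "opening", "flat", "closing"))
  expect_equal(colnames(tr)[1], "L3->6h")
  expect_equal(ncol(tr), 5)  # stages - 1
})

test_that("log2 fold change vs reference has a zero reference column", {
  m <- matrix(c(2, 4, 8, 1, 3, 9), 2, 3, byrow = TRUE,
              dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  lfc <- log2fc_vs_reference(m, "s1", 0)
  expect_equal(unname(lfc["a", ]), c(0, 1, 2))
  lfc2 <- log2fc_vs_reference(m, "s1", 1)
  expect_equal(unname(lfc2["b", 2]), 1)  # log2((3+1)/(1+1))
  z <- matrix(c(0, 0), 1, 2, dimnames = list("g", c("s1", "s2")))
  expect_equal(unname(log2fc_vs_reference(z, "s1", 0.1)["g", 2]), 0)
  expect_error(log2fc_vs_reference(m, "s9"), "s9")
})

test_that("k-means recovers separable blobs and is deterministic", {
  set.seed(3)
  blob1 <- matrix(rnorm(40 * 3, 0, 0.1), 40, 3)
  blob2 <- matrix(rnorm(40 * 3, 5, 0.1), 40, 3)
  x <- rbind(blob1, blob2)
  rownames(x) <- sprintf("r%02d", 1:80)
  truth <- rep(1:2, each = 40)
  res <- kmeans_clusters(x, k = 2, seed = 5)
  expect_equal(oracle_ari(res$assignment, truth), 1)
  res2 <- kmeans_clusters(x, k = 2, seed = 5)
  expect_identical(res$assignment, res2$assignment)

  small <- x[1:5, ]
  res3 <- kmeans_clusters(small, k = 5, seed = 1)
  expect_equal(res3$wcss, 0)
  expect_equal(sort(unique(res3$assignment)), 1:5)
  expect_error(kmeans_clusters(small, k = 6), "at least")
})

test_that("centroid categories separate sharp, broad, oscillating, flat", {
  expect_equal(label_cluster_category(c(0.1, 0.1, 1.0, 0.2, 0.1, 0.1)),
               "sharp")
  expect_equal(label_cluster_category(c(0.2, 0.8, 0.9, 1.0, 0.3, 0.2)),
               "broad")
  expect_equal(label_cluster_category(c(1.0, 0.2, 0.9, 0.1, 0.8, 0.1)),
               "oscillating")
  expect_equal(label_cluster_category(c(0.8, 0.9, 0.8, 0.9, 0.8, 0.9)),
               "flat")
  expect_error(label_cluster_category(numeric(0)), "empty")
})

test_that("dynamic genes require both the RPKM floor and the fold change", {
  m <- tiny_signal(list(low = c(0.2, 0.5, 0.1, 0.3, 0.2, 0.1),
                        dyn = c(0.5, 3.0, 0.5, 0.5, 0.5, 0.5),
                        mod = c(2, 2.5, 3, 2.8, 2, 2.2)))
  calls <- classify_dynamic_genes(m, 1, 2, 0.1)
  expect_equal(calls$dynamic, c(FALSE, TRUE, FALSE))
  expect_equal(calls$max_pairwise_fold[2], 3.1 / 0.6)
  expect_equal(calls$max_pairwise_fold[3], 3.1 / 2.1)
})
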
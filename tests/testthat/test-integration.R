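test_that("pearson_r matches hand values and linearity properties", {
  expect_equal(pearson_r(1:6, 1:6), 1)
  expect_equal(pearson_r(1:6, -(1:6)), -1)
  expect_equal(round(pearson_r(c(1, 2, 3), c(1, 2, 4)), 4), 0.982)
  set.seed(2)
  x <- rnorm(10)
  expect_equal(pearson_r(x, 3 * x + 2), 1)
  expect_equal(pearson_r(x, -0.5 * x + 1), -1)
  expect_true(is.na(pearson_r(x, rep(1, 10))))
  expect_error(pearson_r(1:2, 1:2), "length")
})

test_that("quadrant classification follows the joint 2-fold rule", {
  sig <- matrix(c(1, 4,    # open 4x
                  1, 4,    # open 4x
                  5, 1),   # close 5x
                3, 2, byrow = TRUE,
                dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
  expr <- matrix(c(1, 4,    # up 4x
                   2, 3,    # 1.5x: ns
                   1, 3),   # up 3x
                 3, 2, byrow = TRUE,
                 dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  asg <- data.frame(peak_id = c("p1", "p2", "p3"),
                    gene_id = c("g1", "g2", "g3"),
                    stringsAsFactors = FALSE)
  q <- pairwise_quadrants(sig, expr, asg,
                          stage_pairs = list(c("s1", "s2")),
                          fold_threshold = 2, pseudocount = 0)
  expect_equal(q$table$quadrant, c("open_up", "ns", "close_up"))
  counts <- q$counts
  expect_equal(sum(counts$count), 3)

  # order invariance and unassigned peaks do not change counts
  asg2 <- rbind(asg[c(3, 1, 2), ],
                data.frame(peak_id = "p9", gene_id = NA_character_))
  q2 <- pairwise_quadrants(sig, expr, asg2,
                           stage_pairs = list(c("s1", "s2")),
                           fold_threshold = 2, pseudocount = 0)
  expect_equal(sort(q2$table$quadrant), sort(q$table$quadrant))

  # assigned gene missing from expression: excluded and counted
  asg3 <- rbind(asg, data.frame(peak_id = "p1b", gene_id = "ghost"))
  sig2 <- rbind(sig, p1b = c(1, 4))
  q3 <- pairwise_quadrants(sig2, expr, asg3,
                           stage_pairs = list(c("s1", "s2")),
                           fold_threshold = 2, pseudocount = 0)
  expect_equal(q3$n_excluded, 1L)
})

test_that("default stage pairs are each stage versus its next two", {
  stages <- c("a", "b", "c", "d")
  sig <- matrix(1, 1, 4, dimnames = list("p", stages))
  expr <- matrix(1, 1, 4, dimnames = list("g", stages))
  asg <- data.frame(peak_id = "p", gene_id = "g")
  q <- pairwise_quadrants(sig, expr, asg)
  expect_equal(unique(q$table$pair),
               c("a->b", "a->c", "b->c", "b->d", "c->d"))
})

test_that("sample correlation matrix is symmetric with unit diagonal", {
  set.seed(4)
  m <- matrix(rlnorm(1e4 * 3), 1e4, 3,
              dimnames = list(NULL, c("r1", "r2", "r3")))
  m <- cbind(m, r4 = m[, "r1"])
  r <- sample_correlation_matrix(m)
  expect_equal(r["r1", "r4"], 1)
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 4))
  expect_true(all(abs(r["r1", c("r2", "r3")]) < 0.05))
  mz <- cbind(m[, 1, drop = FALSE], z = rep(2, nrow(m)))
  rz <- sample_correlation_matrix(mz)
  expect_true(is.na(rz["r1", "z"]))
  expect_equal(rz["z", "z"], 1)
})

test_that("trajectory correlations pair genes with their peaks", {
  stages <- c("s1", "s2", "s3", "s4")
  lfc <- matrix(c(0, 1, 2, 3,
                  0, -1, -2, -3), 2, 4, byrow = TRUE,
                dimnames = list(c("gUp", "gDown"), stages))
  fom <- matrix(c(0.1, 0.4, 0.7, 1,
                  0.5, 0.5, 0.5, 0.5), 2, 4, byrow = TRUE,
                dimnames = list(c("pUp", "pFlat"), stages))
  asg <- data.frame(peak_id = c("pUp", "pFlat"),
                    gene_id = c("gUp", "gDown"), stringsAsFactors = FALSE)
  clusters <- c(gUp = 1L, gDown = 1L)
  tc <- cluster_trajectory_correlation(lfc, clusters, fom, asg)
  expect_equal(tc$pairs$r[tc$pairs$gene_id == "gUp"], 1)
  expect_equal(tc$n_zero_variance, 1L)  # constant peak excluded
  expect_equal(tc$summary$n, 1L)
})

test_that("mannwhitney_u matches its examples and the enumeration oracle", {
  mw <- mannwhitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)
  mw2 <- mannwhitney_u(c(1), c(2))
  expect_equal(mw2$U, 0)
  expect_equal(mw2$p, 1)
  # identical multisets: U = nx*ny/2
  mw3 <- mannwhitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(mw3$U, 4.5)
  # degenerate all-tied input
  expect_equal(mannwhitney_u(rep(2, 5), rep(2, 4))$p, 1)
  expect_error(mannwhitney_u(numeric(0), 1), "non-empty")

  # exact mode vs full enumeration for every nx + ny <= 8, tie-free
  set.seed(9)
  for (nx in 1:7) {
    for (ny in 1:(8 - nx)) {
      vals <- sample(seq_len(40), nx + ny)
      x <- vals[seq_len(nx)]
      y <- vals[-seq_len(nx)]
      got <- mannwhitney_u(x, y)
      ora <- oracle_mwu_exact(x, y)
      expect_equal(got$U, ora$U)
      expect_equal(got$p, ora$p, tolerance = 1e-12)
    }
  }
})

test_that("gene-set profiles report per-stage means and rank-sum p-values", {
  stages <- c("L3", "44h")
  sig <- matrix(c(1, 4, 2, 5, 3, 6), 3, 2, byrow = TRUE,
                dimnames = list(c("p1", "p2", "p3"), stages))
  asg <- data.frame(peak_id = c("p1", "p2", "p3"), gene_id = "gA",
                    stringsAsFactors = FALSE)
  prof <- geneset_profile(sig, asg, "gA", reference_stage = "L3")
  expect_equal(prof$mean_signal, c(2, 5))
  expect_true(is.na(prof$p[prof$stage == "L3"]))
  expect_equal(prof$p[prof$stage == "44h"], 0.1)  # [1,2,3] vs [4,5,6]
  expect_error(geneset_profile(sig, asg, "ghost"), "no assigned peaks")
})

test_that("hypergeometric enrichment gives the upper-tail probability", {
  expect_equal(hypergeom_enrichment(2, 2, 2, 4), 1 / 6)
  expect_equal(hypergeom_enrichment(0, 5, 3, 20), 1)
  expect_equal(hypergeom_enrichment(3, 10, 3, 10), 1)  # set = universe
  expect_error(hypergeom_enrichment(5, 2, 2, 4), "inconsistent")
})

test_that("MA tables compute mean log expression and log ratio", {
  ma <- ma_table(c(g1 = 4, g2 = 8), c(g1 = 4, g2 = 2), pseudocount = 0)
  expect_equal(ma$M[ma$gene_id == "g1"], 0)
  expect_equal(ma$A[ma$gene_id == "g1"], 2)
  expect_equal(ma$M[ma$gene_id == "g2"], 2)
  expect_equal(ma$A[ma$gene_id == "g2"], 2)
  ma2 <- ma_table(c(g = 0), c(g = 0), pseudocount = 1)
  expect_equal(ma2$M, 0)
  expect_equal(ma2$A, 0)
  expect_error(ma_table(c(a = 1), c(b = 1)), "match")
})
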
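test_that("nearest-TSS assignment applies the distance, sign and tie rules", {
  peaks <- data.frame(peak_id = c("p1", "p2", "p3"), chrom = "2L",
                      start = c(900, 900, 900), end = c(1100, 1100, 1100))
  # p1: TSSs at 400 (+) and 1800 (+) -> geneA at +600
  # p2 checks the minus-strand sign; p3 the equidistant tie
  tss <- data.frame(
    gene_id = c("geneA", "geneB", "geneM", "geneZ", "geneY"),
    chrom = c("2L", "2L", "2L", "3R", "3R"),
    tss = c(400L, 1800L, 1300L, 1L, 1L),
    strand = c("+", "+", "-", "+", "+"), stringsAsFactors = FALSE)
  asg <- assign_nearest_tss(peaks[1, ], tss[1:2, ])
  expect_equal(asg$gene_id, "geneA")
  expect_equal(asg$signed_distance, 600L)

  # midpoint 1000, minus-strand TSS at 1300: midpoint is downstream -> +300
  asg2 <- assign_nearest_tss(peaks[2, ], tss[3, ])
  expect_equal(asg2$signed_distance, 300L)

  # equidistant between two genes -> lexicographically smallest id
  tie <- data.frame(gene_id = c("gB", "gA"), chrom = "2L",
                    tss = c(900L, 1100L), strand = "+",
                    stringsAsFactors = FALSE)
  asg3 <- assign_nearest_tss(peaks[3, ], tie)
  expect_equal(asg3$gene_id, "gA")

  # chromosome without any TSS: unassigned with a warning
  orphan <- data.frame(peak_id = "pX", chrom = "4", start = 0L, end = 10L)
  expect_warning(asg4 <- assign_nearest_tss(orphan, tss), "unassigned")
  expect_true(is.na(asg4$gene_id))
})

test_that("nearest-TSS matches the exhaustive oracle on random instances", {
  set.seed(21)
  peaks <- random_peaks(100, chroms = c("2L", "2R", "3L"))
  tss <- random_tss(50, chroms = c("2L", "2R", "3L"))
  asg <- assign_nearest_tss(peaks, tss)
  ora <- oracle_nearest_tss(peaks, tss)
  expect_equal(asg$gene_id, ora$gene_id)
  expect_equal(asg$signed_distance, ora$signed_distance)
})

test_that("feature categories follow the priority rule", {
  # + strand gene, TSS 10000: promoter window [-500, 150]
  gm <- data.frame(
    gene_id = "gA", chrom = "2L",
    start = c(10000, 10000, 10200, 10700, 11000, 11500),
    end = c(12000, 10200, 10700, 11000, 11500, 12000),
    strand = "+",
    feature = c("gene", "five_prime_utr", "cds", "intron", "cds",
                "three_prime_utr"),
    nc_gene = FALSE, stringsAsFactors = FALSE)
  tssA <- data.frame(gene_id = "gA", chrom = "2L", tss = 10000L,
                     strand = "+", stringsAsFactors = FALSE)
  mk <- function(mid) {
    data.frame(peak_id = paste0("p", mid), chrom = "2L",
               start = mid - 10L, end = mid + 10L,
               stringsAsFactors = FALSE)
  }
  cat_of <- function(mid) {
    p <- mk(mid)
    a <- assign_nearest_tss(p, tssA)
    classify_features(a, gm, p)$feature_category
  }
  expect_equal(cat_of(9800), "proximal_promoter")   # 200 bp upstream
  expect_equal(cat_of(10100), "proximal_promoter")  # +100, inside 5'UTR too
  expect_equal(cat_of(10400), "cds")
  expect_equal(cat_of(10800), "intron")
  expect_equal(cat_of(11700), "three_prime_utr")
  expect_equal(cat_of(30000), "intergenic")

  # noncoding gene body
  gm_nc <- data.frame(gene_id = "ncX", chrom = "2L", start = 50000,
                      end = 52000, strand = "+", feature = "gene",
                      nc_gene = TRUE, stringsAsFactors = FALSE)
  p <- mk(51000)
  a <- assign_nearest_tss(p, data.frame(gene_id = "ncX", chrom = "2L",
                                        tss = 50000L, strand = "+"))
  expect_equal(classify_features(a, gm_nc, p)$feature_category, "nc_gene")
})

test_that("distance bins are half-open and sum to assigned peaks", {
  asg <- data.frame(peak_id = sprintf("p%d", 1:6),
                    gene_id = "g",
                    midpoint = 0L,
                    signed_distance = c(100L, -700L, 3000L, 7000L, 20000L,
                                        500L),
                    strand = "+", stringsAsFactors = FALSE)
  bins <- distance_bins(asg)
  expect_equal(bins$count, c(1, 2, 1, 1, 1))  # 500 falls in [0.5,1)
  expect_equal(sum(bins$count), nrow(asg))
  empty <- distance_bins(asg[0, ])
  expect_equal(sum(empty$count), 0)
  # stratified counts preserve the total
  strat <- distance_bins(asg, labels = rep(c("static", "dynamic"), 3))
  expect_equal(sum(strat$count), nrow(asg))
})

test_that("peak-set overlap counting uses half-open intersection", {
  a <- data.frame(peak_id = c("a1", "a2", "a3"), chrom = "2L",
                  start = c(100L, 500L, 900L), end = c(200L, 600L, 1000L))
  b <- data.frame(peak_id = c("b1", "b2"), chrom = "2L",
                  start = c(150L, 200L), end = c(250L, 300L))
  ov <- overlap_peaksets(a, b)
  expect_equal(ov$count, 1L)  # a1 via b1; a1/b2 abut without overlap
  expect_equal(ov$pairs$peak_b, "b1")

  # adjacency is not overlap under half-open coordinates
  ov2 <- overlap_peaksets(data.frame(peak_id = "x", chrom = "2L",
                                     start = 100L, end = 200L),
                          data.frame(peak_id = "y", chrom = "2L",
                                     start = 200L, end = 300L))
  expect_equal(ov2$count, 0L)

  # min_bp threshold
  ov3 <- overlap_peaksets(a, b, min_bp = 51L)
  expect_equal(ov3$count, 0L)  # a1/b1 intersect by exactly 50 bp
})

test_that("gene structure statistics compute element lengths and medians", {
  gm <- rbind(
    data.frame(gene_id = "g1", chrom = "2L", start = 0, end = 1000,
               strand = "+", feature = "gene", nc_gene = FALSE),
    data.frame(gene_id = "g1", chrom = "2L", start = 200, end = 800,
               strand = "+", feature = "intron", nc_gene = FALSE),
    data.frame(gene_id = "g2", chrom = "2L", start = 2000, end = 5000,
               strand = "+", feature = "gene", nc_gene = FALSE))
  st <- gene_structure_stats(gm, list(all = c("g1", "g2")))
  gene_lengths <- st$lengths$length[st$lengths$element == "gene"]
  expect_equal(sort(gene_lengths), c(1000, 3000))
  expect_equal(st$lengths$length[st$lengths$element == "intron"], 600)
  med <- st$summary$median[st$summary$element == "gene"]
  expect_equal(med, 2000)
  # intronless gene contributes no intron rows
  expect_equal(sum(st$lengths$element == "intron" &
                     st$lengths$gene_id == "g2"), 0)
  expect_warning(gene_structure_stats(gm, list(s = c("g1", "ghost"))),
                 "absent")
})
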
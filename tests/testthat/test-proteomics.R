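tiny_table <- function() {
  protein_table(paste0("P", 1:5),
                matrix(2^rnorm(15, 25), 5, 3,
                       dimnames = list(NULL, paste0("segment_", 1:3))),
                flags = list(character(0), "reverse", character(0),
                             c("reverse", "potential_contaminant"),
                             "only_identified_by_site"))
}

test_that("filter_flagged removes flagged rows and counts per flag", {
  set.seed(1)
  t <- tiny_table()
  out <- filter_flagged(t)
  expect_equal(out$protein_id, c("P1", "P3"))
  expect_equal(unname(attr(out, "removed")), c(2L, 1L, 1L))

  # no flags -> identity
  clean <- protein_table(c("a", "b"), matrix(c(1, 2, 3, 4), 2))
  out2 <- filter_flagged(clean)
  expect_equal(out2$protein_id, c("a", "b"))
  expect_equal(sum(attr(out2, "removed")), 0L)
})

test_that("log2_zscore standardizes rows with the sample SD", {
  t <- protein_table("p1", matrix(c(4, 2, 2), 1), NULL, paste0("s", 1:3))
  z <- log2_zscore(t)
  expect_equal(unname(z[1, ]), c(2 / sqrt(3), -1 / sqrt(3), -1 / sqrt(3)),
               tolerance = 1e-12)
  expect_equal(round(unname(z[1, 1]), 4), 1.1547)

  # constant rows get z = 0 and are flagged
  tc <- protein_table("c1", matrix(c(8, 8, 8), 1), NULL, paste0("s", 1:3))
  zc <- log2_zscore(tc)
  expect_equal(unname(zc[1, ]), c(0, 0, 0))
  expect_equal(attr(zc, "constant"), "c1")

  # every non-constant row: mean 0, sample SD 1
  set.seed(23)
  tr <- protein_table(paste0("p", 1:50),
                      matrix(2^rnorm(200, 25, 2), 50, 4))
  zr <- log2_zscore(tr)
  expect_equal(unname(rowMeans(zr)), rep(0, 50), tolerance = 1e-12)
  expect_equal(unname(apply(zr, 1, sd)), rep(1, 50), tolerance = 1e-12)

  # rows with too few quantified values are excluded and reported
  tm <- protein_table(c("a", "b"), rbind(c(4, 0, 0), c(2, 4, 8)))
  zm <- log2_zscore(tm, min_valid = 3)
  expect_equal(rownames(zm), "b")
  expect_equal(attr(zm, "excluded"), "a")

  # population-SD option rescales by sqrt((n-1)/n)
  zp <- log2_zscore(t, population_sd = TRUE)
  expect_equal(unname(zp[1, 1]), (2 / sqrt(3)) * sqrt(3 / 2), tolerance = 1e-12)
})

test_that("classify_exclusive calls a protein in exactly one segment", {
  z <- rbind(p1 = c(1.1547, -0.5774, -0.5774),
             p2 = c(0, 0, 0),
             p3 = c(-1.1547, 0.5774, 0.5774))
  colnames(z) <- paste0("s", 1:3)
  calls <- classify_exclusive(z, 1)
  expect_equal(nrow(calls), 2)
  expect_equal(calls$segment[calls$protein_id == "p1"], "s1")
  expect_equal(calls$direction[calls$protein_id == "p1"], "over")
  expect_equal(calls$direction[calls$protein_id == "p3"], "under")

  # a protein crossing the bound in two segments yields no call in that
  # direction
  z2 <- rbind(q = c(1.0, 1.0, -2.0))
  c2 <- classify_exclusive(z2, 1)
  expect_equal(sum(c2$direction == "over"), 0)
  expect_equal(sum(c2$direction == "under"), 1)

  # column-order invariance
  set.seed(3)
  zr <- matrix(rnorm(60), 20, 3, dimnames = list(paste0("p", 1:20),
                                                 paste0("s", 1:3)))
  zr <- t(apply(zr, 1, function(x) (x - mean(x)) / sd(x)))
  c1 <- classify_exclusive(zr, 1)
  c2 <- classify_exclusive(zr[, c(3, 1, 2)], 1)
  expect_equal(nrow(c1), nrow(c2))
  m1 <- c1[order(c1$protein_id, c1$direction), c("protein_id", "segment")]
  m2 <- c2[order(c2$protein_id, c2$direction), c("protein_id", "segment")]
  expect_equal(m1$segment, m2$segment)
})

test_that("with 3 segments the attainable |z| maximum is 2/sqrt(3)", {
  # so a threshold of 1 is attainable but 1.2 can never fire
  set.seed(41)
  tr <- protein_table(paste0("p", 1:200),
                      matrix(2^rnorm(600, 25, 2), 200, 3))
  z <- log2_zscore(tr)
  expect_lte(max(abs(z)), 2 / sqrt(3) + 1e-9)
  expect_gt(nrow(classify_exclusive(z, 1)), 0)
  expect_equal(nrow(classify_exclusive(z, 1.2)), 0)
})

test_that("planted exclusive markers are recovered exactly at high effect size", {
  ph <- make_protein_phantom(n_proteins = 300, planted_per_segment = 10,
                             effect_size = 5, noise_sd = 0.2, seed = 8)
  z <- log2_zscore(filter_flagged(ph$table))
  calls <- classify_exclusive(z, 1)
  # every planted marker is called, in its planted segment and direction
  # (z-scoring is scale-invariant per row, so unplanted noise rows also fire
  # at the 3-segment null rate; exactness is therefore asserted on the
  # planted rows)
  got <- calls[calls$protein_id %in% ph$truth$protein_id, ]
  got <- got[order(got$protein_id, got$direction), ]
  want <- ph$truth[order(ph$truth$protein_id, ph$truth$direction), ]
  expect_equal(got$protein_id, want$protein_id)
  expect_equal(got$segment, want$segment)
  expect_equal(got$direction, want$direction)

  # with noise-free background rows, recovery is exact over the whole table
  ph0 <- make_protein_phantom(n_proteins = 100, planted_per_segment = 4,
                              effect_size = 5, noise_sd = 0, seed = 9)
  z0 <- log2_zscore(ph0$table)
  calls0 <- classify_exclusive(z0, 1)
  expect_setequal(paste(calls0$protein_id, calls0$segment, calls0$direction),
                  paste(ph0$truth$protein_id, ph0$truth$segment,
                        ph0$truth$direction))
})

test_that("hierarchical_cluster merges tight pairs first and matches the linkage oracle", {
  # two tight pairs: the first two merges join the pairs at tiny heights
  X <- rbind(c(0, 0), c(0.1, 0), c(10, 10), c(10.1, 10))
  rownames(X) <- paste0("p", 1:4)
  pc <- hierarchical_cluster(X, n_pre_clusters = 4, seed = 2)
  expect_lte(max(pc$heights[1:2]), 0.11)
  expect_true(all(diff(pc$heights) >= -1e-12))

  # identical rows merge at height 0 (duplicates collapse into one centroid)
  Y <- rbind(a = c(1, 1), b = c(1, 1), c = c(5, 5))
  pc2 <- hierarchical_cluster(Y, n_pre_clusters = 3, seed = 1)
  expect_equal(length(pc2$heights), 1)  # 2 distinct centroids -> 1 merge
  expect_setequal(pc2$row_order, c("a", "b", "c"))

  # 20 random rows, k-means degenerate to singletons: heights equal the
  # O(n^3) complete-linkage oracle
  set.seed(77)
  Z <- matrix(rnorm(60), 20, 3, dimnames = list(paste0("p", 1:20), NULL))
  pc3 <- hierarchical_cluster(Z, n_pre_clusters = 20, seed = 3)
  expect_equal(sort(pc3$heights), sort(oracle_complete_linkage_heights(Z)),
               tolerance = 1e-10)
})

test_that("proteinGroups TSV reading and call/newick writing work end to end", {
  d <- withr::local_tempdir()
  ph <- make_protein_phantom(n_proteins = 60, planted_per_segment = 3,
                             effect_size = 5, seed = 4)
  lfq <- ph$table$intensities
  tab <- data.frame(`Protein IDs` = ph$table$protein_id,
                    Reverse = c("+", rep("", 59)),
                    `Only identified by site` = "",
                    `Potential contaminant` = "", check.names = FALSE)
  for (s in colnames(lfq)) tab[[paste0("LFQ intensity ", s)]] <- lfq[, s]
  f <- file.path(d, "proteinGroups.txt")
  write.table(tab, f, sep = "\t", row.names = FALSE, quote = FALSE)

  t <- read_protein_groups(f)
  expect_equal(length(t$protein_id), 60)
  expect_equal(t$flags[[1]], "reverse")
  filt <- filter_flagged(t)
  expect_equal(length(filt$protein_id), 59)
  expect_equal(unname(filt$intensities), unname(lfq[-1, ]))

  z <- log2_zscore(filt)
  calls <- classify_exclusive(z)
  cf <- file.path(d, "calls.tsv")
  write_calls_tsv(calls, cf)
  expect_equal(nrow(read.delim(cf)), nrow(calls))

  pc <- hierarchical_cluster(z, n_pre_clusters = 30, seed = 5)
  nf <- file.path(d, "dendro.nwk")
  write_dendrogram_newick(pc, nf)
  tree <- ape::read.tree(nf)
  expect_equal(length(tree$tip.label), length(pc$hclust$order))
})
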
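test_that("convolutional difference maps are antisymmetric and localized", {
  # 32-bin windows give a 5x5 final conv map, enough to localize
  model <- tinyModel(seed = 19, window_bins = 32L)
  set.seed(9)
  base <- matrix(runif(32 * 32, 0, 0.3), 32, 32)
  base <- (base + t(base)) / 2
  base[1, 32] <- base[32, 1] <- 1 # shared maximum: no global rescale
  a <- base
  a[4:12, 4:12] <- a[4:12, 4:12] + 0.6 # planted block difference, top corner
  b <- base
  expect_equal(convDifference(model, a, a), matrix(0, 32, 32))
  d_ab <- convDifference(model, a, b)
  d_ba <- convDifference(model, b, a)
  expect_equal(d_ab, -d_ba)
  expect_identical(dim(d_ab), c(32L, 32L))
  # magnitude concentrated near the planted block, not the far corner
  expect_gt(mean(abs(d_ab[4:12, 4:12])), 2 * mean(abs(d_ab[26:32, 26:32])))
})

test_that("amalgamation coverage-averages overlapping windows", {
  # two half-overlapping constant maps 1 and 3: overlap cells average to 2
  m1 <- matrix(1, 8, 8)
  m3 <- matrix(3, 8, 8)
  out <- amalgamateMaps(list(m1, m3), start_bins = c(0L, 4L), n_bins = 12L)
  expect_equal(out[1:4, 1:4], matrix(1, 4, 4))
  expect_equal(out[5:8, 5:8], matrix(2, 4, 4))
  expect_equal(out[9:12, 9:12], matrix(3, 4, 4))
  expect_true(all(is.na(out[1:4, 9:12])))
  # single window: band equals the map
  one <- amalgamateMaps(list(m1), 0L, 8L)
  expect_equal(one, m1)
  expect_error(amalgamateMaps(list(m1, matrix(1, 6, 6)), c(0L, 0L), 12L),
               "inconsistent")
})

test_that("replicate-calibrated thresholding follows the percentile rule", {
  set.seed(10)
  # rep map all zeros: every nonzero condition cell is flagged
  rep0 <- matrix(0, 20, 20)
  cond <- matrix(0, 20, 20)
  cond[3, 7] <- 0.5
  cond[15, 2] <- -0.2
  mask <- thresholdFeatures(cond, rep0)
  expect_identical(sum(mask), 2L)
  expect_true(mask[3, 7] && mask[15, 2])
  # cond == rep: ~5% of cells exceed their own 95th percentile
  r <- matrix(rnorm(10000), 100, 100)
  frac <- mean(thresholdFeatures(r, r))
  expect_lt(abs(frac - 0.05), 0.01)
})

test_that("component labelling and size filters follow the 50kb/2.56Mb rules", {
  res <- 1e4
  mask <- matrix(FALSE, 400, 400)
  mask[10:12, 10:12] <- TRUE        # 30 kb x 30 kb: dropped (both < 50 kb)
  mask[50:59, 70:72] <- TRUE        # 100 kb x 30 kb: kept
  mask[100:399, 100:109] <- TRUE    # 3 Mb x 100 kb: dropped (> 2.56 Mb)
  mask[200, 210] <- TRUE            # single cell: dropped
  comps <- labelAndFilter(mask, res)
  expect_length(comps, 1L)
  expect_equal(comps[[1]]$bbox$rows, c(50, 59))
  # diagonal-adjacent cells join one component (8-connectivity)
  mask2 <- matrix(FALSE, 30, 30)
  mask2[cbind(5:12, 5:12)] <- TRUE # anti-diagonal-like line of 8 cells
  comps2 <- labelAndFilter(mask2, res)
  expect_length(comps2, 1L)
  expect_identical(nrow(comps2[[1]]$cells), 8L)
})

test_that("convex hulls contain their components; signs follow the map", {
  res <- 1e4
  mask <- matrix(FALSE, 60, 60)
  # L-shaped component, 12 cells spanning 70 kb
  mask[10:16, 10] <- TRUE
  mask[16, 10:15] <- TRUE
  cond <- matrix(0, 60, 60)
  cond[mask] <- 0.8 # gained under the fixed ordering
  comps <- labelAndFilter(mask, res)
  feats <- hullAndSign(comps, cond, res)
  expect_identical(nrow(feats), 1L)
  expect_identical(feats$sign, "gained")
  hull <- attr(feats, "hulls")[[1]]
  # hull fills the corner: at least as many cells as the component
  expect_gte(nrow(hull), nrow(comps[[1]]$cells))
  comp_keys <- paste(comps[[1]]$cells[, 1], comps[[1]]$cells[, 2])
  hull_keys <- paste(hull[, 1], hull[, 2])
  expect_true(all(comp_keys %in% hull_keys))
  # convex component is its own hull
  mask2 <- matrix(FALSE, 60, 60)
  mask2[20:27, 30:35] <- TRUE
  comps2 <- labelAndFilter(mask2, res)
  feats2 <- hullAndSign(comps2, -abs(cond) - 0.1, res)
  expect_identical(nrow(attr(feats2, "hulls")[[1]]),
                   nrow(comps2[[1]]$cells))
  expect_identical(feats2$sign, "lost")
})

test_that("shape clustering recovers planted archetypes", {
  set.seed(11)
  # 20 jittered copies each of 3 archetypes: block, triangle, thin bar
  mk_feature <- function(kind) {
    size <- 14 + sample(0:4, 1)
    cells <- switch(kind,
      block = {
        g <- expand.grid(r = 1:size, c = 1:size)
        cbind(g$r, g$c)
      },
      triangle = {
        g <- expand.grid(r = 1:size, c = 1:size)
        g <- g[g$c <= g$r, ]
        cbind(g$r, g$c)
      },
      bar = {
        g <- expand.grid(r = 1:3, c = 1:(3 * size))
        cbind(g$r, g$c)
      })
    keep <- runif(nrow(cells)) > 0.05 # jitter: drop ~5% of cells
    cells[keep, , drop = FALSE]
  }
  kinds <- rep(c("block", "triangle", "bar"), each = 20)
  hulls <- lapply(kinds, mk_feature)
  feats <- data.frame(id = seq_along(kinds))
  attr(feats, "hulls") <- hulls
  cl <- clusterFeatures(feats, k = 3L, seed = 5L, categorize = TRUE)
  purity <- sum(vapply(1:3, function(ci) {
    max(table(kinds[cl$cluster == ci]))
  }, numeric(1))) / length(kinds)
  expect_gte(purity, 0.9)
  # determinism under the seed; stability of assignments
  cl2 <- clusterFeatures(feats, k = 3L, seed = 5L, categorize = TRUE)
  expect_identical(cl$cluster, cl2$cluster)
  # heuristic categories: bars are stripes, blocks are domain-like
  expect_true(all(cl$category[kinds == "bar"] == "stripe"))
  expect_true(mean(cl$category[kinds == "block"] == "domain_like") > 0.9)
  # identical features collapse into one occupied cluster
  same <- data.frame(id = 1:12)
  attr(same, "hulls") <- rep(list(mk_feature("block")), 12)
  cl3 <- clusterFeatures(same, k = 3L, seed = 1L)
  expect_identical(length(unique(cl3$cluster)), 1L)
  # too few features for k errors
  expect_error(clusterFeatures(same, k = 20L), "smaller k")
})

test_that("feature BEDPE and cluster image writers emit valid text", {
  feats <- data.frame(
    id = 1:2, row_start_bp = c(0, 1e5), row_end_bp = c(5e4, 2e5),
    col_start_bp = c(0, 1.2e5), col_end_bp = c(5e4, 2.4e5),
    sign = c("gained", "lost"), mean_value = c(0.2, -0.3),
    score = c(0.2, 0.3), component_area = c(10L, 20L),
    hull_area = c(12L, 24L), chrom = "chr2",
    cluster_id = c(1L, 2L), category = c("domain_like", "stripe"))
  path <- withr::local_tempfile(fileext = ".bedpe")
  writeFeaturesBEDPE(feats, path)
  bed <- read.table(path, sep = "\t")
  expect_identical(nrow(bed), 2L)
  expect_identical(bed$V11, c("gained", "lost"))
  imgs <- list(means = list(matrix(runif(16), 4, 4)))
  prefix <- withr::local_tempfile()
  writeClusterMeans(imgs, prefix)
  pgm <- readLines(paste0(prefix, ".cluster1.pgm"))
  expect_identical(pgm[1], "P2")
})
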
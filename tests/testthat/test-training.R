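test_that("contrastive loss matches hand-computed values", {
  # d = 5: label 0 -> d^2 = 25; label 1 with m = 1 -> hinge inactive -> 0
  expect_equal(contrastiveLoss(c(0, 0), c(3, 4), 0), 25)
  expect_equal(contrastiveLoss(c(0, 0), c(3, 4), 1, margin = 1), 0)
  expect_equal(contrastiveLoss(c(1, 2), c(1, 2), 0), 0)
  # active hinge: d = 0.6, m = 1 -> 0.16
  expect_equal(contrastiveLoss(c(0.6, 0), c(0, 0), 1, margin = 1), 0.16,
               tolerance = 1e-12)
  # batch value is the mean over pairs
  e_a <- cbind(c(0, 0), c(0, 0))
  e_b <- cbind(c(3, 4), c(3, 4))
  expect_equal(contrastiveLoss(e_a, e_b, c(0, 1)), 25 / 2)
})

test_that("cross-embedding loss is BCE with symmetrized orderings", {
  expect_equal(crossEmbeddingLoss(0, 1), log(2), tolerance = 1e-9)
  expect_equal(crossEmbeddingLoss(0, 0), log(2), tolerance = 1e-9)
  expect_lt(crossEmbeddingLoss(30, 1), 1e-9)
  expect_lt(crossEmbeddingLoss(-30, 0), 1e-9)
  # symmetrization: swapping the pair leaves the averaged loss unchanged
  z_ab <- 1.3
  z_ba <- -0.4
  expect_equal(crossEmbeddingLoss(z_ab, 1, z_ba),
               crossEmbeddingLoss(z_ba, 1, z_ab))
})

test_that("total loss applies the 2:1 weighting", {
  expect_equal(totalLoss(0.5, 0.7), 1.7)
  expect_equal(totalLoss(0, 0), 0)
  expect_equal(totalLoss(0.5, 0.7, weights = c(1, 0)), 0.5)
})

test_that("losses are non-negative on random embeddings", {
  set.seed(8)
  for (i in 1:20) {
    e_a <- matrix(rnorm(8), 4)
    e_b <- matrix(rnorm(8), 4)
    lab <- sample(0:1, 2, replace = TRUE)
    l1 <- contrastiveLoss(e_a, e_b, lab)
    l2 <- crossEmbeddingLoss(rnorm(2), lab, rnorm(2))
    expect_gte(l1, 0)
    expect_gte(l2, 0)
    expect_gte(totalLoss(l1, l2), 0)
  }
})

test_that("early stopping halts on a >10% rise over the best after epoch 5", {
  cfg <- trainConfig()
  # monotone decrease: continue throughout
  expect_identical(earlyStop(c(1, .9, .8, .7, .6), cfg), "continue")
  # rise within 10% of the best: continue
  expect_identical(earlyStop(c(1, .9, .8, .7, .6, .65), cfg), "continue")
  # rise beyond 1.1 x best: halt (0.67 > 0.66)
  expect_identical(earlyStop(c(1, .9, .8, .7, .6, .67), cfg), "halt")
  # the rule never fires before min_epochs
  expect_identical(earlyStop(c(1, 10), cfg), "continue")
  expect_identical(earlyStop(c(1, .5, 2, 2, 2), trainConfig(min_epochs = 6L)),
                   "continue")
  # alternative baseline: previous epoch
  cfg_prev <- trainConfig(stop_baseline = "previous")
  expect_identical(earlyStop(c(1, .9, .8, .7, .6, .67), cfg_prev), "halt")
  expect_identical(earlyStop(c(1, .9, .8, .7, .7, .75), cfg_prev),
                   "continue")
})

test_that("autodiff gradients match finite differences on a toy batch", {
  ns <- asNamespace("SiameseHiC")
  cfg <- modelConfig(window_bins = 16L, embed_dim = 3L)
  model <- tinyModel(seed = 7)
  wts <- modelWeights(model)
  tcfg <- trainConfig()
  set.seed(21)
  xa <- array(runif(16 * 16 * 2), c(16, 16, 1, 2))
  xb <- array(runif(16 * 16 * 2), c(16, 16, 1, 2))
  label <- c(0L, 1L)
  lossOf <- function(w) {
    fa <- ns$siameseForward(w, cfg, xa)
    fb <- ns$siameseForward(w, cfg, xb)
    ns$batchLossGrad(w, fa$e, fb$e, label, tcfg)$total
  }
  fa <- ns$siameseForward(wts, cfg, xa)
  fb <- ns$siameseForward(wts, cfg, xb)
  bl <- ns$batchLossGrad(wts, fa$e, fb$e, label, tcfg)
  ga <- ns$siameseBackward(wts, cfg, fa, bl$de_a)
  gb <- ns$siameseBackward(wts, cfg, fb, bl$de_b)
  grads <- Map(`+`, ga, gb)
  grads$Whead <- bl$gWhead
  grads$bhead <- bl$gbhead
  eps <- 1e-5
  for (nm in names(wts)) {
    idx <- sample(length(wts[[nm]]), min(4, length(wts[[nm]])))
    for (ii in idx) {
      wp <- wts; wp[[nm]][ii] <- wp[[nm]][ii] + eps
      wm <- wts; wm[[nm]][ii] <- wm[[nm]][ii] - eps
      num <- (lossOf(wp) - lossOf(wm)) / (2 * eps)
      an <- grads[[nm]][ii]
      # 1e-4 relative with an absolute floor for near-zero gradients
      expect_lt(abs(num - an), 1e-4 * max(abs(num), abs(an), 1e-6))
    }
  }
})

test_that("training runs are deterministic and reduce the training loss", {
  # small planted two-chromosome problem, 16-bin windows
  exp <- tinyExperiment(seed = 5, n_bins = 80L)
  w <- windowExperiment(exp, window_bins = 16L, stride_bp = 8e4)
  pairs <- makePairs(w)
  mcfg <- modelConfig(window_bins = 16L, embed_dim = 4L)
  tcfg <- trainConfig(max_epochs = 6L, batch_size = 32L, seed = 3L)
  fit1 <- trainSiamese(pairs, mcfg, tcfg)
  fit2 <- trainSiamese(pairs, mcfg, tcfg)
  expect_identical(fit1$history, fit2$history)
  expect_identical(modelWeights(fit1$model), modelWeights(fit2$model))
  # training sanity: final train total loss below epoch-1 total loss
  h <- fit1$history
  expect_lt(totalLoss(h$train_l1[nrow(h)], h$train_l2[nrow(h)]),
            totalLoss(h$train_l1[1], h$train_l2[1]))
  # history bookkeeping: one record per completed epoch
  expect_identical(h$epoch, seq_len(nrow(h)))
})

test_that("training validates split and label structure", {
  exp <- tinyExperiment(seed = 5, n_bins = 80L)
  w <- windowExperiment(exp, window_bins = 16L, stride_bp = 8e4)
  pairs <- makePairs(w)
  mcfg <- modelConfig(window_bins = 16L, embed_dim = 4L)
  no_val <- pairs[pairs@split != "val"]
  expect_error(trainSiamese(no_val, mcfg), "empty split: val")
  only_rep <- pairs[pairs@label == 0L]
  expect_error(trainSiamese(only_rep, mcfg), "single label")
})

test_that("depth-mirrored grouping prevents learning (non-learning control)", {
  # one condition, 2 high- + 2 low-depth replicates, no planted differences:
  # the mixed grouping leaves nothing separable. The contrastive loss can
  # still shrink by inflating every distance toward the mixture optimum
  # (label weights 1/3 vs 2/3 give d* = 2/3, loss 2/9), so the meaningful
  # non-learning check is that replicate and condition distance
  # distributions stay inseparable.
  cfg <- syntheticConfig(chroms = c(chr1 = 100L, chr18 = 100L,
                                    chr2 = 100L),
                         depth = 2e5, diff_features = list(), seed = 9)
  exp <- generateExperiment(cfg, conditions = "DP", replicates = 4L,
                            depth_scale = c(R1 = 1, R2 = 1,
                                            R3 = 0.5, R4 = 0.5))
  w <- windowExperiment(exp, window_bins = 16L, stride_bp = 4e4)
  depth <- c(R1 = "high", R2 = "high", R3 = "low", R4 = "low")
  pairs <- makePairs(w, mode = "depth_robust", depth = depth)
  mcfg <- modelConfig(window_bins = 16L, embed_dim = 4L)
  tcfg <- trainConfig(max_epochs = 8L, batch_size = 64L, seed = 2L)
  fit <- trainSiamese(pairs, mcfg, tcfg)
  report <- separationReport(fit$model, pairs)
  expect_lte(separationIndexOf(report), 0.2)
  # the loss can never beat the inseparable-mixture optimum
  expect_gt(min(fit$history$val_l1), 2 / 9 - 0.05)
})
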
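#' Training configuration
#'
#' Defaults follow the published recipe: learning rate 0.01 (a sweep over
#' 0.001–0.05 shows little sensitivity), batch size 128, total loss
#' \code{2*L1 + L2}, a forced minimum of 5 epochs, and a halt when the
#' validation contrastive loss rises more than 10\% above the best seen.
#' The contrastive margin and the optimizer are not pinned by the recipe;
#' the package uses margin 1 (cleaned inputs in \code{[0,1]} keep distances
#' O(1)) and plain SGD (momentum 0, configurable).
#'
#' @param lr learning rate.
#' @param batch_size mini-batch size.
#' @param margin contrastive margin m.
#' @param loss_weights weights for (L1, L2).
#' @param min_epochs forced training epochs before the stop rule applies.
#' @param stop_rise fractional rise in validation L1 that halts training.
#' @param stop_baseline \code{"best"} (default) compares to the minimum
#'   validation L1 so far; \code{"previous"} to the preceding epoch.
#' @param max_epochs epoch cap.
#' @param momentum SGD momentum.
#' @param seed shuffle/init seed.
#' @return a config list.
#' @export
trainConfig <- function(lr = 0.01, batch_size = 128L, margin = 1,
                        loss_weights = c(2, 1), min_epochs = 5L,
                        stop_rise = 0.10, stop_baseline = c("best",
                                                            "previous"),
                        max_epochs = 30L, optimizer = c("adam", "sgd"),
                        momentum = 0, seed = 1L) {
  stop_baseline <- match.arg(stop_baseline)
  optimizer <- match.arg(optimizer)
  stopifnot(lr > 0, batch_size >= 1, margin > 0, all(loss_weights >= 0),
            min_epochs >= 1, stop_rise > 0, max_epochs >= 1)
  list(lr = lr, batch_size = as.integer(batch_size), margin = margin,
       loss_weights = loss_weights, min_epochs = as.integer(min_epochs),
       stop_rise = stop_rise, stop_baseline = stop_baseline,
       max_epochs = as.integer(max_epochs), optimizer = optimizer,
       momentum = momentum, seed = as.integer(seed))
}

#' Contrastive loss on the Euclidean embedding distance
#'
#' With \eqn{d = \|e_a - e_b\|}: replicate pairs (label 0) contribute
#' \eqn{d^2}, condition pairs (label 1) contribute
#' \eqn{\max(0, m - d)^2}; the batch value is the mean over pairs.
#'
#' @param e_a,e_b embedding matrices (dim x n) or vectors.
#' @param label 0/1 per pair.
#' @param margin margin m.
#' @return mean loss (single number).
#' @export
contrastiveLoss <- function(e_a, e_b, label, margin = 1) {
  e_a <- as.matrix(e_a)
  e_b <- as.matrix(e_b)
  d <- sqrt(colSums((e_a - e_b)^2))
  per <- ifelse(label == 0, d^2, pmax(0, margin - d)^2)
  mean(per)
}

#' Cross-embedding loss (binary cross-entropy on the head logit)
#'
#' BCE between \code{sigmoid(logit)} and the label, symmetrized by averaging
#' the two pair orderings (the head sees the signed difference, so the two
#' orderings give different logits).
#'
#' @param logit_ab head logit for ordering (a, b).
#' @param label 0/1 per pair.
#' @param logit_ba head logit for ordering (b, a); when omitted the loss is
#'   the plain one-ordering BCE.
#' @return mean loss.
#' @export
crossEmbeddingLoss <- function(logit_ab, label, logit_ba = NULL) {
  # numerically stable BCE with logits: max(z,0) - z*y + log(1+exp(-|z|))
  bce <- function(z, y) pmax(z, 0) - z * y + log1p(exp(-abs(z)))
  l <- bce(logit_ab, label)
  if (!is.null(logit_ba)) l <- (l + bce(logit_ba, label)) / 2
  mean(l)
}

#' Total training loss
#'
#' @param L1 contrastive loss.
#' @param L2 cross-embedding loss.
#' @param weights loss weights, default \code{c(2, 1)}.
#' @return \code{weights[1]*L1 + weights[2]*L2}.
#' @export
totalLoss <- function(L1, L2, weights = c(2, 1)) {
  weights[1] * L1 + weights[2] * L2
}

#' Early-stopping decision
#'
#' Halt iff the epoch index is at least \code{min_epochs} and the current
#' validation contrastive loss exceeds \code{(1 + stop_rise)} times the
#' baseline (the best validation L1 so far, or the previous epoch's when
#' \code{stop_baseline = "previous"}).
#'
#' @param val_l1 numeric vector of per-epoch validation contrastive losses,
#'   up to and including the current epoch.
#' @param cfg a \code{\link{trainConfig}}.
#' @return \code{"halt"} or \code{"continue"}.
#' @export
earlyStop <- function(val_l1, cfg = trainConfig()) {
  stopifnot(length(val_l1) >= 1)
  epoch <- length(val_l1)
  if (epoch < cfg$min_epochs) return("continue")
  baseline <- if (cfg$stop_baseline == "best") {
    min(val_l1)
  } else {
    val_l1[epoch - 1L]
  }
  if (val_l1[epoch] > (1 + cfg$stop_rise) * baseline) "halt" else "continue"
}

# Loss value and embedding gradients for one batch.
# e_a, e_b: (dim x n); returns grads wrt e_a, e_b and head weights.
batchLossGrad <- function(weights, e_a, e_b, label, tcfg) {
  n <- ncol(e_a)
  diff <- e_a - e_b
  d <- sqrt(colSums(diff^2))
  m <- tcfg$margin
  l1_per <- ifelse(label == 0, d^2, pmax(0, m - d)^2)
  L1 <- mean(l1_per)
  # dL1/ddiff per pair, already divided by n
  coef <- ifelse(label == 0, 2,
                 ifelse(d < m & d > 0, -2 * (m - d) / pmax(d, 1e-12), 0))
  ddiff_l1 <- sweep(diff, 2L, coef / n, "*")

  z_ab <- as.numeric(weights$Whead %*% diff + weights$bhead[1, 1])
  z_ba <- as.numeric(-weights$Whead %*% diff + weights$bhead[1, 1])
  bce <- function(z, y) pmax(z, 0) - z * y + log1p(exp(-abs(z)))
  L2 <- mean((bce(z_ab, label) + bce(z_ba, label)) / 2)
  sig <- function(z) 1 / (1 + exp(-z))
  dz_ab <- (sig(z_ab) - label) / (2 * n)
  dz_ba <- (sig(z_ba) - label) / (2 * n)

  wl <- tcfg$loss_weights
  ddiff <- wl[1] * ddiff_l1 +
    wl[2] * t(weights$Whead)[, 1] %o% (dz_ab - dz_ba)
  gWhead <- wl[2] * matrix(diff %*% (dz_ab - dz_ba), nrow = 1)
  gbhead <- matrix(wl[2] * sum(dz_ab + dz_ba))
  list(L1 = L1, L2 = L2, total = totalLoss(L1, L2, wl),
       de_a = ddiff, de_b = -ddiff, gWhead = gWhead, gbhead = gbhead)
}

# Forward-only losses over a pair set (no gradients).
evalLosses <- function(model, pairs, tcfg, batch = 256L) {
  pairs <- trimPairs(pairs)
  w <- pairs@windows
  cfg <- model@config
  e <- embedWindows(model, w, batch = batch)
  e_a <- e[, pairs@a, drop = FALSE]
  e_b <- e[, pairs@b, drop = FALSE]
  diff <- e_a - e_b
  L1 <- contrastiveLoss(e_a, e_b, pairs@label, tcfg$margin)
  z_ab <- as.numeric(model@weights$Whead %*% diff + model@weights$bhead[1, 1])
  z_ba <- as.numeric(-model@weights$Whead %*% diff +
                       model@weights$bhead[1, 1])
  L2 <- crossEmbeddingLoss(z_ab, pairs@label, z_ba)
  list(L1 = L1, L2 = L2)
}

#' Train the twin network with contrastive + cross-embedding losses
#'
#' Mini-batch SGD over shuffled training pairs (seeded shuffle), validation
#' losses computed each epoch without gradient updates, early stopping per
#' \code{\link{earlyStop}}, and restoration of the best-validation-epoch
#' weights on return.
#'
#' @param pairs a \code{\link{WindowPairs}} with train and val splits.
#' @param mcfg a \code{\link{modelConfig}}; \code{NULL} derives one from the
#'   window geometry.
#' @param tcfg a \code{\link{trainConfig}}.
#' @param init optional \code{\link{SiameseModel}} to start from.
#' @param verbose print per-epoch losses.
#' @return list with \code{model} (best-epoch \code{\link{SiameseModel}})
#'   and \code{history} (data.frame: epoch, train_l1, train_l2, val_l1,
#'   val_l2).
#' @export
trainSiamese <- function(pairs, mcfg = NULL, tcfg = trainConfig(),
                         init = NULL, verbose = FALSE) {
  stopifnot(is(pairs, "WindowPairs"))
  if (!pairs@windows@cleaned) stop("windows must be cleaned before training")
  if (is.null(mcfg)) mcfg <- modelConfig(window_bins = pairs@windows@windowBins)
  train <- pairsForSplit(pairs, "train")
  val <- pairsForSplit(pairs, "val")
  if (length(train) == 0) stop("empty split: train")
  if (length(val) == 0) stop("empty split: val")
  if (length(unique(train@label)) < 2) {
    stop("training pairs contain a single label; need both replicate and",
         " condition pairs")
  }
  model <- if (is.null(init)) initSiameseModel(mcfg, seed = tcfg$seed) else init
  weights <- model@weights
  velocity <- lapply(weights, function(w) w * 0)
  adam_m <- adam_v <- lapply(weights, function(w) w * 0)
  adam_t <- 0L
  w_all <- pairs@windows
  history <- data.frame(epoch = integer(0), train_l1 = numeric(0),
                        train_l2 = numeric(0), val_l1 = numeric(0),
                        val_l2 = numeric(0))
  best_l1 <- Inf
  best_weights <- weights
  n_train <- length(train)
  rng_seeds <- withSeed(tcfg$seed,
                        sample.int(2147483647L, tcfg$max_epochs))
  for (epoch in seq_len(tcfg$max_epochs)) {
    ord <- withSeed(rng_seeds[epoch], sample.int(n_train))
    ep_l1 <- ep_l2 <- 0
    nb <- 0L
    for (at in seq.int(1L, n_train, by = tcfg$batch_size)) {
      bidx <- ord[at:min(n_train, at + tcfg$batch_size - 1L)]
      xa <- windowBatch(w_all, train@a[bidx], mcfg)
      xb <- windowBatch(w_all, train@b[bidx], mcfg)
      fa <- siameseForward(weights, mcfg, xa)
      fb <- siameseForward(weights, mcfg, xb)
      bl <- batchLossGrad(weights, fa$e, fb$e, train@label[bidx], tcfg)
      ga <- siameseBackward(weights, mcfg, fa, bl$de_a)
      gb <- siameseBackward(weights, mcfg, fb, bl$de_b)
      grads <- Map(`+`, ga, gb)
      grads$Whead <- bl$gWhead
      grads$bhead <- bl$gbhead
      if (tcfg$optimizer == "adam") {
        adam_t <- adam_t + 1L
        b1 <- 0.9
        b2 <- 0.999
        for (nm in names(weights)) {
          adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * grads[[nm]]
          adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * grads[[nm]]^2
          mhat <- adam_m[[nm]] / (1 - b1^adam_t)
          vhat <- adam_v[[nm]] / (1 - b2^adam_t)
          weights[[nm]] <- weights[[nm]] -
            tcfg$lr * mhat / (sqrt(vhat) + 1e-8)
        }
      } else {
        for (nm in names(weights)) {
          velocity[[nm]] <- tcfg$momentum * velocity[[nm]] -
            tcfg$lr * grads[[nm]]
          weights[[nm]] <- weights[[nm]] + velocity[[nm]]
        }
      }
      ep_l1 <- ep_l1 + bl$L1
      ep_l2 <- ep_l2 + bl$L2
      nb <- nb + 1L
    }
    model@weights <- weights
    vl <- evalLosses(model, val, tcfg)
    history <- rbind(history,
                     data.frame(epoch = epoch, train_l1 = ep_l1 / nb,
                                train_l2 = ep_l2 / nb, val_l1 = vl$L1,
                                val_l2 = vl$L2))
    if (verbose) {
      message(sprintf("epoch %d: train L1 %.4f L2 %.4f | val L1 %.4f L2 %.4f",
                      epoch, ep_l1 / nb, ep_l2 / nb, vl$L1, vl$L2))
    }
    if (vl$L1 < best_l1) {
      best_l1 <- vl$L1
      best_weights <- weights
    }
    if (earlyStop(history$val_l1, tcfg) == "halt") break
  }
  model@weights <- best_weights
  validObject(model)
  list(model = model, history = history)
}
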
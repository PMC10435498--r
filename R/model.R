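#' @useDynLib SiameseHiC, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Architecture configuration of the twin encoder
#'
#' A LeNet-style stack with GeLU activations (ReLU units die on sparse
#' contact maps): two convolutional stages (6 then 16 filters of 5x5, each
#' followed by 2x2 max pooling), fully connected layers 120 -> 84 ->
#' \code{embed_dim}, and a linear cross-embedding head on the signed
#' embedding difference. The diagonal band \code{|i - j| < mask_bins} of
#' every input window is zeroed (3 pixels, i.e. 3 x R = 30 kb at 10 kb
#' resolution, by default).
#'
#' @param window_bins input window side in bins (default 256).
#' @param mask_bins diagonal mask half-width (default 3).
#' @param embed_dim embedding dimension (default 8).
#' @param conv_filters filters per convolutional stage.
#' @param kernel convolution kernel side.
#' @param pool pooling window/stride.
#' @param fc sizes of the two hidden fully connected layers.
#' @return a config list with derived layer shapes.
#' @export
modelConfig <- function(window_bins = 256L, mask_bins = 3L, embed_dim = 8L,
                        conv_filters = c(6L, 16L), kernel = 5L, pool = 2L,
                        fc = c(120L, 84L)) {
  window_bins <- as.integer(window_bins)
  o1 <- window_bins - kernel + 1L
  p1 <- o1 %/% pool
  o2 <- p1 - kernel + 1L
  p2 <- o2 %/% pool
  if (o1 < 1L || o2 < 1L || p2 < 1L) {
    stop("window_bins = ", window_bins, " too small for the conv stack")
  }
  list(window_bins = window_bins, mask_bins = as.integer(mask_bins),
       embed_dim = as.integer(embed_dim),
       conv_filters = as.integer(conv_filters), kernel = as.integer(kernel),
       pool = as.integer(pool), fc = as.integer(fc),
       shapes = list(conv1 = o1, pool1 = p1, conv2 = o2, pool2 = p2,
                     flat = as.integer(conv_filters[2] * p2 * p2)))
}

#' Initialize a Siamese model
#'
#' Fan-in uniform initialization (each tensor ~ U(-1/sqrt(fan_in),
#' 1/sqrt(fan_in))) with a recorded seed; both twins share these weights by
#' construction.
#'
#' @param cfg a \code{\link{modelConfig}}.
#' @param seed integer seed for the initialization.
#' @return a \code{\link{SiameseModel}}.
#' @export
initSiameseModel <- function(cfg, seed = 1L) {
  k2 <- cfg$kernel^2
  sh <- cfg$shapes
  dims <- list(
    W1 = c(cfg$conv_filters[1], k2),
    b1 = c(cfg$conv_filters[1], 1L),
    W2 = c(cfg$conv_filters[2], k2 * cfg$conv_filters[1]),
    b2 = c(cfg$conv_filters[2], 1L),
    W3 = c(cfg$fc[1], sh$flat),
    b3 = c(cfg$fc[1], 1L),
    W4 = c(cfg$fc[2], cfg$fc[1]),
    b4 = c(cfg$fc[2], 1L),
    W5 = c(cfg$embed_dim, cfg$fc[2]),
    b5 = c(cfg$embed_dim, 1L),
    Whead = c(1L, cfg$embed_dim),
    bhead = c(1L, 1L)
  )
  fanin <- list(W1 = k2, b1 = k2, W2 = k2 * cfg$conv_filters[1],
                b2 = k2 * cfg$conv_filters[1], W3 = sh$flat, b3 = sh$flat,
                W4 = cfg$fc[1], b4 = cfg$fc[1], W5 = cfg$fc[2],
                b5 = cfg$fc[2], Whead = cfg$embed_dim, bhead = cfg$embed_dim)
  weights <- withSeed(seed, {
    out <- list()
    for (nm in names(dims)) {
      bound <- 1 / sqrt(fanin[[nm]])
      out[[nm]] <- matrix(stats::runif(prod(dims[[nm]]), -bound, bound),
                          dims[[nm]][1], dims[[nm]][2])
    }
    out
  })
  new("SiameseModel", config = cfg, weights = weights)
}

#' @rdname SiameseModel-class
#' @export
setMethod("modelWeights", "SiameseModel", function(x) x@weights)

#' @rdname SiameseModel-class
#' @export
setMethod("modelConfigOf", "SiameseModel", function(x) x@config)

setMethod("show", "SiameseModel", function(object) {
  cfg <- object@config
  sh <- cfg$shapes
  npar <- sum(vapply(object@weights, length, numeric(1)))
  cat("SiameseModel: ", cfg$window_bins, "x", cfg$window_bins,
      " -> conv", cfg$conv_filters[1], " (", sh$pool1, ") -> conv",
      cfg$conv_filters[2], " (", sh$pool2, ") -> ",
      paste(cfg$fc, collapse = " -> "), " -> ", cfg$embed_dim,
      " [GeLU, mask ", cfg$mask_bins, "], ", npar, " parameters\n", sep = "")
})

# exact GeLU x * Phi(x); fast C++ kernels for arrays, R fallback for scalars
gelu <- function(x) {
  if (is.double(x)) .geluForward(x) else x * stats::pnorm(x)
}
geluGrad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

# Forward through the convolutional stages.
# x: array (s, s, 1, n). Returns pooled stage-2 maps and caches.
convStageForward <- function(weights, cfg, x) {
  z1 <- .convForward(x, weights$W1, weights$b1)
  a1 <- gelu(z1)
  pf1 <- .poolForward(a1, cfg$pool)
  z2 <- .convForward(pf1$y, weights$W2, weights$b2)
  a2 <- gelu(z2)
  pf2 <- .poolForward(a2, cfg$pool)
  list(out = pf2$y, x = x, z1 = z1, p1 = pf1, z2 = z2, p2 = pf2)
}

# Full encoder forward. Returns embeddings (embed_dim x n) and caches.
siameseForward <- function(weights, cfg, x) {
  cv <- convStageForward(weights, cfg, x)
  n <- dim(x)[4]
  flat <- matrix(cv$out, cfg$shapes$flat, n)
  z3 <- weights$W3 %*% flat + weights$b3[, 1]
  a3 <- gelu(z3)
  z4 <- weights$W4 %*% a3 + weights$b4[, 1]
  a4 <- gelu(z4)
  e <- weights$W5 %*% a4 + weights$b5[, 1]
  list(e = e, conv = cv, flat = flat, z3 = z3, a3 = a3, z4 = z4, a4 = a4)
}

# Backward through the encoder for upstream gradient de (embed_dim x n).
# Returns gradient list matching the weight names (head excluded).
siameseBackward <- function(weights, cfg, cache, de) {
  g <- list()
  g$W5 <- de %*% t(cache$a4)
  g$b5 <- matrix(rowSums(de))
  dz4 <- (t(weights$W5) %*% de) * geluGrad(cache$z4)
  g$W4 <- dz4 %*% t(cache$a3)
  g$b4 <- matrix(rowSums(dz4))
  dz3 <- (t(weights$W4) %*% dz4) * geluGrad(cache$z3)
  g$W3 <- dz3 %*% t(cache$flat)
  g$b3 <- matrix(rowSums(dz3))
  dflat <- t(weights$W3) %*% dz3
  cv <- cache$conv
  dp2 <- array(dflat, dim(cv$out))
  da2 <- .poolBackward(dp2, cv$p2$argmax, dim(cv$z2))
  dz2 <- .geluBackward(cv$z2, da2)
  cb2 <- .convBackward(cv$p1$y, weights$W2, dz2)
  g$W2 <- cb2$dw
  g$b2 <- matrix(cb2$db)
  da1 <- .poolBackward(cb2$dx, cv$p1$argmax, dim(cv$z1))
  dz1 <- .geluBackward(cv$z1, da1)
  cb1 <- .convBackward(cv$x, weights$W1, dz1, want_dx = FALSE)
  g$W1 <- cb1$dw
  g$b1 <- matrix(cb1$db)
  g
}

# Stack a set of windows into the masked network input array (s, s, 1, n).
windowBatch <- function(w, idx, cfg) {
  s <- cfg$window_bins
  x <- array(w@data[, , idx, drop = FALSE], c(s, s, 1L, length(idx)))
  if (cfg$mask_bins > 0) {
    mk <- diagMask(s, cfg$mask_bins)
    for (k in seq_along(idx)) x[, , 1L, k] <- x[, , 1L, k] * mk
  }
  x
}

#' Embed windows with the twin encoder
#'
#' Applies the diagonal mask and the deterministic forward pass. Identical
#' weights and inputs give identical embeddings — both twins are one set of
#' weights.
#'
#' @param model a \code{\link{SiameseModel}}.
#' @param w a cleaned \code{\link{HicWindows}} (or a single matrix).
#' @param batch forward batch size.
#' @return matrix (embed_dim x n) of embeddings.
#' @export
embedWindows <- function(model, w, batch = 256L) {
  cfg <- model@config
  if (is.matrix(w)) {
    if (nrow(w) != cfg$window_bins) {
      stop("window side ", nrow(w), " != expected ", cfg$window_bins)
    }
    x <- array(w, c(nrow(w), ncol(w), 1L, 1L))
    w <- HicWindows(array(w, c(nrow(w), ncol(w), 1L)),
                    DataFrame(chrom = "?", start_bp = 0,
                              condition = "?", replicate = "?"),
                    1, 1, cleaned = TRUE)
  }
  stopifnot(is(w, "HicWindows"))
  if (w@windowBins != cfg$window_bins) {
    stop("window side ", w@windowBins, " != expected ", cfg$window_bins)
  }
  n <- length(w)
  e <- matrix(0, cfg$embed_dim, n)
  for (at in seq.int(1L, n, by = batch)) {
    idx <- at:min(n, at + batch - 1L)
    x <- windowBatch(w, idx, cfg)
    e[, idx] <- siameseForward(model@weights, cfg, x)$e
  }
  e
}

#' Forward a window pair: embeddings plus cross-embedding logit
#'
#' The head is a single linear map on the signed embedding difference
#' \code{e_a - e_b}: swapping the pair members negates the difference fed to
#' the head, and for identical windows the logit equals the head bias.
#'
#' @param model a \code{\link{SiameseModel}}.
#' @param a,b cleaned window matrices (side \code{window_bins}).
#' @return list with \code{e_a}, \code{e_b}, \code{logit}.
#' @export
pairForward <- function(model, a, b) {
  e_a <- embedWindows(model, a)
  e_b <- embedWindows(model, b)
  logit <- headLogit(model@weights, e_a - e_b)
  list(e_a = e_a[, 1], e_b = e_b[, 1], logit = logit[1])
}

headLogit <- function(weights, diff) {
  as.numeric(weights$Whead %*% diff + weights$bhead[1, 1])
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the full \code{\link{modelConfig}} alongside the
#' weights and round-trips bit-exactly.
#'
#' @param model a \code{\link{SiameseModel}}.
#' @param path checkpoint file path.
#' @return \code{path} (save) or the restored \code{\link{SiameseModel}}
#'   (load).
#' @export
saveCheckpoint <- function(model, path) {
  stopifnot(is(model, "SiameseModel"))
  saveRDS(list(config = model@config, weights = model@weights,
               config_json = jsonlite::toJSON(model@config[
                 setdiff(names(model@config), "shapes")], auto_unbox = TRUE)),
          path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  obj <- readRDS(path)
  new("SiameseModel", config = obj$config, weights = obj$weights)
}
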
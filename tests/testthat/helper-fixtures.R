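# Shared fixtures: tiny contact matrices, windows and models built in code.

# symmetric Poisson contact matrix with optional masked bins
randomContactMatrix <- function(n = 50, chrom = "chr1", resolution = 1e4,
                                lambda = 5, seed = 1, masked = integer(0)) {
  set.seed(seed)
  m <- matrix(0, n, n)
  up <- upper.tri(m, diag = TRUE)
  m[up] <- stats::rpois(sum(up), lambda)
  m <- m + t(m) - diag(diag(m))
  m[masked, ] <- NA
  m[, masked] <- NA
  ContactMatrix(m, chrom = chrom, resolution = resolution,
                normalization = "RAW")
}

# HicWindows wrapper around a list of matrices
windowsFromMatrices <- function(mats, chrom = "chr1", start_bp = NULL,
                                condition = "A", replicate = "R1",
                                resolution = 1e4, stride_bp = 4e4,
                                cleaned = FALSE) {
  wb <- nrow(mats[[1]])
  data <- array(0, c(wb, wb, length(mats)))
  for (k in seq_along(mats)) data[, , k] <- mats[[k]]
  n <- length(mats)
  info <- S4Vectors::DataFrame(
    chrom = rep(chrom, length.out = n),
    start_bp = if (is.null(start_bp)) (seq_len(n) - 1) * stride_bp else
      rep(start_bp, length.out = n),
    condition = rep(condition, length.out = n),
    replicate = rep(replicate, length.out = n))
  HicWindows(data, info, resolution, stride_bp, cleaned = cleaned)
}

# small planted synthetic experiment: short chromosomes, quick to window
tinyExperiment <- function(seed = 5, n_bins = 220L, planted = TRUE,
                           depth = 3e5) {
  cfg <- syntheticConfig(
    chroms = c(chr1 = n_bins, chr18 = n_bins, chr2 = n_bins),
    depth = depth,
    diff_features = if (planted) NULL else list(),
    seed = seed)
  generateExperiment(cfg)
}

# tiny model: 16-bin windows keep conv shapes valid and forward passes cheap
tinyModel <- function(seed = 3, window_bins = 16L, embed_dim = 3L,
                      mask_bins = 3L) {
  initSiameseModel(modelConfig(window_bins = window_bins,
                               embed_dim = embed_dim,
                               mask_bins = mask_bins), seed = seed)
}

# random cleaned windows for forward-pass tests
randomCleanWindows <- function(n = 4, wb = 16L, seed = 9) {
  set.seed(seed)
  mats <- lapply(seq_len(n), function(i) {
    m <- matrix(stats::runif(wb * wb), wb, wb)
    m <- (m + t(m)) / 2
    m / max(m)
  })
  windowsFromMatrices(mats, cleaned = TRUE)
}
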
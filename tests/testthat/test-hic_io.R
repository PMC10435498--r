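test_that("dense-text container round-trips contact matrices", {
  m <- matrix(c(4, 2, 0, 2, 4, 1, 0, 1, 4), 3, 3)
  cm <- ContactMatrix(m, chrom = "chr1", resolution = 1e4)
  expect_identical(contactValues(cm), m)
  expect_identical(normMethod(cm), "RAW")

  path <- withr::local_tempfile(fileext = ".tsv")
  writeContactMatrix(cm, path)
  back <- readContactMatrix(path)
  expect_equal(contactValues(back), m)
  expect_identical(chromName(back), "chr1")
  expect_identical(binResolution(back), 1e4)

  # round trip preserves missing bins
  cm2 <- randomContactMatrix(n = 20, masked = 3L)
  writeContactMatrix(cm2, path)
  back2 <- readContactMatrix(path)
  expect_equal(contactValues(back2), contactValues(cm2))

  # synthetic-experiment matrix round trip at R = 10 kb
  exp <- tinyExperiment(seed = 2, n_bins = 60L)
  cm3 <- exp$matrices$A$R1$chr1
  writeContactMatrix(cm3, path)
  expect_equal(contactValues(readContactMatrix(path, chrom = "chr1",
                                               resolution = 1e4)),
               contactValues(cm3))
})

test_that("reader rejects bad inputs with informative errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(matrix(c(1, 5, 2, 1), 2, 2), path,
              row.names = FALSE, col.names = FALSE)
  expect_error(readContactMatrix(path, chrom = "chr1", resolution = 1e4),
               "matrix not symmetric")

  cm <- randomContactMatrix(n = 5)
  writeContactMatrix(cm, path)
  expect_error(readContactMatrix(path, chrom = "chrX"),
               "chromosome not found")
  expect_error(readContactMatrix(path, resolution = 5000),
               "resolution unavailable")
  expect_error(readContactMatrix("/nonexistent/file.tsv", chrom = "chr1",
                                 resolution = 1e4),
               "file not found")
})

test_that("ICE balancing equalizes non-masked row sums", {
  # two-bin symmetric case converges immediately
  cm <- ContactMatrix(matrix(c(0, 6, 6, 0), 2, 2), "chr1", 1e4)
  bal <- iceBalance(cm)
  expect_identical(normMethod(bal), "ICE")
  s <- rowSums(contactValues(bal))
  expect_equal(s[1], s[2])

  # random Poisson 50x50 at tol 1e-5: assert the convergence criterion
  cm <- randomContactMatrix(n = 50, seed = 7)
  bal <- iceBalance(cm, tol = 1e-5)
  s <- rowSums(contactValues(bal))
  expect_lt(max(abs(s / mean(s) - 1)), 1e-5)

  # all-zero row is masked, remaining rows balanced
  v <- contactValues(randomContactMatrix(n = 10, seed = 3))
  v[4, ] <- 0
  v[, 4] <- 0
  bal <- iceBalance(ContactMatrix(v, "chr1", 1e4), tol = 1e-6)
  bv <- contactValues(bal)
  expect_true(all(is.na(bv[4, ])))
  s <- rowSums(bv[-4, -4])
  expect_lt(max(abs(s / mean(s) - 1)), 1e-6)

  expect_error(iceBalance(bal), "RAW")
})

test_that("ICE row sums stay constant on random symmetric inputs", {
  for (seed in 1:5) {
    bal <- iceBalance(randomContactMatrix(n = 30, seed = seed), tol = 1e-6)
    s <- rowSums(contactValues(bal), na.rm = TRUE)
    s <- s[s > 0]
    expect_lt(max(abs(s / mean(s) - 1)), 1e-6)
  }
})

test_that("window extraction follows the stride/anchor arithmetic", {
  cm <- randomContactMatrix(n = 1000, lambda = 2, seed = 11)
  w <- extractWindows(cm, window_bins = 256L, stride_bp = 160e3)
  # enumeration oracle: floor((1000 - 256)/16) + 1 anchors
  starts <- seq(0L, 1000L - 256L, by = 16L)
  expect_identical(length(w), length(starts))
  expect_identical(length(w), 47L)
  expect_equal(windowInfo(w)$start_bp, starts * 1e4)
  # windows are the diagonal submatrices
  k <- 13
  idx <- starts[k] + seq_len(256)
  expect_equal(windowData(w)[, , k], contactValues(cm)[idx, idx])

  # window_bins == n_bins: exactly one window
  cm2 <- randomContactMatrix(n = 40)
  w2 <- extractWindows(cm2, window_bins = 40L, stride_bp = 2e4)
  expect_identical(length(w2), 1L)
  expect_equal(windowData(w2)[, , 1], contactValues(cm2))

  # window larger than chromosome: empty + warning
  expect_warning(w3 <- extractWindows(cm2, window_bins = 64L),
                 "larger than chromosome")
  expect_identical(length(w3), 0L)

  # S = window_bins x R: auto stride scales with resolution
  cm3 <- randomContactMatrix(n = 600, resolution = 25e3)
  w4 <- extractWindows(cm3, window_bins = 256L)
  expect_equal(windowBins(w4) * binResolution(cm3), 6.4e6)
  expect_equal(w4@strideBp, 16 * 25e3)

  expect_error(extractWindows(cm3, 256L, stride_bp = 12345),
               "multiple of the resolution")
})

test_that("window cleaning zeroes NA and max-normalizes", {
  m <- matrix(c(8, 2, NA, 2, 4, 1, NA, 1, 0), 3, 3)
  w <- windowsFromMatrices(list(m))
  cw <- cleanWindows(w)
  got <- windowData(cw)[, , 1]
  want <- m
  want[is.na(want)] <- 0
  want <- want / 8
  expect_equal(got, want)
  expect_equal(max(got), 1)
  expect_true(isCleaned(cw))

  # all-zero window unchanged (no division by zero)
  w0 <- cleanWindows(windowsFromMatrices(list(matrix(0, 3, 3))))
  expect_equal(windowData(w0)[, , 1], matrix(0, 3, 3))

  # idempotence on an already-clean window
  expect_equal(windowData(cleanWindows(cw)), windowData(cw))

  # property: max is exactly 1 whenever any entry is positive
  set.seed(4)
  for (i in 1:10) {
    m <- matrix(runif(25) * sample(c(0.1, 10, 1000), 1), 5, 5)
    m[sample(25, 3)] <- NA
    cm <- cleanWindows(windowsFromMatrices(list(m)))
    expect_equal(max(windowData(cm)), 1)
  }
})

test_that("window filtering drops empty and NA-dominated windows", {
  wb <- 256L
  dense <- matrix(1, wb, wb)

  # 30 fully empty rows > 10% of 256 (= 25.6): dropped
  m_empty <- dense
  m_empty[1:30, ] <- 0
  m_empty[, 1:30] <- 0
  # 25 empty rows and few NAs: kept
  m_ok <- dense
  m_ok[1:25, ] <- 0
  m_ok[, 1:25] <- 0
  m_ok[cbind(40:49, 40:49)] <- NA
  # NA count exceeding nonzero count: dropped
  m_na <- dense
  m_na[upper.tri(m_na)] <- NA
  m_na[lower.tri(m_na)] <- 0
  diag(m_na)[1:100] <- 0

  w <- windowsFromMatrices(list(m_empty, m_ok, dense, m_na))
  kept <- filterWindows(w)
  expect_identical(length(kept), 2L)
  expect_equal(windowInfo(kept)$start_bp, windowInfo(w)$start_bp[c(2, 3)])

  # idempotence
  expect_identical(length(filterWindows(kept)), length(kept))
})

test_that("pairing enumerates replicate and condition combinations", {
  wb <- 16L
  set.seed(1)
  mk <- function() matrix(runif(wb * wb), wb, wb) / 1.0
  parts <- list()
  for (cond in c("A", "B")) for (r in c("R1", "R2")) {
    parts[[length(parts) + 1L]] <- windowsFromMatrices(
      lapply(1:3, function(i) mk()), chrom = c("chr1", "chr18", "chr2"),
      start_bp = 0, condition = cond, replicate = r, cleaned = TRUE)
  }
  w <- do.call(c, parts)
  pairs <- makePairs(w)
  # per location: label-0 = c*r*(r-1)/2 = 2, label-1 = (c(c-1)/2)*r^2 = 4
  loc <- pairLocations(pairs)
  counts <- table(loc$chrom, loc$label)
  expect_true(all(counts[, "0"] == 2L))
  expect_true(all(counts[, "1"] == 4L))
  # split scheme: chr2 test, chr18 val, rest train
  expect_identical(unique(loc$split[loc$chrom == "chr2"]), "test")
  expect_identical(unique(loc$split[loc$chrom == "chr18"]), "val")
  expect_identical(unique(loc$split[loc$chrom == "chr1"]), "train")
  # members co-located and labels match condition groups
  info <- windowInfo(pairs@windows)
  same_cond <- info$condition[pairs@a] == info$condition[pairs@b]
  expect_identical(pairLabels(pairs) == 0L, unname(same_cond))
})

test_that("pair counts match the enumeration oracle for c x r designs", {
  wb <- 16L
  set.seed(2)
  for (cr in list(c(2, 2), c(2, 3), c(3, 2))) {
    conds <- LETTERS[seq_len(cr[1])]
    reps <- paste0("R", seq_len(cr[2]))
    parts <- list()
    for (cond in conds) for (r in reps) {
      parts[[length(parts) + 1L]] <- windowsFromMatrices(
        list(matrix(runif(wb * wb), wb, wb)), chrom = "chr5", start_bp = 0,
        condition = cond, replicate = r, cleaned = TRUE)
    }
    pairs <- makePairs(do.call(c, parts))
    cc <- cr[1]; rr <- cr[2]
    expect_identical(sum(pairLabels(pairs) == 0L),
                     as.integer(cc * rr * (rr - 1) / 2))
    expect_identical(sum(pairLabels(pairs) == 1L),
                     as.integer(cc * (cc - 1) / 2 * rr^2))
  }
})

test_that("pairing handles missing locations and degenerate designs", {
  wb <- 16L
  set.seed(3)
  mkw <- function(cond, r, starts) windowsFromMatrices(
    lapply(starts, function(s) matrix(runif(wb * wb), wb, wb)),
    chrom = "chr1", start_bp = starts, condition = cond, replicate = r,
    cleaned = TRUE)
  # location 4e4 absent from B.R2: omitted entirely
  w <- c(mkw("A", "R1", c(0, 4e4)), mkw("A", "R2", c(0, 4e4)),
         mkw("B", "R1", c(0, 4e4)), mkw("B", "R2", 0))
  expect_message(pairs <- makePairs(w), "omitted from pairing")
  expect_true(all(windowInfo(pairs@windows)$start_bp[pairs@a] == 0))

  # one condition only: standard mode refuses
  expect_error(makePairs(c(mkw("A", "R1", 0), mkw("A", "R2", 0))),
               "need >=2 condition groups")
})

test_that("sequencing-depth pairing modes regroup replicates", {
  wb <- 16L
  set.seed(4)
  parts <- list()
  for (r in c("hi1", "hi2", "lo1", "lo2")) {
    parts[[length(parts) + 1L]] <- windowsFromMatrices(
      list(matrix(runif(wb * wb), wb, wb)), chrom = "chr3", start_bp = 0,
      condition = "DP", replicate = r, cleaned = TRUE)
  }
  w <- do.call(c, parts)
  depth <- c(hi1 = "high", hi2 = "high", lo1 = "low", lo2 = "low")

  # artefact-learning schema: high vs low as pseudo-conditions
  pa <- makePairs(w, mode = "depth_artefact", depth = depth)
  info <- windowInfo(pa@windows)
  key <- function(i) info$replicate[i]
  lab0 <- cbind(key(pa@a[pa@label == 0L]), key(pa@b[pa@label == 0L]))
  expect_true(all(depth[lab0[, 1]] == depth[lab0[, 2]]))
  expect_identical(sum(pa@label == 0L), 2L)
  expect_identical(sum(pa@label == 1L), 4L)

  # robustness schema: each group mixes one high and one low replicate
  pr <- makePairs(w, mode = "depth_robust", depth = depth)
  lab0 <- cbind(key(pr@a[pr@label == 0L]), key(pr@b[pr@label == 0L]))
  expect_true(all(depth[lab0[, 1]] != depth[lab0[, 2]]))
  expect_identical(sum(pr@label == 0L), 2L)
  expect_identical(sum(pr@label == 1L), 4L)
})
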
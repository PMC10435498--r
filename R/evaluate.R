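#' Euclidean embedding distances for a pair set
#'
#' Embeds every distinct window once (masking and forward pass per the model
#' config) and returns the per-pair Euclidean embedding distance — the learnt
#' dissimilarity metric.
#'
#' @param model a trained \code{\link{SiameseModel}}.
#' @param pairs a \code{\link{WindowPairs}}.
#' @param split optional split restriction (\code{"train"}, \code{"val"},
#'   \code{"test"}).
#' @return data.frame: chrom, start_bp, label, split, distance.
#' @export
embeddingDistances <- function(model, pairs, split = NULL) {
  stopifnot(is(pairs, "WindowPairs"))
  if (!is.null(split)) pairs <- pairsForSplit(pairs, split)
  pairs <- trimPairs(pairs)
  e <- embedWindows(model, pairs@windows)
  diff <- e[, pairs@a, drop = FALSE] - e[, pairs@b, drop = FALSE]
  d <- sqrt(colSums(diff^2))
  cbind(pairLocations(pairs), distance = d)
}

#' Per-locus distance track with bootstrap confidence intervals
#'
#' Pools label-0 distances as the replicate group and label-1 distances as
#' the condition group at each genomic anchor, and reports per-locus group
#' means with percentile-bootstrap 95\% confidence intervals. Loci where one
#' group is empty are kept with \code{NA} for that group (and a message).
#'
#' @param distances data.frame from \code{\link{embeddingDistances}}.
#' @param n_boot bootstrap resamples (default 1000).
#' @param conf confidence level.
#' @param seed bootstrap seed.
#' @return data.frame: chrom, start_bp, group, n, mean, lo, hi — ordered by
#'   start_bp within chromosome.
#' @export
buildDistanceTrack <- function(distances, n_boot = 1000L, conf = 0.95,
                               seed = 1L) {
  stopifnot(all(c("chrom", "start_bp", "label", "distance") %in%
                  colnames(distances)))
  alpha <- (1 - conf) / 2
  key <- paste(distances$chrom, distances$start_bp)
  loci <- unique(distances[order(distances$chrom, distances$start_bp),
                           c("chrom", "start_bp")])
  out <- list()
  empty <- 0L
  boot_seeds <- withSeed(seed, sample.int(2147483647L, nrow(loci) * 2L))
  for (i in seq_len(nrow(loci))) {
    sel <- distances[key == paste(loci$chrom[i], loci$start_bp[i]), ]
    for (g in c("replicate", "condition")) {
      v <- sel$distance[sel$label == (if (g == "condition") 1L else 0L)]
      if (length(v) == 0) {
        empty <- empty + 1L
        out[[length(out) + 1L]] <- data.frame(
          chrom = loci$chrom[i], start_bp = loci$start_bp[i], group = g,
          n = 0L, mean = NA_real_, lo = NA_real_, hi = NA_real_)
        next
      }
      bs <- withSeed(boot_seeds[2L * i - (g == "replicate")], {
        means <- vapply(seq_len(n_boot), function(b) {
          mean(v[sample.int(length(v), replace = TRUE)])
        }, numeric(1))
        stats::quantile(means, c(alpha, 1 - alpha), names = FALSE)
      })
      out[[length(out) + 1L]] <- data.frame(
        chrom = loci$chrom[i], start_bp = loci$start_bp[i], group = g,
        n = length(v), mean = mean(v), lo = bs[1], hi = bs[2])
    }
  }
  if (empty > 0) message(empty, " locus/group combinations were empty")
  do.call(rbind, out)
}

# KDE of both samples on a shared grid: Scott's rule bandwidths, 512 grid
# points spanning both ranges padded by 3 bandwidths.
sharedKde <- function(rep, cond, n_grid = 512L) {
  bw_r <- tryCatch(stats::bw.nrd(rep), error = function(e) 0)
  bw_c <- tryCatch(stats::bw.nrd(cond), error = function(e) 0)
  if (!is.finite(bw_r)) bw_r <- 0
  if (!is.finite(bw_c)) bw_c <- 0
  if (bw_r <= 0 && bw_c <= 0) {
    return(NULL) # both samples degenerate; caller falls back
  }
  # one degenerate sample borrows the other's bandwidth
  if (bw_r <= 0) bw_r <- bw_c
  if (bw_c <= 0) bw_c <- bw_r
  pad <- 3 * max(bw_r, bw_c)
  lo <- min(rep, cond) - pad
  hi <- max(rep, cond) + pad
  list(x = seq(lo, hi, length.out = n_grid),
       f_rep = stats::density(rep, bw = bw_r, from = lo, to = hi,
                              n = n_grid)$y,
       f_cond = stats::density(cond, bw = bw_c, from = lo, to = hi,
                               n = n_grid)$y)
}

#' Classification threshold at the distribution overlap point
#'
#' Fits kernel density estimates to the replicate and condition distance
#' samples on a shared grid and returns the density crossing point between
#' the two sample means; when several crossings exist, the one minimizing
#' total misclassification; when none exists (or a sample is degenerate),
#' the midpoint of the means.
#'
#' @param rep,cond numeric distance samples.
#' @return threshold (single number).
#' @export
overlapThreshold <- function(rep, cond) {
  stopifnot(length(rep) > 0, length(cond) > 0)
  m_lo <- min(mean(rep), mean(cond))
  m_hi <- max(mean(rep), mean(cond))
  kde <- sharedKde(rep, cond)
  if (is.null(kde)) return((m_lo + m_hi) / 2)
  h <- kde$f_rep - kde$f_cond
  inside <- which(kde$x >= m_lo & kde$x <= m_hi)
  if (length(inside) < 2) return((m_lo + m_hi) / 2)
  sgn <- sign(h[inside])
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (length(flips) == 0) return((m_lo + m_hi) / 2)
  cand <- (kde$x[inside][flips] + kde$x[inside][flips + 1L]) / 2
  miscls <- vapply(cand, function(t) {
    mean(rep > t) * length(rep) + mean(cond <= t) * length(cond)
  }, numeric(1))
  cand[which.min(miscls)]
}

#' Replicate/condition rates and mean performance at a threshold
#'
#' Replicate rate = fraction of replicate distances below the threshold;
#' condition rate = fraction of condition distances above it; mean
#' performance = their unweighted average (this accounts for the imbalance
#' between the replicate and condition pair counts). The threshold should be
#' fit on train+validation distances and frozen before touching test.
#'
#' @param rep,cond distance samples the rates are measured on.
#' @param threshold classification threshold, from
#'   \code{\link{overlapThreshold}} on train+validation distances.
#' @return list: threshold, replicate_rate, condition_rate, mean_performance.
#' @export
meanPerformance <- function(rep, cond, threshold = overlapThreshold(rep,
                                                                    cond)) {
  rr <- mean(rep < threshold)
  cr <- mean(cond > threshold)
  list(threshold = threshold, replicate_rate = rr, condition_rate = cr,
       mean_performance = (rr + cr) / 2)
}

#' Separation index: one minus the density overlap integral
#'
#' \eqn{1 - \int \min(\hat p_{rep}(x), \hat p_{cond}(x)) dx} with KDE
#' densities on a shared grid and trapezoidal integration, clipped to
#' \code{[0, 1]}: 1 when the two distance distributions do not overlap, 0
#' when they coincide.
#'
#' @param rep,cond numeric distance samples.
#' @return separation index in \code{[0, 1]}.
#' @export
separationIndex <- function(rep, cond) {
  stopifnot(length(rep) > 0, length(cond) > 0)
  kde <- sharedKde(rep, cond)
  if (is.null(kde)) {
    # degenerate (point-mass) samples: overlap is 1 iff the masses coincide
    return(if (isTRUE(all.equal(mean(rep), mean(cond))) &&
               stats::sd(c(rep - mean(rep), cond - mean(cond))) == 0) 0 else 1)
  }
  ov <- pmin(kde$f_rep, kde$f_cond)
  dx <- diff(kde$x)
  integral <- sum(dx * (ov[-1] + ov[-length(ov)]) / 2)
  min(max(1 - integral, 0), 1)
}

#' Full separation report for an evaluation split
#'
#' Threshold fit on pooled train+validation distances, rates measured on the
#' evaluation distances, separation index from the evaluation densities.
#'
#' @param model trained \code{\link{SiameseModel}}.
#' @param pairs \code{\link{WindowPairs}} with all splits.
#' @param eval_split split to report on (default \code{"test"}).
#' @return a \code{\link{SeparationReport}}.
#' @export
separationReport <- function(model, pairs, eval_split = "test") {
  fitd <- rbind(embeddingDistances(model, pairs, "train"),
                embeddingDistances(model, pairs, "val"))
  evd <- embeddingDistances(model, pairs, eval_split)
  thr <- overlapThreshold(fitd$distance[fitd$label == 0],
                          fitd$distance[fitd$label == 1])
  rep <- evd$distance[evd$label == 0]
  cond <- evd$distance[evd$label == 1]
  mp <- meanPerformance(rep, cond, threshold = thr)
  new("SeparationReport", threshold = thr,
      replicateRate = mp$replicate_rate, conditionRate = mp$condition_rate,
      meanPerformance = mp$mean_performance,
      separationIndex = separationIndex(rep, cond),
      n = c(replicate = length(rep), condition = length(cond)))
}

#' @rdname SeparationReport-class
#' @export
setMethod("separationIndexOf", "SeparationReport",
          function(x) x@separationIndex)

#' @rdname SeparationReport-class
#' @export
setMethod("meanPerformanceOf", "SeparationReport",
          function(x) x@meanPerformance)

setMethod("show", "SeparationReport", function(object) {
  cat(sprintf(paste0("SeparationReport (n_rep = %d, n_cond = %d)\n",
                     "  threshold        %.4f\n  replicate rate   %.4f\n",
                     "  condition rate   %.4f\n  mean performance %.4f\n",
                     "  separation index %.4f\n"),
              object@n["replicate"], object@n["condition"], object@threshold,
              object@replicateRate, object@conditionRate,
              object@meanPerformance, object@separationIndex))
})

#' Serialize a SeparationReport to JSON
#'
#' @param report a \code{\link{SeparationReport}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSeparationReport <- function(report, path) {
  jsonlite::write_json(
    list(threshold = report@threshold,
         replicate_rate = report@replicateRate,
         condition_rate = report@conditionRate,
         mean_performance = report@meanPerformance,
         separation_index = report@separationIndex,
         n = as.list(report@n)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Stratify per-locus condition distances by peak density
#'
#' Counts supplied peaks (e.g. ChIP-seq intervals) overlapping each locus's
#' window span, splits loci into high / low peak-density groups at the
#' cutoff, and compares the condition-group mean distances of the two sets
#' with a two-sided two-sample t-test.
#'
#' @param track data.frame from \code{\link{buildDistanceTrack}}.
#' @param peaks a \code{GRanges} of peaks (or a data.frame with chrom,
#'   start, end in 0-based half-open coordinates).
#' @param cutoff peak-count threshold: loci with count > cutoff are "high".
#' @param window_span window span in bp used for overlap.
#' @return list: high / low per-locus means, peak counts, t statistic,
#'   p-value.
#' @export
stratifyByPeaks <- function(track, peaks, cutoff, window_span) {
  cond <- track[track$group == "condition" & !is.na(track$mean), ]
  if (is.data.frame(peaks)) {
    peaks <- GenomicRanges::GRanges(
      peaks$chrom,
      IRanges::IRanges(start = peaks$start + 1L, end = peaks$end))
  }
  loci <- GenomicRanges::GRanges(
    cond$chrom,
    IRanges::IRanges(start = cond$start_bp + 1L,
                     width = as.integer(window_span)))
  counts <- GenomicRanges::countOverlaps(loci, peaks)
  high <- cond$mean[counts > cutoff]
  low <- cond$mean[counts <= cutoff]
  if (length(high) < 2) stop("empty high group at cutoff ", cutoff)
  if (length(low) < 2) stop("empty low group at cutoff ", cutoff)
  tt <- stats::t.test(high, low, alternative = "two.sided")
  list(high = high, low = low, counts = counts,
       t = unname(tt$statistic), p_value = tt$p.value)
}

#' Write a distance track as bedGraph (one file per group) and tidy TSV
#'
#' @param track data.frame from \code{\link{buildDistanceTrack}}.
#' @param prefix output path prefix; writes
#'   \code{<prefix>.replicate.bedGraph}, \code{<prefix>.condition.bedGraph}
#'   and \code{<prefix>.tsv}.
#' @param window_span window span bp for bedGraph intervals.
#' @return invisibly, the paths written.
#' @export
writeDistanceTrack <- function(track, prefix, window_span) {
  paths <- character(0)
  for (g in c("replicate", "condition")) {
    sel <- track[track$group == g & !is.na(track$mean), ]
    bg <- data.frame(chrom = sel$chrom, start = sel$start_bp,
                     end = sel$start_bp + window_span,
                     value = sel$mean)
    p <- paste0(prefix, ".", g, ".bedGraph")
    utils::write.table(bg, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    paths <- c(paths, p)
  }
  p <- paste0(prefix, ".tsv")
  utils::write.table(track, p, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, p))
}
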
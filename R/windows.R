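#' Construct HicWindows
#'
#' @param data array of dim \code{(windowBins, windowBins, n)}.
#' @param info \code{DataFrame}/data.frame with \code{chrom}, \code{start_bp},
#'   \code{condition}, \code{replicate}.
#' @param resolution bin size bp.
#' @param strideBp anchor stride bp.
#' @param cleaned logical.
#' @return a \code{\link{HicWindows}}.
#' @export
HicWindows <- function(data, info, resolution, strideBp, cleaned = FALSE) {
  new("HicWindows", data = data, info = DataFrame(info),
      windowBins = dim(data)[1], resolution = as.numeric(resolution),
      strideBp = as.numeric(strideBp), cleaned = cleaned)
}

#' @rdname HicWindows-class
#' @export
setMethod("windowInfo", "HicWindows", function(x) x@info)

#' @rdname HicWindows-class
#' @export
setMethod("windowBins", "HicWindows", function(x) x@windowBins)

#' @rdname HicWindows-class
#' @export
setMethod("windowData", "HicWindows", function(x) x@data)

#' @rdname HicWindows-class
#' @export
setMethod("isCleaned", "HicWindows", function(x) x@cleaned)

#' @rdname HicWindows-class
#' @export
setMethod("length", "HicWindows", function(x) dim(x@data)[3])

#' @rdname HicWindows-class
#' @param i index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "HicWindows", function(x, i, j, ..., drop = FALSE) {
  idx <- seq_len(length(x))[i]
  new("HicWindows",
      data = x@data[, , idx, drop = FALSE],
      info = x@info[idx, , drop = FALSE],
      windowBins = x@windowBins, resolution = x@resolution,
      strideBp = x@strideBp, cleaned = x@cleaned)
})

setMethod("show", "HicWindows", function(object) {
  cat("HicWindows: ", length(object), " windows of ", object@windowBins,
      "x", object@windowBins, " bins @ ", object@resolution, " bp (",
      if (object@cleaned) "cleaned" else "uncleaned", ")\n", sep = "")
  if (length(object) > 0) {
    cat("  chromosomes:", paste(unique(object@info$chrom), collapse = ", "),
        "\n  datasets:",
        paste(unique(paste(object@info$condition, object@info$replicate,
                           sep = ".")), collapse = ", "), "\n")
  }
})

#' Combine HicWindows objects
#'
#' @param x,... \code{\link{HicWindows}} with identical geometry and
#'   cleaning state.
#' @return a pooled \code{\link{HicWindows}}.
#' @export
setMethod("c", "HicWindows", function(x, ...) {
  all_w <- c(list(x), list(...))
  wb <- unique(vapply(all_w, function(w) w@windowBins, integer(1)))
  cl <- unique(vapply(all_w, function(w) w@cleaned, logical(1)))
  st <- unique(vapply(all_w, function(w) w@strideBp, numeric(1)))
  res <- unique(vapply(all_w, function(w) w@resolution, numeric(1)))
  if (length(wb) != 1L || length(st) != 1L || length(res) != 1L) {
    stop("cannot combine windows with differing window_bins/stride/resolution")
  }
  if (length(cl) != 1L) stop("cannot mix cleaned and uncleaned windows")
  data <- array(0, c(wb, wb, sum(vapply(all_w, length, integer(1)))))
  at <- 0L
  for (w in all_w) {
    if (length(w) > 0) data[, , at + seq_len(length(w))] <- w@data
    at <- at + length(w)
  }
  info <- do.call(rbind, lapply(all_w, function(w) w@info))
  new("HicWindows", data = data, info = info, windowBins = wb,
      resolution = res, strideBp = st, cleaned = cl)
})

#' Extract overlapping diagonal windows from a contact matrix
#'
#' Cuts square submatrices of side \code{window_bins} along the diagonal,
#' anchored at 0, stride, 2*stride, ... bp, keeping only windows fully inside
#' the chromosome. Windows are returned uncleaned (missing values preserved).
#' The default stride is \code{window_bins/16} bins, i.e. the 160 kb stride
#' for a 2.56 Mb window at 10 kb resolution, and scales with resolution so
#' the number of anchors stays constant across a resolution sweep.
#'
#' @param m a \code{\link{ContactMatrix}}.
#' @param window_bins window side in bins (default 256).
#' @param stride_bp stride in bp; must be a multiple of the resolution.
#'   \code{NULL} selects the auto mode \code{window_bins/16} bins.
#' @param condition,replicate labels attached to every window.
#' @return a \code{\link{HicWindows}} (possibly empty, with a warning, when
#'   the window exceeds the chromosome).
#' @export
extractWindows <- function(m, window_bins = 256L, stride_bp = NULL,
                           condition = "cond", replicate = "rep") {
  stopifnot(is(m, "ContactMatrix"))
  window_bins <- as.integer(window_bins)
  if (is.null(stride_bp)) {
    stride_bp <- max(1L, window_bins %/% 16L) * m@resolution
  }
  if (stride_bp %% m@resolution != 0) {
    stop("stride_bp must be a multiple of the resolution")
  }
  stride_bins <- as.integer(stride_bp / m@resolution)
  n <- nBins(m)
  if (window_bins > n) {
    warning("window (", window_bins, " bins) larger than chromosome (",
            n, " bins); no windows extracted")
    return(HicWindows(array(0, c(window_bins, window_bins, 0)),
                      DataFrame(chrom = character(0), start_bp = numeric(0),
                                condition = character(0),
                                replicate = character(0)),
                      m@resolution, stride_bp))
  }
  starts <- seq.int(0L, n - window_bins, by = stride_bins)
  data <- array(0, c(window_bins, window_bins, length(starts)))
  for (k in seq_along(starts)) {
    idx <- starts[k] + seq_len(window_bins)
    data[, , k] <- m@values[idx, idx]
  }
  info <- DataFrame(chrom = rep(m@chrom, length(starts)),
                    start_bp = starts * m@resolution,
                    condition = rep(as.character(condition), length(starts)),
                    replicate = rep(as.character(replicate), length(starts)))
  HicWindows(data, info, m@resolution, stride_bp)
}

#' Clean windows: zero missing values, normalize by the window maximum
#'
#' Each window's \code{NA} entries are set to 0 and the window is divided by
#' its maximum value (skipped for all-zero windows), leaving values in
#' \code{[0, 1]} with max exactly 1 for any window with a positive entry.
#'
#' @param w a \code{\link{HicWindows}}.
#' @return cleaned \code{\link{HicWindows}}.
#' @export
cleanWindows <- function(w) {
  stopifnot(is(w, "HicWindows"))
  d <- w@data
  d[is.na(d)] <- 0
  for (k in seq_len(dim(d)[3])) {
    mx <- max(d[, , k])
    if (mx > 0) d[, , k] <- d[, , k] / mx
  }
  initialize(w, data = d, cleaned = TRUE)
}

#' Filter out windows dominated by missing or empty positions
#'
#' A window is dropped when the number of missing (\code{NA}) entries exceeds
#' the number of nonzero entries, or when the number of empty positions —
#' window rows whose every entry is missing-or-zero — exceeds 10\% of the
#' window side. Applied before cleaning (cleaning destroys the missing-value
#' counts the rule needs).
#'
#' @param w uncleaned \code{\link{HicWindows}}.
#' @param max_empty_frac empty-position fraction threshold (default 0.10).
#' @return the kept windows, original order preserved.
#' @export
filterWindows <- function(w, max_empty_frac = 0.10) {
  stopifnot(is(w, "HicWindows"))
  keep <- vapply(seq_len(length(w)), function(k) {
    m <- w@data[, , k]
    n_na <- sum(is.na(m))
    n_nonzero <- sum(!is.na(m) & m != 0)
    empty_rows <- sum(apply(m, 1L, function(r) all(is.na(r) | r == 0)))
    !(n_na > n_nonzero || empty_rows > max_empty_frac * w@windowBins)
  }, logical(1))
  w[keep]
}

#' Mask the diagonal band of windows
#'
#' Zeroes all entries with \code{|i - j| < mask_bins}; with the default
#' \code{mask_bins = 3} this removes the 3 pixels along the diagonal,
#' spanning 30 kb at 10 kb resolution (3 x R), where noise uninformative for
#' comparison dominates.
#'
#' @param w a \code{\link{HicWindows}} or a plain square matrix.
#' @param mask_bins half-width of the zeroed band.
#' @return same type as \code{w}.
#' @export
maskDiagonal <- function(w, mask_bins = 3L) {
  stopifnot(mask_bins >= 0)
  if (is.matrix(w)) {
    return(w * diagMask(nrow(w), mask_bins))
  }
  stopifnot(is(w, "HicWindows"))
  mk <- diagMask(w@windowBins, mask_bins)
  d <- w@data
  for (k in seq_len(dim(d)[3])) d[, , k] <- d[, , k] * mk
  initialize(w, data = d)
}

diagMask <- function(side, mask_bins) {
  ij <- abs(outer(seq_len(side), seq_len(side), "-"))
  (ij >= mask_bins) * 1
}
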
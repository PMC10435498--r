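#' Construct a ContactMatrix
#'
#' @param values square symmetric numeric matrix (NA = missing bin).
#' @param chrom chromosome name.
#' @param resolution bin size in bp.
#' @param normalization \code{"RAW"}, \code{"ICE"} or \code{"PRECOMPUTED"}.
#' @return a \code{\link{ContactMatrix}}.
#' @export
ContactMatrix <- function(values, chrom, resolution,
                          normalization = c("RAW", "ICE", "PRECOMPUTED")) {
  normalization <- match.arg(normalization)
  values <- as.matrix(values)
  dimnames(values) <- NULL
  new("ContactMatrix", chrom = as.character(chrom),
      resolution = as.numeric(resolution), values = values,
      normalization = normalization)
}

#' @rdname ContactMatrix-class
#' @export
setMethod("chromName", "ContactMatrix", function(x) x@chrom)

#' @rdname ContactMatrix-class
#' @export
setMethod("binResolution", "ContactMatrix", function(x) x@resolution)

#' @rdname ContactMatrix-class
#' @export
setMethod("nBins", "ContactMatrix", function(x) nrow(x@values))

#' @rdname ContactMatrix-class
#' @export
setMethod("contactValues", "ContactMatrix", function(x) x@values)

#' @rdname ContactMatrix-class
#' @export
setMethod("normMethod", "ContactMatrix", function(x) x@normalization)

setMethod("show", "ContactMatrix", function(object) {
  v <- object@values
  cat("ContactMatrix ", object@chrom, ": ", nrow(v), " bins @ ",
      object@resolution, " bp (", object@normalization, "), ",
      sum(is.na(v)), " missing entries\n", sep = "")
})

#' Read a contact matrix from a dense-text container
#'
#' Reads a whitespace-separated dense square matrix with a JSON side-car
#' header (\code{<path>.json}) recording \code{chrom}, \code{resolution} and
#' \code{normalization}. When no side-car exists, \code{chrom} and
#' \code{resolution} must be supplied. \code{NA}/\code{nan} entries mark
#' missing bins.
#'
#' @param path path to the matrix text file.
#' @param chrom chromosome requested; checked against the header when present.
#' @param resolution bin size requested, bp; checked against the header.
#' @param normalization normalization tag for header-less files.
#' @return a \code{\link{ContactMatrix}}.
#' @export
readContactMatrix <- function(path, chrom = NULL, resolution = NULL,
                              normalization = "RAW") {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- NULL
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    header <- jsonlite::read_json(side, simplifyVector = TRUE)
  }
  if (!is.null(header)) {
    if (!is.null(chrom) && !identical(as.character(chrom),
                                      as.character(header$chrom))) {
      stop("chromosome not found: ", chrom, " (file stores ", header$chrom, ")")
    }
    if (!is.null(resolution) &&
        abs(as.numeric(resolution) - as.numeric(header$resolution)) > 0) {
      stop("resolution unavailable: ", resolution,
           " (file stores ", header$resolution, ")")
    }
    chrom <- header$chrom
    resolution <- header$resolution
    if (!is.null(header$normalization)) normalization <- header$normalization
  }
  if (is.null(chrom) || is.null(resolution)) {
    stop("chrom and resolution are required when no side-car header exists")
  }
  m <- as.matrix(utils::read.table(path, header = FALSE,
                                   na.strings = c("NA", "nan", "NaN")))
  dimnames(m) <- NULL
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m)) stop("matrix not square")
  def <- !is.na(m) & !is.na(t(m))
  if (any(abs(m[def] - t(m)[def]) > 1e-8 * (1 + abs(m[def])))) {
    stop("matrix not symmetric")
  }
  ContactMatrix(m, chrom = chrom, resolution = resolution,
                normalization = normalization)
}

#' Write a contact matrix to the dense-text container
#'
#' Writes the dense matrix as whitespace-separated text plus a JSON side-car
#' header (\code{<path>.json}); the round trip through
#' \code{\link{readContactMatrix}} reproduces all defined entries.
#'
#' @param x a \code{\link{ContactMatrix}}.
#' @param path output path for the matrix text file.
#' @return \code{path}, invisibly.
#' @export
writeContactMatrix <- function(x, path) {
  stopifnot(is(x, "ContactMatrix"))
  utils::write.table(x@values, path, row.names = FALSE, col.names = FALSE,
                     sep = "\t", na = "NA")
  jsonlite::write_json(
    list(chrom = x@chrom, resolution = x@resolution,
         n_bins = nrow(x@values), normalization = x@normalization),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' ICE-balance a raw contact matrix
#'
#' Iterative correction: finds diagonal weights \eqn{W} such that all
#' non-masked row sums of \eqn{W A W} are equal. Bins with zero coverage are
#' masked (set to \code{NA}). Convergence is declared when the maximum
#' relative deviation of non-masked row sums from their mean is at most
#' \code{tol}.
#'
#' @param raw a RAW \code{\link{ContactMatrix}}.
#' @param tol relative row-sum tolerance.
#' @param max_iter iteration cap.
#' @return an ICE-normalized \code{\link{ContactMatrix}}; balanced values are
#'   rescaled so non-masked row sums are 1.
#' @export
iceBalance <- function(raw, tol = 1e-5, max_iter = 200L) {
  stopifnot(is(raw, "ContactMatrix"), tol > 0)
  if (raw@normalization != "RAW") {
    stop("iceBalance expects a RAW matrix, got ", raw@normalization)
  }
  a <- raw@values
  a[is.na(a)] <- 0
  n <- nrow(a)
  mask <- rowSums(a) == 0
  b <- a
  resid <- Inf
  for (it in seq_len(max_iter)) {
    s <- rowSums(b)
    s[mask] <- NA
    sbar <- mean(s, na.rm = TRUE)
    if (sbar == 0) break
    resid <- max(abs(s / sbar - 1), na.rm = TRUE)
    if (resid <= tol) {
      b <- b / sbar # unit row sums on the non-masked set
      b[mask, ] <- NA
      b[, mask] <- NA
      return(ContactMatrix(b, raw@chrom, raw@resolution, "ICE"))
    }
    d <- s / sbar
    d[is.na(d)] <- 1
    b <- b / outer(d, d)
  }
  stop("ICE did not converge within ", max_iter,
       " iterations; last residual ", signif(resid, 4))
}
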
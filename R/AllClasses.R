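#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' ContactMatrix: one chromosome's binned contact map
#'
#' A symmetric, non-negative intrachromosomal contact matrix at a fixed bin
#' resolution. Missing bins (e.g. unmappable or zero-coverage regions) are
#' stored as \code{NA}. The normalization tag records whether the values are
#' raw counts (\code{"RAW"}), ICE-balanced in-package (\code{"ICE"}), or were
#' balanced upstream (\code{"PRECOMPUTED"}).
#'
#' @slot chrom chromosome name.
#' @slot resolution bin size in bp.
#' @slot values square symmetric numeric matrix; \code{NA} marks missing bins.
#' @slot normalization one of \code{"RAW"}, \code{"ICE"}, \code{"PRECOMPUTED"}.
#' @exportClass ContactMatrix
setClass("ContactMatrix",
  representation(
    chrom = "character",
    resolution = "numeric",
    values = "matrix",
    normalization = "character"
  )
)

setValidity("ContactMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) {
    return("contact matrix must be square")
  }
  if (!object@normalization %in% c("RAW", "ICE", "PRECOMPUTED")) {
    return("normalization must be RAW, ICE or PRECOMPUTED")
  }
  def <- !is.na(v)
  if (any(v[def] < 0)) {
    return("contact matrix entries must be non-negative")
  }
  both <- def & t(def)
  if (any(abs(v[both] - t(v)[both]) > 1e-8 * (1 + abs(v[both])))) {
    return("matrix not symmetric")
  }
  if (length(object@resolution) != 1L || object@resolution <= 0) {
    return("resolution must be a single positive number")
  }
  TRUE
})

#' HicWindows: diagonal windows cut from contact maps
#'
#' A stack of square diagonal windows (side \code{windowBins} bins) anchored
#' along the genome, each carrying its chromosome, genomic start, condition
#' and replicate labels. Values are either uncleaned (\code{NA} preserved) or
#' cleaned to \code{[0, 1]} with per-window max normalization.
#'
#' @slot data numeric array of dim \code{(windowBins, windowBins, n)}.
#' @slot info \code{DataFrame} with columns \code{chrom}, \code{start_bp},
#'   \code{condition}, \code{replicate}.
#' @slot windowBins window side length in bins.
#' @slot resolution bin size in bp.
#' @slot strideBp stride between window anchors in bp.
#' @slot cleaned logical; \code{TRUE} after \code{\link{cleanWindows}}.
#' @exportClass HicWindows
setClass("HicWindows",
  representation(
    data = "array",
    info = "DataFrame",
    windowBins = "integer",
    resolution = "numeric",
    strideBp = "numeric",
    cleaned = "logical"
  )
)

setValidity("HicWindows", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L || d[1] != d[2] || d[1] != object@windowBins) {
    return("data must be a (windowBins, windowBins, n) array")
  }
  if (d[3] != nrow(object@info)) {
    return("info rows must match number of windows")
  }
  need <- c("chrom", "start_bp", "condition", "replicate")
  if (!all(need %in% colnames(object@info))) {
    return(paste("info needs columns:", paste(need, collapse = ", ")))
  }
  if (object@cleaned) {
    if (anyNA(object@data)) return("cleaned windows may not contain NA")
    rng <- range(object@data)
    if (rng[1] < 0 || rng[2] > 1 + 1e-12) {
      return("cleaned window values must lie in [0, 1]")
    }
  }
  TRUE
})

#' WindowPairs: labelled, split-tagged pairs of co-located windows
#'
#' Pairs of windows taken at the same genomic anchor, labelled 0 when both
#' members come from the same condition group (replicate pair) and 1 when
#' they come from different condition groups (condition pair). Each pair is
#' tagged with its chromosome's split (train / val / test).
#'
#' @slot windows the pooled \code{\link{HicWindows}} the indices refer to.
#' @slot a,b integer indices into \code{windows} for the two pair members.
#' @slot label integer 0/1 per pair.
#' @slot split character per pair: \code{"train"}, \code{"val"} or
#'   \code{"test"}.
#' @slot scheme named list mapping split name to chromosome names.
#' @slot conditionOrder character; fixed condition ordering used downstream
#'   for signed difference maps.
#' @exportClass WindowPairs
setClass("WindowPairs",
  representation(
    windows = "HicWindows",
    a = "integer",
    b = "integer",
    label = "integer",
    split = "character",
    scheme = "list",
    conditionOrder = "character"
  )
)

setValidity("WindowPairs", function(object) {
  n <- length(object@a)
  if (length(object@b) != n || length(object@label) != n ||
      length(object@split) != n) {
    return("a, b, label and split must have equal length")
  }
  if (n > 0) {
    if (!all(object@label %in% c(0L, 1L))) return("labels must be 0 or 1")
    if (!all(object@split %in% c("train", "val", "test"))) {
      return("splits must be train, val or test")
    }
    info <- object@windows@info
    if (!all(info$chrom[object@a] == info$chrom[object@b]) ||
        !all(info$start_bp[object@a] == info$start_bp[object@b])) {
      return("pair members must share chromosome and start_bp")
    }
  }
  sp <- object@scheme
  if (anyDuplicated(unlist(sp))) {
    return("no chromosome may appear in more than one split")
  }
  TRUE
})

#' SiameseModel: the shared-weight convolutional encoder
#'
#' Holds the architecture description (a \code{\link{modelConfig}} list) and
#' the weight tensors of the LeNet-style twin encoder plus the linear
#' cross-embedding head. Both twins are the same weights by construction.
#'
#' @slot config list from \code{\link{modelConfig}}.
#' @slot weights named list of weight matrices / bias vectors.
#' @exportClass SiameseModel
setClass("SiameseModel",
  representation(config = "list", weights = "list")
)

setValidity("SiameseModel", function(object) {
  need <- c("W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4", "W5", "b5",
            "Whead", "bhead")
  if (!all(need %in% names(object@weights))) {
    return(paste("weights need elements:", paste(need, collapse = ", ")))
  }
  if (any(!vapply(object@weights, function(w) all(is.finite(w)), logical(1)))) {
    return("weights must be finite")
  }
  TRUE
})

#' SeparationReport: separability of replicate vs condition distances
#'
#' Classification threshold (fit on train+validation distances), replicate
#' and condition correct-classification rates on the evaluation set, their
#' unweighted mean (mean performance), and the separation index
#' (one minus the overlap integral of the two distance densities).
#'
#' @slot threshold distance threshold.
#' @slot replicateRate fraction of replicate distances below threshold.
#' @slot conditionRate fraction of condition distances above threshold.
#' @slot meanPerformance mean of the two rates.
#' @slot separationIndex in \code{[0, 1]}; 1 = fully separated densities.
#' @slot n named integer vector of sample sizes.
#' @exportClass SeparationReport
setClass("SeparationReport",
  representation(
    threshold = "numeric",
    replicateRate = "numeric",
    conditionRate = "numeric",
    meanPerformance = "numeric",
    separationIndex = "numeric",
    n = "integer"
  )
)

setValidity("SeparationReport", function(object) {
  rates <- c(object@replicateRate, object@conditionRate,
             object@meanPerformance, object@separationIndex)
  if (any(rates < -1e-9 | rates > 1 + 1e-9)) {
    return("rates and indices must lie in [0, 1]")
  }
  TRUE
})
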
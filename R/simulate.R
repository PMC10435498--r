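#' Specification of a planted contact-map feature
#'
#' Describes one multiplicative enrichment planted on the expected contact
#' map: a contact domain (square block on the diagonal), an asymmetric
#' domain, a stripe (a band of width <= 3 bins), or a loop (small dot).
#' Extents are bin intervals, 0-based half-open.
#'
#' @param kind one of \code{"domain"}, \code{"asymmetric_domain"},
#'   \code{"stripe"}, \code{"loop"}.
#' @param row_extent,col_extent integer length-2 vectors \code{c(from, to)}.
#' @param strength multiplicative contact enrichment (> 1 enriches).
#' @param present_in character vector of condition labels carrying the
#'   feature.
#' @return a \code{featureSpec} list.
#' @export
featureSpec <- function(kind = c("domain", "asymmetric_domain", "stripe",
                                 "loop"),
                        row_extent, col_extent = row_extent, strength,
                        present_in = character(0)) {
  kind <- match.arg(kind)
  row_extent <- as.integer(row_extent)
  col_extent <- as.integer(col_extent)
  stopifnot(length(row_extent) == 2L, length(col_extent) == 2L,
            row_extent[2] > row_extent[1], col_extent[2] > col_extent[1],
            strength > 0)
  if (kind == "domain" && !identical(row_extent, col_extent)) {
    stop("domain features must have row_extent == col_extent")
  }
  if (kind == "stripe" &&
      min(diff(row_extent), diff(col_extent)) > 3L) {
    stop("stripe features need one extent of width <= 3 bins")
  }
  structure(list(kind = kind, row_extent = row_extent,
                 col_extent = col_extent, strength = strength,
                 present_in = as.character(present_in)),
            class = "featureSpec")
}

#' Configuration of a synthetic Hi-C experiment
#'
#' The default stated world: three 1,000-bin chromosomes at 10 kb resolution
#' (10 Mb each; "chr1" trains, "chr18" validates, "chr2" tests), power-law
#' distance decay with exponent 1, and 1e6 expected contacts per replicate
#' and chromosome. Background contact domains tile each chromosome in both
#' conditions; five differential features per chromosome (four large domains
#' plus one stripe, fold change 2, jointly covering most window anchors)
#' emulate a cohesin-loss-like global perturbation between the two
#' conditions.
#'
#' @param chroms named integer vector: bins per chromosome.
#' @param resolution bin size bp.
#' @param alpha distance-decay exponent (expected contacts ~
#'   \code{(|i-j|+1)^-alpha}).
#' @param depth expected total contacts per replicate per chromosome.
#' @param features list of per-chromosome background \code{\link{featureSpec}}
#'   lists (present in all conditions); \code{NULL} = default tiling.
#' @param diff_features list of per-chromosome differential
#'   \code{\link{featureSpec}} lists; \code{NULL} = default planted set;
#'   \code{list()} = null experiment.
#' @param seed integer master seed.
#' @return a \code{syntheticConfig} list.
#' @export
syntheticConfig <- function(chroms = c(chr1 = 1000L, chr18 = 1000L,
                                       chr2 = 1000L),
                            resolution = 10000, alpha = 1, depth = 1e6,
                            features = NULL, diff_features = NULL,
                            seed = 1L) {
  stopifnot(alpha >= 0, depth > 0, all(chroms >= 2))
  if (is.null(features)) {
    features <- lapply(chroms, defaultBackgroundFeatures)
  }
  if (is.null(diff_features)) {
    diff_features <- lapply(chroms, defaultDiffFeatures)
  } else if (length(diff_features) == 0) {
    diff_features <- lapply(chroms, function(n) list())
  }
  structure(list(chroms = chroms, resolution = resolution, alpha = alpha,
                 depth = depth, features = features,
                 diff_features = diff_features, seed = as.integer(seed)),
            class = "syntheticConfig")
}

#' Default background domains: TADs tiling the chromosome in all conditions
#'
#' @param n_bins chromosome length in bins.
#' @return list of \code{\link{featureSpec}} (present_in empty = all
#'   conditions).
#' @export
defaultBackgroundFeatures <- function(n_bins) {
  widths <- c(45L, 60L, 40L, 55L, 50L)
  out <- list()
  at <- 0L
  k <- 1L
  while (at + widths[(k - 1L) %% length(widths) + 1L] <= n_bins) {
    wdt <- widths[(k - 1L) %% length(widths) + 1L]
    out[[k]] <- featureSpec("domain", c(at, at + wdt), strength = 1.6)
    at <- at + wdt
    k <- k + 1L
  }
  out
}

#' Default planted differential features
#'
#' Four large contact domains plus one stripe, at fixed fractional positions
#' spanning most of the chromosome, fold change 2; domains 1 and 3 and the
#' stripe are gained in condition "B", domains 2 and 4 are lost (present in
#' "A" only). The layout emulates the genome-wide domain changes of a
#' cohesin-loading-factor perturbation.
#'
#' @param n_bins chromosome length in bins.
#' @param conditions the two condition labels (default \code{c("A", "B")}).
#' @return list of \code{\link{featureSpec}}.
#' @export
defaultDiffFeatures <- function(n_bins, conditions = c("A", "B")) {
  f <- function(lo, hi) {
    out <- as.integer(round(n_bins * c(lo, hi)))
    out[2] <- max(out[2], out[1] + 1L) # short chromosomes: keep width >= 1
    out
  }
  list(
    featureSpec("domain", f(0.03, 0.15), strength = 2,
                present_in = conditions[2]),
    featureSpec("domain", f(0.22, 0.34), strength = 2,
                present_in = conditions[1]),
    featureSpec("asymmetric_domain", f(0.42, 0.53), f(0.44, 0.60),
                strength = 2, present_in = conditions[2]),
    featureSpec("domain", f(0.60, 0.72), strength = 2,
                present_in = conditions[1]),
    featureSpec("stripe", f(0.80, 0.803), f(0.80, 0.86), strength = 2.5,
                present_in = conditions[2])
  )
}

#' Expected-contact base matrix with power-law distance decay
#'
#' \eqn{\Lambda_{ij} \propto (|i-j|+1)^{-\alpha}}: the canonical decay of
#' contact frequency with genomic separation shared by all Hi-C maps.
#'
#' @param n_bins matrix side.
#' @param alpha decay exponent; 0 gives a constant matrix.
#' @return symmetric positive matrix (unnormalized intensities).
#' @export
baseIntensity <- function(n_bins, alpha) {
  stopifnot(n_bins >= 2)
  d <- abs(outer(seq_len(n_bins), seq_len(n_bins), "-"))
  (d + 1)^(-alpha)
}

#' Plant multiplicative features on an expected map
#'
#' Each spec whose \code{present_in} includes \code{condition} (or is empty,
#' meaning all conditions) multiplies the block
#' \code{row_extent x col_extent} and its transpose by \code{strength}.
#' Multiplicative planting is order-independent; the result stays symmetric.
#'
#' @param base symmetric expected matrix.
#' @param specs list of \code{\link{featureSpec}}.
#' @param condition condition label being generated.
#' @return modified matrix.
#' @export
plantFeatures <- function(base, specs, condition) {
  n <- nrow(base)
  out <- base
  for (sp in specs) {
    if (length(sp$present_in) > 0 && !(condition %in% sp$present_in)) next
    if (min(sp$row_extent, sp$col_extent) < 0 ||
        max(sp$row_extent, sp$col_extent) > n) {
      stop("feature extent out of range [0, ", n, ")")
    }
    s <- sp$strength
    ri <- (sp$row_extent[1] + 1):sp$row_extent[2]
    ci <- (sp$col_extent[1] + 1):sp$col_extent[2]
    out[ri, ci] <- out[ri, ci] * s
    out[ci, ri] <- out[ci, ri] * s
    ov <- intersect(ri, ci) # undo the double application on the overlap
    if (length(ov) > 0) out[ov, ov] <- out[ov, ov] / s
    out
  }
  out
}

#' Sample one replicate as Poisson counts at a stated sequencing depth
#'
#' Rescales the expected map so the upper triangle (including the diagonal)
#' sums to \code{depth}, draws independent Poisson counts there, and mirrors
#' to a symmetric integer matrix. Distinct seeds give independent replicates
#' of the same condition; identical seeds reproduce the same matrix.
#'
#' @param expected symmetric expected-intensity matrix.
#' @param depth expected total contacts (upper triangle).
#' @param seed integer seed.
#' @param chrom,resolution metadata for the returned matrix.
#' @return a RAW \code{\link{ContactMatrix}}.
#' @export
sampleReplicate <- function(expected, depth, seed, chrom = "chr1",
                            resolution = 10000) {
  stopifnot(depth > 0)
  n <- nrow(expected)
  up <- upper.tri(expected, diag = TRUE)
  lambda <- expected[up] * (depth / sum(expected[up]))
  counts <- withSeed(seed, stats::rpois(length(lambda), lambda))
  m <- matrix(0, n, n)
  m[up] <- counts
  m <- m + t(m) - diag(diag(m))
  ContactMatrix(m, chrom = chrom, resolution = resolution,
                normalization = "RAW")
}

# Run code under a temporary RNG state.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic per-(condition, replicate, chrom) seed below 2^31.
deriveSeed <- function(master, ...) {
  parts <- paste(c(master, ...), collapse = "|")
  h <- 0
  for (ch in utf8ToInt(parts)) h <- (h * 131 + ch) %% 2147483563
  as.integer(h) + 1L
}

#' Generate a multi-replicate, multi-condition synthetic experiment
#'
#' For each condition the expected map is the decay base with background and
#' condition-specific planted features; each replicate is an independent
#' Poisson draw at the stated depth (per-replicate depths may be scaled via
#' \code{depth_scale} to emulate sequencing-depth discrepancies). The truth
#' table lists every planted differential feature with its genomic extents
#' and sign of change from the first to the second condition.
#'
#' @param cfg a \code{\link{syntheticConfig}}.
#' @param conditions condition labels (default \code{c("A", "B")}).
#' @param replicates replicates per condition (>= 2; the method is
#'   replicate-based).
#' @param depth_scale optional named numeric vector scaling the depth per
#'   replicate label.
#' @return list with \code{matrices} (nested list
#'   \code{[[condition]][[replicate]][[chrom]]} of \code{ContactMatrix}),
#'   \code{expected} (\code{[[condition]][[chrom]]} expected maps) and
#'   \code{truth} (data.frame truth table).
#' @export
generateExperiment <- function(cfg, conditions = c("A", "B"),
                               replicates = 2L, depth_scale = NULL) {
  stopifnot(inherits(cfg, "syntheticConfig"))
  if (replicates < 2) {
    stop("replicate-based method needs >=2 replicates")
  }
  rep_labels <- paste0("R", seq_len(replicates))
  chrom_names <- names(cfg$chroms)
  expected <- list()
  for (cond in conditions) {
    expected[[cond]] <- list()
    for (ch in chrom_names) {
      base <- baseIntensity(cfg$chroms[[ch]], cfg$alpha)
      specs <- c(cfg$features[[ch]], cfg$diff_features[[ch]])
      expected[[cond]][[ch]] <- plantFeatures(base, specs, cond)
    }
  }
  matrices <- list()
  for (cond in conditions) {
    matrices[[cond]] <- list()
    for (r in rep_labels) {
      dscale <- if (!is.null(depth_scale) && r %in% names(depth_scale)) {
        depth_scale[[r]]
      } else 1
      matrices[[cond]][[r]] <- list()
      for (ch in chrom_names) {
        matrices[[cond]][[r]][[ch]] <- sampleReplicate(
          expected[[cond]][[ch]], cfg$depth * dscale,
          seed = deriveSeed(cfg$seed, cond, r, ch),
          chrom = ch, resolution = cfg$resolution)
      }
    }
  }
  truth <- truthTable(cfg, conditions)
  list(matrices = matrices, expected = expected, truth = truth)
}

#' Truth table of planted differential features
#'
#' @param cfg a \code{\link{syntheticConfig}}.
#' @param conditions the condition labels in their fixed order.
#' @return data.frame: id, chrom, kind, row/col extents in bp, present_in,
#'   sign of change from \code{conditions[1]} to \code{conditions[2]}.
#' @export
truthTable <- function(cfg, conditions = c("A", "B")) {
  rows <- list()
  id <- 0L
  for (ch in names(cfg$chroms)) {
    for (sp in cfg$diff_features[[ch]]) {
      id <- id + 1L
      sign <- if (conditions[2] %in% sp$present_in) "gained" else "lost"
      rows[[id]] <- data.frame(
        id = id, chrom = ch, kind = sp$kind,
        row_start_bp = sp$row_extent[1] * cfg$resolution,
        row_end_bp = sp$row_extent[2] * cfg$resolution,
        col_start_bp = sp$col_extent[1] * cfg$resolution,
        col_end_bp = sp$col_extent[2] * cfg$resolution,
        present_in = paste(sp$present_in, collapse = ","),
        sign = sign)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(id = integer(0), chrom = character(0),
                      kind = character(0), row_start_bp = numeric(0),
                      row_end_bp = numeric(0), col_start_bp = numeric(0),
                      col_end_bp = numeric(0), present_in = character(0),
                      sign = character(0)))
  }
  do.call(rbind, rows)
}

#' Window the datasets of a synthetic experiment
#'
#' Extracts, filters and cleans diagonal windows for every condition,
#' replicate and chromosome of a generated experiment and pools them.
#'
#' @param experiment result of \code{\link{generateExperiment}}.
#' @param window_bins window side in bins.
#' @param stride_bp stride bp (\code{NULL} = auto \code{window_bins/16}).
#' @return pooled cleaned \code{\link{HicWindows}}.
#' @export
windowExperiment <- function(experiment, window_bins = 64L, stride_bp = NULL) {
  parts <- list()
  for (cond in names(experiment$matrices)) {
    for (r in names(experiment$matrices[[cond]])) {
      for (ch in names(experiment$matrices[[cond]][[r]])) {
        cm <- experiment$matrices[[cond]][[r]][[ch]]
        w <- extractWindows(cm, window_bins, stride_bp,
                            condition = cond, replicate = r)
        parts[[length(parts) + 1L]] <- cleanWindows(filterWindows(w))
      }
    }
  }
  do.call(c, parts)
}
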
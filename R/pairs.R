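#' Chromosome-held-out split scheme
#'
#' Default scheme: test = chromosome 2, validation = chromosome 18, training
#' = all other chromosomes. No chromosome may appear in more than one split.
#'
#' @param test,val chromosome names held out for test / validation.
#' @return named list with \code{test} and \code{val} chromosome vectors;
#'   every other chromosome falls into \code{train}.
#' @export
chromSplitScheme <- function(test = "chr2", val = "chr18") {
  if (length(intersect(test, val)) > 0) {
    stop("no chromosome may appear in more than one split")
  }
  list(test = as.character(test), val = as.character(val))
}

splitOfChrom <- function(chrom, scheme) {
  out <- rep("train", length(chrom))
  out[chrom %in% scheme$test] <- "test"
  out[chrom %in% scheme$val] <- "val"
  out
}

#' Assemble labelled window pairs by genomic location
#'
#' Windows from all datasets (condition x replicate) are paired at each
#' genomic anchor: label 0 for all within-group cross-replicate combinations
#' (replicate pairs), label 1 for all cross-group combinations (condition
#' pairs). In \code{standard} mode the condition group is the condition
#' label. The sequencing-depth modes regroup replicates of a single
#' condition by their depth tag: \code{depth_artefact} treats the high-depth
#' replicates and the low-depth replicates as two pseudo-conditions (the
#' network can then learn depth artefacts), while \code{depth_robust} puts
#' one high- and one low-depth replicate into each pseudo-condition (depth is
#' mirrored across groups, so depth artefacts cannot be used to separate
#' them).
#'
#' Anchors missing from any dataset (e.g. filtered out in one replicate) are
#' omitted from pairing entirely, with a message.
#'
#' @param windows pooled cleaned \code{\link{HicWindows}} covering all
#'   datasets, identical geometry.
#' @param scheme a \code{\link{chromSplitScheme}}.
#' @param mode \code{"standard"}, \code{"depth_artefact"} or
#'   \code{"depth_robust"}.
#' @param depth named character vector mapping replicate label to
#'   \code{"high"}/\code{"low"}; required for the depth modes.
#' @return a \code{\link{WindowPairs}}.
#' @export
makePairs <- function(windows, scheme = chromSplitScheme(),
                      mode = c("standard", "depth_artefact", "depth_robust"),
                      depth = NULL) {
  stopifnot(is(windows, "HicWindows"))
  mode <- match.arg(mode)
  info <- windows@info
  key <- paste(info$condition, info$replicate, sep = ".")
  datasets <- sort(unique(key))

  group_of <- switch(mode,
    standard = {
      g <- vapply(strsplit(datasets, ".", fixed = TRUE), `[`, "", 1L)
      names(g) <- datasets
      g
    },
    depth_artefact = {
      if (is.null(depth)) stop("depth modes need a 'depth' mapping")
      reps <- vapply(strsplit(datasets, ".", fixed = TRUE), `[`, "", 2L)
      g <- unname(depth[reps])
      names(g) <- datasets
      g
    },
    depth_robust = {
      if (is.null(depth)) stop("depth modes need a 'depth' mapping")
      reps <- vapply(strsplit(datasets, ".", fixed = TRUE), `[`, "", 2L)
      hi <- datasets[depth[reps] == "high"]
      lo <- datasets[depth[reps] == "low"]
      if (length(hi) != length(lo)) {
        stop("depth_robust needs equal numbers of high and low replicates")
      }
      g <- character(length(datasets))
      names(g) <- datasets
      for (i in seq_along(hi)) g[c(hi[i], lo[i])] <- paste0("mixed", i)
      g
    })
  if (length(unique(group_of)) < 2) {
    stop("need >=2 condition groups (got ",
         paste(unique(group_of), collapse = ", "), ")")
  }

  loc <- paste(info$chrom, info$start_bp, sep = ":")
  tab <- table(loc, key)
  full <- rownames(tab)[apply(tab, 1L, function(r) all(r == 1))]
  dropped <- setdiff(unique(loc), full)
  if (length(dropped) > 0) {
    message(length(dropped),
            " location(s) not present in every dataset; omitted from pairing")
  }

  combos <- utils::combn(datasets, 2L)
  combo_label <- as.integer(group_of[combos[1L, ]] != group_of[combos[2L, ]])

  keep <- loc %in% full
  ord <- order(info$chrom[keep], info$start_bp[keep], key[keep])
  widx <- which(keep)[ord]
  # index windows by (location, dataset)
  lut <- split(widx, paste(loc[widx], key[widx], sep = "|"))
  a <- b <- integer(0)
  lab <- integer(0)
  for (j in seq_len(ncol(combos))) {
    ia <- unlist(lut[paste(full, combos[1L, j], sep = "|")], use.names = FALSE)
    ib <- unlist(lut[paste(full, combos[2L, j], sep = "|")], use.names = FALSE)
    a <- c(a, ia)
    b <- c(b, ib)
    lab <- c(lab, rep(combo_label[j], length(ia)))
  }
  split_tag <- splitOfChrom(info$chrom[a], scheme)
  cond_order <- sort(unique(group_of))
  new("WindowPairs", windows = windows, a = a, b = b, label = lab,
      split = split_tag, scheme = scheme, conditionOrder = cond_order)
}

#' @rdname WindowPairs-class
#' @export
setMethod("pairLabels", "WindowPairs", function(x) x@label)

#' @rdname WindowPairs-class
#' @export
setMethod("pairSplits", "WindowPairs", function(x) x@split)

#' @rdname WindowPairs-class
#' @export
setMethod("length", "WindowPairs", function(x) length(x@a))

#' @rdname WindowPairs-class
#' @param i index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "WindowPairs", function(x, i, j, ..., drop = FALSE) {
  idx <- seq_len(length(x))[i]
  initialize(x, a = x@a[idx], b = x@b[idx], label = x@label[idx],
             split = x@split[idx])
})

setMethod("show", "WindowPairs", function(object) {
  cat("WindowPairs:", length(object), "pairs over",
      length(object@windows), "windows\n")
  if (length(object) > 0) {
    print(table(split = object@split, label = object@label))
  }
})

#' Restrict pairs to one split
#'
#' @param x a \code{\link{WindowPairs}}.
#' @param split \code{"train"}, \code{"val"} or \code{"test"}.
#' @return the subset of pairs in that split.
#' @export
pairsForSplit <- function(x, split) {
  stopifnot(is(x, "WindowPairs"), split %in% c("train", "val", "test"))
  x[x@split == split]
}

# Drop windows not referenced by any pair and remap indices (keeps
# evaluation of a split from embedding the whole pooled window set).
trimPairs <- function(x) {
  used <- sort(unique(c(x@a, x@b)))
  if (length(used) == length(x@windows)) return(x)
  remap <- integer(length(x@windows))
  remap[used] <- seq_along(used)
  initialize(x, windows = x@windows[used], a = remap[x@a], b = remap[x@b])
}

#' Locations of each pair
#'
#' @param x a \code{\link{WindowPairs}}.
#' @return data.frame with one row per pair: chrom, start_bp, label, split.
#' @export
pairLocations <- function(x) {
  info <- x@windows@info
  data.frame(chrom = info$chrom[x@a], start_bp = info$start_bp[x@a],
             label = x@label, split = x@split)
}
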
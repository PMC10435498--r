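#' Convolutional difference map for one window pair
#'
#' Feeds each window individually through the convolutional stages of the
#' trained network (for a side-256 input the final stage yields 16 maps of
#' side 61), subtracts the outputs filterwise (\code{a - b}), takes the mean
#' over filters, and upsamples back to window scale by mapping each
#' convolutional cell to its receptive-field centre (nearest-neighbour).
#'
#' @param model trained \code{\link{SiameseModel}}.
#' @param a,b cleaned co-located window matrices (masked internally).
#' @return signed \code{window_bins x window_bins} matrix;
#'   \code{convDifference(a, b) == -convDifference(b, a)}.
#' @export
convDifference <- function(model, a, b) {
  cfg <- model@config
  fa <- convFeatureMap(model, a)
  fb <- convFeatureMap(model, b)
  upsampleConvMap(fa - fb, cfg)
}

# Mean-over-filters stage-2 conv map for one window (matrix, side pool2).
convFeatureMap <- function(model, w) {
  cfg <- model@config
  x <- array(maskDiagonal(w, cfg$mask_bins), c(nrow(w), ncol(w), 1L, 1L))
  out <- convStageForward(model@weights, cfg, x)$out
  apply(out[, , , 1L, drop = FALSE], c(1L, 2L), mean)
}

# Receptive-field geometry of the two-stage conv stack: cumulative stride
# and receptive-field size, used to back-map conv cells to input bins.
convGeometry <- function(cfg) {
  k <- cfg$kernel
  p <- cfg$pool
  # conv k: r=k, j=1; pool p: r+=(p-1)j, j*=p; conv k: r+=(k-1)j;
  # pool p: r+=(p-1)j, j*=p
  r <- k
  j <- 1
  r <- r + (p - 1) * j; j <- j * p
  r <- r + (k - 1) * j
  r <- r + (p - 1) * j; j <- j * p
  list(jump = j, rf = r, center0 = (r - 1) / 2)
}

# Bilinear upsample of a conv-scale map to window scale: conv cell t is
# anchored at its receptive-field centre t*jump + (rf-1)/2 (0-based) and
# values vary continuously between anchors (avoids quantizing single-cell
# noise into jump-sized blocks).
upsampleConvMap <- function(cm, cfg) {
  geo <- convGeometry(cfg)
  side <- cfg$window_bins
  n_cells <- nrow(cm)
  if (n_cells == 1L) return(matrix(cm[1, 1], side, side))
  px <- seq_len(side) - 1
  pos <- pmin(pmax((px - geo$center0) / geo$jump, 0), n_cells - 1)
  i0 <- pmin(floor(pos), n_cells - 2) + 1
  frac <- pos - (i0 - 1)
  # separable interpolation: rows then columns
  a <- cm[i0, , drop = FALSE] * (1 - frac) + cm[i0 + 1, , drop = FALSE] * frac
  a[, i0, drop = FALSE] * rep(1 - frac, each = side) +
    a[, i0 + 1, drop = FALSE] * rep(frac, each = side)
}

#' Amalgamate per-locus window maps into a genome-scale difference map
#'
#' Each genomic cell of the chromosome band receives the mean of all
#' window-scale map values covering it (coverage-weighted across overlapping
#' windows); cells covered by no window are \code{NA}.
#'
#' @param maps list of \code{window_bins x window_bins} matrices.
#' @param start_bins integer vector of window anchor bins (0-based), same
#'   length as \code{maps}.
#' @param n_bins chromosome length in bins.
#' @return \code{n_bins x n_bins} matrix (NA outside coverage).
#' @export
amalgamateMaps <- function(maps, start_bins, n_bins) {
  stopifnot(length(maps) == length(start_bins))
  sides <- vapply(maps, nrow, integer(1))
  if (length(unique(sides)) > 1) {
    stop("inconsistent window geometry across maps")
  }
  acc <- matrix(0, n_bins, n_bins)
  cov <- matrix(0L, n_bins, n_bins)
  for (k in seq_along(maps)) {
    idx <- start_bins[k] + seq_len(nrow(maps[[k]]))
    acc[idx, idx] <- acc[idx, idx] + maps[[k]]
    cov[idx, idx] <- cov[idx, idx] + 1L
  }
  out <- acc / cov
  out[cov == 0L] <- NA_real_
  out
}

#' Replicate and condition difference maps for one chromosome
#'
#' For every replicate pairing (label 0) and condition pairing (label 1) the
#' per-locus convolutional difference maps are amalgamated across the
#' chromosome; the replicate map is the mean across replicate pairings and
#' the condition map the mean across condition pairings. Condition pairs are
#' oriented by the fixed condition ordering (second condition minus first),
#' so positive condition-map values mean contacts gained in the second
#' condition.
#'
#' @param model trained \code{\link{SiameseModel}}.
#' @param pairs \code{\link{WindowPairs}} restricted to one chromosome (or
#'   use \code{chrom}).
#' @param chrom chromosome to extract (default: the single chromosome
#'   present).
#' @param condition_order length-2 character giving the condition ordering;
#'   default the pair set's stored order.
#' @return list: \code{replicate}, \code{condition} (genome-band matrices),
#'   \code{n_bins}, \code{chrom}.
#' @export
buildGroupMaps <- function(model, pairs, chrom = NULL,
                           condition_order = NULL) {
  stopifnot(is(pairs, "WindowPairs"))
  info <- pairs@windows@info
  if (is.null(chrom)) {
    chrom <- unique(info$chrom[pairs@a])
    if (length(chrom) != 1) stop("pairs span several chromosomes; set chrom")
  }
  keep <- info$chrom[pairs@a] == chrom
  if (!any(keep & pairs@label == 0L) || !any(keep & pairs@label == 1L)) {
    stop("chromosome ", chrom, " lacks one of the pair label classes")
  }
  if (is.null(condition_order)) condition_order <- pairs@conditionOrder
  res <- pairs@windows@resolution
  wb <- pairs@windows@windowBins
  n_bins <- max(info$start_bp[keep]) / res + wb
  # conv feature map per distinct window (cache)
  widx <- sort(unique(c(pairs@a[keep], pairs@b[keep])))
  fmaps <- vector("list", length(widx))
  names(fmaps) <- as.character(widx)
  for (i in seq_along(widx)) {
    fmaps[[i]] <- convFeatureMap(model,
                                 pairs@windows@data[, , widx[i]])
  }
  cfg <- model@config
  combo_key <- function(i, j) {
    paste(info$condition[i], info$replicate[i], "|",
          info$condition[j], info$replicate[j])
  }
  group_maps <- list(replicate = list(), condition = list())
  for (lab in c(0L, 1L)) {
    sel <- which(keep & pairs@label == lab)
    ia <- pairs@a[sel]
    ib <- pairs@b[sel]
    if (lab == 1L) {
      # orient: member from the later condition first
      ca <- match(info$condition[ia], condition_order)
      flip <- ca == 1L
      tmp <- ia[flip]; ia[flip] <- ib[flip]; ib[flip] <- tmp
    }
    combos <- combo_key(ia, ib)
    for (cb in unique(combos)) {
      s <- which(combos == cb)
      maps <- lapply(s, function(q) {
        upsampleConvMap(fmaps[[as.character(ia[q])]] -
                          fmaps[[as.character(ib[q])]], cfg)
      })
      starts <- info$start_bp[ia[s]] / res
      g <- if (lab == 0L) "replicate" else "condition"
      group_maps[[g]][[cb]] <- amalgamateMaps(maps, starts, n_bins)
    }
  }
  mean_maps <- lapply(group_maps, function(lst) {
    Reduce(`+`, lst) / length(lst)
  })
  list(replicate = mean_maps$replicate, condition = mean_maps$condition,
       n_bins = n_bins, chrom = chrom, resolution = res,
       condition_order = condition_order)
}

#' Replicate-calibrated feature mask
#'
#' Threshold = the \code{pct}-th percentile of the absolute replicate-map
#' values over defined cells; the mask marks condition-map cells whose
#' absolute value exceeds it. (The replicate map measures what pure
#' technical noise produces under the same pipeline.)
#'
#' @param cond,rep condition and replicate difference maps (identical
#'   geometry).
#' @param pct percentile (default 95).
#' @return logical matrix mask (\code{FALSE} where undefined).
#' @export
thresholdFeatures <- function(cond, rep, pct = 95) {
  stopifnot(all(dim(cond) == dim(rep)))
  t <- stats::quantile(abs(rep[!is.na(rep)]), pct / 100, names = FALSE)
  mask <- !is.na(cond) & abs(cond) > t
  mask
}

#' Label connected components and apply the size filters
#'
#' 8-connected component labelling of the mask; components whose bounding
#' box is smaller than \code{min_span} (50 kb) in both dimensions, or larger
#' than \code{max_span} (2.56 Mb, the window span) in either dimension, are
#' removed.
#'
#' @param mask logical matrix.
#' @param resolution bin size bp.
#' @param min_span,max_span size filters in bp.
#' @return list of components, each with \code{cells} (2-column matrix of
#'   row/col indices) and \code{bbox} (row/col index ranges).
#' @export
labelAndFilter <- function(mask, resolution, min_span = 5e4,
                           max_span = 2.56e6) {
  comps <- connectedComponents(mask)
  keep <- list()
  for (cp in comps) {
    h <- (diff(cp$bbox$rows) + 1) * resolution
    w <- (diff(cp$bbox$cols) + 1) * resolution
    if (h < min_span && w < min_span) next
    if (h > max_span || w > max_span) next
    keep[[length(keep) + 1L]] <- cp
  }
  keep
}

# 8-connected component labelling via iterative flood fill.
connectedComponents <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  comps <- list()
  nxt <- 0L
  todo <- which(mask & lab == 0L)
  for (start in todo) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    stack <- start
    cells <- integer(0)
    lab[start] <- nxt
    while (length(stack) > 0) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      cells <- c(cells, cur)
      r <- (cur - 1L) %% nr + 1L
      cl <- (cur - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr
        cc <- cl + dc
        if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc) {
          q <- rr + nr * (cc - 1L)
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- nxt
            stack <- c(stack, q)
          }
        }
      }
    }
    rows <- (cells - 1L) %% nr + 1L
    cols <- (cells - 1L) %/% nr + 1L
    comps[[nxt]] <- list(cells = cbind(row = rows, col = cols),
                         bbox = list(rows = range(rows), cols = range(cols)))
  }
  comps
}

#' Convex hulls and signs of filtered components
#'
#' Each component's hull mask is the discrete convex hull of its cells
#' (always a superset of the component); the sign is gained when the mean
#' signed condition-map value inside the component is positive under the
#' fixed condition ordering (second condition minus first), else lost.
#'
#' @param components from \code{\link{labelAndFilter}}.
#' @param cond signed condition difference map.
#' @param resolution bin size bp.
#' @return data.frame of features (id, bbox in bp, sign, mean value, area)
#'   with hull cell matrices attached as the \code{hulls} attribute.
#' @export
hullAndSign <- function(components, cond, resolution) {
  rows <- list()
  hulls <- list()
  for (i in seq_along(components)) {
    cp <- components[[i]]
    hull_cells <- discreteConvexHull(cp$cells)
    vals <- cond[cp$cells]
    mv <- mean(vals, na.rm = TRUE)
    rows[[i]] <- data.frame(
      id = i,
      row_start_bp = (cp$bbox$rows[1] - 1) * resolution,
      row_end_bp = cp$bbox$rows[2] * resolution,
      col_start_bp = (cp$bbox$cols[1] - 1) * resolution,
      col_end_bp = cp$bbox$cols[2] * resolution,
      sign = if (mv > 0) "gained" else "lost",
      mean_value = mv,
      score = mean(abs(vals), na.rm = TRUE),
      component_area = nrow(cp$cells),
      hull_area = nrow(hull_cells))
    hulls[[i]] <- hull_cells
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(id = integer(0), row_start_bp = numeric(0),
               row_end_bp = numeric(0), col_start_bp = numeric(0),
               col_end_bp = numeric(0), sign = character(0),
               mean_value = numeric(0), score = numeric(0),
               component_area = integer(0), hull_area = integer(0))
  attr(out, "hulls") <- hulls
  out
}

# Discrete convex hull: all integer cells inside the convex hull of the
# component's cell centres (point-in-convex-polygon over the bounding box).
discreteConvexHull <- function(cells) {
  if (nrow(cells) <= 2) return(cells)
  pts <- unique(cells)
  h <- grDevices::chull(pts[, 1], pts[, 2])
  poly <- pts[h, , drop = FALSE]
  if (nrow(poly) <= 2) return(pts)
  rr <- seq(min(pts[, 1]), max(pts[, 1]))
  cc <- seq(min(pts[, 2]), max(pts[, 2]))
  grid <- cbind(row = rep(rr, times = length(cc)),
                col = rep(cc, each = length(rr)))
  inside <- rep(TRUE, nrow(grid))
  np <- nrow(poly)
  # chull returns vertices clockwise; points must lie right of every edge
  for (k in seq_len(np)) {
    p1 <- poly[k, ]
    p2 <- poly[k %% np + 1L, ]
    cross <- (p2[1] - p1[1]) * (grid[, 2] - p1[2]) -
      (p2[2] - p1[2]) * (grid[, 1] - p1[1])
    inside <- inside & (cross <= 1e-9)
  }
  grid[inside, , drop = FALSE]
}

#' Cluster feature shapes with k-means
#'
#' Hull masks are resampled to \code{shape_side x shape_side} binary images,
#' flattened, and clustered with seeded k-means (10 restarts). Per-cluster
#' mean images are returned for manual grouping into domain-like,
#' asymmetric-domain-like and stripe categories; an automated heuristic
#' (transpose symmetry => domain-like, strong bounding-box aspect ratio =>
#' stripe, else asymmetric) is applied only on request and labelled as such.
#'
#' @param features data.frame from \code{\link{hullAndSign}} (with
#'   \code{hulls} attribute).
#' @param k number of clusters (default 10).
#' @param shape_side resampled image side (default 32).
#' @param seed k-means seed.
#' @param categorize apply the automated category heuristic.
#' @return list: \code{cluster} (assignment per feature), \code{means}
#'   (list of k mean images), \code{category} (per feature;
#'   \code{"unassigned"} unless \code{categorize = TRUE}).
#' @export
clusterFeatures <- function(features, k = 10L, shape_side = 32L, seed = 1L,
                            categorize = FALSE) {
  hulls <- attr(features, "hulls")
  n <- length(hulls)
  if (n < k) {
    stop("fewer features (", n, ") than clusters (", k,
         "); use a smaller k")
  }
  imgs <- t(vapply(hulls, function(cells) {
    as.numeric(rasterizeShape(cells, shape_side))
  }, numeric(shape_side^2)))
  n_distinct <- nrow(unique(imgs))
  if (n_distinct < k) {
    # fewer distinct shapes than clusters: one cluster per distinct shape,
    # remaining clusters stay empty
    uim <- unique(imgs)
    keys <- apply(imgs, 1L, paste, collapse = ",")
    ukeys <- apply(uim, 1L, paste, collapse = ",")
    cluster <- match(keys, ukeys)
    means <- c(lapply(seq_len(n_distinct), function(ci) {
      matrix(uim[ci, ], shape_side, shape_side)
    }), rep(list(matrix(0, shape_side, shape_side)), k - n_distinct))
    km <- list(cluster = cluster)
  } else {
    km <- withSeed(seed, stats::kmeans(imgs, centers = k, nstart = 10L,
                                       iter.max = 50L))
    means <- lapply(seq_len(k), function(ci) {
      matrix(km$centers[ci, ], shape_side, shape_side)
    })
  }
  category <- rep("unassigned", n)
  if (categorize) {
    category <- vapply(seq_len(n), function(i) {
      shapeCategory(matrix(imgs[i, ], shape_side, shape_side), hulls[[i]])
    }, character(1))
  }
  list(cluster = km$cluster, means = means, category = category)
}

# Aspect-preserving nearest-neighbour resample of a cell set to a
# side x side binary image: one common scale factor for both dimensions so
# elongated shapes (stripes) stay elongated, centred in the square.
rasterizeShape <- function(cells, side) {
  rr <- range(cells[, 1])
  cc <- range(cells[, 2])
  h <- diff(rr) + 1
  w <- diff(cc) + 1
  f <- max(h, w) / side # common scale preserves aspect ratio
  th <- max(1L, min(side, round(h / f)))
  tw <- max(1L, min(side, round(w / f)))
  src <- matrix(0, h, w)
  src[cbind(cells[, 1] - rr[1] + 1, cells[, 2] - cc[1] + 1)] <- 1
  tr <- pmin(h, floor((seq_len(th) - 0.5) * (h / th)) + 1)
  tc <- pmin(w, floor((seq_len(tw) - 0.5) * (w / tw)) + 1)
  img <- matrix(0, side, side)
  r0 <- (side - th) %/% 2
  c0 <- (side - tw) %/% 2
  img[r0 + seq_len(th), c0 + seq_len(tw)] <- src[tr, tc, drop = FALSE]
  img
}

# Heuristic category: documented as a heuristic stand-in for the manual
# grouping of cluster mean images.
shapeCategory <- function(img, cells) {
  h <- diff(range(cells[, 1])) + 1
  w <- diff(range(cells[, 2])) + 1
  aspect <- max(h, w) / min(h, w)
  if (aspect >= 3) return("stripe")
  sym <- sum(abs(img - t(img))) / max(sum(img), 1)
  if (sym <= 0.4) "domain_like" else "asymmetric_domain_like"
}

#' End-to-end differential feature extraction for one chromosome
#'
#' Builds the replicate and condition difference maps, thresholds the
#' condition map at the 95th percentile of the absolute replicate map,
#' labels 8-connected components, applies the 50 kb / 2.56 Mb size filters,
#' takes convex hulls and signs, and (when enough features exist) clusters
#' hull shapes with k-means.
#'
#' @param model trained \code{\link{SiameseModel}}.
#' @param pairs \code{\link{WindowPairs}}.
#' @param chrom chromosome name.
#' @param pct replicate-map percentile for the threshold.
#' @param k shape clusters (skipped when fewer features than k).
#' @param min_span,max_span size filters bp.
#' @param seed k-means seed.
#' @param categorize apply the heuristic category labels.
#' @return list: \code{features} data.frame (with \code{hulls} attribute),
#'   \code{maps} (the group maps), \code{cluster} info or NULL.
#' @export
extractDifferentialFeatures <- function(model, pairs, chrom = NULL,
                                        pct = 95, k = 10L, min_span = 5e4,
                                        max_span = 2.56e6, seed = 1L,
                                        categorize = FALSE) {
  maps <- buildGroupMaps(model, pairs, chrom = chrom)
  mask <- thresholdFeatures(maps$condition, maps$replicate, pct = pct)
  comps <- labelAndFilter(mask, maps$resolution, min_span = min_span,
                          max_span = max_span)
  feats <- hullAndSign(comps, maps$condition, maps$resolution)
  if (nrow(feats) > 0) feats$chrom <- maps$chrom
  cl <- NULL
  if (nrow(feats) >= k) {
    cl <- clusterFeatures(feats, k = k, seed = seed,
                          categorize = categorize)
    feats$cluster_id <- cl$cluster
    feats$category <- cl$category
  } else if (nrow(feats) > 0) {
    feats$cluster_id <- NA_integer_
    feats$category <- "unassigned"
  }
  list(features = feats, maps = maps, cluster = cl)
}

#' Write features as BEDPE
#'
#' Columns: chrom1, start1, end1, chrom2, start2, end2, name, score,
#' strand1, strand2, sign, cluster_id, category.
#'
#' @param features feature data.frame from
#'   \code{\link{extractDifferentialFeatures}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFeaturesBEDPE <- function(features, path) {
  df <- data.frame(
    chrom1 = features$chrom, start1 = features$row_start_bp,
    end1 = features$row_end_bp, chrom2 = features$chrom,
    start2 = features$col_start_bp, end2 = features$col_end_bp,
    name = paste0("feature_", features$id), score = features$score,
    strand1 = ".", strand2 = ".", sign = features$sign,
    cluster_id = if ("cluster_id" %in% names(features)) {
      features$cluster_id
    } else NA,
    category = if ("category" %in% names(features)) {
      features$category
    } else "unassigned")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write cluster mean images as portable greymaps (PGM)
#'
#' @param cluster result of \code{\link{clusterFeatures}}.
#' @param prefix output prefix; files \code{<prefix>.cluster<i>.pgm}.
#' @return paths, invisibly.
#' @export
writeClusterMeans <- function(cluster, prefix) {
  paths <- character(0)
  for (i in seq_along(cluster$means)) {
    img <- cluster$means[[i]]
    mx <- max(img)
    g <- if (mx > 0) round(img / mx * 255) else img * 0
    p <- paste0(prefix, ".cluster", i, ".pgm")
    con <- file(p, "w")
    writeLines(c("P2", paste(ncol(g), nrow(g)), "255"), con)
    utils::write.table(g, con, row.names = FALSE, col.names = FALSE)
    close(con)
    paths <- c(paths, p)
  }
  invisible(paths)
}
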
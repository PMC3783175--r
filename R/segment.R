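# Molecule segmentation and morphological skeletonization.
#
# Thinning (Zhang-Suen) and the skeleton-graph utilities are implemented
# here; component labelling and the Otsu threshold fallback come from
# EBImage.

# Shift a logical matrix by (dr, dc), padding with FALSE.
mshift <- function(M, dr, dc) {
  nr <- nrow(M); nc <- ncol(M)
  out <- matrix(FALSE, nr, nc)
  rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
  rok <- rs >= 1 & rs <= nr; cok <- cs >= 1 & cs <= nc
  out[rok, cok] <- M[rs[rok], cs[cok]]
  out
}

#' Zhang-Suen morphological thinning
#'
#' Reduces a binary mask to a unit-width 8-connected skeleton.
#'
#' @param mask logical matrix.
#' @return logical matrix of the same shape.
#' @export
skeletonize_mask <- function(mask) {
  M <- mask
  storage.mode(M) <- "logical"
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      P2 <- mshift(M, -1, 0); P3 <- mshift(M, -1, 1); P4 <- mshift(M, 0, 1)
      P5 <- mshift(M, 1, 1);  P6 <- mshift(M, 1, 0);  P7 <- mshift(M, 1, -1)
      P8 <- mshift(M, 0, -1); P9 <- mshift(M, -1, -1)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (!P2 & P3) + (!P3 & P4) + (!P4 & P5) + (!P5 & P6) +
           (!P6 & P7) + (!P7 & P8) + (!P8 & P9) + (!P9 & P2)
      if (sub == 1) {
        cond <- !(P2 & P4 & P6) & !(P4 & P6 & P8)
      } else {
        cond <- !(P2 & P4 & P8) & !(P2 & P6 & P8)
      }
      del <- M & B >= 2 & B <= 6 & A == 1 & cond
      if (any(del)) { M[del] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  M
}

# 8-neighbor degree of each skeleton pixel.
skel_degree <- function(S) {
  (mshift(S, -1, 0) + mshift(S, -1, 1) + mshift(S, 0, 1) + mshift(S, 1, 1) +
   mshift(S, 1, 0) + mshift(S, 1, -1) + mshift(S, 0, -1) + mshift(S, -1, -1)) *
    S
}

# Crossing number: 0->1 transitions around each pixel's 8-neighborhood.
# Robust to diagonal staircase redundancy: 1 = endpoint, 2 = path pixel,
# >= 3 = true branch point.
skel_crossing <- function(S) {
  P2 <- mshift(S, -1, 0); P3 <- mshift(S, -1, 1); P4 <- mshift(S, 0, 1)
  P5 <- mshift(S, 1, 1);  P6 <- mshift(S, 1, 0);  P7 <- mshift(S, 1, -1)
  P8 <- mshift(S, 0, -1); P9 <- mshift(S, -1, -1)
  ((!P2 & P3) + (!P3 & P4) + (!P4 & P5) + (!P5 & P6) +
   (!P6 & P7) + (!P7 & P8) + (!P8 & P9) + (!P9 & P2)) * S
}

#' Prune short spur branches from a skeleton
#'
#' Walks inward from each endpoint; branches shorter than `max_spur_px`
#' pixels that terminate at a junction are deleted. Repeated until stable.
#'
#' @param S logical skeleton matrix.
#' @param max_spur_px spur length threshold in pixels.
#' @return pruned logical skeleton.
#' @export
prune_skeleton <- function(S, max_spur_px = 3L) {
  repeat {
    deg <- skel_crossing(S)
    if (!any(deg >= 3)) return(S)
    ep <- which(S & skel_degree(S) == 1, arr.ind = TRUE)
    if (nrow(ep) == 0) return(S)
    to_remove <- NULL
    for (e in seq_len(nrow(ep))) {
      path <- matrix(as.integer(ep[e, ]), ncol = 2)
      cur <- as.integer(ep[e, ]); prev <- c(NA_integer_, NA_integer_)
      hit_junction <- FALSE
      for (s in seq_len(max_spur_px + 1L)) {
        if (deg[cur[1], cur[2]] >= 3) {
          hit_junction <- TRUE
          path <- path[-nrow(path), , drop = FALSE]  # keep the junction
          break
        }
        nb <- skel_neighbors(S, cur)
        if (!is.na(prev[1]))
          nb <- nb[!(nb[, 1] == prev[1] & nb[, 2] == prev[2]), , drop = FALSE]
        if (nrow(nb) == 0) break
        prev <- cur; cur <- as.integer(nb[1, ])
        path <- rbind(path, cur)
      }
      if (hit_junction && nrow(path) >= 1 && nrow(path) <= max_spur_px)
        to_remove <- rbind(to_remove, path)
    }
    if (is.null(to_remove)) return(S)
    S[to_remove] <- FALSE
  }
}

# 8-neighbors of pixel (r, c) that are in the skeleton.
skel_neighbors <- function(S, p) {
  offs <- cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  nb <- sweep(offs, 2, as.integer(p), "+")
  ok <- nb[, 1] >= 1 & nb[, 1] <= nrow(S) & nb[, 2] >= 1 & nb[, 2] <= ncol(S)
  nb <- nb[ok, , drop = FALSE]
  nb[S[nb], , drop = FALSE]
}

# Build the skeleton pixel graph; returns list(coords, edges, weights).
# Edges connect 8-neighbor pixel pairs, weighted by Euclidean pixel distance.
skel_graph <- function(S) {
  coords <- which(S, arr.ind = TRUE)
  n <- nrow(coords)
  id <- matrix(0L, nrow(S), ncol(S))
  id[coords] <- seq_len(n)
  e_from <- integer(0); e_to <- integer(0); w <- numeric(0)
  for (k in seq_len(4)) {   # unique directions: E, SE, S, SW
    off <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1))[[k]]
    nb <- sweep(coords, 2, off, "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= nrow(S) & nb[, 2] >= 1 & nb[, 2] <= ncol(S)
    ok[ok] <- S[nb[ok, , drop = FALSE]]
    if (!any(ok)) next
    e_from <- c(e_from, id[coords[ok, , drop = FALSE]])
    e_to <- c(e_to, id[nb[ok, , drop = FALSE]])
    w <- c(w, rep(sqrt(sum(off^2)), sum(ok)))
  }
  list(coords = coords, from = e_from, to = e_to, w = w, n = n)
}

# Total skeletal curve length in pixels: weight of a minimum spanning
# forest of the skeleton graph (exact for simple paths, sums branch lengths
# for trees, and undercounts a cycle by one step).
skel_length_px <- function(S) {
  g <- skel_graph(S)
  if (g$n < 2) return(0)
  gr <- igraph::graph_from_data_frame(
    data.frame(from = g$from, to = g$to, weight = g$w),
    directed = FALSE, vertices = data.frame(name = seq_len(g$n)))
  sum(igraph::E(igraph::mst(gr))$weight)
}

#' A segmented molecule region
#' @keywords internal
molecule_region <- function(mask, image, class_hint, skeleton, n_endpoints,
                            n_junctions, skel_len_nm, id) {
  idx <- which(mask, arr.ind = TRUE)
  hts <- image$heights[mask]
  # mean over the plateau (above 60% of the region peak): excludes the
  # blurred skirt so filled compact particles read near their true height
  structure(list(
    mask = mask,
    bbox = c(rmin = min(idx[, 1]), rmax = max(idx[, 1]),
             cmin = min(idx[, 2]), cmax = max(idx[, 2])),
    mean_height_nm = mean(hts[hts > 0.6 * max(hts)]),
    area_nm2 = sum(mask) * image$pixel_nm^2,
    class_hint = class_hint,
    skeleton = skeleton,
    n_endpoints = n_endpoints,
    n_junctions = n_junctions,
    skel_len_nm = skel_len_nm,
    molecule_id = id), class = "molecule_region")
}

#' @export
print.molecule_region <- function(x, ...) {
  cat(sprintf(
    "molecule_region %s: class %s, area %.0f nm^2, mean height %.2f nm, skeletal length %.0f nm\n",
    x$molecule_id, x$class_hint, x$area_nm2, x$mean_height_nm, x$skel_len_nm))
  invisible(x)
}

#' Segment individual molecules in a height image
#'
#' Thresholds the image (at `thresh_nm` if given, otherwise by Otsu's
#' method), labels 8-connected components, discards components touching the
#' image border or with skeletal length below `min_len_nm`, and assigns a
#' class hint per component: `compact` when the mean height over the mask
#' exceeds `compact_height_nm` (densely collapsed molecules image much
#' higher than a single duplex); otherwise by skeleton topology --
#' `circular` for 0 endpoints, `linear` for 2, `reject` for branched or
#' ambiguous skeletons (overlapping molecules).
#'
#' @param image an [afm_image].
#' @param min_len_nm minimum skeletal length for a traceable molecule, nm.
#' @param height_band expected (lo, hi) imaged height of a single strand,
#'   nm; the threshold defaults to half of `height_band[1]`.
#' @param compact_height_nm plateau-height threshold for the compact class,
#'   nm. A region is compact when its plateau mean height exceeds this AND
#'   its skeletal length is below `compact_max_len_nm`: collapsed particles
#'   are both tall and short, which separates them from extended interwound
#'   bodies of comparable height.
#' @param compact_max_len_nm maximum skeletal length of a compact particle,
#'   nm.
#' @param thresh_nm explicit binarization threshold; `NULL` uses half the
#'   lower height-band edge, `NA` forces the Otsu fallback.
#' @param prune_px spur-pruning length in pixels.
#' @return list of `molecule_region` objects (possibly empty).
#' @export
segment_molecules <- function(image, min_len_nm = 50,
                              height_band = c(0.4, 1.2),
                              compact_height_nm = 1.2, thresh_nm = NULL,
                              prune_px = 3L, compact_max_len_nm = 100) {
  H <- image$heights
  if (length(H) == 0) stop("empty image", call. = FALSE)
  if (is.null(thresh_nm)) thresh_nm <- height_band[1] / 2
  if (is.na(thresh_nm)) {
    rng <- range(H)
    if (diff(rng) <= 0) return(list())
    norm <- (H - rng[1]) / diff(rng)
    thresh_nm <- rng[1] + diff(rng) *
      EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  }
  mask <- H > thresh_nm
  if (!any(mask)) return(list())
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- matrix(as.integer(lab), nrow(H), ncol(H))
  regions <- list()
  for (l in seq_len(max(lab))) {
    m <- lab == l
    idx <- which(m, arr.ind = TRUE)
    if (min(idx) == 1 || max(idx[, 1]) == nrow(H) || max(idx[, 2]) == ncol(H))
      next  # touches border
    # thin within the component bounding box only (padded), then paste back
    r0 <- max(1L, min(idx[, 1]) - 2L); r1 <- min(nrow(H), max(idx[, 1]) + 2L)
    c0 <- max(1L, min(idx[, 2]) - 2L); c1 <- min(ncol(H), max(idx[, 2]) + 2L)
    Sc <- prune_skeleton(skeletonize_mask(m[r0:r1, c0:c1, drop = FALSE]),
                         prune_px)
    S <- matrix(FALSE, nrow(H), ncol(H))
    S[r0:r1, c0:c1] <- Sc
    if (!any(S)) next
    cx <- skel_crossing(S)
    n_ep <- sum(S & skel_degree(S) == 1)
    n_jn <- sum(S & cx >= 3)
    len_nm <- skel_length_px(S) * image$pixel_nm
    hts <- H[m]
    mh <- mean(hts[hts > 0.6 * max(hts)])   # plateau mean, skirt excluded
    if (mh > compact_height_nm && len_nm < compact_max_len_nm) {
      cls <- "compact"
    } else if (len_nm < min_len_nm) {
      next
    } else if (n_ep == 0) {
      cls <- "circular"
    } else if (n_ep == 2 && n_jn == 0) {
      cls <- "linear"
    } else {
      cls <- "reject"
    }
    regions[[length(regions) + 1L]] <-
      molecule_region(m, image, cls, S, n_ep, n_jn, len_nm,
                      id = sprintf("mol%02d", length(regions) + 1L))
  }
  regions
}
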
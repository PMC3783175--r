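#' Ordered backbone trace of a molecule
#'
#' Points are in nm, resampled at a uniform arc step. For closed traces the
#' first point is not repeated; the closing segment is implicit.
#'
#' @param points two-column matrix of (x, y) in nm.
#' @param step_nm nominal arc spacing, nm.
#' @param closed logical.
#' @param molecule_id identifier string.
#' @param tangent_chord_nm chord length over which segment tangents average
#'   the underlying path heading: `step_nm` for traces resampled from a
#'   finer path (images, resampled polylines), 0 when the segments are the
#'   exact generator headings. Consumed by [fit_persistence_length()].
#' @return object of class `trace_result`.
#' @export
trace_result <- function(points, step_nm, closed, molecule_id = "mol",
                         tangent_chord_nm = step_nm) {
  points <- as.matrix(points)
  stopifnot(is.numeric(points), ncol(points) == 2, nrow(points) >= 4)
  structure(list(points = unname(points), step_nm = as.numeric(step_nm),
                 closed = isTRUE(closed),
                 molecule_id = as.character(molecule_id),
                 tangent_chord_nm = as.numeric(tangent_chord_nm)),
            class = "trace_result")
}

#' @export
print.trace_result <- function(x, ...) {
  cat(sprintf("trace_result %s: %d points at %.3g nm step, %s, length %.1f nm\n",
              x$molecule_id, nrow(x$points), x$step_nm,
              if (x$closed) "closed" else "open",
              measure_contour_length(x)))
  invisible(x)
}

#' Convert a ground-truth polymer to a trace
#'
#' When `step_nm` is `NULL` the polymer's own vertices are used unchanged,
#' so tangents are the generator's exact segment directions (the form in
#' which the discrete worm-like-chain laws hold exactly). Otherwise the
#' polyline is resampled at the requested step; note that tangents of a
#' resampled chain are chord averages of the finer chain.
#'
#' @param polymer a [polymer2d].
#' @param step_nm arc step in nm, or `NULL` to keep native vertices.
#' @return a [trace_result].
#' @export
as_trace <- function(polymer, step_nm = NULL) {
  v <- polymer$vertices
  if (is.null(step_nm)) {
    step <- segment_geometry(v)$len[1]
    pts <- if (polymer$closed) v[-nrow(v), , drop = FALSE] else v
    return(trace_result(pts, step, polymer$closed,
                        paste0("truth-", polymer$seed),
                        tangent_chord_nm = 0))
  }
  pts <- resample_polyline(v, step_nm, closed = polymer$closed)
  trace_result(pts, step_nm, polymer$closed, paste0("truth-", polymer$seed))
}

#' Contour length of a trace
#'
#' Sum of consecutive inter-point distances, plus the closing segment for
#' closed traces.
#'
#' @param trace a [trace_result].
#' @return length in nm.
#' @export
measure_contour_length <- function(trace) {
  p <- trace$points
  L <- sum(sqrt(rowSums(diff(p)^2)))
  if (trace$closed) L <- L + sqrt(sum((p[1, ] - p[nrow(p), ])^2))
  L
}

# Bilinear interpolation of image heights at (x, y) nm positions.
# Pixel [r, c] (1-based) is centered at ((c - 0.5) px, (r - 0.5) px).
interp_height <- function(image, xy) {
  H <- image$heights; px <- image$pixel_nm
  cf <- xy[, 1] / px + 0.5   # fractional column index
  rf <- xy[, 2] / px + 0.5
  c0 <- pmax(1L, pmin(ncol(H) - 1L, floor(cf)))
  r0 <- pmax(1L, pmin(nrow(H) - 1L, floor(rf)))
  tc <- pmax(0, pmin(1, cf - c0)); tr <- pmax(0, pmin(1, rf - r0))
  h00 <- H[cbind(r0, c0)];     h01 <- H[cbind(r0, c0 + 1L)]
  h10 <- H[cbind(r0 + 1L, c0)]; h11 <- H[cbind(r0 + 1L, c0 + 1L)]
  (1 - tr) * ((1 - tc) * h00 + tc * h01) + tr * ((1 - tc) * h10 + tc * h11)
}

# Order the pixels of a pruned unit-width skeleton into a path (open) or
# cycle (closed). Returns an n x 2 matrix of (row, col). Orientation: open
# paths start at the endpoint with the smaller (row, col) lexicographic
# index; cycles start at the smallest (row, col) pixel and run
# counter-clockwise (positive signed area in image x, y coordinates).
order_skeleton <- function(S) {
  g <- skel_graph(S)
  if (g$n < 3) stop("skeleton too small to order", call. = FALSE)
  gr <- igraph::graph_from_data_frame(
    data.frame(from = g$from, to = g$to, weight = g$w),
    directed = FALSE, vertices = data.frame(name = seq_len(g$n)))
  ep <- which(S & skel_degree(S) == 1, arr.ind = TRUE)
  if (nrow(ep) > 2)
    stop("branched skeleton: more than 2 endpoints after pruning",
         call. = FALSE)
  if (nrow(ep) == 1)
    stop("ambiguous skeleton: exactly one endpoint", call. = FALSE)
  id_of <- function(rc) which(g$coords[, 1] == rc[1] & g$coords[, 2] == rc[2])
  if (nrow(ep) == 2) {
    ord <- order(ep[, 1], ep[, 2])
    ep <- ep[ord, , drop = FALSE]
    sp <- igraph::shortest_paths(gr, from = id_of(ep[1, ]), to = id_of(ep[2, ]),
                                 output = "vpath")$vpath[[1]]
    path <- g$coords[as.integer(igraph::as_ids(sp)), , drop = FALSE]
    return(list(path = path, closed = FALSE))
  }
  # cycle: greedy walk from the smallest (row, col) pixel, preferring
  # 4-connected steps (robust to diagonal staircase triangles)
  start <- g$coords[order(g$coords[, 1], g$coords[, 2])[1], ]
  visited <- matrix(FALSE, nrow(S), ncol(S))
  visited[start[1], start[2]] <- TRUE
  path <- matrix(as.integer(start), ncol = 2)
  cur <- as.integer(start)
  repeat {
    nb <- skel_neighbors(S, cur)
    nb <- nb[!visited[nb], , drop = FALSE]
    if (nrow(nb) == 0) break
    man <- abs(nb[, 1] - cur[1]) + abs(nb[, 2] - cur[2])
    nb <- nb[order(man, nb[, 1], nb[, 2]), , drop = FALSE]
    cur <- as.integer(nb[1, ])
    visited[cur[1], cur[2]] <- TRUE
    path <- rbind(path, cur)
  }
  if (nrow(path) < 0.8 * g$n || nrow(path) < 4)
    stop("could not order skeleton cycle", call. = FALSE)
  # orient counter-clockwise by the shoelace sign in (x, y) = (col, row)
  x <- path[, 2]; y <- path[, 1]
  area2 <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
  if (area2 < 0) path <- path[rev(seq_len(nrow(path))), , drop = FALSE]
  list(path = path, closed = TRUE)
}

# Local unit tangents of an ordered point path by central differences over
# +/- span points (ends one-sided for open paths).
path_tangents <- function(pts, closed, span = 2L) {
  n <- nrow(pts)
  idx_fw <- function(i, k) if (closed) ((i + k - 1L) %% n) + 1L else pmin(n, i + k)
  idx_bk <- function(i, k) if (closed) ((i - k - 1L) %% n) + 1L else pmax(1L, i - k)
  i <- seq_len(n)
  d <- pts[idx_fw(i, span), , drop = FALSE] - pts[idx_bk(i, span), , drop = FALSE]
  len <- sqrt(rowSums(d^2))
  len[len == 0] <- 1
  d / len
}

# Quadratic-apex subpixel refinement: move each path point along its local
# normal to the parabola apex fitted through height samples on the normal.
refine_subpixel <- function(image, pts, closed, halfwidth_nm, n_samp = 7L) {
  tang <- path_tangents(pts, closed)
  nrm <- cbind(-tang[, 2], tang[, 1])
  u <- seq(-halfwidth_nm, halfwidth_nm, length.out = n_samp)
  n <- nrow(pts)
  hmat <- matrix(0, n, n_samp)
  for (j in seq_len(n_samp))
    hmat[, j] <- interp_height(image, pts + u[j] * nrm)
  # least-squares quadratic h = a u^2 + b u + c per point (u fixed design)
  X <- cbind(u^2, u, 1)
  XtXi <- solve(crossprod(X))
  coefs <- hmat %*% X %*% XtXi          # n x 3: (a, b, c)
  apex <- ifelse(coefs[, 1] < 0, -coefs[, 2] / (2 * coefs[, 1]), 0)
  apex <- pmax(-halfwidth_nm, pmin(halfwidth_nm, apex))
  pts + apex * nrm
}

# Short moving-average smoothing of an ordered path (circular for closed).
smooth_path <- function(pts, closed, window = 3L) {
  n <- nrow(pts); half <- (window - 1L) %/% 2L
  out <- pts
  for (k in seq_len(half)) {
    if (closed) {
      fw <- pts[c((k + 1):n, 1:k), , drop = FALSE]
      bk <- pts[c((n - k + 1):n, 1:(n - k)), , drop = FALSE]
      out <- out + fw + bk
    } else {
      fw <- pts[pmin(n, seq_len(n) + k), , drop = FALSE]
      bk <- pts[pmax(1L, seq_len(n) - k), , drop = FALSE]
      out <- out + fw + bk
    }
  }
  out / (2 * half + 1)
}

# Extend an open path end along its outward tangent to the half-maximum
# height point, then pull back by the transverse half-width at half maximum
# measured near the end (corrects skeleton erosion of the Gaussian end cap).
extend_end <- function(image, pts, at_start) {
  if (at_start) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
  n <- nrow(pts)
  tang <- pts[n, ] - pts[n - 2L, ]
  tang <- tang / sqrt(sum(tang^2))
  nrm <- c(-tang[2], tang[1])
  end <- pts[n, ]
  # local peak height and transverse HWHM a little inside the end
  ref <- pts[n - 2L, ]
  u <- seq(-8, 8, by = 0.25)
  prof <- interp_height(image, sweep(outer(u, nrm), 2, ref, "+"))
  pk <- max(prof)
  above <- which(prof >= pk / 2)
  hwhm <- (u[max(above)] - u[min(above)]) / 2
  # march outward to the half-max point
  s <- seq(0, 3 * hwhm + 4, by = 0.25)
  line <- sweep(outer(s, tang), 2, end, "+")
  h <- interp_height(image, line)
  below <- which(h < pk / 2)
  reach <- if (length(below)) s[min(below)] else 0
  ext <- max(0, reach - hwhm)
  out <- rbind(pts, end + ext * tang)
  if (at_start) out <- out[rev(seq_len(nrow(out))), , drop = FALSE]
  out
}

#' Trace the backbone of a segmented molecule
#'
#' Extracts an ordered centerline by (1) skeletonizing the region mask,
#' (2) pruning short side branches, (3) ordering the skeleton pixels
#' between its two endpoints (or around the cycle for circular molecules),
#' (4) refining each point to subpixel accuracy by fitting a parabola to
#' the height profile along the local normal and moving to its apex (the
#' "brightest point" of the ridge), (5) smoothing with a short moving
#' average and, for open molecules, restoring the Gaussian end caps eroded
#' by skeletonization, and (6) resampling at a uniform arc step.
#'
#' @param image an [afm_image].
#' @param region a `molecule_region` of class hint `linear` or `circular`.
#' @param step_nm resampling arc step, nm (half the apparent cross-sectional
#'   diameter of the imaged duplex; 8 nm by default).
#' @param refine_halfwidth_nm half-width of the normal refinement profile,
#'   nm (about twice the imaged ridge width).
#' @param extend_ends restore end caps of open traces (recommended).
#' @return a [trace_result].
#' @export
trace_backbone <- function(image, region, step_nm = 8,
                           refine_halfwidth_nm = 6, extend_ends = TRUE) {
  if (!region$class_hint %in% c("linear", "circular"))
    stop("can only trace regions classed linear or circular", call. = FALSE)
  ord <- order_skeleton(region$skeleton)
  if (nrow(ord$path) * image$pixel_nm < 3 * step_nm)
    stop("skeletal length below 3 resampling steps: molecule too short",
         call. = FALSE)
  px <- image$pixel_nm
  pts <- cbind((ord$path[, 2] - 0.5) * px, (ord$path[, 1] - 0.5) * px)
  pts <- refine_subpixel(image, pts, ord$closed, refine_halfwidth_nm)
  pts <- smooth_path(pts, ord$closed, window = 3L)
  if (!ord$closed && extend_ends && nrow(pts) >= 4) {
    pts <- extend_end(image, pts, at_start = FALSE)
    pts <- extend_end(image, pts, at_start = TRUE)
  }
  poly <- if (ord$closed) rbind(pts, pts[1, ]) else pts
  rs <- resample_polyline(poly, step_nm, closed = ord$closed)
  trace_result(rs, step_nm, ord$closed, region$molecule_id)
}

#' Height statistics along a traced filament
#'
#' Samples transverse height profiles at randomly chosen arc positions
#' along the trace (excluding `end_excl_nm` at each open end), records the
#' apex height above the local background (median of the profile tails),
#' and returns the mean and standard deviation. Deterministic for a fixed
#' seed.
#'
#' @param image an [afm_image].
#' @param trace a [trace_result].
#' @param n_positions number of sampled arc positions (> 0).
#' @param seed integer seed.
#' @param profile_halfwidth_nm transverse profile half-width, nm.
#' @param end_excl_nm excluded arc length at each open end, nm.
#' @return list with `mean_nm`, `sd_nm`, `samples`.
#' @export
height_profile <- function(image, trace, n_positions = 50, seed = 1L,
                           profile_halfwidth_nm = 12, end_excl_nm = 10) {
  if (n_positions < 1) stop("`n_positions` must be >= 1", call. = FALSE)
  p <- trace$points
  poly <- if (trace$closed) rbind(p, p[1, ]) else p
  g <- segment_geometry(poly)
  s <- c(0, cumsum(g$len)); L <- s[length(s)]
  lo <- if (trace$closed) 0 else end_excl_nm
  hi <- if (trace$closed) L else L - end_excl_nm
  if (hi - lo <= 0) stop("trace too short for height sampling", call. = FALSE)
  set.seed(as.integer(seed))
  pos <- stats::runif(n_positions, lo, hi)
  xs <- stats::approx(s, poly[, 1], xout = pos, ties = "ordered")$y
  ys <- stats::approx(s, poly[, 2], xout = pos, ties = "ordered")$y
  # local tangent from neighbouring arc positions
  eps <- 2
  x2 <- stats::approx(s, poly[, 1], xout = pmin(hi, pos + eps), ties = "ordered")$y
  y2 <- stats::approx(s, poly[, 2], xout = pmin(hi, pos + eps), ties = "ordered")$y
  x1 <- stats::approx(s, poly[, 1], xout = pmax(lo, pos - eps), ties = "ordered")$y
  y1 <- stats::approx(s, poly[, 2], xout = pmax(lo, pos - eps), ties = "ordered")$y
  tx <- x2 - x1; ty <- y2 - y1
  tl <- sqrt(tx^2 + ty^2); tl[tl == 0] <- 1
  nx <- -ty / tl; ny <- tx / tl
  u <- seq(-profile_halfwidth_nm, profile_halfwidth_nm, by = 0.5)
  m <- length(u); tail_n <- max(2L, floor(m / 8))
  px <- image$pixel_nm
  samples <- numeric(n_positions)
  for (i in seq_len(n_positions)) {
    prof <- interp_height(image, cbind(xs[i] + u * nx[i], ys[i] + u * ny[i]))
    bg <- stats::median(c(prof[seq_len(tail_n)], prof[(m - tail_n + 1):m]))
    j <- which.max(prof)
    # apex via log-quadratic through samples aligned to pixel centers
    # along the normal's dominant axis: those values are not flattened by
    # bilinear interpolation, so a Gaussian cross-section inverts exactly
    nd <- c(nx[i], ny[i]); dom <- which.max(abs(nd))
    pos <- c(xs[i], ys[i])
    peak_dom <- pos[dom] + u[j] * nd[dom]
    c0 <- round(peak_dom / px + 0.5)
    uk <- ((c0 + (-1:1) - 0.5) * px - pos[dom]) / nd[dom]
    pk <- NA_real_
    if (all(abs(uk) <= profile_halfwidth_nm)) {
      vk <- interp_height(image, cbind(pos[1] + uk * nx[i],
                                       pos[2] + uk * ny[i])) - bg
      if (all(vk > 0)) {
        lv <- log(vk)
        A <- cbind(uk^2, uk, 1)
        co <- solve(A, lv)
        if (co[1] < 0) pk <- exp(co[3] - co[2]^2 / (4 * co[1]))
      }
    }
    if (!is.finite(pk)) {   # fallback: plain quadratic on the fine profile
      if (j > 1 && j < m) {
        a <- (prof[j - 1] - 2 * prof[j] + prof[j + 1]) / 2
        b <- (prof[j + 1] - prof[j - 1]) / 2
        pk <- if (a < 0) prof[j] - b^2 / (4 * a) - bg else prof[j] - bg
      } else pk <- prof[j] - bg
    }
    samples[i] <- pk
  }
  list(mean_nm = mean(samples), sd_nm = stats::sd(samples), samples = samples)
}
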
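#' Ground-truth 2D polymer chains
#'
#' A `polymer2d` object stores an ordered polyline of vertex positions (nm)
#' for a single simulated molecule, together with the generator's ground
#' truth: the persistence length and contour length used to sample it, the
#' seed, and a free-text condition label.
#'
#' @param vertices two-column numeric matrix of (x, y) positions in nm.
#'   For closed chains the first and last rows coincide.
#' @param closed logical; is the chain covalently closed (circular)?
#' @param true_lp ground-truth persistence length in nm.
#' @param true_contour ground-truth contour length in nm.
#' @param seed integer seed the chain was sampled with.
#' @param label free-text condition name.
#' @return An object of class `polymer2d`.
#' @export
polymer2d <- function(vertices, closed, true_lp, true_contour, seed,
                      label = "") {
  vertices <- as.matrix(vertices)
  stopifnot(is.numeric(vertices), ncol(vertices) == 2, nrow(vertices) >= 2,
            all(is.finite(vertices)))
  obj <- structure(
    list(vertices = unname(vertices), closed = isTRUE(closed),
         true_lp = as.numeric(true_lp), true_contour = as.numeric(true_contour),
         seed = as.integer(seed), label = as.character(label)),
    class = "polymer2d")
  obj
}

#' @export
print.polymer2d <- function(x, ...) {
  cat(sprintf("polymer2d: %d vertices, %s, Lp = %.4g nm, contour = %.4g nm%s\n",
              nrow(x$vertices), if (x$closed) "closed" else "open",
              x$true_lp, x$true_contour,
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

#' Segment vectors and lengths of a polyline
#' @param vertices two-column matrix of points.
#' @return list with `vec` (n x 2 matrix) and `len` (numeric vector).
#' @keywords internal
segment_geometry <- function(vertices) {
  vec <- diff(vertices)
  list(vec = vec, len = sqrt(rowSums(vec^2)))
}

#' Total contour length of a polymer
#' @param polymer a `polymer2d`.
#' @return length in nm (includes the closing segment for closed chains,
#'   which is zero-length in the stored representation since the first
#'   vertex is repeated).
#' @export
polymer_contour_length <- function(polymer) {
  sum(segment_geometry(polymer$vertices)$len)
}

#' Signed turning angles along a polymer
#'
#' Angles between consecutive segment directions, wrapped to (-pi, pi].
#' For closed chains (first vertex repeated) the wrap-around turn between
#' the last and first segment is included, so the angles sum to +/- 2*pi
#' for a simple closed curve.
#'
#' @param polymer a `polymer2d`.
#' @return numeric vector of turning angles in rad.
#' @export
polymer_turning_angles <- function(polymer) {
  g <- segment_geometry(polymer$vertices)
  phi <- atan2(g$vec[, 2], g$vec[, 1])
  d <- diff(phi)
  if (polymer$closed) d <- c(d, phi[1] - phi[length(phi)])
  wrap_angle(d)
}

#' Wrap angles to (-pi, pi]
#' @param a numeric vector of angles in rad.
#' @keywords internal
wrap_angle <- function(a) {
  w <- a - 2 * pi * floor((a + pi) / (2 * pi))
  w[w <= -pi] <- pi  # boundary: map -pi to +pi
  w
}

#' Sample an open 2D worm-like chain
#'
#' Realizes a discrete worm-like chain equilibrated in two dimensions:
#' successive turning angles are independent zero-mean Gaussians with
#' variance `seg_len / lp`, which yields the tangent correlation
#' `<cos theta(L)> = exp(-L / (2 lp))` characteristic of 2D-equilibrated
#' semiflexible polymers.
#'
#' @param n_segments number of segments (vertices = n_segments + 1).
#' @param seg_len segment length in nm; must satisfy `seg_len <= lp / 4` so
#'   the Gaussian-increment discretization is faithful.
#' @param lp persistence length in nm.
#' @param seed integer seed; output is deterministic given the seed.
#' @param label condition label stored on the result.
#' @return a [polymer2d] with `true_contour = n_segments * seg_len`.
#' @export
sample_wlc_2d <- function(n_segments, seg_len, lp, seed, label = "wlc") {
  if (!is.numeric(lp) || lp <= 0 || !is.numeric(seg_len) || seg_len <= 0)
    stop("`lp` and `seg_len` must be positive", call. = FALSE)
  if (n_segments < 1) stop("`n_segments` must be >= 1", call. = FALSE)
  if (seg_len > lp / 4)
    stop("discretization too coarse: require seg_len <= lp / 4", call. = FALSE)
  n <- as.integer(n_segments)
  set.seed(as.integer(seed))
  phi0 <- stats::runif(1, 0, 2 * pi)
  theta <- stats::rnorm(n - 1, mean = 0, sd = sqrt(seg_len / lp))
  phi <- phi0 + cumsum(c(0, theta))
  verts <- rbind(c(0, 0),
                 cbind(cumsum(seg_len * cos(phi)), cumsum(seg_len * sin(phi))))
  polymer2d(verts, closed = FALSE, true_lp = lp,
            true_contour = n * seg_len, seed = seed, label = label)
}

#' Check that a polyline has no self-intersections
#'
#' Exact all-pairs segment intersection test (vectorized cross products),
#' skipping adjacent segments (and the wrap pair for closed curves).
#'
#' @param vertices two-column matrix; for closed curves repeat the first row.
#' @param closed logical.
#' @return TRUE if simple.
#' @keywords internal
is_simple_path <- function(vertices, closed = FALSE) {
  g <- segment_geometry(vertices)
  n <- nrow(g$vec)
  if (n < 3) return(TRUE)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  keep <- j - i > 1L
  if (closed) keep <- keep & !(i == 1L & j == n)
  i <- i[keep]; j <- j[keep]
  if (!length(i)) return(TRUE)
  p <- vertices[i, , drop = FALSE];  r <- g$vec[i, , drop = FALSE]
  q <- vertices[j, , drop = FALSE];  s <- g$vec[j, , drop = FALSE]
  # quick bounding-box rejection
  bb <- !(pmin(p[, 1], p[, 1] + r[, 1]) > pmax(q[, 1], q[, 1] + s[, 1]) |
          pmax(p[, 1], p[, 1] + r[, 1]) < pmin(q[, 1], q[, 1] + s[, 1]) |
          pmin(p[, 2], p[, 2] + r[, 2]) > pmax(q[, 2], q[, 2] + s[, 2]) |
          pmax(p[, 2], p[, 2] + r[, 2]) < pmin(q[, 2], q[, 2] + s[, 2]))
  if (!any(bb)) return(TRUE)
  p <- p[bb, , drop = FALSE]; r <- r[bb, , drop = FALSE]
  q <- q[bb, , drop = FALSE]; s <- s[bb, , drop = FALSE]
  cross <- function(a, b) a[, 1] * b[, 2] - a[, 2] * b[, 1]
  d <- cross(r, s)
  qp <- q - p
  t_num <- cross(qp, s)
  u_num <- cross(qp, r)
  nonpar <- abs(d) > 1e-12
  hit <- nonpar & t_num / d >= 0 & t_num / d <= 1 &
         u_num / d >= 0 & u_num / d <= 1
  hit[!nonpar] <- FALSE  # parallel segments: treat as non-crossing
  !any(hit, na.rm = TRUE)
}

#' Minimum distance between contour-distant vertices
#'
#' Used as a clearance criterion: vertices farther apart than
#' `exclude_nm` along the contour must be at least some spatial distance
#' apart for the rendered strands to stay resolvable.
#'
#' @keywords internal
min_nonlocal_distance <- function(vertices, closed, seg_len, exclude_nm) {
  v <- if (closed) vertices[-nrow(vertices), , drop = FALSE] else vertices
  n <- nrow(v)
  k <- ceiling(exclude_nm / seg_len)
  if (n <= 2 * k) return(Inf)
  d <- as.matrix(stats::dist(v))
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  if (closed) sep <- pmin(sep, n - sep)
  d[sep <= k] <- Inf
  min(d)
}

#' Sample a closed (circular) 2D worm-like chain
#'
#' Draws turning angles as in [sample_wlc_2d()], conditions them by a
#' Gaussian bridge so they sum to 2*pi, then closes the residual end-gap by
#' iteratively redistributing it over the segments while renormalizing every
#' segment back to the fixed segment length (quadratically convergent).
#' Chains whose initial per-segment correction would exceed half a segment
#' length, or that self-intersect, or that violate the optional clearance
#' criterion, are rejected and resampled from a derived seed.
#'
#' @inheritParams sample_wlc_2d
#' @param n_segments number of segments, at least 16.
#' @param max_tries rejection-sampling budget.
#' @param min_clearance_nm if positive, minimum spatial distance required
#'   between vertices more than ~4 segment lengths apart along the contour
#'   (keeps rendered strands resolvable); 0 disables the check.
#' @return a closed [polymer2d]; first and last vertices coincide exactly
#'   and every segment has length `seg_len` to within 1e-9 relative.
#' @export
sample_closed_wlc_2d <- function(n_segments, seg_len, lp, seed,
                                 label = "closed-wlc", max_tries = 200,
                                 min_clearance_nm = 0) {
  if (!is.numeric(lp) || lp <= 0 || !is.numeric(seg_len) || seg_len <= 0)
    stop("`lp` and `seg_len` must be positive", call. = FALSE)
  if (seg_len > lp / 4)
    stop("discretization too coarse: require seg_len <= lp / 4", call. = FALSE)
  n <- as.integer(n_segments)
  if (n < 16) stop("`n_segments` must be >= 16 for a closed chain", call. = FALSE)

  set.seed(as.integer(seed))
  try_seeds <- sample.int(.Machine$integer.max - 1L, max_tries)
  for (t in seq_len(max_tries)) {
    set.seed(try_seeds[t])
    theta <- stats::rnorm(n, 0, sqrt(seg_len / lp))
    theta <- theta + (2 * pi - sum(theta)) / n       # bridge: sum == 2*pi
    phi0 <- stats::runif(1, 0, 2 * pi)
    # Newton projection of the turning angles onto the position-closure
    # constraints, in the metric of the bridged prior (P = I - J/n): only
    # headings change, so segment lengths stay exactly seg_len and the
    # perturbation is spread according to the prior covariance instead of
    # distorting local bending statistics
    ok <- FALSE
    for (it in 1:50) {
      phi <- phi0 + cumsum(theta) - theta[1]          # theta[1] = wrap turn
      cs <- cos(phi); sn <- sin(phi)
      g <- seg_len * c(sum(cs), sum(sn))
      if (sqrt(sum(g^2)) < 1e-9 * seg_len) { ok <- TRUE; break }
      # Jacobian rows: dg/dtheta_k = seg_len * sum_{i >= k} (-sin, cos)
      rx <- rev(cumsum(rev(-sn))) * seg_len
      ry <- rev(cumsum(rev(cs))) * seg_len
      M <- rbind(c(0, rx[-1]), c(0, ry[-1]))          # theta[1] not in positions
      PMt <- t(M) - matrix(rowMeans(M), n, 2, byrow = TRUE)
      A <- M %*% PMt
      delta <- try(PMt %*% solve(A, -g), silent = TRUE)
      if (inherits(delta, "try-error")) break
      theta <- theta + as.numeric(delta)
    }
    if (!ok) next
    if (max(abs(theta)) > pi / 2) next                # grossly kinked: reject
    phi <- phi0 + cumsum(theta) - theta[1]
    seg <- seg_len * cbind(cos(phi), sin(phi))
    verts <- rbind(c(0, 0), cbind(cumsum(seg[, 1]), cumsum(seg[, 2])))
    verts[n + 1, ] <- verts[1, ]                      # snap sub-1e-9 residual
    if (!is_simple_path(verts, closed = TRUE)) next
    if (min_clearance_nm > 0 &&
        min_nonlocal_distance(verts, TRUE, seg_len,
                              exclude_nm = 2 * min_clearance_nm) <
          min_clearance_nm) next
    return(polymer2d(verts, closed = TRUE, true_lp = lp,
                     true_contour = n * seg_len, seed = seed, label = label))
  }
  stop(sprintf(
    "closed-chain sampling failed after %d tries (lp = %g nm, n_segments = %d)",
    max_tries, lp, n), call. = FALSE)
}

#' Sample an open chain subject to a clearance criterion
#'
#' Rejection wrapper around [sample_wlc_2d()] that discards conformations
#' with self-crossings or with contour-distant strands closer than
#' `min_clearance_nm`, emulating the selection of individually resolvable,
#' non-overlapping molecules on the mica surface.
#'
#' @inheritParams sample_closed_wlc_2d
#' @export
sample_wlc_2d_clear <- function(n_segments, seg_len, lp, seed,
                                label = "wlc", max_tries = 200,
                                min_clearance_nm = 0) {
  set.seed(as.integer(seed))
  try_seeds <- sample.int(.Machine$integer.max - 1L, max_tries)
  for (t in seq_len(max_tries)) {
    p <- sample_wlc_2d(n_segments, seg_len, lp, try_seeds[t], label = label)
    if (min_clearance_nm > 0) {
      if (!is_simple_path(p$vertices, closed = FALSE)) next
      if (min_nonlocal_distance(p$vertices, FALSE, seg_len,
                                exclude_nm = 2 * min_clearance_nm) <
            min_clearance_nm) next
    }
    p$seed <- as.integer(seed)
    return(p)
  }
  stop(sprintf("open-chain sampling failed after %d tries (lp = %g nm)",
               max_tries, lp), call. = FALSE)
}

#' Resample a polyline at uniform arc-length steps
#'
#' @param vertices two-column matrix of points (closed curves: first row
#'   repeated at the end).
#' @param step_nm arc step.
#' @param closed logical; closed curves are resampled at `n = round(L/step)`
#'   exactly uniform steps covering the whole loop; open curves at
#'   `0, step, 2 step, ...` with the true endpoint appended so no length is
#'   discarded.
#' @return two-column matrix of resampled points (closed: first point not
#'   repeated).
#' @keywords internal
resample_polyline <- function(vertices, step_nm, closed = FALSE) {
  g <- segment_geometry(vertices)
  s <- c(0, cumsum(g$len))
  L <- s[length(s)]
  if (closed) {
    npts <- max(4L, as.integer(round(L / step_nm)))
    targets <- (seq_len(npts) - 1) * L / npts
  } else {
    targets <- seq(0, L, by = step_nm)
    if (L - targets[length(targets)] > 1e-6 * step_nm) targets <- c(targets, L)
  }
  x <- stats::approx(s, vertices[, 1], xout = targets, ties = "ordered")$y
  y <- stats::approx(s, vertices[, 2], xout = targets, ties = "ordered")$y
  cbind(x, y)
}
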
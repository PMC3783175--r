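#' AFM height image container
#'
#' Height grid in nm with its pixel size. The physical position of the
#' (1-based) pixel `[r, c]` is `x = (c - 0.5) * pixel_nm`,
#' `y = (r - 0.5) * pixel_nm` (origin at the top-left image corner, y
#' increasing down rows).
#'
#' @param heights numeric matrix of heights in nm.
#' @param pixel_nm nm per pixel (> 0).
#' @return An object of class `afm_image`.
#' @export
afm_image <- function(heights, pixel_nm) {
  heights <- as.matrix(heights)
  stopifnot(is.numeric(heights), all(is.finite(heights)),
            is.numeric(pixel_nm), pixel_nm > 0)
  structure(list(heights = unname(heights), pixel_nm = as.numeric(pixel_nm)),
            class = "afm_image")
}

#' @export
print.afm_image <- function(x, ...) {
  cat(sprintf("afm_image: %d x %d px at %.3g nm/px, height range [%.3g, %.3g] nm\n",
              nrow(x$heights), ncol(x$heights), x$pixel_nm,
              min(x$heights), max(x$heights)))
  invisible(x)
}

#' Rendering parameters for synthetic AFM images
#'
#' DNA strands are drawn as Gaussian ridges (peak `ridge_height_nm`,
#' transverse s.d. `ridge_sigma_nm`) along the ground-truth polyline, then
#' blurred by an isotropic Gaussian of s.d. `tip_sigma_nm` emulating finite
#' tip sharpness, with optional free-protein background dots and additive
#' pixel noise.
#'
#' @param pixel_nm nm per pixel.
#' @param ridge_height_nm pre-blur peak height of the ridge, nm; must lie
#'   in `[0.3, 3]` (the span of bare to compacted DNA apparent heights).
#' @param ridge_sigma_nm transverse Gaussian width of the ridge, nm.
#' @param tip_sigma_nm tip-blur Gaussian s.d., nm.
#' @param noise_sd_nm additive i.i.d. Gaussian noise s.d., nm.
#' @param background_particles number of free-protein dots per image.
#' @param particle_height_nm peak height of background dots, nm.
#' @param particle_sigma_nm Gaussian s.d. of background dots, nm.
#' @param image_shape integer (rows, cols).
#' @return list of class `render_params`.
#' @export
render_params <- function(pixel_nm = 2, ridge_height_nm = 0.85,
                          ridge_sigma_nm = 2, tip_sigma_nm = 2,
                          noise_sd_nm = 0.05, background_particles = 0,
                          particle_height_nm = 1, particle_sigma_nm = 2,
                          image_shape = c(512L, 512L)) {
  p <- list(pixel_nm = pixel_nm, ridge_height_nm = ridge_height_nm,
            ridge_sigma_nm = ridge_sigma_nm, tip_sigma_nm = tip_sigma_nm,
            noise_sd_nm = noise_sd_nm,
            background_particles = as.integer(background_particles),
            particle_height_nm = particle_height_nm,
            particle_sigma_nm = particle_sigma_nm,
            image_shape = as.integer(image_shape))
  lens <- c(p$pixel_nm, p$ridge_sigma_nm, p$tip_sigma_nm, p$ridge_height_nm)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all rendering length scales must be positive", call. = FALSE)
  if (p$ridge_height_nm < 0.3 || p$ridge_height_nm > 3)
    stop("`ridge_height_nm` must lie in [0.3, 3] nm", call. = FALSE)
  if (p$noise_sd_nm < 0 || p$background_particles < 0)
    stop("noise s.d. and particle count must be non-negative", call. = FALSE)
  structure(p, class = "render_params")
}

#' Post-blur peak height of a rendered straight ridge
#'
#' A Gaussian ridge of peak `h` and width `sigma_r` convolved with an
#' isotropic Gaussian of width `sigma_t` remains Gaussian in the transverse
#' direction with width `sqrt(sigma_r^2 + sigma_t^2)` and peak
#' `h * sigma_r / sqrt(sigma_r^2 + sigma_t^2)`.
#'
#' @param params a [render_params].
#' @return effective (imaged) peak height in nm.
#' @export
effective_ridge_height <- function(params) {
  params$ridge_height_nm * params$ridge_sigma_nm /
    sqrt(params$ridge_sigma_nm^2 + params$tip_sigma_nm^2)
}

#' Pre-blur peak needed to image at a target apparent height
#' @param height_nm target imaged (post-blur) ridge peak, nm.
#' @param ridge_sigma_nm,tip_sigma_nm ridge and tip widths, nm.
#' @return pre-blur `ridge_height_nm`.
#' @export
preblur_ridge_height <- function(height_nm, ridge_sigma_nm = 2,
                                 tip_sigma_nm = 2) {
  height_nm * sqrt(ridge_sigma_nm^2 + tip_sigma_nm^2) / ridge_sigma_nm
}

#' Transverse half-width at half maximum of the imaged ridge
#' @param params a [render_params].
#' @return HWHM in nm.
#' @export
ridge_hwhm <- function(params) {
  sqrt(params$ridge_sigma_nm^2 + params$tip_sigma_nm^2) * sqrt(2 * log(2))
}

# Exact distance field from pixel centers to a polyline, evaluated only
# within `reach_nm` of the path (Inf elsewhere). Vertices in nm.
distance_field <- function(vertices, shape, pixel_nm, reach_nm) {
  nr <- shape[1]; nc <- shape[2]
  D <- matrix(Inf, nr, nc)
  xs <- (seq_len(nc) - 0.5) * pixel_nm
  ys <- (seq_len(nr) - 0.5) * pixel_nm
  reach_px <- ceiling(reach_nm / pixel_nm) + 1L
  g <- segment_geometry(vertices)
  for (i in seq_len(nrow(g$vec))) {
    a <- vertices[i, ]; v <- g$vec[i, ]; L2 <- sum(v^2)
    c_lo <- max(1L, floor(min(a[1], a[1] + v[1]) / pixel_nm) - reach_px)
    c_hi <- min(nc, ceiling(max(a[1], a[1] + v[1]) / pixel_nm) + reach_px)
    r_lo <- max(1L, floor(min(a[2], a[2] + v[2]) / pixel_nm) - reach_px)
    r_hi <- min(nr, ceiling(max(a[2], a[2] + v[2]) / pixel_nm) + reach_px)
    if (c_lo > c_hi || r_lo > r_hi) next
    px <- xs[c_lo:c_hi]; py <- ys[r_lo:r_hi]
    dx <- outer(py * 0, px - a[1], "+")      # (rows x cols) of x offsets
    dy <- outer(py - a[2], px * 0, "+")
    t <- if (L2 > 0) pmin(1, pmax(0, (dx * v[1] + dy * v[2]) / L2)) else 0
    d2 <- (dx - t * v[1])^2 + (dy - t * v[2])^2
    blk <- D[r_lo:r_hi, c_lo:c_hi]
    D[r_lo:r_hi, c_lo:c_hi] <- pmin(blk, d2)
  }
  sqrt(D)
}

# Separable Gaussian convolution (zero-padded borders), sigma in pixels.
gaussian_blur <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  r <- max(1L, ceiling(4 * sigma_px))
  k <- stats::dnorm(seq(-r, r), sd = sigma_px)
  k <- k / sum(k)
  n <- length(k)
  conv1 <- function(mat) {   # convolve along rows (dim 1)
    nr <- nrow(mat)
    pad <- rbind(matrix(0, r, ncol(mat)), mat, matrix(0, r, ncol(mat)))
    out <- matrix(0, nr, ncol(mat))
    for (j in seq_len(n)) out <- out + k[j] * pad[j:(j + nr - 1L), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(m))))
}

#' Render a polymer as a synthetic AFM height image
#'
#' The height map is the Gaussian-ridge profile of the polyline (peak
#' `ridge_height_nm`, transverse width `ridge_sigma_nm`; overlapping strands
#' combine by maximum), convolved with the Gaussian tip kernel, plus
#' optional background protein dots and i.i.d. Gaussian noise. Deterministic
#' for a fixed seed. The polymer is translated to the image center;
#' rendering fails if it cannot fit with a `3 * ridge_sigma` margin.
#'
#' @param polymer a [polymer2d] (or bare two-column matrix of nm points).
#' @param params a [render_params].
#' @param seed integer seed controlling noise and background dots.
#' @param height_scale multiplier applied to the ridge peak along the whole
#'   path (used internally, e.g. doubled interwound plectoneme bodies render
#'   at twice the single-strand height).
#' @return an [afm_image]; attribute `"vertices_nm"` carries the rendered
#'   (translated) ground-truth polyline in image coordinates.
#' @export
render_afm <- function(polymer, params, seed = 1L, height_scale = 1) {
  verts <- if (inherits(polymer, "polymer2d")) polymer$vertices else as.matrix(polymer)
  if (is.null(verts) || nrow(verts) < 2)
    stop("polymer must contain at least 2 vertices", call. = FALSE)
  shape <- params$image_shape
  ext_x <- range(verts[, 1]); ext_y <- range(verts[, 2])
  margin <- 3 * params$ridge_sigma_nm + 4 * params$tip_sigma_nm
  fw <- shape[2] * params$pixel_nm; fh <- shape[1] * params$pixel_nm
  if (diff(ext_x) + 2 * margin > fw || diff(ext_y) + 2 * margin > fh)
    stop("polymer does not fit in the image with the required margin",
         call. = FALSE)
  shift <- c(fw / 2 - mean(ext_x), fh / 2 - mean(ext_y))
  v <- sweep(verts, 2, shift, "+")

  reach <- 4 * params$ridge_sigma_nm
  D <- distance_field(v, shape, params$pixel_nm, reach)
  H <- height_scale * params$ridge_height_nm *
    exp(-pmin(D, reach)^2 / (2 * params$ridge_sigma_nm^2))
  H[D >= reach] <- 0

  set.seed(as.integer(seed))
  if (params$background_particles > 0) {
    for (b in seq_len(params$background_particles)) {
      pc <- c(stats::runif(1, margin, fw - margin),
              stats::runif(1, margin, fh - margin))
      Dp <- distance_field(rbind(pc, pc + 1e-9), shape, params$pixel_nm,
                           4 * params$particle_sigma_nm)
      Hp <- params$particle_height_nm *
        exp(-pmin(Dp, 4 * params$particle_sigma_nm)^2 /
              (2 * params$particle_sigma_nm^2))
      Hp[!is.finite(Hp)] <- 0
      H <- pmax(H, Hp)
    }
  }
  H <- gaussian_blur(H, params$tip_sigma_nm / params$pixel_nm)
  if (params$noise_sd_nm > 0)
    H <- H + matrix(stats::rnorm(length(H), 0, params$noise_sd_nm),
                    nrow(H), ncol(H))
  img <- afm_image(H, params$pixel_nm)
  attr(img, "vertices_nm") <- v
  img
}
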
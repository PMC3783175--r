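# Condition-level generators: paired ground truth + rendered images for a
# named experimental condition, plectonemic supercoils, and compacted
# molecules.

# Deterministic per-item seed streams derived from one master seed.
derive_seeds <- function(master_seed, n, stream = 1L) {
  set.seed(as.integer(master_seed) + 77777L * as.integer(stream))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Describe a simulated imaging condition
#'
#' @param n_molecules number of molecules (>= 1).
#' @param lp_nm ground-truth persistence length, nm.
#' @param contour_nm ground-truth contour length, nm.
#' @param height_nm imaged (post-blur) ridge peak height, nm — e.g. 0.6 for
#'   bare DNA, ~1.0 for a protein-coated filament.
#' @param closed circular molecules?
#' @param label condition name.
#' @param seg_len_nm internal generator segment length, nm.
#' @param min_clearance_nm strand clearance enforced by rejection, nm.
#' @return list of class `afm_condition`.
#' @export
afm_condition <- function(n_molecules, lp_nm = 56, contour_nm = 328,
                          height_nm = 0.6, closed = FALSE, label = "condition",
                          seg_len_nm = 2, min_clearance_nm = 12) {
  if (n_molecules < 1) stop("`n_molecules` must be >= 1", call. = FALSE)
  if (lp_nm <= 0 || contour_nm <= 0 || height_nm <= 0)
    stop("condition parameters must be positive", call. = FALSE)
  structure(list(n_molecules = as.integer(n_molecules), lp_nm = lp_nm,
                 contour_nm = contour_nm, height_nm = height_nm,
                 closed = isTRUE(closed), label = label,
                 seg_len_nm = seg_len_nm,
                 min_clearance_nm = min_clearance_nm),
            class = "afm_condition")
}

#' Reference imaging conditions
#'
#' `condition_bare_dna()`: 1000 bp linear DNA, contour 328 nm, Lp 56 nm,
#' imaged height 0.6 nm. `condition_coated_dna()`: the fully protein-coated
#' filament after long incubation — contour 347 nm, imaged height 1.0 nm.
#' `condition_relaxed_circle()`: relaxed circular plasmid-scale DNA,
#' contour 856 nm, closed.
#'
#' @param n_molecules number of molecules.
#' @return an [afm_condition].
#' @export
condition_bare_dna <- function(n_molecules = 30) {
  afm_condition(n_molecules, lp_nm = 56, contour_nm = 328, height_nm = 0.6,
                closed = FALSE, label = "bare-dna")
}

#' @rdname condition_bare_dna
#' @export
condition_coated_dna <- function(n_molecules = 30) {
  afm_condition(n_molecules, lp_nm = 56, contour_nm = 347, height_nm = 1.0,
                closed = FALSE, label = "coated-2h")
}

#' @rdname condition_bare_dna
#' @export
condition_relaxed_circle <- function(n_molecules = 30) {
  afm_condition(n_molecules, lp_nm = 56, contour_nm = 856, height_nm = 0.6,
                closed = TRUE, label = "relaxed-circle")
}

#' Generate a paired ground-truth / image ensemble for a condition
#'
#' Per-molecule seeds are derived deterministically from the master seed,
#' so two calls with the same arguments are identical.
#'
#' @param condition an [afm_condition] (or list with the same fields).
#' @param seed master seed.
#' @param params a [render_params]; its `ridge_height_nm` is overridden so
#'   the imaged peak equals the condition's `height_nm`.
#' @return list of `list(polymer, image)` pairs, length `n_molecules`.
#' @export
make_condition_ensemble <- function(condition, seed, params = render_params()) {
  if (condition$n_molecules < 1)
    stop("`n_molecules` must be >= 1", call. = FALSE)
  params$ridge_height_nm <- preblur_ridge_height(
    condition$height_nm, params$ridge_sigma_nm, params$tip_sigma_nm)
  n_seg <- as.integer(round(condition$contour_nm / condition$seg_len_nm))
  chain_seeds <- derive_seeds(seed, condition$n_molecules, stream = 1L)
  noise_seeds <- derive_seeds(seed, condition$n_molecules, stream = 2L)
  out <- vector("list", condition$n_molecules)
  for (i in seq_len(condition$n_molecules)) {
    poly <- if (condition$closed) {
      sample_closed_wlc_2d(n_seg, condition$seg_len_nm, condition$lp_nm,
                           chain_seeds[i], label = condition$label,
                           min_clearance_nm = condition$min_clearance_nm)
    } else {
      sample_wlc_2d_clear(n_seg, condition$seg_len_nm, condition$lp_nm,
                          chain_seeds[i], label = condition$label,
                          min_clearance_nm = condition$min_clearance_nm)
    }
    img <- render_afm(poly, params, seed = noise_seeds[i])
    out[[i]] <- list(polymer = poly, image = img)
  }
  out
}

# Heading/positions of a gently curved axis path of length `len_nm`,
# sampled every `ds` nm. Curvature is a low-frequency sine so the axis
# stays far from self-contact.
curved_axis <- function(len_nm, ds = 1, bend_amp = 0.004, seed = 1L) {
  set.seed(as.integer(seed))
  s <- seq(0, len_nm, by = ds)
  psi0 <- stats::runif(1, 0, 2 * pi)
  psi <- psi0 + bend_amp * len_nm / (2 * pi) *
    sin(2 * pi * s / len_nm + stats::runif(1, 0, 2 * pi))
  x <- c(0, cumsum(ds * cos(psi[-1])))
  y <- c(0, cumsum(ds * sin(psi[-1])))
  cbind(x, y)
}

#' Generate a plectonemic (interwound) molecule and its image
#'
#' Builds a gently curved superhelical axis of length
#' `axis_ratio * contour_nm`, winds two strands about it, closes the ends
#' with apical loops, and renders the interwound body at twice the
#' single-strand ridge height (two stacked duplexes) with the loops at
#' single height. The construction's true axis length is recorded.
#'
#' @param contour_nm DNA contour length, nm.
#' @param axis_ratio superhelical-axis-to-contour ratio, in `[0.2, 0.5]`.
#' @param seed integer seed.
#' @param params a [render_params]; `ridge_height_nm` is interpreted as the
#'   pre-blur single-strand peak.
#' @param wind_amp_nm winding amplitude of the strands about the axis, nm.
#' @param wind_period_nm winding period along the axis, nm.
#' @return list with `axis_nm` (truth), `axis_path`, `strands` (list of
#'   point matrices), `image`, `contour_nm`.
#' @export
generate_plectoneme <- function(contour_nm, axis_ratio, seed = 1L,
                                params = render_params(ridge_height_nm = 0.85),
                                wind_amp_nm = 2.5, wind_period_nm = 30) {
  if (axis_ratio < 0.2 || axis_ratio > 0.5)
    stop("`axis_ratio` must lie in [0.2, 0.5]", call. = FALSE)
  axis_len <- axis_ratio * contour_nm
  ax <- curved_axis(axis_len, ds = 1, seed = seed)
  s <- seq(0, axis_len, length.out = nrow(ax))
  tang <- path_tangents(ax, closed = FALSE)
  nrm <- cbind(-tang[, 2], tang[, 1])
  off1 <- wind_amp_nm * sin(2 * pi * s / wind_period_nm)
  strand1 <- ax + off1 * nrm
  strand2 <- ax - off1 * nrm
  # apical loops: semicircles of radius ~ loop_r closing each end
  loop_r <- 7
  mkloop <- function(endpt, t_out, n_side) {
    ang0 <- atan2(n_side[2], n_side[1])
    th <- seq(ang0, ang0 - pi, length.out = 25)
    ctr <- endpt + loop_r * t_out
    sweep(loop_r * cbind(cos(th), sin(th)), 2, ctr, "+")
  }
  n_end <- nrow(ax)
  loopA <- mkloop(ax[1, ], -tang[1, ], nrm[1, ])
  loopB <- mkloop(ax[n_end, ], tang[n_end, ], nrm[n_end, ])

  shape <- params$image_shape
  px <- params$pixel_nm
  allpts <- rbind(strand1, strand2, loopA, loopB)
  fw <- shape[2] * px; fh <- shape[1] * px
  shift <- c(fw / 2 - mean(range(allpts[, 1])), fh / 2 - mean(range(allpts[, 2])))
  sh <- function(m) sweep(m, 2, shift, "+")
  reach <- 4 * params$ridge_sigma_nm
  Dbody <- pmin(distance_field(sh(strand1), shape, px, reach),
                distance_field(sh(strand2), shape, px, reach))
  Dloop <- pmin(distance_field(sh(loopA), shape, px, reach),
                distance_field(sh(loopB), shape, px, reach))
  h1 <- params$ridge_height_nm
  ridge <- function(D, h) { z <- h * exp(-pmin(D, reach)^2 /
                                           (2 * params$ridge_sigma_nm^2))
                            z[D >= reach] <- 0; z }
  H <- pmax(ridge(Dbody, 2 * h1), ridge(Dloop, h1))
  H <- gaussian_blur(H, params$tip_sigma_nm / px)
  set.seed(as.integer(seed))
  if (params$noise_sd_nm > 0)
    H <- H + matrix(stats::rnorm(length(H), 0, params$noise_sd_nm),
                    nrow(H), ncol(H))
  list(axis_nm = axis_len, axis_path = sh(ax),
       strands = list(sh(strand1), sh(strand2), sh(loopA), sh(loopB)),
       image = afm_image(H, px), contour_nm = contour_nm)
}

#' Generate a compacted (collapsed rod) molecule image
#'
#' Renders the compact morphology of a fully collapsed molecule as a
#' filled rounded rectangle (capsule) of the given length, width and
#' plateau height, blurred by the tip kernel — used to exercise the
#' compact-class filter; the internal structure of such particles is not
#' modelled.
#'
#' @param length_nm,width_nm,height_nm capsule dimensions (defaults 45 x 17
#'   nm at 1.5 nm plateau height).
#' @param seed integer seed (noise).
#' @param params a [render_params].
#' @return list with `image` and the true dimensions.
#' @export
generate_compact <- function(length_nm = 45, width_nm = 17, height_nm = 1.5,
                             seed = 1L, params = render_params()) {
  shape <- params$image_shape; px <- params$pixel_nm
  fw <- shape[2] * px; fh <- shape[1] * px
  half_core <- max(0, (length_nm - width_nm) / 2)
  a <- c(fw / 2 - half_core, fh / 2)
  b <- c(fw / 2 + half_core, fh / 2)
  D <- distance_field(rbind(a, b), shape, px, reach_nm = width_nm)
  H <- ifelse(D <= width_nm / 2, height_nm, 0)
  H <- gaussian_blur(H, params$tip_sigma_nm / px)
  set.seed(as.integer(seed))
  if (params$noise_sd_nm > 0)
    H <- H + matrix(stats::rnorm(length(H), 0, params$noise_sd_nm),
                    nrow(H), ncol(H))
  list(image = afm_image(H, px), length_nm = length_nm, width_nm = width_nm,
       height_nm = height_nm)
}
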
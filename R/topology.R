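# Topology classification, superhelical-axis measurement and
# twist/writhe/linking-number bookkeeping.

#' Classify the topology of a segmented molecule
#'
#' Decision rule: mean mask height above `compact_height_nm` is `compact`
#' (collapsed molecules image far higher than a single duplex); otherwise
#' the pruned skeleton decides — any branch point, or a body imaging above
#' `plectoneme_factor` times the single-strand height (two interwound
#' duplexes stack), is `plectoneme`; 0 endpoints is `open_circle`;
#' 2 endpoints is `linear`. A skeleton with exactly one endpoint is
#' ambiguous and raises an error.
#'
#' Contour length is traced for linear and open-circle molecules; for
#' plectonemes the DNA contour cannot be recovered from the projected
#' image, so `contour_nm` is `NA` unless supplied, and the superhelical
#' axis length is measured instead.
#'
#' Sign convention note: for closed DNA, protein-induced *unwinding*
#' (negative twist change) at fixed linking number converts into
#' *positive* writhe — see [unwinding_model()].
#'
#' @param image an [afm_image].
#' @param region a `molecule_region` from [segment_molecules()].
#' @param single_height_nm calibrated imaged height of a single duplex
#'   strand, nm.
#' @param compact_height_nm compact-class plateau-height threshold, nm.
#' @param compact_max_len_nm maximum skeletal length of a compact particle,
#'   nm (collapsed particles are short as well as tall; extended interwound
#'   bodies of similar height are not compact).
#' @param plectoneme_factor doubled-body detection factor (default 1.6).
#' @param step_nm trace step for contour measurement, nm.
#' @param contour_nm optional known DNA contour length, nm (used for the
#'   axis ratio of plectonemes).
#' @return object of class `topology_report` with fields `molecule_id`,
#'   `class`, `contour_nm`, `axis_nm`, `axis_ratio`, `n_branches`.
#' @export
classify_topology <- function(image, region, single_height_nm = 0.6,
                              compact_height_nm = 1.2,
                              plectoneme_factor = 1.6, step_nm = 8,
                              contour_nm = NA_real_,
                              compact_max_len_nm = 100) {
  cls <- NULL
  axis_nm <- NA_real_
  traced_contour <- NA_real_
  n_branches <- region$n_junctions
  if (region$mean_height_nm > compact_height_nm &&
      region$skel_len_nm < compact_max_len_nm) {
    cls <- "compact"
  } else {
    # ridge height along the skeleton: doubled-body check
    ridge_h <- stats::median(image$heights[region$skeleton])
    doubled <- ridge_h > plectoneme_factor * single_height_nm
    if (region$n_endpoints == 1 && region$n_junctions == 0 && !doubled)
      stop("ambiguous skeleton: one endpoint", call. = FALSE)
    if (region$n_junctions >= 1 || doubled) {
      cls <- "plectoneme"
      pl_region <- region
      pl_region$class_hint <- "plectoneme"
      axis_nm <- tryCatch(
        measure_superhelical_axis(image, pl_region,
                                  single_height_nm = single_height_nm),
        error = function(e) NA_real_)
    } else if (region$n_endpoints == 0) {
      cls <- "open_circle"
    } else {
      cls <- "linear"
    }
    if (cls %in% c("linear", "open_circle")) {
      tr_region <- region
      tr_region$class_hint <- if (cls == "linear") "linear" else "circular"
      traced_contour <- tryCatch(
        measure_contour_length(trace_backbone(image, tr_region, step_nm)),
        error = function(e) NA_real_)
    }
  }
  contour_out <- if (!is.na(traced_contour)) traced_contour else contour_nm
  ratio <- if (!is.na(axis_nm) && !is.na(contour_out) && contour_out > 0)
    axis_to_contour_ratio(axis_nm, contour_out) else NA_real_
  structure(list(molecule_id = region$molecule_id, class = cls,
                 contour_nm = contour_out, axis_nm = axis_nm,
                 axis_ratio = ratio, n_branches = n_branches),
            class = "topology_report")
}

#' @export
print.topology_report <- function(x, ...) {
  cat(sprintf(
    "topology_report %s: %s, contour %.4g nm, axis %.4g nm, ratio %.4g, %d branch point(s)\n",
    x$molecule_id, x$class, x$contour_nm, x$axis_nm, x$axis_ratio,
    x$n_branches))
  invisible(x)
}

#' Measure the superhelical axis length of a plectoneme
#'
#' The interwound body images at roughly twice the single-strand height, so
#' thresholding well above the single-strand level isolates it; the
#' skeleton of that body is the superhelical axis. Its length is the total
#' weight of a minimum spanning tree of the skeleton pixel graph (exact for
#' a simple path, summing branch paths for branched plectonemes), plus an
#' end-cap correction of one transverse half-width per skeleton endpoint.
#' Apical end loops image at single height and are excluded by the
#' threshold.
#'
#' @param image an [afm_image].
#' @param region a `molecule_region` (plectoneme candidate).
#' @param single_height_nm calibrated single-strand imaged height, nm.
#' @param body_factor body threshold as a multiple of the single height.
#' @param axis_smooth_nm smoothing scale for the ordered axis path, nm;
#'   should exceed the apparent strand-winding period and stay well below
#'   the axis length.
#' @return axis length in nm.
#' @export
measure_superhelical_axis <- function(image, region, single_height_nm = 0.6,
                                      body_factor = 1.4,
                                      axis_smooth_nm = 30) {
  if (region$class_hint %in% c("circular", "linear", "compact"))
    stop("superhelical axis is only defined for plectonemes", call. = FALSE)
  body <- region$mask & image$heights > body_factor * single_height_nm
  if (!any(body)) stop("no interwound body above the doubled-height threshold",
                       call. = FALSE)
  S0 <- skeletonize_mask(body)
  # spurs shorter than the body half-width are thinning artifacts of the
  # wide interwound band, not branches
  hw_px0 <- max(3L, ceiling(sum(body) / max(1, sum(S0)) / 2) + 2L)
  S <- prune_skeleton(S0, hw_px0)
  if (!any(S)) stop("plectoneme body produced an empty skeleton",
                    call. = FALSE)
  n_ep <- sum(S & skel_degree(S) == 1)
  n_jn <- sum(S & skel_crossing(S) >= 3)
  px <- image$pixel_nm
  len_nm <- NA_real_
  if (n_ep <= 2 && n_jn == 0) {
    # simple body: order the skeleton and measure the *smoothed* path, so
    # residual weaving of the medial axis at the strand-winding scale does
    # not inflate the axis length
    ord <- tryCatch(order_skeleton(S), error = function(e) NULL)
    if (!is.null(ord)) {
      pts <- cbind((ord$path[, 2] - 0.5) * px, (ord$path[, 1] - 0.5) * px)
      w <- max(3L, 2L * floor(axis_smooth_nm / px / 2) + 1L)
      raw <- pts
      pts <- smooth_path(pts, ord$closed, window = w)
      if (!ord$closed) {   # re-anchor ends: edge replication pulls them in
        pts[1, ] <- raw[1, ]
        pts[nrow(pts), ] <- raw[nrow(raw), ]
      }
      poly <- if (ord$closed) rbind(pts, pts[1, ]) else pts
      len_nm <- sum(sqrt(rowSums(diff(poly)^2)))
    }
  }
  if (is.na(len_nm)) len_nm <- skel_length_px(S) * px  # branched fallback
  # end-cap correction: the medial axis of a capsule stops one cap radius
  # short of the mask end at each endpoint
  hw_px <- sum(body) / max(1, skel_length_px(S)) / 2   # mean half-width
  len_nm + n_ep * hw_px * px
}

#' Superhelical-axis-to-contour ratio
#'
#' @param axis_nm superhelical axis length, nm.
#' @param contour_nm DNA contour length, nm.
#' @return the ratio, rounded to two decimals (the precision at which it is
#'   conventionally reported); invariant under common rescaling.
#' @export
axis_to_contour_ratio <- function(axis_nm, contour_nm) {
  if (!is.finite(axis_nm) || !is.finite(contour_nm) ||
      axis_nm <= 0 || contour_nm <= 0)
    stop("axis and contour lengths must be positive", call. = FALSE)
  round(axis_nm / contour_nm, 2)
}

#' Linking-number bookkeeping state
#'
#' Enforces White's relation `dLk = dTw + Wr` as an exact identity.
#'
#' @param n_bp base pairs in the circle.
#' @param pitch_bp_per_turn helical pitch, bp per turn.
#' @param d_tw twist change, turns.
#' @param wr writhe, turns.
#' @param d_lk linking-number change, turns.
#' @return object of class `linking_state` with `lk0 = n_bp / pitch`.
#' @export
linking_state <- function(n_bp, pitch_bp_per_turn, d_tw, wr, d_lk) {
  if (abs(d_lk - (d_tw + wr)) > 1e-12 * max(1, abs(d_lk)))
    stop("White's relation dLk = dTw + Wr violated", call. = FALSE)
  structure(list(lk0 = n_bp / pitch_bp_per_turn, d_lk = d_lk, d_tw = d_tw,
                 wr = wr, n_bp = as.integer(n_bp),
                 pitch_bp_per_turn = pitch_bp_per_turn),
            class = "linking_state")
}

#' @export
print.linking_state <- function(x, ...) {
  cat(sprintf(
    "linking_state: Lk0 = %.2f, dLk = %+.3f, dTw = %+.3f, Wr = %+.3f turns (%d bp at %.3g bp/turn)\n",
    x$lk0, x$d_lk, x$d_tw, x$wr, x$n_bp, x$pitch_bp_per_turn))
  invisible(x)
}

#' Duplex-unwinding bookkeeping for bound protein dimers
#'
#' Pure arithmetic, no mechanics: each bound dimer unwinds the duplex by
#' `unwind_deg_per_dimer` degrees over its `footprint_bp` base-pair site
#' and stretches each covered base pair by `d_rise_nm_per_bound_bp`.
#' For a covalently closed chain the linking number is fixed (`dLk = 0`)
#' and the twist change converts entirely into writhe (`Wr = -dTw`:
#' unwinding, negative `dTw`, gives positive writhe — interwinding of a
#' previously relaxed circle). For a nicked or linear chain the twist
#' change relaxes freely (`Wr = 0`, `dLk = dTw`).
#'
#' The fractional contour extension is
#' `occupancy * d_rise_nm_per_bound_bp / rise_nm_per_bp` with
#' `occupancy = n_bound_dimers * footprint_bp / n_bp`.
#'
#' @param n_bp base pairs.
#' @param pitch_bp_per_turn helical pitch (default 10.5 bp/turn).
#' @param n_bound_dimers bound protein dimers.
#' @param unwind_deg_per_dimer unwinding angle per dimer, degrees.
#' @param rise_nm_per_bp axial rise, nm/bp (default 0.34).
#' @param d_rise_nm_per_bound_bp rise change per covered bp, nm.
#' @param footprint_bp binding-site size, bp (default 9).
#' @param closed covalently closed (fixed Lk)?
#' @return list with `linking` (a [linking_state]) and
#'   `extension_fraction`.
#' @export
unwinding_model <- function(n_bp, pitch_bp_per_turn = 10.5,
                            n_bound_dimers = 0, unwind_deg_per_dimer = 0,
                            rise_nm_per_bp = 0.34,
                            d_rise_nm_per_bound_bp = 0, footprint_bp = 9,
                            closed = TRUE) {
  occupancy <- n_bound_dimers * footprint_bp / n_bp
  if (occupancy > 1 + 1e-12)
    stop("occupancy exceeds 1: too many dimers for the chain", call. = FALSE)
  if (n_bound_dimers < 0) stop("negative dimer count", call. = FALSE)
  d_tw <- -n_bound_dimers * unwind_deg_per_dimer / 360
  if (closed) {
    d_lk <- 0; wr <- -d_tw
  } else {
    wr <- 0; d_lk <- d_tw
  }
  list(linking = linking_state(n_bp, pitch_bp_per_turn, d_tw, wr, d_lk),
       extension_fraction = occupancy * d_rise_nm_per_bound_bp / rise_nm_per_bp,
       occupancy = occupancy)
}
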
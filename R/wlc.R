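#' Tangent-tangent correlation of traced molecules
#'
#' For tangents (unit vectors of consecutive resampled segments) separated
#' by arc length `L = k * step_nm`, averages `cos(theta)` over all valid
#' position pairs pooled across molecules (each pair weighted equally).
#' Closed traces contribute wrap-around pairs. Standard errors are
#' between-molecule jackknife estimates.
#'
#' For a polymer equilibrated in two dimensions the curve decays as
#' `exp(-L / (2 Lp))`.
#'
#' @param traces list of [trace_result] sharing one `step_nm`.
#' @param max_sep_nm largest separation retained, nm.
#' @return object of class `correlation_curve` with fields `sep_nm`,
#'   `mean_corr`, `n_pairs`, `se`, `step_nm`, `n_molecules`.
#' @export
tangent_correlation <- function(traces, max_sep_nm = 200) {
  if (inherits(traces, "trace_result")) traces <- list(traces)
  if (length(traces) == 0) stop("no traces supplied", call. = FALSE)
  steps <- vapply(traces, function(t) t$step_nm, numeric(1))
  if (diff(range(steps)) > 1e-6 * steps[1])
    stop("all traces must share the same step_nm", call. = FALSE)
  step <- steps[1]
  kmax <- max(1L, floor(max_sep_nm / step))
  m <- length(traces)
  sums <- matrix(0, m, kmax + 1L)   # per-molecule sum of cos over pairs
  cnts <- matrix(0, m, kmax + 1L)
  for (j in seq_len(m)) {
    tr <- traces[[j]]
    p <- if (tr$closed) rbind(tr$points, tr$points[1, ]) else tr$points
    g <- segment_geometry(p)
    phi <- atan2(g$vec[, 2], g$vec[, 1])
    n <- length(phi)
    sums[j, 1] <- n; cnts[j, 1] <- n          # L = 0: cos(0) per tangent
    for (k in seq_len(kmax)) {
      if (tr$closed) {
        if (k >= n) break
        dphi <- phi[((seq_len(n) + k - 1L) %% n) + 1L] - phi
      } else {
        if (k > n - 1L) break
        dphi <- phi[(1L + k):n] - phi[1L:(n - k)]
      }
      sums[j, k + 1L] <- sum(cos(dphi))
      cnts[j, k + 1L] <- length(dphi)
    }
  }
  tot_n <- colSums(cnts)
  keep <- which(tot_n > 0)
  mc <- colSums(sums)[keep] / tot_n[keep]
  # between-molecule jackknife on the pooled ratio estimator
  se <- rep(NA_real_, length(keep))
  if (m >= 2) {
    for (ii in seq_along(keep)) {
      kk <- keep[ii]
      if (sum(cnts[, kk] > 0) < 2) next
      loo <- (sum(sums[, kk]) - sums[, kk]) / (sum(cnts[, kk]) - cnts[, kk])
      loo <- loo[is.finite(loo)]
      g <- length(loo)
      se[ii] <- sqrt((g - 1) / g * sum((loo - mean(loo))^2))
    }
  }
  # for an all-circular ensemble, record the mean closed contour length:
  # closure modifies the decay law (deterministic winding + bridge variance)
  closed_contour <- NA_real_
  if (all(vapply(traces, function(t) t$closed, logical(1))))
    closed_contour <- mean(vapply(traces, measure_contour_length, numeric(1)))
  chords <- vapply(traces, function(t)
    if (is.null(t$tangent_chord_nm)) t$step_nm else t$tangent_chord_nm,
    numeric(1))
  structure(list(sep_nm = (keep - 1L) * step, mean_corr = mc,
                 n_pairs = tot_n[keep], se = se, step_nm = step,
                 n_molecules = m, closed_contour_nm = closed_contour,
                 chord_step_nm = max(chords)),
            class = "correlation_curve")
}

# Ring-closure variance factor gamma(x), x = L/C: the variance of the net
# tangent angle over arc L of a closed chain is (L/Lp) * gamma(L/C).
# Closure conditions the turning angles on (i) their sum (2 pi) and (ii)
# the two linearized position-closure functionals (the first Fourier modes
# of the heading fluctuation). Computed once by covariance algebra on a
# fine discretization and memoized; position-independent by ring symmetry.
.gamma_cache <- new.env(parent = emptyenv())
ring_gamma <- function(x) {
  key <- "g400"
  if (!exists(key, envir = .gamma_cache)) {
    n <- 400L
    P <- diag(n) - 1 / n                      # sum-bridge covariance (unit rate)
    phi <- 2 * pi * seq_len(n) / n
    # d(closure)/d(theta_k) ~ sum_{i >= k} (-sin phi_i, cos phi_i)
    M <- rbind(rev(cumsum(rev(-sin(phi)))), rev(cumsum(rev(cos(phi)))))
    PMt <- P %*% t(M)
    W <- t(M) %*% solve(M %*% PMt, M)         # M' (M P M')^-1 M
    ks <- seq_len(n - 1L)
    g <- vapply(ks, function(k) {
      l <- c(rep(1, k), rep(0, n - k))        # window functional
      lP <- as.numeric(P %*% l)
      v <- sum(l * lP) - as.numeric(t(lP) %*% W %*% lP)
      v / k
    }, numeric(1))
    assign(key, stats::approxfun(c(0, ks / n, 1), c(1, g, 0), rule = 2),
           envir = .gamma_cache)
  }
  get(key, envir = .gamma_cache)(x)
}

#' Construct a correlation curve from explicit values
#'
#' Mainly useful for analytic curves (e.g. exact exponentials) fed to
#' [fit_persistence_length()].
#'
#' @param sep_nm separations, nm (must include regular multiples of
#'   `step_nm`).
#' @param mean_corr mean cosine values in `[-1, 1]`.
#' @param step_nm underlying trace step, nm.
#' @param n_pairs pair counts (defaults to 1 per bin).
#' @param se standard errors (defaults to `NA`: equal fit weights).
#' @param n_molecules number of molecules represented.
#' @param chord_step_nm chord length of the tangent estimates (0 for exact
#'   analytic correlations; see [fit_persistence_length()]).
#' @return a `correlation_curve`.
#' @export
correlation_curve <- function(sep_nm, mean_corr, step_nm,
                              n_pairs = rep(1L, length(sep_nm)),
                              se = rep(NA_real_, length(sep_nm)),
                              n_molecules = 1L, chord_step_nm = 0) {
  stopifnot(length(sep_nm) == length(mean_corr),
            all(mean_corr >= -1 - 1e-12 & mean_corr <= 1 + 1e-12))
  structure(list(sep_nm = sep_nm, mean_corr = mean_corr, n_pairs = n_pairs,
                 se = se, step_nm = step_nm, n_molecules = n_molecules,
                 closed_contour_nm = NA_real_,
                 chord_step_nm = chord_step_nm),
            class = "correlation_curve")
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat(sprintf(
    "correlation_curve: %d separations (0..%.0f nm), %d molecules, %d pairs at L = step\n",
    length(x$sep_nm), max(x$sep_nm), x$n_molecules,
    if (length(x$n_pairs) > 1) x$n_pairs[2] else NA_integer_))
  invisible(x)
}

#' Fit the 2D worm-like-chain persistence length
#'
#' Weighted nonlinear least squares of the correlation curve against
#' `exp(-L / (2 Lp))`, the decay of an open worm-like chain equilibrated in
#' two dimensions. For a curve computed from an all-circular ensemble
#' (closed contour `C` recorded on the curve) the closure-corrected form
#' `cos(2 pi L / C) * exp(-(L / (2 Lp)) (1 - L / C))` is fitted instead:
#' going around a closed loop the tangent must wind by 2 pi (the cosine
#' factor) and the angular fluctuations are bridge-constrained (the
#' `1 - L/C` factor), so fitting the open-chain form to circles
#' underestimates Lp.
#'
#' Tangents measured from a trace are chords of length `step_nm`, i.e.
#' averages of the underlying headings over one step, and the traced path
#' is additionally smoothed by the tip blur. Both suppress short-wavelength
#' bending, so the net angle between two chord tangents at separation `L`
#' has variance `(L - L0) / Lp` with a dead-zone offset `L0` (of order
#' `step/3` for pure chord averaging, larger with blur) instead of
#' `L / Lp`. The lifted short-separation bins carry most of the fit weight,
#' so ignoring `L0` inflates Lp substantially. For curves measured from
#' chord tangents (`chord_step_nm > 0`) `L0` is therefore fitted as a
#' nuisance parameter (bounded to `[0, 2 step]`) and Lp is carried by the
#' decay constant alone; analytic or native-resolution curves
#' (`chord_step_nm = 0`) are fitted with `L0 = 0` and invert exactly.
#'
#' Weights are `1/se^2` where jackknife standard errors are available
#' (equal weights otherwise). The starting value comes from a log-linear
#' prefit; when `fit_range` is `NULL` it defaults to
#' `(step_nm, 2 * prefit Lp)` since long-separation bins are sparse and
#' noisy.
#'
#' @param curve a `correlation_curve`.
#' @param fit_range numeric `(Lmin, Lmax)` in nm, or `NULL` for the
#'   default.
#' @return object of class `pl_fit` with `lp`, `lp_se`, `fit_range`,
#'   `residual_rms`, `n_molecules`.
#' @export
fit_persistence_length <- function(curve, fit_range = NULL) {
  L <- curve$sep_nm; mc <- curve$mean_corr
  pos <- L > 0 & mc > 0.05 & is.finite(mc)
  if (sum(pos) < 2) stop("correlation curve decays too fast to fit",
                         call. = FALSE)
  slope <- stats::coef(stats::lm(log(mc[pos]) ~ L[pos]))[2]
  lp0 <- if (is.finite(slope) && slope < 0) -1 / (2 * slope) else max(L) / 2
  lp0 <- min(max(lp0, 0.5), 5e5)
  if (is.null(fit_range)) fit_range <- c(curve$step_nm, 2 * lp0)
  inr <- L >= fit_range[1] - 1e-9 & L <= fit_range[2] + 1e-9 &
    curve$n_pairs > 0
  if (sum(inr) < 4)
    stop("need >= 4 populated separations inside fit_range", call. = FALSE)
  Lf <- L[inr]; yf <- mc[inr]; sef <- curve$se[inr]
  w <- if (all(is.finite(sef)) && all(sef > 0)) 1 / sef^2 else rep(1, length(Lf))
  w <- w / mean(w)
  chord <- curve$chord_step_nm
  if (is.null(chord) || !is.finite(chord)) chord <- 0
  df <- data.frame(L = Lf, y = yf)
  C <- curve$closed_contour_nm
  closed_form <- is.finite(C) %in% TRUE && C > 0
  if (closed_form) {
    df$wind <- cos(2 * pi * Lf / C)
    df$bridge <- ring_gamma(Lf / C)
  }
  if (chord > 0) {
    form <- if (closed_form)
      y ~ wind * exp(-pmax(L - L0, 0) * bridge / (2 * lp))
    else y ~ exp(-pmax(L - L0, 0) / (2 * lp))
    start <- list(lp = lp0, L0 = chord / 3)
    lower <- c(0.1, 0); upper <- c(1e6, 2 * curve$step_nm)
  } else {
    form <- if (closed_form) y ~ wind * exp(-L * bridge / (2 * lp))
            else y ~ exp(-L / (2 * lp))
    start <- list(lp = lp0)
    lower <- 0.1; upper <- 1e6
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = df,
                      start = start, weights = w,
                      lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(
                        ftol = 1e-14, ptol = 1e-14, maxiter = 200)),
    error = function(e) stop("persistence-length fit failed: ",
                             conditionMessage(e), call. = FALSE))
  lp <- as.numeric(stats::coef(fit)["lp"])
  if (lp <= 0.1 * 1.0001 || lp >= 1e6 * 0.9999)
    stop("persistence-length fit hit its bounds", call. = FALSE)
  lp_se <- tryCatch(summary(fit)$coefficients["lp", "Std. Error"],
                    error = function(e) NA_real_)
  structure(list(lp = lp, lp_se = lp_se, fit_range = fit_range,
                 residual_rms = sqrt(mean(stats::residuals(fit)^2)),
                 n_molecules = curve$n_molecules),
            class = "pl_fit")
}

#' @export
print.pl_fit <- function(x, ...) {
  cat(sprintf(
    "pl_fit: Lp = %.2f +/- %.2f nm (fit over %.0f-%.0f nm, residual RMS %.3g, %d molecules)\n",
    x$lp, x$lp_se, x$fit_range[1], x$fit_range[2], x$residual_rms,
    x$n_molecules))
  invisible(x)
}

#' Distribution of signed bending angles at a fixed contour separation
#'
#' The signed angle between tangents separated by `separation_nm` along
#' the contour, pooled over positions and molecules, wrapped to
#' `(-pi, pi]`. If the separation is not a multiple of the trace step the
#' traces are resampled at `separation_nm` first (tangent angles are never
#' interpolated directly).
#'
#' @param traces list of [trace_result].
#' @param separation_nm contour separation, nm.
#' @param bins number of histogram bins over `(-pi, pi]`.
#' @return object of class `angle_distribution` with `separation_nm`,
#'   `angles`, `breaks`, `density`.
#' @export
bending_angle_distribution <- function(traces, separation_nm = 10,
                                       bins = 36) {
  if (inherits(traces, "trace_result")) traces <- list(traces)
  if (length(traces) == 0) stop("no traces supplied", call. = FALSE)
  angles <- c()
  for (tr in traces) {
    step <- tr$step_nm
    ratio <- separation_nm / step
    if (abs(ratio - round(ratio)) > 1e-6) {
      poly <- if (tr$closed) rbind(tr$points, tr$points[1, ]) else tr$points
      pts <- resample_polyline(poly, separation_nm, closed = tr$closed)
      tr <- trace_result(pts, separation_nm, tr$closed, tr$molecule_id)
      k <- 1L
    } else k <- as.integer(round(ratio))
    p <- if (tr$closed) rbind(tr$points, tr$points[1, ]) else tr$points
    g <- segment_geometry(p)
    phi <- atan2(g$vec[, 2], g$vec[, 1])
    n <- length(phi)
    if (tr$closed) {
      if (k >= n) stop("separation exceeds a closed trace", call. = FALSE)
      d <- phi[((seq_len(n) + k - 1L) %% n) + 1L] - phi
    } else {
      if (k > n - 1L) stop("separation exceeds the shortest trace",
                           call. = FALSE)
      d <- phi[(1L + k):n] - phi[1L:(n - k)]
    }
    angles <- c(angles, wrap_angle(d))
  }
  breaks <- seq(-pi, pi, length.out = bins + 1L)
  h <- graphics::hist(angles, breaks = breaks, plot = FALSE)
  structure(list(separation_nm = separation_nm, angles = angles,
                 breaks = breaks, density = h$density),
            class = "angle_distribution")
}

#' Contour-length statistics over an ensemble
#'
#' @param traces list of at least 2 [trace_result].
#' @return list with `mean_nm`, `sd_nm`, `lengths_nm` (per molecule).
#' @export
contour_length_stats <- function(traces) {
  if (length(traces) < 2) stop("need >= 2 traces", call. = FALSE)
  lens <- vapply(traces, measure_contour_length, numeric(1))
  list(mean_nm = mean(lens), sd_nm = stats::sd(lens), lengths_nm = lens)
}

#' Percent change of a mean contour length versus a reference
#' @param mean_nm measured mean, nm.
#' @param ref_nm reference mean, nm.
#' @return percent change `100 * (mean - ref) / ref`.
#' @export
percent_change <- function(mean_nm, ref_nm) 100 * (mean_nm - ref_nm) / ref_nm

#' Bootstrap confidence interval for the persistence length
#'
#' Resamples molecules with replacement, recomputes the pooled correlation
#' curve and refits per replicate. Deterministic for a fixed seed.
#'
#' @param traces list of at least 5 [trace_result].
#' @param n_boot number of replicates (>= 10).
#' @param fit_range passed to [fit_persistence_length()].
#' @param seed integer seed.
#' @param max_sep_nm passed to [tangent_correlation()].
#' @return list with `lp` (full-data fit), `ci` (2.5 and 97.5 percent
#'   quantiles), `replicates`.
#' @export
bootstrap_lp <- function(traces, n_boot = 200, fit_range = NULL, seed = 1L,
                         max_sep_nm = 200) {
  if (n_boot < 10) stop("`n_boot` must be >= 10", call. = FALSE)
  if (length(traces) < 5) stop("need >= 5 traces", call. = FALSE)
  full <- fit_persistence_length(tangent_correlation(traces, max_sep_nm),
                                 fit_range)
  set.seed(as.integer(seed))
  reps <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(length(traces), replace = TRUE)
    reps[b] <- tryCatch(
      fit_persistence_length(tangent_correlation(traces[idx], max_sep_nm),
                             fit_range)$lp,
      error = function(e) NA_real_)
  }
  if (mean(is.na(reps)) > 0.2)
    stop("more than 20% of bootstrap replicate fits failed", call. = FALSE)
  ci <- stats::quantile(reps, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  list(lp = full$lp, ci = ci, replicates = reps)
}
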
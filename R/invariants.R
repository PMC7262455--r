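#' Guinier analysis of a scattering curve
#'
#' Weighted least-squares fit of \eqn{\ln I} versus \eqn{q^2} at low angle,
#' where the Guinier approximation
#' \eqn{\ln I(q) \approx \ln I(0) - q^2 R_g^2 / 3} holds. The gradient `m` of
#' the line gives the radius of gyration through \eqn{m = -R_g^2/3}, i.e.
#' \eqn{R_g = \sqrt{-3m}}. Weights are \eqn{1/\sigma_{\ln I}^2} with
#' \eqn{\sigma_{\ln I} = \sigma/I} (first-order propagation); the fit is
#' unweighted when sigma is absent. The fitting window is expressed in the
#' dimensionless product \eqn{qR_g} and re-evaluated iteratively, since the
#' window bounds themselves depend on the fitted \eqn{R_g}.
#'
#' @param curve A [saxs_curve()].
#' @param window `c(low, high)` bounds on \eqn{qR_g}; default `c(0, 1.3)`.
#' @param rg0 Optional starting estimate of Rg, Angstrom; estimated from the
#'   lowest-q points when omitted.
#' @param max_iter Maximum window/fit iterations (default 20).
#' @return An object of class `guinier_fit`: `Rg`, `Rg_err` (SEM, via
#'   propagation of the slope SEM through \eqn{R_g = \sqrt{-3m}}), `I0`,
#'   `slope_m` (Angstrom^2), `window` (achieved qRg range), `n_points`,
#'   `r_squared`, standardized `residuals`, and the point indices `idx`.
#' @export
guinier_fit <- function(curve, window = c(0, 1.3), rg0 = NULL, max_iter = 20L) {
  stopifnot(inherits(curve, "saxs_curve"))
  if (length(window) != 2L || window[1] < 0 || window[2] <= window[1])
    fs_stop("window must be increasing non-negative qRg bounds",
            "fs_argument_error")
  rg <- if (is.null(rg0)) .guinier_seed_rg(curve) else rg0
  idx_prev <- integer(0)
  fit <- NULL
  for (it in seq_len(max_iter)) {
    qrg <- curve$q * rg
    idx <- which(qrg >= window[1] & qrg <= window[2] & curve$I > 0)
    if (length(idx) < 5L)
      fs_stop("fewer than 5 points in the Guinier window",
              "fs_insufficient_data")
    fit <- .guinier_ls(curve, idx)
    rg <- fit$Rg
    if (identical(idx, idx_prev)) break
    idx_prev <- idx
  }
  fit
}

# Initial Rg from an unweighted fit over the lowest-q positive-I points,
# widening the point set until a decaying slope is found (noise on a short
# low-q stretch can flip the local slope).
.guinier_seed_rg <- function(curve) {
  pos <- which(curve$I > 0)
  if (length(pos) < 5L)
    fs_stop("fewer than 5 positive intensities", "fs_insufficient_data")
  for (k in unique(pmin(c(10L, 25L, 50L, length(pos) %/% 2L, length(pos)),
                        length(pos)))) {
    if (k < 5L) next
    idx <- head(pos, k)
    m <- suppressWarnings(coef(lm(log(curve$I[idx]) ~ I(curve$q[idx]^2)))[2])
    if (is.finite(m) && m < 0) return(sqrt(-3 * m))
  }
  fs_stop("no decaying low-q region (non-negative Guinier slope)",
          "fs_no_guinier_region")
}

# One weighted linear fit of ln I vs q^2 over the given point indices.
.guinier_ls <- function(curve, idx) {
  q2 <- curve$q[idx]^2
  y <- log(curve$I[idx])
  w <- if (is.null(curve$sigma)) rep(1, length(idx))
       else (curve$I[idx] / curve$sigma[idx])^2
  fit <- lm(y ~ q2, weights = w)
  m <- unname(coef(fit)[2])
  if (!is.finite(m) || m >= 0)
    fs_stop("non-negative Guinier slope: no Guinier region",
            "fs_no_guinier_region")
  rg <- sqrt(-3 * m)
  se_m <- sqrt(diag(suppressWarnings(vcov(fit))))[2]
  sm <- suppressWarnings(summary(fit))
  structure(list(
    Rg = rg,
    Rg_err = unname(3 * se_m / (2 * rg)),
    I0 = exp(unname(coef(fit)[1])),
    slope_m = m,
    window = range(curve$q[idx]) * rg,
    q_range = range(curve$q[idx]),
    n_points = length(idx),
    r_squared = sm$r.squared,
    residuals = unname(rstandard_safe(fit)),
    idx = idx), class = "guinier_fit")
}

# rstandard() errors on a perfect fit (zero residual variance); fall back to
# raw residuals there.
rstandard_safe <- function(fit) {
  r <- tryCatch(stats::rstandard(fit), error = function(e) stats::residuals(fit))
  r[!is.finite(r)] <- 0
  r
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat(sprintf(paste0("<guinier_fit> Rg = %.3g +/- %.2g A  I0 = %.4g\n",
                     "  m = %.4g A^2, window %.3g < qRg < %.3g, n = %d, R2 = %.4f\n"),
              x$Rg, x$Rg_err, x$I0, x$slope_m, x$window[1], x$window[2],
              x$n_points, x$r_squared))
  invisible(x)
}

#' Automatic Guinier window selection
#'
#' Searches for the widest contiguous low-q window with achieved
#' \eqn{qR_g \le} `qrg_max` whose fit satisfies \eqn{R^2 \ge} `r2_min` and
#' whose Rg is stable: dropping either endpoint changes Rg by less than
#' `stability` (fractional). Candidate start points walk up from the lowest q,
#' which excludes aggregation upturns confined to the first few points. Ties
#' between windows of equal size are broken toward lower starting q.
#'
#' @param curve A [saxs_curve()].
#' @param qrg_max Upper qRg bound (default 1.3).
#' @param r2_min Minimum fit R-squared (default 0.95).
#' @param stability Maximum fractional Rg change on dropping an endpoint
#'   (default 0.05).
#' @param max_start How many low-q start points to try (default 15).
#' @return The selected `guinier_fit` (its `idx`/`window` fields give the
#'   chosen window).
#' @export
auto_guinier_range <- function(curve, qrg_max = 1.3, r2_min = 0.95,
                               stability = 0.05, max_start = 15L) {
  stopifnot(inherits(curve, "saxs_curve"))
  best <- NULL
  for (s in seq_len(min(max_start, length(curve$q) - 5L))) {
    sub <- .drop_low(curve, s)
    fit <- tryCatch(guinier_fit(sub, window = c(0, qrg_max)),
                    flexscatter_error = function(e) NULL)
    if (is.null(fit) || fit$r_squared < r2_min) next
    if (!.endpoint_stable(sub, fit, stability)) next
    fit$idx <- fit$idx + (s - 1L)  # back to original curve indexing
    if (is.null(best) || fit$n_points > best$n_points) best <- fit
  }
  if (is.null(best))
    fs_stop("no window satisfies the Guinier acceptance constraints",
            "fs_no_guinier_region")
  best
}

.drop_low <- function(curve, s) {
  saxs_curve(curve$q[s:length(curve$q)], curve$I[s:length(curve$q)],
             if (is.null(curve$sigma)) NULL else curve$sigma[s:length(curve$q)],
             label = curve$label)
}

.endpoint_stable <- function(curve, fit, tol) {
  idx <- fit$idx
  if (length(idx) < 6L) return(TRUE)
  for (drop in list(idx[-1L], idx[-length(idx)])) {
    f2 <- tryCatch(.guinier_ls(curve, drop),
                   flexscatter_error = function(e) NULL)
    if (is.null(f2) || abs(f2$Rg - fit$Rg) / fit$Rg > tol) return(FALSE)
  }
  TRUE
}

#' Dimensionless Kratky transformation
#'
#' Rescales a curve into the dimensionless Kratky representation
#' \eqn{(qR_g)^2 I(q)/I(0)} versus \eqn{qR_g}, using Guinier-derived Rg and
#' I(0). Compact globular particles peak at the reference point
#' \eqn{(\sqrt 3,\ 3/e \approx 1.10)}; flexible chains plateau above it and
#' fully disordered chains keep rising. The transformation is invariant under
#' rescaling of I.
#'
#' @param curve A [saxs_curve()].
#' @param fit A `guinier_fit` for the same curve (supplies Rg and I0).
#' @return An object of class `kratky_curve`: `x` (qRg), `y`, and the
#'   globular `reference` point.
#' @export
dimensionless_kratky <- function(curve, fit) {
  stopifnot(inherits(curve, "saxs_curve"), inherits(fit, "guinier_fit"))
  if (fit$Rg <= 0 || fit$I0 <= 0)
    fs_stop("fit must have positive Rg and I0", "fs_argument_error")
  x <- curve$q * fit$Rg
  y <- x^2 * curve$I / fit$I0
  structure(list(x = x, y = y,
                 reference = c(x = sqrt(3), y = 3 / exp(1)),
                 Rg = fit$Rg, I0 = fit$I0),
            class = "kratky_curve")
}

#' @export
print.kratky_curve <- function(x, ...) {
  i <- which.max(x$y)
  cat(sprintf(paste0("<kratky_curve> peak (qRg = %.3f, y = %.3f); ",
                     "globular reference (%.3f, %.3f)\n"),
              x$x[i], x$y[i], x$reference["x"], x$reference["y"]))
  invisible(x)
}

#' @export
plot.kratky_curve <- function(x, ...) {
  plot(x$x, x$y, type = "l", xlab = expression(qR[g]),
       ylab = expression((qR[g])^2 * I(q) / I(0)), ...)
  points(x$reference["x"], x$reference["y"], col = "red", pch = 19)
  invisible(x)
}

#' Per-frame Rg evolution across a SEC-SAXS series
#'
#' Runs Guinier analysis on every frame of an elution series and summarizes
#' requested frame subsets (by default the first and last thirds, the
#' comparison used to detect slow oligomeric equilibria or column
#' interactions as a drift in mean Rg). Frames where the analysis fails are
#' flagged with the failure reason, never silently dropped.
#'
#' @param series A [saxs_series()].
#' @param policy `"auto"` refits the Guinier window per frame
#'   ([auto_guinier_range()]); `"fixed"` selects one window on the averaged
#'   series and applies the same q points to every frame.
#' @param groups `"thirds"` (first/last third) or a named list of frame-index
#'   vectors.
#' @param qrg_max Upper qRg bound passed to the window search.
#' @return An object of class `rg_trace`: `trace` data frame
#'   (frame_index, Rg, Rg_err, ok, reason) and `groups` summary data frame
#'   (group, n, mean, sd).
#' @export
rg_evolution <- function(series, policy = c("auto", "fixed"),
                         groups = "thirds", qrg_max = 1.3) {
  stopifnot(inherits(series, "saxs_series"))
  policy <- match.arg(policy)
  nf <- length(series$frames)
  if (nf < 2L) fs_stop("need at least 2 frames", "fs_insufficient_data")

  fixed_idx <- NULL
  if (policy == "fixed") {
    avg <- average_frames(series)
    fixed_idx <- auto_guinier_range(avg, qrg_max = qrg_max)$idx
  }
  res <- lapply(series$frames, function(fr) {
    tryCatch({
      fit <- if (is.null(fixed_idx)) auto_guinier_range(fr, qrg_max = qrg_max)
             else .guinier_ls(fr, fixed_idx)
      list(Rg = fit$Rg, Rg_err = fit$Rg_err, ok = TRUE, reason = "")
    }, flexscatter_error = function(e)
      list(Rg = NA_real_, Rg_err = NA_real_, ok = FALSE,
           reason = conditionMessage(e)))
  })
  trace <- data.frame(
    frame_index = series$frame_index,
    Rg = vapply(res, `[[`, numeric(1), "Rg"),
    Rg_err = vapply(res, `[[`, numeric(1), "Rg_err"),
    ok = vapply(res, `[[`, logical(1), "ok"),
    reason = vapply(res, `[[`, character(1), "reason"))

  if (identical(groups, "thirds")) {
    k <- nf %/% 3L
    groups <- list(first_third = seq_len(k),
                   last_third = seq.int(nf - k + 1L, nf))
  }
  gs <- do.call(rbind, lapply(names(groups), function(g) {
    v <- trace$Rg[groups[[g]]]
    v <- v[is.finite(v)]
    data.frame(group = g, n = length(v), mean = mean(v), sd = sd(v))
  }))
  structure(list(trace = trace, groups = gs, group_indices = groups,
                 policy = policy), class = "rg_trace")
}

#' @export
print.rg_trace <- function(x, ...) {
  cat(sprintf("<rg_trace> %d frames (%d analysed), policy = %s\n",
              nrow(x$trace), sum(x$trace$ok), x$policy))
  print(x$groups, row.names = FALSE)
  invisible(x)
}
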
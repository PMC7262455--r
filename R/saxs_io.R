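#' Construct a scattering curve
#'
#' The universal experimental object: intensity \eqn{I(q)} on a strictly
#' ascending momentum-transfer grid \eqn{q = 4\pi \sin\theta / \lambda}
#' (\eqn{\mathrm{\AA}^{-1}}), with optional 1-sigma uncertainties.
#'
#' @param q Numeric vector of momentum transfer values, 1/Angstrom; strictly
#'   increasing, all positive, length >= 3.
#' @param I Numeric vector of intensities (arbitrary units), same length.
#' @param sigma Optional numeric vector of 1-sigma uncertainties of `I`
#'   (same units); all positive.
#' @param label Free-text label carried through analyses.
#' @return An object of class `saxs_curve`: a list with elements `q`, `I`,
#'   `sigma` (or `NULL`) and `label`.
#' @export
saxs_curve <- function(q, I, sigma = NULL, label = "") {
  q <- as.numeric(q); I <- as.numeric(I)
  if (length(q) != length(I))
    fs_stop("q and I must have equal length", "fs_validation_error")
  if (length(q) < 3L)
    fs_stop("a scattering curve needs at least 3 points", "fs_insufficient_data")
  if (anyNA(q) || anyNA(I))
    fs_stop("q and I must be finite", "fs_validation_error")
  if (any(q <= 0) || any(diff(q) <= 0))
    fs_stop("q must be strictly increasing and positive", "fs_validation_error")
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q))
      fs_stop("sigma must match q in length", "fs_validation_error")
    if (anyNA(sigma) || any(sigma <= 0))
      fs_stop("all sigma must be positive", "fs_validation_error")
  }
  structure(list(q = q, I = I, sigma = sigma, label = as.character(label)[1]),
            class = "saxs_curve")
}

#' @export
print.saxs_curve <- function(x, ...) {
  cat(sprintf("<saxs_curve> %s\n  %d points, q = %.4g..%.4g 1/A, sigma %s\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$q), min(x$q), max(x$q),
              if (is.null(x$sigma)) "absent" else "present"))
  invisible(x)
}

#' @export
length.saxs_curve <- function(x) length(x$q)

#' Read a 3-column ASCII scattering file
#'
#' Parses whitespace-separated `q I [sigma]` columns. Lines starting with `#`
#' and any non-numeric header/footer lines are skipped. The sigma column is
#' kept only if present on every data line.
#'
#' @param path Path to a `.dat`-style text file.
#' @param label Label for the curve; defaults to the file name.
#' @return A [saxs_curve()].
#' @export
read_dat <- function(path, label = basename(path)) {
  if (!file.exists(path))
    fs_stop(sprintf("file not found: %s", path), "fs_format_error")
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rows <- lapply(strsplit(lines, "[[:space:]]+"), function(tok) {
    v <- suppressWarnings(as.numeric(tok))
    if (length(v) >= 2 && !anyNA(v[1:2])) v else NULL
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L)
    fs_stop(sprintf("no numeric data rows in %s", path), "fs_format_error")
  if (length(rows) < 3L)
    fs_stop(sprintf("fewer than 3 data points in %s", path),
            "fs_insufficient_data")
  q <- vapply(rows, `[`, numeric(1), 1L)
  I <- vapply(rows, `[`, numeric(1), 2L)
  has_sigma <- all(vapply(rows, function(v) length(v) >= 3 && !is.na(v[3]),
                          logical(1)))
  sigma <- if (has_sigma) vapply(rows, `[`, numeric(1), 3L) else NULL
  saxs_curve(q, I, sigma, label = label)
}

#' Write a scattering curve as whitespace-separated text
#'
#' @param curve A [saxs_curve()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dat <- function(curve, path) {
  stopifnot(inherits(curve, "saxs_curve"))
  hdr <- if (is.null(curve$sigma)) "# q(1/A) I" else "# q(1/A) I sigma"
  m <- cbind(curve$q, curve$I, curve$sigma)
  body <- apply(m, 1L, function(r) paste(sprintf("%.8g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Restrict a curve to a q-range
#'
#' Keeps exactly the points with `qmin <= q <= qmax`; used e.g. to cut data to
#' a usable angular range such as 0.0084-0.35 1/Angstrom.
#'
#' @param curve A [saxs_curve()].
#' @param qmin,qmax Inclusive bounds, 1/Angstrom; `qmin < qmax`.
#' @return The truncated [saxs_curve()].
#' @export
truncate_curve <- function(curve, qmin, qmax) {
  stopifnot(inherits(curve, "saxs_curve"))
  if (!is.finite(qmin) || !is.finite(qmax) || qmin >= qmax)
    fs_stop("qmin must be < qmax", "fs_argument_error")
  keep <- curve$q >= qmin & curve$q <= qmax
  if (sum(keep) < 3L)
    fs_stop("fewer than 3 points remain after truncation",
            "fs_insufficient_data")
  saxs_curve(curve$q[keep], curve$I[keep],
             if (is.null(curve$sigma)) NULL else curve$sigma[keep],
             label = curve$label)
}

#' Construct a SEC-SAXS frame series
#'
#' An ordered set of scattering frames on one common q grid, as produced by
#' successive detector exposures across a size-exclusion elution.
#'
#' @param frames List of [saxs_curve()] objects sharing an identical q grid.
#' @param frame_index Integer index per frame (default `seq_along(frames)`).
#' @return An object of class `saxs_series`.
#' @export
saxs_series <- function(frames, frame_index = seq_along(frames)) {
  if (!length(frames) || !all(vapply(frames, inherits, logical(1), "saxs_curve")))
    fs_stop("frames must be a non-empty list of saxs_curve objects",
            "fs_validation_error")
  q0 <- frames[[1]]$q
  same <- vapply(frames, function(f)
    length(f$q) == length(q0) && all(f$q == q0), logical(1))
  if (!all(same))
    fs_stop("all frames must share an identical q grid", "fs_validation_error")
  if (length(frame_index) != length(frames))
    fs_stop("frame_index must match frames in length", "fs_validation_error")
  structure(list(frames = frames, frame_index = as.integer(frame_index)),
            class = "saxs_series")
}

#' @export
print.saxs_series <- function(x, ...) {
  cat(sprintf("<saxs_series> %d frames, %d q points each\n",
              length(x$frames), length(x$frames[[1]]$q)))
  invisible(x)
}

#' @export
length.saxs_series <- function(x) length(x$frames)

#' Average frames of a SEC-SAXS series
#'
#' Pointwise unweighted mean of the selected frames' intensities. Sigmas are
#' propagated for a plain mean: \eqn{\sigma = \sqrt{\sum_i \sigma_i^2} / n},
#' so averaging n identical frames reduces sigma by \eqn{1/\sqrt{n}}.
#'
#' @param series A [saxs_series()].
#' @param indices Positions (into `series$frames`) to average; default all.
#' @return A [saxs_curve()].
#' @export
average_frames <- function(series, indices = seq_along(series$frames)) {
  stopifnot(inherits(series, "saxs_series"))
  indices <- unique(as.integer(indices))
  if (length(indices) == 0L)
    fs_stop("indices must be non-empty", "fs_argument_error")
  if (any(indices < 1L | indices > length(series$frames)))
    fs_stop("frame index out of range", "fs_argument_error")
  fr <- series$frames[indices]
  n <- length(fr)
  I <- Reduce(`+`, lapply(fr, `[[`, "I")) / n
  sig <- NULL
  if (all(vapply(fr, function(f) !is.null(f$sigma), logical(1)))) {
    sig <- sqrt(Reduce(`+`, lapply(fr, function(f) f$sigma^2))) / n
  }
  saxs_curve(fr[[1]]$q, I, sig,
             label = sprintf("mean of %d frames", n))
}

#' Plot a scattering curve
#'
#' Log-intensity plot of I(q); the standard first look at SAXS data.
#'
#' @param x A [saxs_curve()].
#' @param ... Passed to [plot()].
#' @export
plot.saxs_curve <- function(x, ...) {
  plot(x$q, x$I, log = "y", xlab = expression(q ~ (ring(A)^-1)),
       ylab = "I(q)", type = "l", main = x$label, ...)
  invisible(x)
}
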
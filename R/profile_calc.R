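#' Per-residue electron counts for coarse-grained scattering
#'
#' Effective, q-independent scattering weight (number of electrons) of each
#' standard amino-acid residue in a polypeptide chain, used when one bead per
#' residue is placed at the C-alpha position. Charged side chains use their
#' physiological protonation state.
#'
#' @return Named numeric vector of electrons per residue (three-letter codes).
#' @export
residue_electrons <- function() {
  c(ALA = 38, ARG = 85, ASN = 60, ASP = 59, CYS = 54, GLN = 68, GLU = 67,
    GLY = 30, HIS = 72, ILE = 62, LEU = 62, LYS = 71, MET = 70, PHE = 78,
    PRO = 52, SER = 46, THR = 54, TRP = 98, TYR = 86, VAL = 54)
}

# Average residue weight used when no sequence is available (constant-f beads
# keep all geometry-driven behaviour; see the methods vignette).
.default_residue_f <- 54

#' Construct a bead model
#'
#' Point-scatterer representation of a molecule: positions with effective
#' scattering lengths. The coarse-graining used throughout the package is one
#' bead per residue at the C-alpha position.
#'
#' @param positions N x 3 numeric matrix of coordinates, Angstrom.
#' @param f Scattering weights (electrons); scalar or length-N vector, all > 0.
#' @param resno Optional residue numbers (length N).
#' @param resid Optional residue labels, three-letter codes (length N); when
#'   given and `f` is missing, weights are looked up in [residue_electrons()].
#' @param source Provenance string.
#' @return An object of class `bead_model`.
#' @export
bead_model <- function(positions, f = NULL, resno = NULL, resid = NULL,
                       source = "") {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L || nrow(positions) < 1L)
    fs_stop("positions must be an N x 3 matrix with N >= 1",
            "fs_validation_error")
  n <- nrow(positions)
  if (is.null(f)) {
    f <- if (is.null(resid)) rep(.default_residue_f, n) else {
      tab <- residue_electrons()
      w <- unname(tab[toupper(resid)])
      w[is.na(w)] <- .default_residue_f
      w
    }
  }
  f <- rep_len(as.numeric(f), n)
  if (any(!is.finite(f)) || any(f <= 0))
    fs_stop("all bead weights must be positive", "fs_validation_error")
  structure(list(positions = unname(positions), f = f,
                 resno = if (is.null(resno)) seq_len(n) else as.integer(resno),
                 resid = resid, source = source),
            class = "bead_model")
}

#' @export
print.bead_model <- function(x, ...) {
  cat(sprintf("<bead_model> %d beads, total f = %.4g e- [%s]\n",
              nrow(x$positions), sum(x$f), x$source))
  invisible(x)
}

# Accept a bead_model, conformer or dimer wherever beads are expected.
as_bead_model <- function(model) {
  if (inherits(model, "bead_model")) return(model)
  if (inherits(model, "conformer") || inherits(model, "conformer_dimer"))
    return(bead_model(model$xyz, resno = model$resno, resid = model$resid,
                      source = sprintf("conformer seed %s", model$seed)))
  fs_stop("expected a bead_model or conformer", "fs_argument_error")
}

#' Theoretical scattering profile by the Debye formula
#'
#' Exact orientational average for point scatterers:
#' \deqn{I(q) = \sum_i \sum_j f_i f_j \frac{\sin(q r_{ij})}{q r_{ij}},}
#' with the \eqn{i = j} and \eqn{q \to 0} limits equal to 1.
#'
#' @param beads A [bead_model()] or conformer.
#' @param qgrid Ascending positive q values, 1/Angstrom.
#' @return A [saxs_curve()] without sigma.
#' @export
debye_profile <- function(beads, qgrid) {
  beads <- as_bead_model(beads)
  qgrid <- as.numeric(qgrid)
  if (length(qgrid) == 0L)
    fs_stop("qgrid must be non-empty", "fs_argument_error")
  if (any(qgrid <= 0) || is.unsorted(qgrid, strictly = TRUE))
    fs_stop("qgrid must be positive and strictly ascending",
            "fs_argument_error")
  I <- cpp_debye(beads$positions, beads$f, qgrid)
  saxs_curve(qgrid, I, label = sprintf("Debye profile [%s]", beads$source))
}

#' Analytic sphere form factor
#'
#' Normalized scattering of a homogeneous sphere of radius `R`:
#' \deqn{I(q)/I(0) = \left[\frac{3(\sin qR - qR\cos qR)}{(qR)^3}\right]^2.}
#' Serves as a closed-form oracle: its Guinier radius is
#' \eqn{\sqrt{3/5}\,R} and its first zero sits at \eqn{qR \approx 4.4934}.
#'
#' @param R Sphere radius, Angstrom.
#' @param qgrid Ascending positive q values, 1/Angstrom.
#' @return A [saxs_curve()] with I(0) = 1 normalization.
#' @export
sphere_form_factor <- function(R, qgrid) {
  if (!is.finite(R) || R <= 0) fs_stop("R must be positive", "fs_argument_error")
  qgrid <- as.numeric(qgrid)
  x <- qgrid * R
  I <- ifelse(x < 1e-6, 1, (3 * (sin(x) - x * cos(x)) / x^3)^2)
  saxs_curve(qgrid, I, label = sprintf("sphere R = %g A", R))
}

#' Debye form factor of an ideal Gaussian chain
#'
#' \deqn{I(q)/I(0) = 2\,(e^{-x} + x - 1)/x^2, \quad x = (q R_g)^2.}
#' The standard flexible-polymer reference curve; its dimensionless Kratky
#' representation plateaus at 2 instead of peaking at the globular point.
#'
#' @param Rg Radius of gyration, Angstrom.
#' @param qgrid Ascending positive q values, 1/Angstrom.
#' @return A [saxs_curve()] with I(0) = 1 normalization.
#' @export
gaussian_chain_form_factor <- function(Rg, qgrid) {
  if (!is.finite(Rg) || Rg <= 0)
    fs_stop("Rg must be positive", "fs_argument_error")
  x <- (as.numeric(qgrid) * Rg)^2
  I <- ifelse(x < 1e-8, 1, 2 * (exp(-x) + x - 1) / x^2)
  saxs_curve(qgrid, I, label = sprintf("Gaussian chain Rg = %g A", Rg))
}

#' Fit a model curve to experimental data by weighted least squares
#'
#' Minimizes \eqn{\sum_k \left((c I_m(q_k) + b - I_d(q_k))/\sigma_k\right)^2}
#' over the scale `c` (and flat background `b` when requested) in closed form,
#' and reports the reduced chi-square \eqn{\chi^2 = \min / \mathrm{dof}} with
#' \eqn{\mathrm{dof} = n - p}, `p` the number of fitted parameters. The model
#' is cubic-spline interpolated onto the data grid when the grids differ.
#'
#' @param model A [saxs_curve()] (theoretical; sigma ignored).
#' @param data A [saxs_curve()] with sigma present.
#' @param fit_background Also fit a flat background term? Default `FALSE`.
#' @return An object of class `profile_fit`: list with `chi2`, `c`, `b`,
#'   `n_points`, `dof`, and the convention note in `meta`.
#' @export
chi2_fit <- function(model, data, fit_background = FALSE) {
  stopifnot(inherits(model, "saxs_curve"), inherits(data, "saxs_curve"))
  if (is.null(data$sigma))
    fs_stop("chi-square fitting requires data uncertainties (sigma)",
            "fs_missing_sigma_error")
  Im <- if (length(model$q) == length(data$q) &&
            isTRUE(all.equal(model$q, data$q))) {
    model$I
  } else {
    if (min(data$q) < min(model$q) - 1e-9 || max(data$q) > max(model$q) + 1e-9)
      fs_stop("model q range does not cover the data q range",
              "fs_argument_error")
    spline(model$q, model$I, xout = data$q, method = "natural")$y
  }
  w <- 1 / data$sigma^2
  y <- data$I
  if (fit_background) {
    X <- cbind(Im, 1)
    XtW <- t(X * w)
    M <- XtW %*% X
    if (rcond(M) < 1e-12)
      fs_stop("rank-deficient fit (constant model with background?)",
              "fs_rank_deficiency_error")
    beta <- solve(M, XtW %*% y)
    cc <- beta[1]; b <- beta[2]
  } else {
    denom <- sum(w * Im^2)
    if (denom <= 0)
      fs_stop("degenerate model curve", "fs_rank_deficiency_error")
    cc <- sum(w * Im * y) / denom
    b <- 0
  }
  resid <- (cc * Im + b - y) / data$sigma
  p <- 1L + as.integer(fit_background)
  dof <- length(y) - p
  structure(list(chi2 = sum(resid^2) / dof, c = cc, b = b,
                 n_points = length(y), dof = dof, residuals = resid,
                 meta = "reduced chi2 = RSS/(n - p), p = fitted parameters"),
            class = "profile_fit")
}

#' @export
print.profile_fit <- function(x, ...) {
  cat(sprintf("<profile_fit> chi2 = %.4g  c = %.4g  b = %.4g  (n = %d, dof = %d)\n",
              x$chi2, x$c, x$b, x$n_points, x$dof))
  invisible(x)
}

#' Coordinate-space size metrics
#'
#' Weighted radius of gyration
#' \eqn{R_g = \sqrt{\sum_i f_i |r_i - \bar r|^2 / \sum_i f_i}} about the
#' f-weighted centroid, and the maximum pairwise distance Dmax. An optional
#' residue interval restricts the calculation to a chain region (e.g. the
#' folded N-terminal two-thirds, residues 1-258, of a 414-residue chain).
#'
#' @param model A [bead_model()] or conformer.
#' @param residue_range Optional `c(first, last)` residue numbers.
#' @return List with `Rg` and `Dmax`, Angstrom.
#' @export
coords_metrics <- function(model, residue_range = NULL) {
  beads <- as_bead_model(model)
  pos <- beads$positions; f <- beads$f
  if (!is.null(residue_range)) {
    keep <- beads$resno >= residue_range[1] & beads$resno <= residue_range[2]
    if (sum(keep) < 2L)
      fs_stop("residue range selects fewer than 2 beads", "fs_argument_error")
    pos <- pos[keep, , drop = FALSE]; f <- f[keep]
  }
  if (nrow(pos) < 2L)
    fs_stop("need at least 2 beads", "fs_argument_error")
  ctr <- colSums(pos * f) / sum(f)
  d2 <- rowSums((pos - matrix(ctr, nrow(pos), 3, byrow = TRUE))^2)
  list(Rg = sqrt(sum(f * d2) / sum(f)), Dmax = cpp_max_pair_dist(pos))
}
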
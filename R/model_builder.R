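# Assembly of full-length chain models: rigid domains joined by self-avoiding
# disordered linkers, conformer pools, chi-square ranking, and enforced
# dimers. Pool generation is Monte-Carlo geometric sampling of linker
# conformations (not molecular dynamics); the ranking and region-Rg analyses
# operate on any pool regardless of how it was generated.

#' Define a rigid domain
#'
#' @param name Domain name (e.g. `"NTD"`, `"RRM1"`).
#' @param range `c(first, last)` residue numbers on the full chain.
#' @param coords N x 3 C-alpha coordinates covering the range, Angstrom.
#' @param source Provenance string (PDB id, file, or "synthetic").
#' @return A `domain_definition`.
#' @export
domain_definition <- function(name, range, coords, source = "") {
  coords <- as.matrix(coords)
  n <- range[2] - range[1] + 1L
  if (nrow(coords) != n)
    fs_stop(sprintf("domain %s: %d coordinates for %d residues", name,
                    nrow(coords), n), "fs_specification_error")
  structure(list(name = name, range = as.integer(range),
                 coords = unname(coords), source = source),
            class = "domain_definition")
}

#' Define a disordered linker
#'
#' Linkers are sampled as self-avoiding virtual C-alpha walks: successive
#' bonds of fixed length with the pseudo-bond angle at each residue
#' constrained to a band, and every non-bonded pair at least `clash_radius`
#' apart.
#'
#' @param range `c(first, last)` residue numbers.
#' @param bond_length Virtual C-alpha bond length, Angstrom (default 3.8).
#' @param angle_bounds Pseudo-angle bounds in degrees, within (0, 180);
#'   default `c(75, 155)`, the band observed for C-alpha pseudo-angles in
#'   coil regions.
#' @param clash_radius Minimum non-bonded C-alpha separation, Angstrom
#'   (default 3.0).
#' @return A `linker_spec`.
#' @export
linker_spec <- function(range, bond_length = 3.8, angle_bounds = c(75, 155),
                        clash_radius = 3.0) {
  if (any(angle_bounds <= 0) || any(angle_bounds >= 180) ||
      angle_bounds[1] >= angle_bounds[2])
    fs_stop("angle bounds must lie within (0, 180) degrees",
            "fs_specification_error")
  structure(list(range = as.integer(range), bond_length = bond_length,
                 angle_bounds = angle_bounds, clash_radius = clash_radius),
            class = "linker_spec")
}

#' Chain layout from domains and linkers
#'
#' Validates that the domain and linker residue ranges tile the chain
#' `1..L` exactly once with no gaps or overlaps.
#'
#' @param domains List of [domain_definition()] objects.
#' @param linkers List of [linker_spec()] objects.
#' @return A `chain_layout`: elements ordered along the chain.
#' @export
chain_layout <- function(domains, linkers) {
  elems <- c(domains, linkers)
  starts <- vapply(elems, function(e) e$range[1], integer(1))
  elems <- elems[order(starts)]
  covered <- unlist(lapply(elems, function(e) seq.int(e$range[1], e$range[2])),
                    use.names = FALSE)
  L <- max(covered)
  if (anyDuplicated(covered) || length(covered) != L ||
      !all(sort(covered) == seq_len(L)))
    fs_stop("domain/linker ranges must tile residues 1..L exactly once",
            "fs_specification_error")
  structure(list(elements = elems, length = L), class = "chain_layout")
}

#' @export
print.chain_layout <- function(x, ...) {
  cat(sprintf("<chain_layout> %d residues, %d elements\n", x$length,
              length(x$elements)))
  for (e in x$elements) {
    if (inherits(e, "domain_definition"))
      cat(sprintf("  domain %-10s %d-%d [%s]\n", e$name, e$range[1],
                  e$range[2], e$source))
    else
      cat(sprintf("  linker %14d-%d\n", e$range[1], e$range[2]))
  }
  invisible(x)
}

# --- synthetic rigid domains -------------------------------------------------

#' Synthetic compact domain fold
#'
#' Deterministic stand-in C-alpha coordinates for a folded domain when no
#' experimental structure is supplied: a self-avoiding 3.8-Angstrom-bond walk
#' collapsed into a confining sphere sized so the radius of gyration follows
#' the globular-protein scaling \eqn{R_g \approx 2.2 N^{0.38}} Angstrom.
#' These are synthetic coordinates — they reproduce the size, density and
#' connectivity of a folded domain, not its fold.
#'
#' @param n_res Number of residues.
#' @param seed RNG seed (fixed per domain in [tdp43_layout()], so layouts are
#'   reproducible across sessions).
#' @return n_res x 3 coordinate matrix, centred on the origin.
#' @export
synthetic_domain_fold <- function(n_res, seed) {
  rg_target <- 2.2 * n_res^0.38
  r_conf <- sqrt(5 / 3) * rg_target
  with_seed(seed, {
    for (attempt in 1:50) {
      xyz <- .confined_walk(n_res, r_conf, bond = 3.8, clash = 3.0)
      if (!is.null(xyz)) break
      xyz <- NULL
    }
    if (is.null(xyz))
      fs_stop("failed to generate a compact fold", "fs_sampling_failure")
    sweep(xyz, 2, colMeans(xyz))
  })
}

.confined_walk <- function(n, r_conf, bond, clash) {
  xyz <- matrix(NA_real_, n, 3)
  xyz[1, ] <- runif(3, -1, 1) * r_conf / 4
  i <- 2L
  fails <- 0L
  while (i <= n) {
    placed <- FALSE
    for (try in 1:40) {
      d <- .random_unit()
      cand <- xyz[i - 1L, ] + bond * d
      if (sqrt(sum(cand^2)) > r_conf) next
      if (i > 2L) {
        prev <- xyz[seq_len(i - 2L), , drop = FALSE]
        if (min(rowSums((prev - matrix(cand, i - 2L, 3, byrow = TRUE))^2)) <
            clash^2) next
      }
      xyz[i, ] <- cand
      placed <- TRUE
      break
    }
    if (placed) { i <- i + 1L } else {
      i <- max(2L, i - 2L)      # backtrack
      fails <- fails + 1L
      if (fails > 500L) return(NULL)
    }
  }
  xyz
}

.random_unit <- function() {
  repeat {
    v <- rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

# Ideal C-alpha alpha-helix: 1.5 A rise, 2.3 A radius, 100 degrees/residue.
.helix_coords <- function(n_res) {
  i <- seq_len(n_res) - 1
  th <- i * 100 * pi / 180
  cbind(2.3 * cos(th), 2.3 * sin(th), 1.5 * i)
}

#' Default TDP-43 full-length chain layout
#'
#' The 414-residue chain as three folded domains plus a short C-terminal
#' helical segment joined by disordered linkers: NTD 1-80, linker 81-105,
#' RRM1 106-176, linker 177-190, RRM2 191-258, disordered region 259-319,
#' helical segment 320-334, disordered tail 335-414. Domain boundaries are
#' configurable; the rigid coordinates default to deterministic synthetic
#' compact folds ([synthetic_domain_fold()]) and an ideal helix, and can be
#' replaced by experimentally determined C-alpha sets via
#' [domain_definition()].
#'
#' @param boundaries Named list overriding any of the default residue ranges
#'   (`ntd`, `linker1`, `rrm1`, `linker2`, `rrm2`, `linker3`, `helix`,
#'   `linker4`).
#' @return A [chain_layout()].
#' @export
tdp43_layout <- function(boundaries = list()) {
  b <- utils::modifyList(list(
    ntd = c(1L, 80L), linker1 = c(81L, 105L), rrm1 = c(106L, 176L),
    linker2 = c(177L, 190L), rrm2 = c(191L, 258L), linker3 = c(259L, 319L),
    helix = c(320L, 334L), linker4 = c(335L, 414L)), boundaries)
  nres <- function(r) r[2] - r[1] + 1L
  domains <- list(
    domain_definition("NTD", b$ntd, synthetic_domain_fold(nres(b$ntd), 101L),
                      source = "synthetic"),
    domain_definition("RRM1", b$rrm1, synthetic_domain_fold(nres(b$rrm1), 102L),
                      source = "synthetic"),
    domain_definition("RRM2", b$rrm2, synthetic_domain_fold(nres(b$rrm2), 103L),
                      source = "synthetic"),
    domain_definition("CTD-helix", b$helix, .helix_coords(nres(b$helix)),
                      source = "ideal helix"))
  linkers <- lapply(b[c("linker1", "linker2", "linker3", "linker4")],
                    linker_spec)
  chain_layout(domains, linkers)
}

# --- linker sampling ---------------------------------------------------------

#' Sample a self-avoiding disordered linker
#'
#' Grows a virtual C-alpha walk from an anchor: successive bonds of fixed
#' length, pseudo-bond angle at every residue within the spec bounds, and all
#' non-bonded pairs (including against `context` coordinates) at least the
#' clash radius apart. Sampling is by whole-walk rejection — any clash
#' restarts the walk (up to 1000 restarts) — so accepted walks follow the
#' self-avoiding proposal distribution exactly, with no growth bias.
#'
#' @param anchor 3D position of the last placed residue.
#' @param direction Unit vector of the incoming bond at the anchor.
#' @param n_res Number of linker residues to place.
#' @param spec A [linker_spec()].
#' @param context Optional M x 3 matrix of coordinates the walk must avoid.
#' @param seed Optional RNG seed; when `NULL` the current RNG stream is used.
#' @return n_res x 3 matrix of positions (empty matrix for `n_res = 0`).
#' @export
sample_linker <- function(anchor, direction, n_res, spec = linker_spec(c(1L, 2L)),
                          context = NULL, seed = NULL) {
  if (n_res == 0L) return(matrix(numeric(0), 0L, 3L))
  run <- function() .grow_walk(anchor, direction, n_res, spec, context)
  out <- if (is.null(seed)) run() else with_seed(seed, run())
  if (is.null(out))
    fs_stop(sprintf("linker sampling dead end (seed %s)",
                    if (is.null(seed)) "current stream" else seed),
            "fs_sampling_failure")
  out
}

# Whole-walk rejection: one clash anywhere discards the attempt. Restart
# rejection keeps the accepted-walk distribution identical to brute-force
# sampling of the self-avoiding proposal (no growth/Rosenbluth bias).
.grow_walk <- function(anchor, direction, n_res, spec, context,
                       max_restarts = 1000L) {
  b <- spec$bond_length
  clash2 <- spec$clash_radius^2
  dir0 <- direction / sqrt(sum(direction^2))
  for (attempt in seq_len(max_restarts)) {
    xyz <- matrix(NA_real_, n_res, 3)
    prev_dir <- dir0
    prev_pos <- anchor
    ok <- TRUE
    for (i in seq_len(n_res)) {
      d <- .bend_direction(prev_dir, spec$angle_bounds)
      cand <- prev_pos + b * d
      if (.clashes(cand, xyz, i, context, clash2)) { ok <- FALSE; break }
      xyz[i, ] <- cand
      prev_pos <- cand
      prev_dir <- d
    }
    if (ok) return(xyz)
  }
  NULL
}

# New bond direction making a pseudo-angle within [lo, hi] degrees with the
# previous bond (angle at the shared residue between -b1 and b2), azimuth
# uniform.
.bend_direction <- function(prev_dir, angle_bounds) {
  theta <- runif(1, angle_bounds[1], angle_bounds[2]) * pi / 180
  bend <- pi - theta              # angle between consecutive bond vectors
  # orthonormal frame around prev_dir
  a <- if (abs(prev_dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- .cross3(prev_dir, a); u <- u / sqrt(sum(u^2))
  v <- .cross3(prev_dir, u)
  phi <- runif(1, 0, 2 * pi)
  cos(bend) * prev_dir + sin(bend) * (cos(phi) * u + sin(phi) * v)
}

.cross3 <- function(x, y) {
  c(x[2] * y[3] - x[3] * y[2],
    x[3] * y[1] - x[1] * y[3],
    x[1] * y[2] - x[2] * y[1])
}

# cand vs non-bonded walk beads (all but the immediately preceding one) and
# vs context coordinates.
.clashes <- function(cand, xyz, i, context, clash2) {
  if (i > 2L) {
    prev <- xyz[seq_len(i - 2L), , drop = FALSE]
    if (min(rowSums(sweep(prev, 2, cand)^2)) < clash2) return(TRUE)
  }
  if (!is.null(context) && nrow(context)) {
    if (min(rowSums(sweep(context, 2, cand)^2)) < clash2) return(TRUE)
  }
  FALSE
}

# --- conformer assembly ------------------------------------------------------

# Uniform random rotation matrix (quaternion method).
.random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2*(y*y + z*z), 2*(x*y - w*z),     2*(x*z + w*y),
           2*(x*y + w*z),     1 - 2*(x*x + z*z), 2*(y*z - w*x),
           2*(x*z - w*y),     2*(y*z + w*x),     1 - 2*(x*x + y*y)),
         3, 3, byrow = TRUE)
}

#' Assemble one full-chain conformer
#'
#' Builds a C-alpha model covering the whole layout: the first element is
#' placed at the origin, then linkers are grown ([sample_linker()]) and each
#' subsequent rigid domain is attached in a uniformly random orientation with
#' a 3.8-Angstrom connecting bond, subject to global clash checks against
#' everything already placed. Rigid domains are moved only by rotation plus
#' translation, so their internal geometry is preserved exactly.
#'
#' @param layout A [chain_layout()].
#' @param seed Optional RNG seed.
#' @param max_domain_tries Placement attempts per rigid domain (default 200).
#' @return An object of class `conformer`: `xyz` (L x 3), `resno`,
#'   `provenance` (domain name or `"linker"` per residue), `seed`, `Rg`,
#'   `Dmax`.
#' @export
assemble_conformer <- function(layout, seed = NULL, max_domain_tries = 200L) {
  stopifnot(inherits(layout, "chain_layout"))
  run <- function() .assemble(layout, max_domain_tries)
  out <- if (is.null(seed)) run() else with_seed(seed, run())
  out$seed <- if (is.null(seed)) NA_integer_ else seed
  m <- coords_metrics(bead_model(out$xyz))
  out$Rg <- m$Rg
  out$Dmax <- m$Dmax
  out
}

.assemble <- function(layout, max_tries) {
  L <- layout$length
  xyz <- matrix(NA_real_, L, 3)
  prov <- character(L)
  placed <- 0L  # residues 1..placed are set
  clash <- 3.0
  for (e in layout$elements) {
    rng <- seq.int(e$range[1], e$range[2])
    if (inherits(e, "domain_definition")) {
      if (placed == 0L) {
        xyz[rng, ] <- sweep(e$coords, 2, e$coords[1, ])
      } else {
        ok <- FALSE
        ctx <- xyz[seq_len(placed - 1L), , drop = FALSE]
        anchor <- xyz[placed, ]
        prev <- if (placed >= 2L) xyz[placed - 1L, ] else anchor - c(1, 0, 0)
        dir0 <- (anchor - prev) / sqrt(sum((anchor - prev)^2))
        for (try in seq_len(max_tries)) {
          R <- .random_rotation()
          d <- .bend_direction(dir0, c(75, 155))
          head_pos <- anchor + 3.8 * d
          cand <- e$coords %*% t(R)
          cand <- sweep(cand, 2, cand[1, ] - head_pos)
          # whole domain vs all earlier residues; the anchor is excluded for
          # the bonded head bead but not for the rest of the domain
          if (.min_cross2(cand, ctx) >= clash^2 &&
              .min_cross2(cand[-1L, , drop = FALSE],
                          matrix(anchor, 1L, 3L)) >= clash^2) {
            ok <- TRUE
            break
          }
        }
        if (!ok)
          fs_stop(sprintf("could not place domain %s without clashes", e$name),
                  "fs_sampling_failure")
        xyz[rng, ] <- cand
      }
      prov[rng] <- e$name
    } else {  # linker
      n <- length(rng)
      if (placed == 0L) {
        anchor <- c(0, 0, 0)
        dir0 <- .random_unit()
        ctx <- NULL
        w <- .grow_walk(anchor - 3.8 * dir0, dir0, n + 1L, e, ctx)
        if (is.null(w))
          fs_stop("linker sampling dead end", "fs_sampling_failure")
        xyz[rng, ] <- w[-1L, , drop = FALSE]
      } else {
        anchor <- xyz[placed, ]
        prev <- if (placed >= 2L) xyz[placed - 1L, ] else anchor - c(3.8, 0, 0)
        dir0 <- (anchor - prev) / sqrt(sum((anchor - prev)^2))
        # context includes the anchor: the bonded first walk bead sits at
        # 3.8 A > clash radius, later beads must keep their distance
        ctx <- xyz[seq_len(placed), , drop = FALSE]
        w <- .grow_walk(anchor, dir0, n, e, ctx)
        if (is.null(w))
          fs_stop("linker sampling dead end", "fs_sampling_failure")
        xyz[rng, ] <- w
      }
      prov[rng] <- "linker"
    }
    placed <- e$range[2]
  }
  structure(list(xyz = xyz, resno = seq_len(L), provenance = prov,
                 resid = NULL, seed = NA_integer_),
            class = "conformer")
}

.min_cross2 <- function(a, b) {
  if (is.null(b) || nrow(b) == 0L) return(Inf)
  cpp_min_cross_dist(a, b, 0)^2
}

#' @export
print.conformer <- function(x, ...) {
  cat(sprintf("<conformer> %d residues, Rg = %.4g A, Dmax = %.4g A (seed %s)\n",
              nrow(x$xyz), x$Rg, x$Dmax, x$seed))
  invisible(x)
}

#' Write a conformer as a C-alpha-only PDB file
#'
#' @param conformer A `conformer`.
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
write_conformer_pdb <- function(conformer, path) {
  n <- nrow(conformer$xyz)
  bio3d::write.pdb(file = path, xyz = as.numeric(t(conformer$xyz)),
                   resno = conformer$resno, resid = rep("ALA", n),
                   elety = rep("CA", n), chain = rep("A", n))
  invisible(path)
}

# --- pools -------------------------------------------------------------------

#' Generate a conformer pool
#'
#' Draws `n` independent conformers from a layout using per-conformer seeds
#' split deterministically from one master seed, so `(n, seed)` fully
#' reproduces the pool. Assembly failures are retried (up to 10 fresh seeds
#' per slot) before aborting.
#'
#' @param n Pool size; defaults to 7,000 (the scale used for published
#'   conformer-pool analyses of this kind); any n is allowed and the
#'   analyses scale down cleanly.
#' @param seed Master seed.
#' @param layout A [chain_layout()]; default [tdp43_layout()].
#' @return An object of class `conformer_pool`: `conformers`, `scores`
#'   (`NULL` until ranked), `meta`.
#' @export
generate_pool <- function(n = 7000L, seed = 1L, layout = tdp43_layout()) {
  if (n < 1L) fs_stop("n must be >= 1", "fs_argument_error")
  seeds <- split_seeds(seed, n)
  confs <- vector("list", n)
  for (i in seq_len(n)) {
    conf <- NULL
    for (retry in 0:9) {
      s <- (seeds[i] + retry * 7919L) %% (.Machine$integer.max - 1L)
      conf <- tryCatch(assemble_conformer(layout, seed = s),
                       flexscatter_error = function(e) NULL)
      if (!is.null(conf)) break
    }
    if (is.null(conf))
      fs_stop(sprintf("conformer %d failed assembly after 10 retries", i),
              "fs_sampling_failure")
    confs[[i]] <- conf
  }
  structure(list(conformers = confs, scores = NULL,
                 meta = list(n = n, seed = seed, method = "MC-linker-sampling")),
            class = "conformer_pool")
}

#' @export
print.conformer_pool <- function(x, ...) {
  rgs <- vapply(x$conformers, `[[`, numeric(1), "Rg")
  cat(sprintf("<conformer_pool> n = %d (seed %s), Rg %.3g-%.3g A%s\n",
              length(x$conformers), x$meta$seed, min(rgs), max(rgs),
              if (is.null(x$scores)) "" else ", scored"))
  invisible(x)
}

#' @export
length.conformer_pool <- function(x) length(x$conformers)

# End-to-end distance of each linker stretch of a conformer.
.linker_end_to_end <- function(conformer) {
  runs <- rle(conformer$provenance == "linker")
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  idx <- which(runs$values)
  vapply(idx, function(k) {
    sqrt(sum((conformer$xyz[ends[k], ] - conformer$xyz[starts[k], ])^2))
  }, numeric(1))
}

#' Score and rank a conformer pool against scattering data
#'
#' Computes each conformer's Debye profile on the data's q grid, fits it to
#' the data by [chi2_fit()], and sorts the pool by ascending reduced
#' chi-square. The report tabulates, for the `k` best and `k` worst
#' conformers, the whole-chain Rg, the Rg of a folded-core region (default
#' residues 1-258, the NTD+RRM1+RRM2 block), and the mean linker end-to-end
#' distance — the quantities that separate compact, well-fitting arrangements
#' from extended, poorly fitting ones.
#'
#' @param pool A `conformer_pool`.
#' @param data A [saxs_curve()] with sigma.
#' @param k Report size (default 10).
#' @param region `c(first, last)` residue range for the region Rg.
#' @param fit_background Passed to [chi2_fit()].
#' @return The pool, ranked: `conformers` sorted by score, `scores`, `order`
#'   (permutation applied), and `report` with `top` and `bottom` data frames.
#' @export
rank_pool <- function(pool, data, k = 10L, region = c(1L, 258L),
                      fit_background = FALSE) {
  stopifnot(inherits(pool, "conformer_pool"), inherits(data, "saxs_curve"))
  if (is.null(data$sigma))
    fs_stop("ranking requires data uncertainties (sigma)",
            "fs_missing_sigma_error")
  n <- length(pool$conformers)
  if (k > n) fs_stop("k exceeds the pool size", "fs_argument_error")
  scores <- vapply(pool$conformers, function(cf) {
    prof <- debye_profile(cf, data$q)
    chi2_fit(prof, data, fit_background = fit_background)$chi2
  }, numeric(1))
  ord <- order(scores)
  describe <- function(ids) {
    do.call(rbind, lapply(ids, function(i) {
      cf <- pool$conformers[[i]]
      reg <- coords_metrics(cf, residue_range = region)
      data.frame(id = i, chi2 = scores[i], Rg = cf$Rg, Dmax = cf$Dmax,
                 region_Rg = reg$Rg,
                 mean_linker_e2e = mean(.linker_end_to_end(cf)))
    }))
  }
  structure(list(conformers = pool$conformers[ord], scores = scores[ord],
                 order = ord, meta = pool$meta,
                 report = list(top = describe(ord[seq_len(k)]),
                               bottom = describe(rev(ord)[seq_len(k)]),
                               region = region)),
            class = c("ranked_pool", "conformer_pool"))
}

#' @export
print.ranked_pool <- function(x, ...) {
  cat(sprintf("<ranked_pool> n = %d, chi2 %.3g (best) .. %.3g (worst)\n",
              length(x$conformers), x$scores[1], x$scores[length(x$scores)]))
  cat("top models:\n"); print(x$report$top, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Pool manifest as a data frame
#'
#' One row per conformer: id, seed, Rg, Dmax and (if ranked) chi2. Suitable
#' for writing with [write.csv()].
#'
#' @param pool A `conformer_pool` or `ranked_pool`.
#' @return A data frame.
#' @export
pool_manifest <- function(pool) {
  data.frame(
    id = seq_along(pool$conformers),
    seed = vapply(pool$conformers, `[[`, numeric(1), "seed"),
    Rg = vapply(pool$conformers, `[[`, numeric(1), "Rg"),
    Dmax = vapply(pool$conformers, `[[`, numeric(1), "Dmax"),
    chi2 = if (is.null(pool$scores)) NA_real_ else pool$scores)
}

# --- dimers ------------------------------------------------------------------

#' Head-to-tail dimer of a full-length conformer
#'
#' Duplicates the chain and places the copy by a head-to-tail rigid transform
#' through the N-terminal domain, emulating dimerization enforced through the
#' NTD oligomerization interface. The default transform is the filament step
#' observed in the crystal packing: a rotation of 360/10 degrees about an
#' axis parallel to the NTD principal axis at 46 Angstrom from the NTD
#' centre of mass, plus a 3.62-Angstrom rise.
#'
#' @param conformer A `conformer` containing the NTD range.
#' @param transform Optional 4 x 4 homogeneous transform applied to the copy;
#'   default as described.
#' @param ntd_range NTD residue range (default `c(1, 80)`).
#' @param clash_radius Steric cutoff, Angstrom (default 3.0); more than 5% of
#'   inter-chain bead pairs below it is an error.
#' @return An object of class `conformer_dimer`: `xyz` (2L x 3), `resno`
#'   (repeated), `chain`, plus derived `Rg`, `Dmax`.
#' @export
build_dimer <- function(conformer, transform = NULL, ntd_range = c(1L, 80L),
                        clash_radius = 3.0) {
  stopifnot(inherits(conformer, "conformer"))
  if (max(ntd_range) > nrow(conformer$xyz))
    fs_stop("conformer does not contain the NTD range", "fs_argument_error")
  if (is.null(transform))
    transform <- filament_step_transform(conformer, ntd_range)
  xyz2 <- cbind(conformer$xyz, 1) %*% t(transform)
  xyz2 <- xyz2[, 1:3]
  d2 <- as.numeric(t(
    outer(rowSums(conformer$xyz^2), rowSums(xyz2^2), `+`) -
      2 * conformer$xyz %*% t(xyz2)))
  frac <- mean(d2 < clash_radius^2)
  if (frac > 0.05)
    fs_stop(sprintf("severe steric clash: %.1f%% of inter-chain pairs below %g A",
                    100 * frac, clash_radius), "fs_clash_error")
  xyz <- rbind(conformer$xyz, xyz2)
  m <- coords_metrics(bead_model(xyz))
  structure(list(xyz = xyz, resno = rep(conformer$resno, 2L),
                 chain = rep(c("A", "B"), each = nrow(conformer$xyz)),
                 provenance = rep(conformer$provenance, 2L),
                 seed = conformer$seed, Rg = m$Rg, Dmax = m$Dmax),
            class = "conformer_dimer")
}

#' Filament-step transform through the NTD
#'
#' Builds the 4 x 4 head-to-tail step of a 10-molecules-per-turn spiral
#' relative to a conformer's NTD: rotation by 36 degrees about an axis
#' parallel to the NTD principal axis, offset 46 Angstrom from the NTD
#' centre of mass, with a 3.62-Angstrom axial rise (one tenth of the
#' 36.2-Angstrom pitch).
#'
#' @param conformer A `conformer`.
#' @param ntd_range NTD residue range.
#' @param radius Axis offset, Angstrom (default 46).
#' @param turn_deg Rotation per step, degrees (default 36).
#' @param rise Axial rise per step, Angstrom (default 3.62).
#' @return A 4 x 4 homogeneous transform matrix.
#' @export
filament_step_transform <- function(conformer, ntd_range = c(1L, 80L),
                                    radius = 46, turn_deg = 36, rise = 3.62) {
  ntd <- conformer$xyz[seq.int(ntd_range[1], ntd_range[2]), , drop = FALSE]
  com <- colMeans(ntd)
  pc <- svd(sweep(ntd, 2, com))$v[, 1]
  ref <- if (abs(pc[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  w <- .cross3(pc, ref); w <- w / sqrt(sum(w^2))
  axis_point <- com + radius * w
  R <- .rodrigues(pc, turn_deg * pi / 180)
  t_vec <- axis_point - R %*% axis_point + rise * pc
  rbind(cbind(R, as.numeric(t_vec)), c(0, 0, 0, 1))
}

.rodrigues <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' @export
print.conformer_dimer <- function(x, ...) {
  cat(sprintf("<conformer_dimer> %d residues (2 chains), Rg = %.4g A, Dmax = %.4g A\n",
              nrow(x$xyz), x$Rg, x$Dmax))
  invisible(x)
}
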
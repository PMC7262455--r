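# Independent oracles and small fixture builders used across the suite.

# Closed-form pair-distance distribution of a homogeneous sphere (unit peak),
# written out independently of the package implementation.
oracle_sphere_pr <- function(R, r) {
  p <- ifelse(r < 0 | r > 2 * R, 0,
              r^2 * (1 - 3 * r / (4 * R) + r^3 / (16 * R^3)))
  p / max(p)
}

# Brute-force self-avoiding walk sampler with the same rules as
# sample_linker (bond 3.8, pseudo-angle uniform in bounds, azimuth uniform,
# non-bonded pairs >= clash radius) but a different algorithm: the whole walk
# is restarted from scratch on any clash (pure rejection, no per-bead retry
# or backtracking). Serves as the independent reference distribution.
oracle_linker_walk <- function(anchor, direction, n_res, bond = 3.8,
                               angle_bounds = c(75, 155), clash = 3.0) {
  cross3 <- function(x, y) c(x[2]*y[3] - x[3]*y[2],
                             x[3]*y[1] - x[1]*y[3],
                             x[1]*y[2] - x[2]*y[1])
  repeat {
    xyz <- matrix(NA_real_, n_res, 3)
    pd <- direction / sqrt(sum(direction^2))
    pp <- anchor
    ok <- TRUE
    for (i in seq_len(n_res)) {
      theta <- runif(1, angle_bounds[1], angle_bounds[2]) * pi / 180
      bend <- pi - theta
      a <- if (abs(pd[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      u <- cross3(pd, a); u <- u / sqrt(sum(u^2))
      v <- cross3(pd, u)
      phi <- runif(1, 0, 2 * pi)
      d <- cos(bend) * pd + sin(bend) * (cos(phi) * u + sin(phi) * v)
      cand <- pp + bond * d
      if (i > 2 && min(rowSums(sweep(xyz[seq_len(i - 2), , drop = FALSE],
                                     2, cand)^2)) < clash^2) {
        ok <- FALSE
        break
      }
      xyz[i, ] <- cand
      pp <- cand
      pd <- d
    }
    if (ok) return(xyz)
  }
}

# Uniformly bead-filled sphere (rejection sampling).
fill_sphere <- function(n, R, seed = 1) {
  set.seed(seed)
  pts <- matrix(numeric(0), 0, 3)
  while (nrow(pts) < n) {
    cand <- matrix(runif(3 * 2 * n, -R, R), ncol = 3)
    pts <- rbind(pts, cand[rowSums(cand^2) < R^2, , drop = FALSE])
  }
  pts[seq_len(n), ]
}

# Atom data frame shortcut for SASA/contact tests.
atom_df <- function(x, y, z, element = "C", elety = element, resno = 1,
                    resid = "GLY", chain = "A") {
  data.frame(chain = chain, resno = resno, resid = resid, elety = elety,
             element = element, x = x, y = y, z = z)
}

# A small layout (shorter chain) for fast model-builder tests.
small_layout <- function() {
  doms <- list(
    domain_definition("D1", c(1L, 20L), synthetic_domain_fold(20L, 11L),
                      source = "synthetic"),
    domain_definition("D2", c(31L, 50L), synthetic_domain_fold(20L, 12L),
                      source = "synthetic"))
  links <- list(linker_spec(c(21L, 30L)), linker_spec(c(51L, 70L)))
  chain_layout(doms, links)
}
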
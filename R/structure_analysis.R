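# Crystal-structure analyses: space-group symmetry expansion, helical
# filament tracing and geometry, interface polar contacts, and Shrake-Rupley
# solvent accessible surface area with empirical percentile scoring.

#' Construct a crystal structure object
#'
#' @param atoms Data frame with columns `chain`, `resno`, `resid`, `elety`,
#'   `element`, `x`, `y`, `z` (Cartesian Angstrom).
#' @param cell Numeric `c(a, b, c, alpha, beta, gamma)` (Angstrom, degrees).
#' @param spacegroup Space-group symbol, e.g. `"P 21 21 21"`.
#' @return An object of class `crystal_structure`.
#' @export
crystal_structure <- function(atoms, cell, spacegroup) {
  need <- c("chain", "resno", "resid", "elety", "element", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    fs_stop(paste("atoms must have columns", paste(need, collapse = ", ")),
            "fs_validation_error")
  structure(list(atoms = atoms, cell = as.numeric(cell),
                 spacegroup = spacegroup), class = "crystal_structure")
}

#' @export
print.crystal_structure <- function(x, ...) {
  cat(sprintf("<crystal_structure> %d atoms, %d chain(s), %s, cell %.3f %.3f %.3f\n",
              nrow(x$atoms), length(unique(x$atoms$chain)), x$spacegroup,
              x$cell[1], x$cell[2], x$cell[3]))
  invisible(x)
}

#' Read a crystal structure from a PDB file
#'
#' Atom records are parsed with [bio3d::read.pdb()]; the unit cell and
#' space-group symbol are taken from the CRYST1 record.
#'
#' @param path PDB file path.
#' @return A [crystal_structure()] (cell/spacegroup `NULL` when no CRYST1
#'   record is present).
#' @export
read_structure <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  element <- if (!is.null(a$elesy) && any(nzchar(trimws(a$elesy))))
    toupper(trimws(a$elesy)) else toupper(substr(trimws(a$elety), 1, 1))
  atoms <- data.frame(chain = a$chain, resno = a$resno, resid = a$resid,
                      elety = trimws(a$elety), element = element,
                      x = a$x, y = a$y, z = a$z)
  cell <- NULL; sg <- NULL
  ln <- grep("^CRYST1", readLines(path, warn = FALSE), value = TRUE)
  if (length(ln)) {
    ln <- ln[1]
    cell <- as.numeric(c(substr(ln, 7, 15), substr(ln, 16, 24),
                         substr(ln, 25, 33), substr(ln, 34, 40),
                         substr(ln, 41, 47), substr(ln, 48, 54)))
    sg <- trimws(substr(ln, 56, 66))
  }
  crystal_structure(atoms, cell, sg)
}

#' Write a crystal structure as a PDB file with a CRYST1 record
#'
#' @param struct A [crystal_structure()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(struct, path) {
  a <- struct$atoms
  cr <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s", struct$cell[1],
                struct$cell[2], struct$cell[3], struct$cell[4], struct$cell[5],
                struct$cell[6], struct$spacegroup)
  at <- sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                seq_len(nrow(a)), a$elety, a$resid, a$chain, a$resno,
                a$x, a$y, a$z, a$element)
  writeLines(c(cr, at, "END"), path)
  invisible(path)
}

# --- space-group machinery ---------------------------------------------------

# Built-in operator tables (fractional coordinates): rotation matrix R and
# translation t, so x' = R x + t. Additional symbols can be registered by
# passing an `ops` list directly to expand_symmetry().
space_group_ops <- function(symbol) {
  key <- toupper(gsub("[ _]", "", symbol))
  op <- function(R, t) list(R = matrix(R, 3, 3, byrow = TRUE), t = t)
  tabs <- list(
    P1 = list(op(c(1,0,0, 0,1,0, 0,0,1), c(0, 0, 0))),
    P212121 = list(
      op(c( 1,0,0, 0, 1,0, 0,0, 1), c(0, 0, 0)),
      op(c( 1,0,0, 0,-1,0, 0,0,-1), c(0.5, 0.5, 0)),
      op(c(-1,0,0, 0, 1,0, 0,0,-1), c(0, 0.5, 0.5)),
      op(c(-1,0,0, 0,-1,0, 0,0, 1), c(0.5, 0, 0.5))),
    P63 = list(
      op(c( 1, 0,0, 0, 1,0, 0,0,1), c(0, 0, 0)),
      op(c( 0,-1,0, 1,-1,0, 0,0,1), c(0, 0, 0)),
      op(c(-1, 1,0, -1, 0,0, 0,0,1), c(0, 0, 0)),
      op(c(-1, 0,0, 0,-1,0, 0,0,1), c(0, 0, 0.5)),
      op(c( 0, 1,0, -1, 1,0, 0,0,1), c(0, 0, 0.5)),
      op(c( 1,-1,0, 1, 0,0, 0,0,1), c(0, 0, 0.5))))
  if (is.null(tabs[[key]]))
    fs_stop(sprintf("unsupported space group '%s' (supported: P1, P21 21 21, P63)",
                    symbol), "fs_unsupported_space_group")
  tabs[[key]]
}

# Fractional -> Cartesian cell matrix (a along x, b in the xy plane).
cell_matrix <- function(cell) {
  a <- cell[1]; b <- cell[2]; cc <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  v <- sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 +
              2 * cos(al) * cos(be) * cos(ga))
  matrix(c(a, b * cos(ga), cc * cos(be),
           0, b * sin(ga), cc * (cos(al) - cos(be) * cos(ga)) / sin(ga),
           0, 0, cc * v / sin(ga)), 3, 3, byrow = TRUE)
}

#' Expand crystal symmetry into a contact assembly
#'
#' Applies the space-group operators plus lattice translations and retains
#' every symmetry copy of every chain that touches the growing assembly
#' (any interatomic distance below `contact_radius`), starting from the
#' reference asymmetric unit and iterating so that contiguous filaments are
#' extended across multiple unit cells.
#'
#' @param struct A [crystal_structure()] with cell and space group set.
#' @param contact_radius Contact distance, Angstrom (default 4.5).
#' @param shells Lattice translation range, cells (default 2, i.e. -2..2 in
#'   each direction).
#' @param max_iter Contact-growth sweeps (default 10; growth usually
#'   completes in one breadth-first sweep).
#' @param ops Optional explicit operator list overriding the built-in table.
#' @return An object of class `crystal_assembly`: `molecules`, each with
#'   `chain`, `op` (operator index), `shift` (lattice translation), `xyz`,
#'   `atoms` (row indices into `struct$atoms`), plus `cell`, `spacegroup`.
#' @export
expand_symmetry <- function(struct, contact_radius = 4.5, shells = 2L,
                            max_iter = 10L, ops = NULL) {
  stopifnot(inherits(struct, "crystal_structure"))
  if (is.null(struct$cell) || is.null(struct$spacegroup))
    fs_stop("structure lacks cell/space-group information (CRYST1)",
            "fs_validation_error")
  if (is.null(ops)) ops <- space_group_ops(struct$spacegroup)
  M <- cell_matrix(struct$cell)
  Minv <- solve(M)
  chains <- split(seq_len(nrow(struct$atoms)), struct$atoms$chain)
  frac <- lapply(chains, function(idx)
    unname(t(Minv %*% t(as.matrix(struct$atoms[idx, c("x", "y", "z")])))))

  sh <- seq.int(-shells, shells)
  grid <- expand.grid(sx = sh, sy = sh, sz = sh)
  # all candidate molecules
  cand <- list()
  for (ci in seq_along(chains)) for (oi in seq_along(ops)) {
    f1 <- t(ops[[oi]]$R %*% t(frac[[ci]])) +
      matrix(ops[[oi]]$t, nrow(frac[[ci]]), 3, byrow = TRUE)
    for (g in seq_len(nrow(grid))) {
      shift <- as.numeric(grid[g, ])
      xyz <- t(M %*% t(f1 + matrix(shift, nrow(f1), 3, byrow = TRUE)))
      cand[[length(cand) + 1L]] <- list(
        chain = names(chains)[ci], op = oi, shift = shift, xyz = xyz,
        atoms = chains[[ci]], com = colMeans(xyz),
        rad = sqrt(max(rowSums(sweep(xyz, 2, colMeans(xyz))^2))),
        is_ref = oi == 1L && all(shift == 0))
    }
  }
  retained <- vapply(cand, `[[`, logical(1), "is_ref")
  for (it in seq_len(max_iter)) {
    grew <- FALSE
    ridx <- which(retained)   # grows within the sweep (breadth-first)
    for (k in which(!retained)) {
      for (r in ridx) {
        gap <- sqrt(sum((cand[[k]]$com - cand[[r]]$com)^2)) -
          cand[[k]]$rad - cand[[r]]$rad
        if (gap > contact_radius) next
        if (cpp_min_cross_dist(cand[[k]]$xyz, cand[[r]]$xyz,
                               contact_radius) < contact_radius) {
          retained[k] <- TRUE
          ridx <- c(ridx, k)
          grew <- TRUE
          break
        }
      }
    }
    if (!grew) break
  }
  mols <- cand[retained]
  # stable ordering, no duplicate (chain, op, shift) possible by construction
  structure(list(molecules = mols, cell = struct$cell,
                 spacegroup = struct$spacegroup, struct = struct),
            class = "crystal_assembly")
}

#' @export
print.crystal_assembly <- function(x, ...) {
  cat(sprintf("<crystal_assembly> %d molecules (%s)\n", length(x$molecules),
              x$spacegroup))
  invisible(x)
}

#' Trace a head-to-tail filament through an assembly
#'
#' Builds the molecule contact graph (adjacent when any interatomic distance
#' is below `contact_cutoff`), takes its largest connected component, and
#' returns the molecules in path order. The component must be an unbranched
#' simple path — a branched contact graph has no unique filament order and
#' raises an ambiguity error reporting the degree distribution.
#'
#' @param assembly A `crystal_assembly`, or a list of molecules each carrying
#'   an `xyz` matrix.
#' @param contact_cutoff Contact distance, Angstrom (default 4.5).
#' @return The molecules of the filament, ordered, as a list; the ordering
#'   indices are in `attr(, "order")`.
#' @export
trace_filament <- function(assembly, contact_cutoff = 4.5) {
  mols <- if (inherits(assembly, "crystal_assembly")) assembly$molecules
          else assembly
  if (!length(mols)) fs_stop("empty assembly", "fs_argument_error")
  n <- length(mols)
  if (n == 1L) return(structure(mols, order = 1L))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    adj[i, j] <- adj[j, i] <-
      cpp_min_cross_dist(mols[[i]]$xyz, mols[[j]]$xyz, contact_cutoff) <
        contact_cutoff
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  main <- which(comp$membership == which.max(comp$csize))
  sub <- igraph::induced_subgraph(g, main)
  deg <- igraph::degree(sub)
  if (any(deg > 2) || igraph::ecount(sub) != length(main) - 1L)
    fs_stop(sprintf("branched/cyclic contact graph, no unique path (degrees: %s)",
                    paste(sort(unique(deg)), collapse = ",")),
            "fs_ambiguity_error")
  ends <- which(deg <= 1L)
  ord_local <- as.integer(igraph::dfs(sub, root = ends[1])$order)
  ord <- main[ord_local]
  structure(mols[ord], order = ord)
}

# --- helix geometry ----------------------------------------------------------

#' Fit helical parameters to an ordered filament
#'
#' Estimates the helix axis from the centres of mass of the ordered
#' molecules: for an ideal helix the second differences of consecutive COMs
#' have no axial component, so the axis direction is the smallest principal
#' direction of the stacked second differences; the axis position is then an
#' algebraic circle fit of the COMs projected onto the normal plane. Per-step
#' azimuth and rise give
#' `molecules_per_turn = 360 / mean(delta_phi)` and
#' `pitch = molecules_per_turn * mean(delta_z)` (exact identity, enforced by
#' construction). Atomic coordinates, when supplied, give the outer and
#' inner radii of the spiral.
#'
#' @param ordered_coms m x 3 matrix of molecule centres of mass in filament
#'   order (m >= 4), or an ordered molecule list from [trace_filament()]
#'   (COMs and atoms are then taken from it).
#' @param atoms Optional matrix of all atomic coordinates of the filament.
#' @return An object of class `helix_params`: `axis_point`, `axis_dir`,
#'   `radius` (mean COM-to-axis distance), `rise_per_molecule`,
#'   `molecules_per_turn`, `pitch`, `outer_radius`, `inner_radius`.
#' @export
fit_helix <- function(ordered_coms, atoms = NULL) {
  if (is.list(ordered_coms) && !is.matrix(ordered_coms)) {
    mols <- ordered_coms
    ordered_coms <- do.call(rbind, lapply(mols, `[[`, "com"))
    if (is.null(atoms)) atoms <- do.call(rbind, lapply(mols, `[[`, "xyz"))
  }
  P <- as.matrix(ordered_coms)
  m <- nrow(P)
  if (m < 4L) fs_stop("need at least 4 ordered points", "fs_insufficient_data")
  ctr <- colMeans(P)
  sv <- svd(sweep(P, 2, ctr))
  if (sv$d[2] / sv$d[1] < 1e-8)
    fs_stop("points are collinear; helix axis undefined",
            "fs_degenerate_geometry")
  # axis direction: null direction of the second differences
  S <- P[-c(1, 2), , drop = FALSE] - 2 * P[-c(1, m), , drop = FALSE] +
    P[-c(m - 1, m), , drop = FALSE]
  axis_dir <- svd(S)$v[, 3]
  # orient along the filament
  if (sum((P[m, ] - P[1, ]) * axis_dir) < 0) axis_dir <- -axis_dir
  # in-plane frame
  ref <- if (abs(axis_dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- .cross3(axis_dir, ref); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- .cross3(axis_dir, e1)
  u <- sweep(P, 2, ctr) %*% cbind(e1, e2)   # projected COMs
  # Kasa algebraic circle fit: |p - c|^2 = r^2
  A <- cbind(2 * u, 1)
  sol <- qr.solve(A, rowSums(u^2))
  c2d <- sol[1:2]
  axis_point <- ctr + c2d[1] * e1 + c2d[2] * e2
  rel <- sweep(P, 2, axis_point)
  z <- as.numeric(rel %*% axis_dir)
  uu <- rel %*% cbind(e1, e2)
  phi <- atan2(uu[, 2], uu[, 1])
  dphi <- diff(phi)
  dphi <- (dphi + pi) %% (2 * pi) - pi      # unwrap to (-pi, pi]
  radius <- mean(sqrt(rowSums(uu^2)))
  step_phi <- mean(abs(dphi)) * 180 / pi
  rise <- mean(abs(diff(z)))
  mpt <- 360 / step_phi
  outer_r <- inner_r <- NA_real_
  if (!is.null(atoms)) {
    ra <- sweep(as.matrix(atoms), 2, axis_point)
    d_ax <- sqrt(rowSums(ra^2) - as.numeric(ra %*% axis_dir)^2)
    outer_r <- max(d_ax); inner_r <- min(d_ax)
  }
  structure(list(axis_point = axis_point, axis_dir = axis_dir,
                 radius = radius, rise_per_molecule = rise,
                 molecules_per_turn = mpt, pitch = mpt * rise,
                 outer_radius = outer_r, inner_radius = inner_r),
            class = "helix_params")
}

#' @export
print.helix_params <- function(x, ...) {
  cat(sprintf(paste0("<helix_params> %.4g molecules/turn, COM radius %.4g A,",
                     " rise %.4g A, pitch %.4g A\n  atomic radii: inner %.4g,",
                     " outer %.4g A\n"),
              x$molecules_per_turn, x$radius, x$rise_per_molecule, x$pitch,
              x$inner_radius, x$outer_radius))
  invisible(x)
}

# --- SASA --------------------------------------------------------------------

.default_vdw <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)

.backbone_elety <- c("N", "CA", "C", "O", "OXT")

#' Shrake-Rupley solvent accessible surface area
#'
#' Samples `n_points` test points on each atom's solvent-expanded sphere
#' (van der Waals radius + probe) by a golden-angle spiral; points falling
#' inside any neighbour's expanded sphere are occluded, and the accessible
#' fraction scales the sphere area. Per-residue sums are reported for the
#' whole residue and for the side chain (all atoms beyond and including
#' C-beta, i.e. everything except N, CA, C, O, OXT).
#'
#' @param struct A [crystal_structure()] or an atoms data frame with
#'   `element`, `x`, `y`, `z` (and `chain`, `resno`, `resid`, `elety` for the
#'   per-residue table).
#' @param probe Probe radius, Angstrom (default 1.4).
#' @param n_points Test points per atom (default 960).
#' @param radii Named van der Waals radius table, Angstrom; defaults to
#'   C 1.70, N 1.55, O 1.52, S 1.80 (plus H 1.20, P 1.80).
#' @return An object of class `sasa_result`: `atom_sasa` (per atom, Angstrom
#'   squared) and `residues` data frame (chain, resno, resid,
#'   sidechain_sasa, total_sasa).
#' @export
shrake_rupley <- function(struct, probe = 1.4, n_points = 960L,
                          radii = .default_vdw) {
  atoms <- if (inherits(struct, "crystal_structure")) struct$atoms else struct
  el <- toupper(atoms$element)
  unknown <- setdiff(unique(el), names(radii))
  if (length(unknown))
    fs_stop(sprintf("unknown element(s): %s (extend the radius table)",
                    paste(unknown, collapse = ", ")), "fs_unknown_element")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  sasa <- cpp_sasa(xyz, unname(radii[el]), probe, as.integer(n_points))
  residues <- NULL
  if (all(c("chain", "resno", "resid", "elety") %in% names(atoms))) {
    key <- paste(atoms$chain, atoms$resno, sep = "|")
    side <- !(toupper(trimws(atoms$elety)) %in% .backbone_elety)
    residues <- do.call(rbind, lapply(split(seq_along(key), key), function(i) {
      data.frame(chain = atoms$chain[i[1]], resno = atoms$resno[i[1]],
                 resid = atoms$resid[i[1]],
                 sidechain_sasa = sum(sasa[i][side[i]]),
                 total_sasa = sum(sasa[i]))
    }))
    residues <- residues[order(residues$chain, residues$resno), ]
    rownames(residues) <- NULL
  }
  structure(list(atom_sasa = sasa, residues = residues, probe = probe,
                 n_points = n_points), class = "sasa_result")
}

#' Empirical SASA reference distribution
#'
#' A sorted set of solvent-accessibility values for one residue type, drawn
#' from a database of protein structures, against which an observed value is
#' scored as a cumulative percentile.
#'
#' @param values Numeric SASA values, Angstrom squared.
#' @param residue Residue type (default `"TRP"`).
#' @param source Free-text provenance.
#' @return An object of class `reference_distribution`.
#' @export
reference_distribution <- function(values, residue = "TRP", source = "") {
  values <- sort(as.numeric(values))
  if (!length(values))
    fs_stop("reference must be non-empty", "fs_argument_error")
  structure(list(residue = residue, values = values, n = length(values),
                 source = source), class = "reference_distribution")
}

#' Read a SASA reference distribution from a text file
#'
#' One numeric value per line (Angstrom squared); `#` comment lines are
#' skipped. A small synthetic tryptophan reference ships with the package:
#' `system.file("extdata", "trp_sasa_reference_synthetic.txt", package =
#' "flexscatter")`. It is a generated stand-in shaped like an empirical
#' side-chain accessibility distribution, for demonstration only — percentile
#' claims about real structures require a real database reference.
#'
#' @param path File path.
#' @param residue Residue type label (default `"TRP"`).
#' @return A [reference_distribution()].
#' @export
read_reference_distribution <- function(path, residue = "TRP") {
  ln <- readLines(path, warn = FALSE)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  v <- suppressWarnings(as.numeric(ln))
  if (anyNA(v))
    fs_stop(sprintf("non-numeric reference values in %s", path),
            "fs_format_error")
  reference_distribution(v, residue = residue, source = path)
}

#' Percentile of a SASA value in a reference distribution
#'
#' Empirical CDF with midpoint tie handling:
#' \eqn{100 (\#\mathrm{below} + 0.5\,\#\mathrm{equal}) / n}.
#'
#' @param value SASA value(s), Angstrom squared.
#' @param ref A [reference_distribution()].
#' @return Percentile(s) in 0-100.
#' @export
sasa_percentile <- function(value, ref) {
  stopifnot(inherits(ref, "reference_distribution"))
  vapply(value, function(v)
    100 * (sum(ref$values < v) + 0.5 * sum(ref$values == v)) / ref$n,
    numeric(1))
}

#' Polar contacts across a molecular interface
#'
#' All donor/acceptor-capable atom pairs (elements N, O, S) with one atom in
#' each molecule and interatomic distance at most `cutoff` — the
#' hydrogen-bond-distance contacts of a packing interface.
#'
#' @param molA,molB Atom data frames (`element`, `x`, `y`, `z`, and
#'   optionally `resno`, `resid`, `elety`) or molecules carrying `xyz`.
#' @param cutoff Distance cutoff, Angstrom (default 3.5).
#' @return Data frame: residue/atom identifiers of both partners and the
#'   distance; zero rows when no contact exists.
#' @export
interface_contacts <- function(molA, molB, cutoff = 3.5) {
  fa <- .contact_atoms(molA); fb <- .contact_atoms(molB)
  if (!nrow(fa) || !nrow(fb))
    fs_stop("both molecules must contain atoms", "fs_argument_error")
  pa <- as.matrix(fa[, c("x", "y", "z")])
  pb <- as.matrix(fb[, c("x", "y", "z")])
  keepA <- fa$element %in% c("N", "O", "S")
  keepB <- fb$element %in% c("N", "O", "S")
  out <- list()
  for (i in which(keepA)) {
    d <- sqrt(colSums((t(pb[keepB, , drop = FALSE]) - pa[i, ])^2))
    hit <- which(d <= cutoff)
    for (h in seq_along(hit)) {
      j <- which(keepB)[hit[h]]
      out[[length(out) + 1L]] <- data.frame(
        resno_a = fa$resno[i], resid_a = fa$resid[i], atom_a = fa$elety[i],
        resno_b = fb$resno[j], resid_b = fb$resid[j], atom_b = fb$elety[j],
        distance = d[hit[h]])
    }
  }
  if (!length(out))
    return(data.frame(resno_a = integer(), resid_a = character(),
                      atom_a = character(), resno_b = integer(),
                      resid_b = character(), atom_b = character(),
                      distance = numeric()))
  do.call(rbind, out)
}

.contact_atoms <- function(mol) {
  if (is.data.frame(mol)) {
    df <- mol
  } else if (!is.null(mol$xyz)) {
    df <- data.frame(x = mol$xyz[, 1], y = mol$xyz[, 2], z = mol$xyz[, 3])
    src <- if (!is.null(mol$struct_atoms)) mol$struct_atoms else NULL
    if (!is.null(src)) df <- cbind(src, df)
  } else fs_stop("cannot interpret molecule", "fs_argument_error")
  for (col in c("resno", "resid", "elety", "element")) {
    if (is.null(df[[col]]))
      df[[col]] <- if (col == "resno") seq_len(nrow(df)) else ""
  }
  df
}

#' Molecule atoms of an assembly member as a data frame
#'
#' Joins a symmetry copy's transformed coordinates with the reference atom
#' metadata, for contact and SASA analyses.
#'
#' @param assembly A `crystal_assembly`.
#' @param i Molecule index.
#' @return Atoms data frame.
#' @export
assembly_atoms <- function(assembly, i) {
  m <- assembly$molecules[[i]]
  df <- assembly$struct$atoms[m$atoms, ]
  df$x <- m$xyz[, 1]; df$y <- m$xyz[, 2]; df$z <- m$xyz[, 3]
  rownames(df) <- NULL
  df
}

# --- synthetic filament crystal ----------------------------------------------

#' Synthetic filament crystal (stand-in for a deposited NTD crystal)
#'
#' A programmatically constructed P2(1)2(1)2(1) crystal whose asymmetric unit
#' holds five identical synthetic molecules arranged so that the 2(1) screw
#' along `a` continues them into a head-to-tail spiral with the published
#' TDP-43 NTD filament geometry: 10 molecules per full turn (two asymmetric
#' units), centre-of-mass radius 46 Angstrom, pitch 36.2 Angstrom (the `a`
#' axis), and outer atomic radius 92 Angstrom. The molecules are SYNTHETIC
#' geometric bodies (an arc of backbone-like atoms following the spiral plus
#' a thin radial arm reaching the outer radius), not protein models: the
#' object exists so the symmetry-expansion, filament-tracing and helix-fitting
#' machinery can be exercised end to end against known geometry when the real
#' accession is not at hand.
#'
#' @param com_radius Target COM-to-axis distance, Angstrom (default 46).
#' @param pitch Helix pitch = cell `a` axis, Angstrom (default 36.2).
#' @param outer_radius Outermost atom radius, Angstrom (default 92).
#' @param mols_per_turn Molecules per full turn (default 10; 5 per ASU).
#' @param n_arc Arc atoms per molecule (default 60).
#' @return A [crystal_structure()].
#' @export
synthetic_filament_crystal <- function(com_radius = 46, pitch = 36.2,
                                       outer_radius = 92, mols_per_turn = 10L,
                                       n_arc = 60L) {
  # b and c are set large enough that symmetry-related spirals (axis
  # separation sqrt(2)*b/2) can never contact the reference spiral.
  cell <- c(pitch, 300, 300, 90, 90, 90)
  axis_y <- cell[2] / 4  # rotation axis of the 2(1) screw along a: (x, b/4, 0)
  per_asu <- mols_per_turn %/% 2L
  rise <- pitch / mols_per_turn
  dphi <- 2 * pi / mols_per_turn
  arm_r <- c(0.5, 0.75, 1) * (outer_radius - com_radius) + com_radius
  span <- 0.93  # fraction of the inter-molecule step covered by the arc

  mol_atoms <- function(k, r_arc) {
    t0 <- k; tt <- seq(t0, t0 + span, length.out = n_arc)
    phi <- tt * dphi
    arc <- cbind(x = tt * rise,
                 y = axis_y + r_arc * cos(phi),
                 z = r_arc * sin(phi))
    pm <- phi[n_arc %/% 2]
    arm <- cbind(x = tt[n_arc %/% 2] * rise,
                 y = axis_y + arm_r * cos(pm),
                 z = arm_r * sin(pm))
    rbind(arc, arm)
  }
  com_r_of <- function(r_arc) {
    a <- mol_atoms(0L, r_arc)
    com <- colMeans(a)
    sqrt((com[2] - axis_y)^2 + com[3]^2)
  }
  r_arc <- uniroot(function(r) com_r_of(r) - com_radius,
                   c(com_radius - 10, com_radius + 5), tol = 1e-10)$root

  chains <- LETTERS[seq_len(per_asu)]
  atoms <- do.call(rbind, lapply(seq_len(per_asu), function(k) {
    a <- mol_atoms(k - 1L, r_arc)
    n <- nrow(a)
    elety <- c("N", rep("CA", n_arc - 2L), "O", rep("CB", n - n_arc))
    data.frame(chain = chains[k], resno = seq_len(n), resid = "GLY",
               elety = elety,
               element = c("N", rep("C", n_arc - 2L), "O",
                           rep("C", n - n_arc)),
               x = a[, 1], y = a[, 2], z = a[, 3])
  }))
  crystal_structure(atoms, cell, "P 21 21 21")
}
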
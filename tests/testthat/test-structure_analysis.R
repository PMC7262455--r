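# small helper: cluster of points around a centre
blob <- function(center, n = 12, spread = 2, seed = 1) {
  set.seed(seed)
  sweep(matrix(rnorm(n * 3, sd = spread), ncol = 3), 2, center, `+`)
}

helix_points <- function(m, radius = 46, dphi_deg = 36, rise = 3.62) {
  i <- seq_len(m) - 1
  cbind(radius * cos(i * dphi_deg * pi / 180),
        radius * sin(i * dphi_deg * pi / 180),
        i * rise)
}

test_that("P1 expansion of an isolated chain keeps only the identity copy", {
  at <- atom_df(c(0, 1.5, 3), c(0, 0, 0), c(0, 0, 0), resno = 1:3)
  st <- crystal_structure(at, cell = c(200, 200, 200, 90, 90, 90), "P 1")
  asm <- expand_symmetry(st, contact_radius = 4.0)
  expect_length(asm$molecules, 1L)
  expect_equal(asm$molecules[[1]]$xyz,
               unname(as.matrix(at[, c("x", "y", "z")])), tolerance = 1e-9)
})

test_that("every expanded copy superposes on the reference after inverting its operator", {
  st <- synthetic_filament_crystal()
  asm <- expand_symmetry(st, contact_radius = 3.0)
  M <- flexscatter:::cell_matrix(st$cell)
  Minv <- solve(M)
  ops <- flexscatter:::space_group_ops(st$spacegroup)
  for (mol in asm$molecules[seq_len(min(10, length(asm$molecules)))]) {
    ref <- as.matrix(st$atoms[mol$atoms, c("x", "y", "z")])
    frac <- t(Minv %*% t(mol$xyz)) -
      matrix(mol$shift, nrow(mol$xyz), 3, byrow = TRUE)
    op <- ops[[mol$op]]
    undone <- t(solve(op$R) %*% t(frac - matrix(op$t, nrow(frac), 3, byrow = TRUE)))
    back <- t(M %*% t(undone))
    expect_lt(sqrt(mean((back - ref)^2)), 1e-6)
  }
  expect_error(space_group_ops("I 4 3 2"), class = "fs_unsupported_space_group")
})

test_that("filament tracing returns construction order and flags branches", {
  coms <- helix_points(8)
  mols <- lapply(seq_len(8), function(i)
    list(xyz = blob(coms[i, ], seed = i), com = coms[i, ]))
  # make consecutive blobs touch via a bridging atom near the neighbour
  for (i in 1:7)
    mols[[i]]$xyz <- rbind(mols[[i]]$xyz, mols[[i + 1]]$xyz[1, ] + 0.5)
  fil <- trace_filament(mols, contact_cutoff = 2.0)
  ord <- attr(fil, "order")
  expect_true(identical(ord, 1:8) || identical(ord, 8:1))

  single <- trace_filament(mols[1], contact_cutoff = 2.0)
  expect_length(single, 1L)

  # 3-branch star: centre touches three arms
  ctr <- list(xyz = matrix(0, 1, 3))
  arms <- lapply(list(c(3, 0, 0), c(0, 3, 0), c(0, 0, 3)),
                 function(p) list(xyz = matrix(p, 1, 3)))
  expect_error(trace_filament(c(list(ctr), arms), contact_cutoff = 4),
               class = "fs_ambiguity_error")
})

test_that("helix fitting inverts a constructed helix exactly and is rotation invariant", {
  P <- helix_points(20)
  hx <- fit_helix(P)
  expect_equal(hx$molecules_per_turn, 10, tolerance = 1e-6)
  expect_equal(hx$radius, 46, tolerance = 1e-6)
  expect_equal(hx$rise_per_molecule, 3.62, tolerance = 1e-6)
  expect_equal(hx$pitch, 36.2, tolerance = 1e-6)
  expect_equal(hx$pitch, hx$molecules_per_turn * hx$rise_per_molecule)

  R <- flexscatter:::.rodrigues(c(1, 1, 0), 0.9)
  Pr <- P %*% t(R) + matrix(c(10, -5, 2), 20, 3, byrow = TRUE)
  hr <- fit_helix(Pr)
  expect_equal(hr$radius, hx$radius, tolerance = 1e-6)
  expect_equal(hr$pitch, hx$pitch, tolerance = 1e-6)
  expect_equal(hr$molecules_per_turn, hx$molecules_per_turn, tolerance = 1e-6)

  line <- cbind(seq_len(10), 2 * seq_len(10), -seq_len(10))
  expect_error(fit_helix(line), class = "fs_degenerate_geometry")
})

test_that("Shrake-Rupley matches sphere areas, occlusion and additivity", {
  iso <- atom_df(0, 0, 0, element = "C")
  s <- shrake_rupley(iso)
  expect_equal(s$atom_sasa, 4 * pi * (1.70 + 1.4)^2, tolerance = 0.01)

  # fully enclosed atom: cage of 60 neighbours at 3 A
  set.seed(2)
  th <- acos(seq(-1 + 1/60, 1 - 1/60, length.out = 60))
  ph <- pi * (3 - sqrt(5)) * seq_len(60)
  cage <- atom_df(c(0, 3 * sin(th) * cos(ph)), c(0, 3 * sin(th) * sin(ph)),
                  c(0, 3 * cos(th)), element = "C", resno = 1:61)
  sc <- shrake_rupley(cage)
  expect_equal(sc$atom_sasa[1], 0)

  # two distant atoms are independent
  pair <- atom_df(c(0, 50), c(0, 0), c(0, 0), element = c("C", "S"),
                  resno = 1:2)
  sp <- shrake_rupley(pair)
  expect_equal(sp$atom_sasa[1], 4 * pi * 3.1^2, tolerance = 0.01)
  expect_equal(sp$atom_sasa[2], 4 * pi * (1.8 + 1.4)^2, tolerance = 0.01)

  expect_error(shrake_rupley(atom_df(0, 0, 0, element = "ZZ")),
               class = "fs_unknown_element")
})

test_that("Shrake-Rupley converges in the number of test points", {
  set.seed(5)
  fx <- atom_df(rnorm(50, sd = 7), rnorm(50, sd = 7), rnorm(50, sd = 7),
                element = sample(c("C", "N", "O", "S"), 50, replace = TRUE),
                resno = 1:50)
  # worst-case per-atom quasi-sampling error scales ~ n^(-3/4); doubling
  # from 1920 points moves no atom by 0.5% of a full sphere area
  a <- shrake_rupley(fx, n_points = 1920)$atom_sasa
  b <- shrake_rupley(fx, n_points = 3840)$atom_sasa
  area <- 4 * pi * 3.1^2
  expect_lt(max(abs(a - b)) / area, 0.005)
  # and the default 960-point grid already sits within 1% of the refined one
  a0 <- shrake_rupley(fx, n_points = 960)$atom_sasa
  expect_lt(max(abs(a0 - b)) / area, 0.01)
})

test_that("side-chain SASA excludes backbone atoms", {
  res <- atom_df(c(0, 1.5, 3.0, 4.0, 1.5), c(0, 0, 0, 1, -1.5), rep(0, 5),
                 element = c("N", "C", "C", "O", "C"),
                 elety = c("N", "CA", "C", "O", "CB"), resno = 1)
  s <- shrake_rupley(res)
  expect_equal(nrow(s$residues), 1L)
  cb <- s$atom_sasa[5]
  expect_equal(s$residues$sidechain_sasa, cb)
  expect_equal(s$residues$total_sasa, sum(s$atom_sasa))
})

test_that("percentile scoring follows the midpoint empirical CDF", {
  ref <- reference_distribution(c(5, 10, 15, 20, 25))
  expect_equal(sasa_percentile(15, ref), 50)          # median of odd-sized ref
  expect_equal(sasa_percentile(100, ref), 100)        # above every entry
  expect_equal(sasa_percentile(1, reference_distribution(7)), 0)
  expect_equal(sasa_percentile(12, ref), 40)          # 2 below, none equal
  # monotone non-decreasing
  v <- sasa_percentile(seq(0, 30, by = 0.5), ref)
  expect_true(all(diff(v) >= 0))
  expect_error(reference_distribution(numeric(0)), class = "fs_argument_error")
})

test_that("the shipped synthetic reference file loads and scores sensibly", {
  f <- system.file("extdata", "trp_sasa_reference_synthetic.txt",
                   package = "flexscatter")
  ref <- read_reference_distribution(f)
  expect_equal(ref$n, 600L)
  expect_true(!is.unsorted(ref$values))
  expect_equal(sasa_percentile(max(ref$values) + 1, ref), 100)
  expect_gt(sasa_percentile(150, ref), sasa_percentile(10, ref))
})

test_that("interface contacts pick up polar pairs within the cutoff", {
  a <- atom_df(0, 0, 0, element = "N", elety = "NH1", resno = 52,
               resid = "ARG")
  b34 <- atom_df(3.4, 0, 0, element = "O", elety = "O1", resno = 1,
                 resid = "SO4")
  hits <- interface_contacts(a, b34)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$distance, 3.4)
  expect_equal(hits$resid_a, "ARG")

  b36 <- atom_df(3.6, 0, 0, element = "O", elety = "O1", resno = 1)
  expect_equal(nrow(interface_contacts(a, b36)), 0L)

  # carbon pairs never count
  c1 <- atom_df(0, 0, 0, element = "C")
  c2 <- atom_df(3.0, 0, 0, element = "C")
  expect_equal(nrow(interface_contacts(c1, c2)), 0L)
})

test_that("structure PDB round trip preserves cell, symbol and coordinates", {
  st <- synthetic_filament_crystal(n_arc = 20)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(st, f)
  back <- read_structure(f)
  expect_equal(back$cell, st$cell, tolerance = 1e-3)
  expect_equal(back$spacegroup, st$spacegroup)
  expect_equal(back$atoms$x, st$atoms$x, tolerance = 1e-3)
  expect_equal(sort(unique(back$atoms$chain)), sort(unique(st$atoms$chain)))
})

test_that("head-to-tail neighbours in the synthetic filament share a polar contact", {
  st <- synthetic_filament_crystal()
  asm <- expand_symmetry(st, contact_radius = 3.0, shells = 1L, max_iter = 2L)
  fil <- trace_filament(asm, contact_cutoff = 3.0)
  ord <- attr(fil, "order")
  a1 <- assembly_atoms(asm, ord[1])
  a2 <- assembly_atoms(asm, ord[2])
  hits <- interface_contacts(a1, a2, cutoff = 3.0)
  expect_gt(nrow(hits), 0L)
  expect_true(all(hits$atom_a %in% c("N", "O") | hits$atom_b %in% c("N", "O")))
})
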
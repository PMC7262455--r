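test_that("linker walks respect bond length, angle bounds and clash radius", {
  spec <- linker_spec(c(1L, 20L))
  w <- sample_linker(c(0, 0, 0), c(1, 0, 0), 20L, spec, seed = 5)
  full <- rbind(c(0, 0, 0), w)
  bonds <- sqrt(rowSums(diff(full)^2))
  expect_equal(bonds, rep(3.8, 20), tolerance = 1e-6)

  # pseudo-angles within bounds
  v <- diff(full)
  ang <- sapply(seq_len(nrow(v) - 1), function(i) {
    ct <- sum(-v[i, ] * v[i + 1, ]) / (3.8 * 3.8)
    acos(pmin(1, pmax(-1, ct))) * 180 / pi
  })
  expect_true(all(ang >= 75 - 1e-6 & ang <= 155 + 1e-6))

  # non-bonded self-avoidance
  d <- as.matrix(dist(full))
  nb <- abs(row(d) - col(d)) >= 2
  expect_true(all(d[nb] >= 3.0 - 1e-9))

  expect_equal(nrow(sample_linker(c(0, 0, 0), c(1, 0, 0), 0L, spec)), 0L)
})

test_that("linker statistics match an independent brute-force sampler", {
  n <- 3000
  spec <- linker_spec(c(1L, 20L))
  set.seed(71)
  e2e_pkg <- replicate(n, {
    w <- sample_linker(c(0, 0, 0), c(1, 0, 0), 20L, spec)
    sqrt(sum(w[20, ]^2))
  })
  set.seed(72)
  e2e_oracle <- replicate(n, {
    w <- oracle_linker_walk(c(0, 0, 0), c(1, 0, 0), 20L)
    sqrt(sum(w[20, ]^2))
  })
  expect_lt(abs(mean(e2e_pkg) - mean(e2e_oracle)) / mean(e2e_oracle), 0.10)
  ks <- suppressWarnings(ks.test(e2e_pkg, e2e_oracle))
  expect_gt(ks$p.value, 0.01)
})

test_that("assembled conformers tile the chain with exact rigid domains", {
  lay <- tdp43_layout()
  cf <- assemble_conformer(lay, seed = 42)
  expect_equal(nrow(cf$xyz), 414L)
  expect_equal(cf$resno, 1:414)
  expect_false(anyNA(cf$xyz))
  counts <- table(cf$provenance)
  expect_equal(as.integer(counts[c("NTD", "RRM1", "RRM2", "CTD-helix")]),
               c(80L, 71L, 68L, 15L))

  # rigid domains keep their internal geometry exactly (distance matrices)
  for (e in lay$elements) {
    if (!inherits(e, "domain_definition")) next
    sub <- cf$xyz[seq.int(e$range[1], e$range[2]), ]
    expect_lt(max(abs(dist(sub) - dist(e$coords))), 1e-6)
  }

  # no inter-element clash below the radius (non-bonded pairs)
  d <- as.matrix(dist(cf$xyz))
  elem_id <- cumsum(c(TRUE, cf$provenance[-1] != cf$provenance[-414]))
  cross <- outer(elem_id, elem_id, `!=`) & abs(row(d) - col(d)) >= 2
  expect_true(all(d[cross] >= 3.0 - 1e-9))

  # tiling violations are caught
  bad_dom <- list(domain_definition("X", c(1L, 10L), matrix(0, 10, 3)))
  expect_error(chain_layout(bad_dom, list(linker_spec(c(12L, 20L)))),
               class = "fs_specification_error")
})

test_that("pool generation is reproducible and spans compact to extended", {
  lay <- small_layout()
  p1 <- generate_pool(10, seed = 31, lay)
  p2 <- generate_pool(10, seed = 31, lay)
  expect_length(p1$conformers, 10L)
  expect_identical(lapply(p1$conformers, `[[`, "xyz"),
                   lapply(p2$conformers, `[[`, "xyz"))

  pool <- generate_pool(500, seed = 55, lay)
  rg <- vapply(pool$conformers, `[[`, numeric(1), "Rg")
  expect_gt(sd(rg) / mean(rg), 0.10)
  man <- pool_manifest(pool)
  expect_equal(nrow(man), 500L)
})

test_that("ranking recovers the generating conformer and orders chi-square", {
  lay <- small_layout()
  ds <- make_flexible_dataset(lay, seed = 17, qgrid = default_qgrid(200))
  pool <- generate_pool(25, seed = 91, lay)
  pool$conformers <- c(pool$conformers, list(ds$truth$conformer))

  rk <- rank_pool(pool, ds$curve, k = 5, region = c(1L, 50L))
  expect_equal(rk$report$top$id[1], 26L)           # the generating conformer
  expect_lt(rk$scores[1], 1.3)
  expect_true(!is.unsorted(rk$scores))
  expect_lte(max(rk$report$top$chi2), min(rk$report$bottom$chi2))

  # permutation invariance of the ranking
  perm <- c(11:26, 1:10)
  poolp <- pool
  poolp$conformers <- pool$conformers[perm]
  rkp <- rank_pool(poolp, ds$curve, k = 5, region = c(1L, 50L))
  expect_equal(rkp$scores, rk$scores, tolerance = 1e-9)

  expect_error(rank_pool(pool, ds$curve, k = 100),
               class = "fs_argument_error")
  nosig <- saxs_curve(ds$curve$q, ds$curve$I)
  expect_error(rank_pool(pool, nosig, k = 5),
               class = "fs_missing_sigma_error")
})

test_that("enforced head-to-tail dimers double the chain and scatter worse", {
  lay <- tdp43_layout()
  ds <- make_flexible_dataset(lay, seed = 23, qgrid = default_qgrid(150))
  mono <- ds$truth$conformer
  dim <- build_dimer(mono)
  expect_equal(nrow(dim$xyz), 828L)
  expect_equal(dim$chain, rep(c("A", "B"), each = 414L))
  expect_gt(dim$Rg, mono$Rg)

  # against monomer-generated data the dimer fits worse than the monomer
  chi_m <- chi2_fit(debye_profile(mono, ds$curve$q), ds$curve)$chi2
  chi_d <- chi2_fit(debye_profile(dim, ds$curve$q), ds$curve)$chi2
  expect_gt(chi_d, chi_m)
  expect_lt(chi_m, 1.3)
  expect_gt(chi_d, 2)

  # the steric check trips when more than 5% of inter-chain pairs fall
  # under the cutoff (superposed copy judged at a generous radius)
  expect_error(build_dimer(mono, transform = diag(4), clash_radius = 30),
               class = "fs_clash_error")
})
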
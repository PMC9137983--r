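# PDB ingest rules, Kabsch superposition, RMSD matrices and clustering.

test_that("chain cleanup keeps polymer + Mg, converts MSE, parses annotations", {
  f <- write_pdb_fixture(tempfile(fileext = ".pdb"))
  s <- load_structure(f, chain = "A")
  expect_false(any(s$atoms$resid %in% c("HOH", "NAD")))
  expect_true("MG" %in% s$atoms$resid[s$atoms$het])
  expect_false(any(s$atoms$chain == "B"))
  expect_identical(sum(s$atoms$elety == "CB"), 1L)  # altloc B dropped
  expect_identical(extract_sequence(s)$seq, "AMG")  # MSE read as methionine
  expect_identical(residue_table(s)$ss, c("helix", "helix", "sheet"))
  expect_equal(s$metadata$resolution, 1.8)

  expect_error(load_structure(f, chain = "C"), "available chains: A, B")
  empty <- tempfile(fileext = ".pdb"); writeLines("", empty)
  expect_error(load_structure(empty))
})

test_that("ligand-only input yields an empty sequence with a warning", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  PA  NAD A 201      -3.000  -3.000  -3.000  1.00 20.00           P",
    "HETATM    2 MG    MG A 301      -1.000   2.000   3.000  1.00 20.00          MG",
    "END"), f)
  s <- load_structure(f, chain = "A")
  expect_warning(sq <- extract_sequence(s), "empty")
  expect_identical(sq$seq, "")
})

test_that("superposition is exact under rigid motions and proper", {
  s <- fx_cavity(cavity = 3, shell = 11, seed = 5)
  expect_equal(superpose(s, s)$rmsd, 0, tolerance = 1e-9)

  set.seed(42)
  for (i in 1:100) {
    th <- runif(3, 0, 2 * pi)
    Rz <- matrix(c(cos(th[1]), sin(th[1]), 0, -sin(th[1]), cos(th[1]), 0,
                   0, 0, 1), 3, 3)
    Rx <- matrix(c(1, 0, 0, 0, cos(th[2]), sin(th[2]),
                   0, -sin(th[2]), cos(th[2])), 3, 3)
    R <- Rz %*% Rx
    b <- s
    xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(R)
    shift <- runif(3, -20, 20)
    b$atoms$x <- xyz[, 1] + shift[1]
    b$atoms$y <- xyz[, 2] + shift[2]
    b$atoms$z <- xyz[, 3] + shift[3]
    fit <- superpose(s, b)
    expect_lt(fit$rmsd, 1e-6)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  }
})

test_that("small-case RMSD agrees with an independent least-squares oracle", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(3:4, 1)
    P <- matrix(rnorm(n * 3, sd = 3), n, 3)
    Q <- P + matrix(rnorm(n * 3, sd = 0.5), n, 3)
    ours <- pocketcons:::kabsch(P, Q)$rmsd
    # oracle: bio3d's independent superposition implementation
    ref <- bio3d::fit.xyz(fixed = as.vector(t(Q)), mobile = as.vector(t(P)),
                          fixed.inds = 1:(3 * n), mobile.inds = 1:(3 * n))
    oracle <- sqrt(mean(colSums(matrix(ref - as.vector(t(Q)), 3)^2)))
    expect_equal(ours, oracle, tolerance = 1e-6)
  }
  # one point displaced: best fit beats the naive unfitted distance
  P <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0))
  Q <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 1))
  expect_lt(pocketcons:::kabsch(P, Q)$rmsd, sqrt(mean(c(0, 0, 1))))
})

test_that("RMSD matrices are symmetric and separate planted families", {
  base <- structure_spec(shell_radius = 10, cavity_radius = 3,
                         residue_count = 30, seed = 2)
  copies <- generate_ensemble(base, families = 1, members_per_family = 3,
                              within_noise = 0, seed = 1)
  expect_lt(max(rmsd_matrix(copies)), 1e-9)

  ens <- generate_ensemble(base, families = 6, members_per_family = 2,
                           within_noise = 0.05, between_shift = 5, seed = 9)
  m <- rmsd_matrix(ens)
  expect_identical(m, t(m))
  fam <- attr(ens, "families")$family
  within <- m[outer(fam, fam, "==") & upper.tri(m)]
  between <- m[outer(fam, fam, "!=") & upper.tri(m)]
  expect_lt(max(within), min(between))
})

test_that("k-means on the MDS embedding recovers planted partitions", {
  base <- structure_spec(shell_radius = 9, cavity_radius = 2.5,
                         residue_count = 20, seed = 4)
  for (seed in 1:20) {
    ens <- generate_ensemble(base, families = 3, members_per_family = 3,
                             within_noise = 0.05, between_shift = 2,
                             seed = seed)
    m <- rmsd_matrix(ens)
    cl <- cluster_representatives(m, k = 3, seed = seed)
    tab <- table(cl$assignments$cluster, attr(ens, "families")$family)
    expect_true(all(colSums(tab > 0) == 1) && all(rowSums(tab > 0) == 1))
  }
})

test_that("k is capped and representative selection follows the tie-break chain", {
  base <- structure_spec(shell_radius = 9, cavity_radius = 2.5,
                         residue_count = 20, seed = 4)
  ens <- generate_ensemble(base, families = 4, members_per_family = 1,
                           within_noise = 0.2, between_shift = 3, seed = 2)
  m <- rmsd_matrix(ens)
  cl <- cluster_representatives(m, k = 6, seed = 1)
  expect_identical(cl$k, 4L)
  expect_identical(sort(unique(cl$assignments$cluster)), 1:4)

  cl2 <- cluster_representatives(m, k = 6, seed = 1)
  expect_identical(cl$assignments, cl2$assignments)

  # all four in one cluster: resolution, then missing, then B, then id
  meta <- tibble::tibble(id = names(ens),
                         resolution = c(2.0, 1.5, 1.5, 1.5),
                         n_missing = c(0L, 4L, 2L, 2L),
                         mean_b = c(10, 10, 30, 20))
  one <- cluster_representatives(matrix(0, 4, 4,
                                        dimnames = list(names(ens),
                                                        names(ens))),
                                 k = 1, metadata = meta, seed = 1)
  expect_identical(one$representatives$id, names(ens)[4])

  bad <- m; bad[1, 2] <- NA
  expect_error(cluster_representatives(bad), "finite")
})
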
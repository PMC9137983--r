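# Grid construction, site-point detection, descriptors and the score
# equations.

test_that("grids enclose the structure with the requested margin", {
  one <- structure_from_xyz(c(0, 0, 0))
  g <- build_grid(one, spacing = 1, margin = 6)
  expect_identical(g$dims, c(13L, 13L, 13L))
  g2 <- build_grid(one, spacing = 0.5, margin = 6)
  expect_identical(g2$dims, c(25L, 25L, 25L))
  expect_error(build_grid(one, spacing = 0), "positive")
  empty <- one; empty$atoms <- one$atoms[0, ]
  expect_error(build_grid(empty), "empty")
})

test_that("site points obey exclusion, proximity and burial rules", {
  # small enclosed cavity: its centre is within 4 A of the wall, fully buried
  s <- generate_structure(structure_spec(shell_radius = 9.5,
                                         cavity_radius = 1.5,
                                         mouth_fraction = 0,
                                         residue_count = 30, seed = 1))
  g <- build_grid(s, spacing = 0.7)
  pts <- find_site_points(s, g)
  d_centre <- sqrt(rowSums(pts$coords^2))
  expect_true(any(d_centre < 0.7))          # the cavity centre is accepted
  expect_equal(max(pts$burial[d_centre < 0.7]), 1.0)
  # every accepted point is within 4 A of an atom and outside vdW + 0.5
  a <- s$atoms[!s$atoms$het, ]
  d_atom <- sqrt(pocketcons:::cross_dist2(pts$coords,
                                          as.matrix(a[, c("x", "y", "z")])))
  gap <- sweep(d_atom, 2, pocketcons:::vdw_radius(a$elem))
  expect_true(all(apply(d_atom, 1, min) <= 4))       # none 20 A away
  expect_true(all(apply(gap, 1, min) > 0.5))
  expect_true(all(pts$burial >= 0.5))
})

test_that("half-space burial matches the analytic 0.5 within quadrature error", {
  hs <- fx_halfspace()
  b <- burial_fraction(rbind(c(0.75, 0.75, 2.0)), hs)
  expect_lt(abs(b - 0.5), 0.05)
  # threshold is inclusive: a point at exactly burial_min is accepted
  g <- structure(list(origin = c(0.75, 0.75, 2.0), spacing = 1,
                      dims = c(1L, 1L, 1L)), class = "pocket_grid")
  pts <- find_site_points(hs, g, burial_min = b)
  expect_identical(nrow(pts$coords), 1L)
})

test_that("component size filtering and the site cap follow the retention rules", {
  hs <- fx_halfspace()
  # two blobs of 40 and 12 points: only the 40-point component is reported
  two <- fake_site_points(list(list(origin = c(5, 5, 8), dims = c(4, 5, 2)),
                               list(origin = c(30, 5, 8), dims = c(3, 2, 2))))
  sites <- cluster_site_points(two, hs, min_points = 15)
  expect_identical(nrow(sites), 1L)
  expect_identical(sites$n_points, 40L)

  # 14 cavities of >= 15 points each: at most 10 reported
  blobs <- lapply(seq_len(14), function(i)
    list(origin = c(6 * i, 5, 8), dims = c(3, 3, 2)))
  many <- fake_site_points(blobs)
  sites14 <- cluster_site_points(many, hs, min_points = 15)
  expect_identical(nrow(sites14), 10L)

  # a single component keeps its full point count
  one <- fake_site_points(list(list(origin = c(5, 5, 8), dims = c(4, 4, 2))))
  s1 <- cluster_site_points(one, hs, min_points = 15)
  expect_identical(s1$n_points, 32L)

  none <- fake_site_points(list(list(origin = c(5, 5, 8), dims = c(2, 2, 2))))
  expect_warning(s0 <- cluster_site_points(none, hs, min_points = 15),
                 "no site")
  expect_identical(nrow(s0), 0L)
})

test_that("volume identity and descriptor ranges hold on detected pockets", {
  sites <- fx_sites(cavity = 4, mouth = 0, spacing = 0.7)
  expect_equal(sites$volume, sites$n_points * 0.7^3, tolerance = 1e-9)
  expect_true(all(sites$exposure >= 0 & sites$exposure <= 1))
  expect_true(all(sites$enclosure >= 0 & sites$enclosure <= 1))
  expect_true(all(sites$charged_fraction >= 0 & sites$charged_fraction <= 1))
  expect_true(all(sites$n_points >= 15))
})

test_that("lining polarity drives the charged fraction and phobic/philic split", {
  # ring of 12 residues, 3 charged, with a central probe point
  ang <- seq(0, 2 * pi, length.out = 13)[1:12]
  resid <- c("ASP", "GLU", "LYS", rep("LEU", 9))
  elem <- c("O", "O", "N", rep("C", 9))
  atoms <- tibble::tibble(
    eleno = 1:12, elety = c("OD1", "OE1", "NZ", rep("CG", 9)),
    resid = resid, chain = "A", resno = 1:12,
    x = 3.2 * cos(ang), y = 3.2 * sin(ang), z = 0, b = 20,
    elem = elem, het = FALSE)
  ring <- pocketcons:::new_structure(atoms)
  d <- compute_descriptors(coords = rbind(c(0, 0, 0)), burial = 1,
                           open = matrix(FALSE, 1, 110),
                           rays = pocketcons:::fibonacci_sphere(110),
                           s = ring, spacing = 0.7)
  expect_equal(d$charged_fraction, 0.25)
  expect_identical(sort(d$lining[[1]]), 1:12)

  apolar <- atoms
  apolar$resid <- "LEU"; apolar$elety <- "CG"; apolar$elem <- "C"
  ring2 <- pocketcons:::new_structure(apolar)
  d2 <- compute_descriptors(coords = rbind(c(0, 0, 0)), burial = 1,
                            open = matrix(FALSE, 1, 110),
                            rays = pocketcons:::fibonacci_sphere(110),
                            s = ring2, spacing = 0.7)
  expect_lt(d2$philic, d2$phobic)
  expect_equal(d2$charged_fraction, 0)
})

test_that("score equations match hand arithmetic, caps and monotonicity", {
  # reference inputs: n = 132 -> capped 100, e = 0.78, p = 1.0
  expect_equal(site_score(132, 0.78, 1.0),
               0.0733 * 10 + 0.6688 * 0.78 - 0.20, tolerance = 1e-9)
  expect_equal(d_score(132, 0.78, 1.0),
               0.94 + 0.468 - 0.324, tolerance = 1e-9)
  expect_equal(site_score(0, 0, 0), 0)
  expect_equal(d_score(0, 0, 0), 0)

  # SiteScore hydrophilic cap at 1; DScore penalty uncapped and linear
  expect_equal(site_score(80, 0.7, 1.4), site_score(80, 0.7, 1.0))
  expect_equal(d_score(80, 0.7, 1.4) - d_score(80, 0.7, 1.0),
               -0.324 * 0.4, tolerance = 1e-12)

  # strict monotonicity: up in n (below cap) and e, down in p
  set.seed(1)
  for (i in 1:50) {
    n <- sample(15:99, 1); e <- runif(1); p <- runif(1, 0, 0.99)
    expect_gt(site_score(n + 1, e, p), site_score(n, e, p))
    expect_gt(d_score(n + 1, e, p), d_score(n, e, p))
    expect_gt(site_score(n, e + 0.01, p), site_score(n, e, p))
    expect_lt(site_score(n, e, p + 0.01), site_score(n, e, p))
    expect_lt(d_score(n, e, p + 0.01), d_score(n, e, p))
  }
  # above the point cap both scores are flat in n
  expect_equal(site_score(101, 0.5, 0.5), site_score(150, 0.5, 0.5))

  # the literal linear reading remains available
  expect_equal(site_score(132, 0.78, 1.0, n_transform = "linear"),
               0.0733 * 100 + 0.6688 * 0.78 - 0.20, tolerance = 1e-9)
})

test_that("the reference profile scores as ligandable and druggable", {
  ref <- reference_profile()
  expect_gte(site_score(ref$n_points, ref$enclosure, ref$philic), 0.8)
  expect_gte(d_score(ref$n_points, ref$enclosure, ref$philic), 0.8)
})
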
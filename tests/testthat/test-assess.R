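# Site typing, conserved fractions, quadrants, the combined filter, group
# statistics, inhibitor comparison and the full pipeline.

toy_sites <- function(lining) {
  tibble::tibble(site_id = "s1", site_score = 1, d_score = 1,
                 charged_fraction = 0.1, lining = list(lining))
}

test_that("site typing follows the 4 A ligand/cofactor rule with merging", {
  s <- fx_cavity(cavity = 3, shell = 11, seed = 5, ligand = TRUE)
  sites <- find_sites(s, spacing = 0.8)
  lig <- s$atoms[s$atoms$het & s$atoms$resid == "LIG", c("x", "y", "z")]
  typed <- label_site_type(sites, s, ligand_xyz = as.matrix(lig))
  expect_identical(typed$site_type[1], "orthosteric")
  expect_false(typed$merged[1])

  far <- label_site_type(sites, s, ligand_xyz = rbind(c(50, 50, 50)))
  expect_identical(far$site_type[1], "other")

  both <- label_site_type(sites, s, ligand_xyz = as.matrix(lig),
                          cofactor_xyz = as.matrix(lig))
  expect_identical(both$site_type[1], "orthosteric")
  expect_true(both$merged[1])

  expect_warning(none <- label_site_type(sites, s), "other")
  expect_identical(none$site_type[1], "other")
})

test_that("conserved fractions count grade 8-9 residues over graded lining", {
  grades <- tibble::tibble(resno = 1:10, grade = c(rep(9L, 6), rep(3L, 4)))
  expect_equal(conserved_fraction(1:10, grades), 0.6)
  expect_equal(conserved_fraction(1:6, grades), 1.0)
  grades5 <- tibble::tibble(resno = 1:10, grade = c(rep(8L, 5), rep(2L, 5)))
  expect_equal(conserved_fraction(1:10, grades5), 0.5)  # passes >= 0.5
  ungraded <- tibble::tibble(resno = 1:10, grade = rep(NA_integer_, 10))
  expect_error(conserved_fraction(1:10, ungraded), "graded")
})

test_that("quadrant classification partitions the score plane inclusively", {
  expect_identical(classify_quadrant(1.13, 1.0), "UR")
  expect_identical(classify_quadrant(0.79, 0.79), "LL")
  expect_identical(classify_quadrant(0.9, 0.7), "LR")
  expect_identical(classify_quadrant(0.7, 0.9), "UL")
  expect_identical(classify_quadrant(0.8, 0.8), "UR")  # inclusive boundary
  set.seed(2)
  ss <- runif(200, 0, 1.6); ds <- runif(200, 0, 1.6)
  q <- classify_quadrant(ss, ds)
  expect_true(all(q %in% c("UR", "UL", "LR", "LL")))
  expect_error(classify_quadrant(NA_real_, 1), "finite")
})

test_that("the combined filter equals the brute-force predicate row for row", {
  tab <- make_candidate_sites(1000, seed = 2)
  f <- apply_combined_filter(tab)
  oracle <- tab[tab$site_score >= 0.8 & tab$d_score >= 0.8 &
                  tab$conserved_fraction >= 0.5, ]
  expect_identical(f$retained, oracle)
  expect_identical(f$n_after_scores,
                   sum(tab$site_score >= 0.8 & tab$d_score >= 0.8))

  low <- tab; low$site_score <- 0.5; low$d_score <- 0.5
  f0 <- apply_combined_filter(low)
  expect_identical(c(f0$n_after_scores, f0$n_after_conservation), c(0L, 0L))

  border <- tibble::tibble(site_score = 0.8, d_score = 0.8,
                           conserved_fraction = 0.5)
  expect_identical(apply_combined_filter(border)$n_after_conservation, 1L)
})

test_that("assessment flags mirror their thresholds", {
  tab <- make_candidate_sites(50, seed = 6)
  a <- assess_sites(tab)
  expect_identical(a$retained,
                   a$ligandable & a$druggable & a$conserved)
  expect_identical(a$charged_exceeds, a$charged_fraction > 0.263)
  expect_identical(a$quadrant == "UR", a$ligandable & a$druggable)
})

test_that("conservation summaries split conserved residues over SS classes", {
  grades <- tibble::tibble(resno = 1:20,
                           grade = ifelse(1:20 %in% c(2, 3, 12, 20), 9L, 4L))
  ss <- tibble::tibble(resno = 1:20,
                       ss = c(rep("helix", 10), rep("sheet", 5),
                              rep("loop", 5)))
  cs <- conservation_summary(grades, ss)
  expect_equal(cs$pct_conserved, 20)
  expect_equal(unname(cs$ss_split), c(0.5, 0.25, 0.25))
  expect_equal(sum(cs$ss_split), 1)

  none <- conservation_summary(
    tibble::tibble(resno = 1:20, grade = rep(4L, 20)), ss)
  expect_equal(none$pct_conserved, 0)
  expect_equal(unname(none$ss_split), c(0, 0, 0))

  all9 <- conservation_summary(
    tibble::tibble(resno = 1:20, grade = rep(9L, 20)), ss)
  expect_equal(all9$pct_conserved, 100)
})

test_that("exact Mann-Whitney handles ties and extreme separations", {
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$u, 4.5)
  expect_equal(same$p, 1.0)
  expect_false(same$significant)

  apart <- compare_groups(c(1, 2, 3), c(10, 11, 12))
  expect_equal(apart$u, 0)
  expect_equal(apart$p, 0.1)

  const <- compare_groups(c(5, 5, 5), c(5, 5, 5))
  expect_false(const$significant)

  expect_error(compare_groups(c(1, 2), c(1, 2, 3)), ">= 3")
})

test_that("exact p equals exhaustive enumeration and the tie-free reference", {
  # independent oracle: enumerate group labellings recursively
  enum_p <- function(a, b) {
    n1 <- length(a); n <- n1 + length(b)
    r <- rank(c(a, b))
    centre <- n1 * length(b) / 2
    obs <- abs(sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2 - centre)
    sets <- utils::combn(n, n1)
    hits <- 0
    for (j in seq_len(ncol(sets))) {
      u <- sum(r[sets[, j]]) - n1 * (n1 + 1) / 2
      if (abs(u - centre) >= obs - 1e-12) hits <- hits + 1
    }
    hits / ncol(sets)
  }
  set.seed(9)
  for (i in 1:20) {
    n1 <- sample(3:5, 1); n2 <- sample(3:5, 1)
    a <- sample(1:6, n1, replace = TRUE)  # ties likely
    b <- sample(1:6, n2, replace = TRUE)
    ours <- pocketcons:::mann_whitney_exact(a, b)
    expect_equal(ours$p, enum_p(a, b), tolerance = 1e-12)
  }
  # tie-free case agrees with the standard exact implementation
  for (i in 1:10) {
    a <- sample(seq(0, 1, by = 0.001), 5)
    b <- sample(seq(2, 3, by = 0.001), 5)
    w <- stats::wilcox.test(a, b, exact = TRUE)
    ours <- pocketcons:::mann_whitney_exact(a, b)
    expect_equal(ours$p, w$p.value, tolerance = 1e-12)
    expect_equal(ours$u, unname(w$statistic))
  }
})

test_that("inhibitor profiles compare pocket and ligand donor/acceptor character", {
  assessments <- tibble::tibble(enzyme = c("E1", "E1", "E2"),
                                donacc = c(0.8, 0.72, 1.2))
  inhibitors <- tibble::tibble(
    enzyme = c("E1", "E1"), compound_id = c("c1", "c2"),
    tpsa = c(90, 110), hbd = c(1, 2), hba = c(4, 4))
  cmp <- compare_inhibitor_profile(assessments, inhibitors)
  e1 <- cmp[cmp$enzyme == "E1", ]
  expect_equal(e1$median_donacc_inhibitors, 0.375)
  expect_equal(e1$median_tpsa, 100)
  expect_equal(e1$mismatch_sign, 1)  # pocket favours more donors
  e2 <- cmp[cmp$enzyme == "E2", ]
  expect_true(is.na(e2$median_tpsa))

  empty <- compare_inhibitor_profile(assessments,
                                     inhibitors[0, ])
  expect_true(all(is.na(empty$median_tpsa)))
})

test_that("the pipeline retains exactly what the filter oracle retains", {
  cfg <- pipeline_config(
    structure = structure_spec(shell_radius = 12, cavity_radius = 4,
                               mouth_fraction = 0.1, residue_count = 40,
                               plant_ligand = TRUE, seed = 5),
    spacing = 0.8, seed = 11)
  rep <- run_pipeline(cfg)
  a <- rep$assessments
  oracle <- a[a$site_score >= 0.8 & a$d_score >= 0.8 &
                a$conserved_fraction >= 0.5, ]
  expect_identical(rep$filter$retained, oracle)

  d1 <- tempfile(); d2 <- tempfile()
  write_report(rep, d1)
  write_report(run_pipeline(cfg), d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))

  expect_error(run_pipeline(pipeline_config(structure = NULL)), "structio")
})

test_that("a conserved druggable cavity is the only retained site", {
  for (seed in 1:20) {
    cfg <- pipeline_config(
      structure = structure_spec(shell_radius = 11, cavity_radius = 4,
                                 mouth_fraction = 0.1, residue_count = 40,
                                 plant_ligand = TRUE, seed = seed),
      spacing = 1.0, seed = seed)
    rep <- run_pipeline(cfg)
    ret <- rep$filter$retained
    expect_identical(nrow(ret), 1L)
    # the survivor is the planted cavity: its lining touches the ligand
    expect_identical(ret$site_type, "orthosteric")
  }
})

test_that("tidiers and plots expose the standard surfaces", {
  tab <- make_candidate_sites(30, seed = 3)
  a <- assess_sites(tab)
  f <- apply_combined_filter(a)
  expect_s3_class(tidy(f), "tbl_df")
  expect_identical(glance(f)$n_input, 30L)
  g <- compare_groups(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_identical(nrow(tidy(g)), 1L)
  expect_s3_class(plot_quadrants(a), "ggplot")
  p <- autoplot(a)
  expect_s3_class(p, "ggplot")
})
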
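# Sequence curation, distances, trees, conservation grading and mapping.

mkseqs <- function(lens, org = NULL) {
  tibble::tibble(id = sprintf("s%02d", seq_along(lens)),
                 organism = org %||% sprintf("o%02d", seq_along(lens)),
                 seq = vapply(lens, function(l)
                   paste(rep("A", l), collapse = ""), character(1)))
}

test_that("length-outlier filtering uses the mean-length fraction rule", {
  expect_identical(nrow(filter_length_outliers(mkseqs(c(100, 95, 61, 59)))),
                   4L)
  expect_identical(nrow(filter_length_outliers(mkseqs(c(100, 100, 100, 59)))),
                   4L)
  kept <- filter_length_outliers(mkseqs(c(100, 100, 100, 40)))
  expect_identical(nrow(kept), 3L)
  expect_false("s04" %in% kept$id)
  expect_identical(nrow(filter_length_outliers(mkseqs(150))), 1L)
  expect_error(filter_length_outliers(mkseqs(integer(0))), "empty")
})

test_that("one representative per organism, longest then lexicographic", {
  seqs <- mkseqs(c(50, 60, 70, 80, 90),
                 org = c("a", "a", "b", "b", "c"))
  reps <- select_representatives(seqs)
  expect_identical(nrow(reps), 3L)
  expect_setequal(reps$id, c("s02", "s04", "s05"))

  same <- mkseqs(c(50, 50), org = c("a", "a"))
  expect_identical(select_representatives(same)$id, "s01")  # tie -> id order

  bad <- mkseqs(c(10, 20), org = c("a", ""))
  expect_error(select_representatives(bad), "s02")
})

test_that("BLOSUM62 distances are rescaled per pair to [0, 1]", {
  aln <- tibble::tibble(id = c("a", "b"), organism = c("a", "b"),
                        seq = c("A", "A"))
  expect_equal(pairwise_distance(aln)[1, 2], 0)
  aln$seq <- c("A", "W")  # the minimum-score pairing for this pair
  expect_equal(pairwise_distance(aln)[1, 2], 1)

  set.seed(4)
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G")
  rnd <- tibble::tibble(id = letters[1:4], organism = letters[1:4],
                        seq = replicate(4, paste(sample(aa, 30, TRUE),
                                                 collapse = "")))
  d <- pairwise_distance(rnd)
  expect_equal(d, t(d))
  expect_equal(diag(d), setNames(rep(0, 4), letters[1:4]))
  expect_true(all(d >= 0 & d <= 1))

  gapped <- tibble::tibble(id = c("a", "b"), organism = c("a", "b"),
                           seq = c("A--", "--W"))
  expect_error(pairwise_distance(gapped), "comparable")
})

test_that("neighbor joining recovers additive trees and is label-order invariant", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);")
  dm <- ape::cophenetic.phylo(tr)
  nj1 <- build_nj_tree(dm)
  expect_equal(phangorn::RF.dist(ape::unroot(tr), nj1), 0)
  # exact branch lengths on the additive matrix
  tip_edge <- function(t, lab) t$edge.length[t$edge[, 2] ==
                                               match(lab, t$tip.label)]
  expect_equal(tip_edge(nj1, "A"), 1)
  expect_equal(tip_edge(nj1, "D"), 4)

  perm <- c("C", "A", "D", "B")
  nj2 <- build_nj_tree(dm[perm, perm])
  expect_equal(phangorn::RF.dist(nj1, nj2), 0)

  # three taxa give the single-internal-node star
  nj3 <- build_nj_tree(dm[1:3, 1:3])
  expect_identical(nj3$Nnode, 1L)

  asym <- dm; asym[1, 2] <- asym[1, 2] + 1
  expect_error(build_nj_tree(asym), "symmetric")
})

test_that("invariant columns score maximally and grades are monotone in score", {
  aln <- tibble::tibble(
    id = c("a", "b", "c", "d"), organism = c("a", "b", "c", "d"),
    seq = c("WAKDF", "WRKEF", "WNKDY", "WQKEY"))
  prof <- assign_grades(score_conservation(aln))
  # columns 1 (all W) and 3 (all K) are invariant: both at the raw maximum
  expect_equal(max(prof$raw), prof$raw[1])
  expect_equal(prof$raw[1], prof$raw[3])
  expect_true(all(prof$raw[c(2, 4, 5)] < prof$raw[1]))
  expect_identical(prof$grade[1], 9L)
  ord <- order(prof$score)
  expect_true(all(diff(prof$grade[ord]) >= 0))
})

test_that("scores are standardised and redundant sequences are down-weighted", {
  ev <- evolve_alignment(alignment_spec(fx_tree(8), 200,
                                        tibble::tibble(rate = c(0.1, 5),
                                                       prop = c(0.5, 0.5)),
                                        seed = 11))
  prof <- score_conservation(ev$alignment)
  expect_equal(mean(prof$score), 0, tolerance = 1e-9)
  expect_equal(sd(prof$score), 1, tolerance = 1e-9)

  dup <- ev$alignment[c(1:8, 1), ]
  dup$id[9] <- "dup"; dup$organism[9] <- "dup"
  prof_dup <- score_conservation(dup)
  expect_lt(max(abs(prof$score - prof_dup$score)), 0.25)
})

test_that("gappy columns are flagged and graded 1", {
  aln <- tibble::tibble(
    id = c("a", "b", "c", "d"), organism = c("a", "b", "c", "d"),
    seq = c("WA--", "WR--", "WN-A", "WQ--"))
  prof <- assign_grades(score_conservation(aln))
  expect_identical(prof$flag[3:4], c("all_gap", "gappy"))
  expect_identical(prof$grade[3:4], c(1L, 1L))
})

test_that("wide-rate alignments populate all nine grades", {
  ev <- evolve_alignment(alignment_spec(
    fx_tree(8, seed = 5), 500,
    tibble::tibble(rate = c(0, 0.3, 1, 3, 10), prop = rep(0.2, 5)),
    seed = 13))
  prof <- assign_grades(score_conservation(ev$alignment))
  expect_setequal(unique(prof$grade), 1:9)
})

test_that("fully conserved alignments hit the degenerate all-9 rule", {
  aln <- tibble::tibble(id = c("a", "b", "c"), organism = c("a", "b", "c"),
                        seq = rep("ACDEF", 3))
  prof <- assign_grades(score_conservation(aln))
  expect_true(all(prof$grade == 9L))
})

test_that("grades project onto structure residues through sequence alignment", {
  s <- fx_cavity(cavity = 3, shell = 11, seed = 5)
  sq <- extract_sequence(s)$seq
  aln <- tibble::tibble(id = c("ref", "h1", "h2"),
                        organism = c("ref", "h1", "h2"),
                        seq = rep(sq, 3))
  prof <- assign_grades(score_conservation(aln))
  g <- map_to_structure(prof, "ref", s)
  expect_identical(nrow(g), n_residues(s))
  expect_true(all(g$grade == 9L))
  expect_identical(g$column, seq_len(nchar(sq)))  # identity offset

  # structure missing 5 N-terminal residues: those columns unmapped
  s_tr <- s
  s_tr$atoms <- s$atoms[s$atoms$resno > 5, ]
  g_tr <- map_to_structure(prof, "ref", s_tr)
  expect_identical(nrow(g_tr), n_residues(s) - 5L)
  expect_false(any(g_tr$column %in% 1:5))
  expect_true(all(!is.na(g_tr$grade)))
  # mapped residues inherit exactly their column's grade
  expect_identical(g_tr$grade, prof$grade[g_tr$column])

  unrelated <- tibble::tibble(
    id = c("x", "y", "z"), organism = c("x", "y", "z"),
    seq = rep(paste(rep("WCH", 60), collapse = ""), 3))
  prof_u <- assign_grades(score_conservation(unrelated))
  expect_error(map_to_structure(prof_u, "x", s), "identity")
})
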
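# Per-column conservation scoring, nine-grade binning and projection onto
# structure residues.
#
# The per-column statistic is a tree-aware weighted sum-of-pairs similarity:
# sequence weights are Gerstein–Sonnhammer–Chothia weights computed from the
# neighbor-joining tree (so redundant, recently diverged sequences are
# down-weighted), and the pair similarity is the self-score-normalised
# BLOSUM62 entry, which puts every invariant column at the per-column
# maximum of 1.  Scores are standardised across columns (mean 0, sd 1;
# higher = more conserved) and binned into nine equal-width grades
# (9 = most conserved).

#' Gerstein–Sonnhammer–Chothia sequence weights from a tree
#'
#' Each edge's length is divided among the leaves below it in proportion to
#' their accumulated weights (equally when none has any yet); weights are
#' normalised to mean 1.
#'
#' @param tree an `ape::phylo` tree (rooted internally at its midpoint)
#' @return named numeric vector of weights over the tip labels
#' @export
gsc_weights <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0, nrow(tree$edge))
  if (!ape::is.rooted(tree))
    tree <- tryCatch(phangorn::midpoint(tree), error = function(e) tree)
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  w <- rep(0, n_tip)
  # leaves below each node, built tips-first
  below <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) below[[i]] <- i
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    leaves <- below[[child]]
    len <- tree$edge.length[e]
    tot <- sum(w[leaves])
    if (tot <= 0) {
      w[leaves] <- w[leaves] + len / length(leaves)
    } else {
      w[leaves] <- w[leaves] + len * w[leaves] / tot
    }
    below[[parent]] <- c(below[[parent]], leaves)
  }
  if (sum(w) <= 0) w <- rep(1, n_tip) else w <- w / mean(w)
  setNames(w, tree$tip.label)
}

#' Score per-column conservation of an alignment
#'
#' @param aln an `msa` tibble (>= 3 rows)
#' @param tree optional `ape::phylo` whose tips match the alignment ids;
#'   when `NULL`, a neighbor-joining tree is built from
#'   [pairwise_distance()]
#' @param gap_max columns with a gap fraction above this are flagged
#'   `"gappy"`, excluded from standardisation and later graded 1
#' @return a `conservation_profile`: tibble with `column`, `raw`, `score`
#'   (standardised; higher = more conserved) and `flag`
#' @export
score_conservation <- function(aln, tree = NULL, gap_max = 0.5) {
  aln <- as_tibble(aln)
  if (nrow(aln) < 3) stop_pc("need >= 3 rows for conservation scoring")
  if (length(unique(nchar(aln$seq))) != 1)
    stop_pc("alignment rows have unequal length")
  if (is.null(tree)) tree <- build_nj_tree(pairwise_distance(aln))
  if (!setequal(tree$tip.label, aln$id))
    stop_pc("tree tips do not match alignment row ids")
  w <- gsc_weights(tree)[aln$id]
  m <- msa_matrix(aln)
  bn <- blosum62_normalised()
  nc <- ncol(m)

  raw <- rep(NA_real_, nc)
  flag <- rep("", nc)
  single <- rep(FALSE, nc)
  for (c in seq_len(nc)) {
    col <- m[, c]
    is_gap <- col %in% c("-", ".")
    valid <- which(!is_gap & col %in% aa_alphabet)
    if (mean(is_gap) > gap_max) {
      flag[c] <- if (all(is_gap)) "all_gap" else "gappy"
      next
    }
    if (length(valid) < 2) { flag[c] <- "gappy"; next }
    a <- col[valid]; wv <- w[valid]
    single[c] <- length(unique(a)) == 1
    ww <- outer(wv, wv)
    bb <- bn[a, a, drop = FALSE]
    ut <- upper.tri(ww)
    raw[c] <- sum(ww[ut] * bb[ut]) / sum(ww[ut])
  }

  ok <- flag == ""
  score <- rep(NA_real_, nc)
  if (any(ok)) {
    mu <- mean(raw[ok]); sdev <- sd(raw[ok])
    score[ok] <- if (!is.finite(sdev) || sdev < 1e-12) 0 else
      (raw[ok] - mu) / sdev
  }
  out <- tibble(column = seq_len(nc), raw = raw, score = score, flag = flag)
  class(out) <- c("conservation_profile", class(out))
  attr(out, "single_residue") <- single
  attr(out, "alignment") <- aln
  attr(out, "weights") <- w
  out
}

#' Bin conservation scores into nine grades
#'
#' The observed standardised score range is split into `n_grades`
#' equal-width intervals; the most-conserved interval is grade `n_grades`
#' (9 by default).  When all scores are equal, every column gets grade 9 if
#' every column is invariant, otherwise grade 5.  Flagged (gappy/all-gap)
#' columns get grade 1.
#'
#' @param profile a `conservation_profile` from [score_conservation()]
#' @param n_grades number of grades (default 9)
#' @return the profile with a `grade` column added
#' @export
assign_grades <- function(profile, n_grades = 9) {
  stopifnot(inherits(profile, "conservation_profile"))
  s <- profile$score
  ok <- profile$flag == "" & !is.na(s)
  grade <- rep(1L, nrow(profile))
  if (any(ok)) {
    rng <- range(s[ok])
    if (diff(rng) < 1e-12) {
      single <- attr(profile, "single_residue")
      grade[ok] <- if (all(single[ok])) as.integer(n_grades) else
        as.integer(ceiling(n_grades / 2))
    } else {
      grade[ok] <- pmin(n_grades,
                        1L + as.integer(floor(n_grades * (s[ok] - rng[1]) /
                                                diff(rng))))
    }
  }
  profile$grade <- as.integer(grade)
  profile
}

#' Project alignment-column grades onto structure residues
#'
#' Globally aligns the chosen alignment row's ungapped sequence to the
#' structure-derived sequence (BLOSUM62, affine gaps); matched residues
#' inherit the column score and grade, unmatched structure residues are
#' flagged `"ungraded"`.
#'
#' @param profile a graded `conservation_profile` (see [assign_grades()])
#' @param aln_row id of the alignment row corresponding to the structure
#' @param structure a `protein_structure`
#' @param min_identity minimum percent sequence identity of the pairwise
#'   alignment; below this the mapping errors (wrong chain/protein)
#' @return a `residue_grades` tibble: `resno`, `aa`, `column`, `score`,
#'   `grade`, `flag` for every structure residue
#' @export
map_to_structure <- function(profile, aln_row, structure, min_identity = 30) {
  stopifnot(inherits(profile, "conservation_profile"))
  if (is.null(profile$grade)) profile <- assign_grades(profile)
  aln <- attr(profile, "alignment")
  if (!aln_row %in% aln$id) stop_pc("'", aln_row, "' is not an alignment row")
  row_aln <- strsplit(aln$seq[aln$id == aln_row], "")[[1]]
  row_cols <- which(!row_aln %in% c("-", "."))
  row_seq <- paste(row_aln[row_cols], collapse = "")

  res <- residue_table(structure)
  if (!nrow(res)) stop_pc("structure has no polymer residues")
  str_seq <- paste(res$aa, collapse = "")

  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(row_seq), Biostrings::AAString(str_seq),
    type = "global", substitutionMatrix = blosum62(),
    gapOpening = 10, gapExtension = 0.5)
  identity <- Biostrings::pid(al, type = "PID2")
  if (identity < min_identity)
    stop_pc(sprintf(
      "pairwise identity %.1f%% below %s%% - row '%s' does not match this chain",
      identity, min_identity, aln_row))

  pat <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  pi <- 0L; si <- 0L
  col_of_res <- rep(NA_integer_, nrow(res))
  for (k in seq_along(pat)) {
    if (pat[k] != "-") pi <- pi + 1L
    if (sub[k] != "-") si <- si + 1L
    if (pat[k] != "-" && sub[k] != "-") col_of_res[si] <- row_cols[pi]
  }

  out <- tibble(
    resno = res$resno, aa = res$aa, column = col_of_res,
    score = profile$score[col_of_res],
    grade = profile$grade[col_of_res],
    flag = ifelse(is.na(col_of_res), "ungraded",
                  profile$flag[col_of_res])
  )
  class(out) <- c("residue_grades", class(out))
  out
}

#' Write a per-residue grades table (TSV)
#' @param grades a `residue_grades` tibble
#' @param path output path
#' @return `path`, invisibly
#' @export
write_grades_table <- function(grades, path) {
  utils::write.table(grades, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
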
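# Sequence-set curation, BLOSUM62 distances and the neighbor-joining tree.

ungapped_length <- function(seq) nchar(gsub("[-.]", "", seq))

#' Filter length outliers from a sequence set
#'
#' Removes sequences whose ungapped length falls strictly below
#' `fraction` times the mean ungapped length of the input set.
#'
#' @param seqs tibble of sequence records (`id`, `organism`, `seq`)
#' @param fraction retention cutoff as a fraction of the mean length
#'   (default 0.6)
#' @return the retained rows, input order preserved
#' @export
filter_length_outliers <- function(seqs, fraction = 0.6) {
  seqs <- as_tibble(seqs)
  if (!nrow(seqs)) stop_pc("empty sequence set")
  len <- ungapped_length(seqs$seq)
  cutoff <- fraction * mean(len)
  seqs[len >= cutoff, ]
}

#' Select one representative sequence per organism
#'
#' Ties within an organism are resolved by the longest ungapped sequence,
#' then by lexicographic id, so the pick is deterministic.
#'
#' @param seqs tibble of sequence records with a populated `organism` column
#' @return one row per distinct organism
#' @export
select_representatives <- function(seqs) {
  seqs <- as_tibble(seqs)
  bad <- is.na(seqs$organism) | seqs$organism == ""
  if (any(bad))
    stop_pc("missing organism for record(s): ",
            paste(seqs$id[bad], collapse = ", "))
  seqs |>
    mutate(.len = ungapped_length(.data$seq)) |>
    group_by(.data$organism) |>
    arrange(desc(.data$.len), .data$id, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select(-".len")
}

#' BLOSUM62 distance matrix over an alignment
#'
#' For each pair of rows, similarity is the mean BLOSUM62 score over columns
#' where neither row is gapped, rescaled per pair to `[0, 1]`: the maximum
#' achievable score is the mean of the two rows' averaged self-scores over
#' the same columns, and the minimum is the worst BLOSUM62 score over the
#' cross product of the two rows' residues.  Distance is one minus the
#' rescaled similarity.
#'
#' @param aln an `msa` tibble with >= 2 rows
#' @return symmetric labelled distance matrix with zero diagonal
#' @export
pairwise_distance <- function(aln) {
  aln <- as_tibble(aln)
  if (nrow(aln) < 2) stop_pc("need >= 2 aligned sequences")
  m <- msa_matrix(aln)
  b <- blosum62()
  nr <- nrow(m)
  d <- matrix(0, nr, nr, dimnames = list(aln$id, aln$id))
  known <- rownames(b)
  for (i in seq_len(nr - 1)) {
    for (j in (i + 1):nr) {
      a1 <- m[i, ]; a2 <- m[j, ]
      ok <- !(a1 %in% c("-", ".")) & !(a2 %in% c("-", ".")) &
        a1 %in% known & a2 %in% known
      if (!any(ok))
        stop_pc("no comparable columns for pair ", aln$id[i], " / ", aln$id[j])
      s <- mean(b[cbind(a1[ok], a2[ok])])
      s_max <- mean((b[cbind(a1[ok], a1[ok])] + b[cbind(a2[ok], a2[ok])]) / 2)
      s_min <- min(b[unique(a1[ok]), unique(a2[ok]), drop = FALSE])
      sim <- if (s_max - s_min < 1e-12) 1 else
        min(1, max(0, (s - s_min) / (s_max - s_min)))
      d[i, j] <- d[j, i] <- 1 - sim
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou–Nei neighbor joining; negative branch lengths are
#' clamped to zero.
#'
#' @param d symmetric labelled distance matrix (>= 3 labels)
#' @return an unrooted `ape::phylo` tree over the matrix labels
#' @export
build_nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop_pc("need >= 3 labels for a tree")
  if (is.null(rownames(d))) stop_pc("distance matrix must be labelled")
  if (max(abs(d - t(d))) > 1e-8) stop_pc("distance matrix is not symmetric")
  if (any(!is.finite(d))) stop_pc("non-finite distances")
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}
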
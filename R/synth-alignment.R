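# Alignments evolved along a known tree with site-rate classes.
#
# Columns evolve under a continuous-time Markov chain whose exchangeabilities
# are derived from BLOSUM62 (s_ij = 2^(B62_ij / 2), i.e. the implied
# odds-ratio of the half-bit log-odds entries) and whose stationary
# frequencies come from the user specification.  Each column belongs to one rate
# class; a zero-rate class freezes the root residue down the whole tree.

#' Specification of a synthetic alignment
#'
#' @param tree an `ape::phylo` tree with branch lengths in expected
#'   substitutions/site (>= 3 leaves)
#' @param n_columns number of alignment columns
#' @param rate_classes data frame with columns `rate` (relative rate >= 0)
#'   and `prop` (proportions summing to 1)
#' @param residue_frequencies stationary frequencies over the 20 canonical
#'   residues (BLOSUM row order), summing to 1
#' @param seed integer seed
#' @return an `alignment_spec` list
#' @export
alignment_spec <- function(tree, n_columns,
                           rate_classes = tibble(rate = c(0.1, 5),
                                                 prop = c(0.5, 0.5)),
                           residue_frequencies = rep(1 / 20, 20), seed = 1) {
  if (!inherits(tree, "phylo")) stop_pc("tree must be an ape phylo object")
  if (length(tree$tip.label) < 3) stop_pc("tree must have >= 3 leaves")
  rate_classes <- as_tibble(rate_classes)
  if (any(rate_classes$rate < 0)) stop_pc("rates must be >= 0")
  if (abs(sum(rate_classes$prop) - 1) > 1e-9)
    stop_pc("rate-class proportions must sum to 1")
  if (length(residue_frequencies) != 20 ||
      abs(sum(residue_frequencies) - 1) > 1e-9)
    stop_pc("residue_frequencies must be a 20-vector summing to 1")
  structure(list(tree = tree, n_columns = as.integer(n_columns),
                 rate_classes = rate_classes,
                 residue_frequencies = residue_frequencies,
                 seed = as.integer(seed)),
            class = "alignment_spec")
}

# lower-triangle exchangeabilities in phangorn's amino-acid order
b62_exchangeabilities <- function(levels) {
  b <- blosum62()[levels, levels]
  ex <- 2^(b / 2)
  ex[lower.tri(ex)]
}

#' Evolve a gap-free alignment along a tree with known site-rate classes
#'
#' @param spec an [alignment_spec()]
#' @param root_seq optional character vector or string of canonical residues
#'   used as the root sequence (recycled/truncated to `n_columns`); when
#'   `NULL` the root is drawn from the stationary frequencies
#' @return list with `alignment` (tibble `id`, `organism`, `seq`, class
#'   `msa`) and `column_rates` (tibble `column`, `class`, `rate`)
#' @export
evolve_alignment <- function(spec, root_seq = NULL) {
  stopifnot(inherits(spec, "alignment_spec"))
  tree <- spec$tree
  set.seed(spec$seed)
  levels_aa <- attr(phangorn::phyDat(matrix("A", 1, 1), type = "AA"),
                    "levels")
  bf <- spec$residue_frequencies[match(levels_aa, aa_alphabet)]
  Q <- b62_exchangeabilities(levels_aa)

  n <- spec$n_columns
  counts <- apportion(spec$rate_classes$prop, n)
  class_of <- sample(rep(seq_len(nrow(spec$rate_classes)), counts))
  tips <- tree$tip.label

  if (!is.null(root_seq)) {
    if (length(root_seq) == 1) root_seq <- strsplit(root_seq, "")[[1]]
    root_seq[!root_seq %in% aa_alphabet] <-
      sample(aa_alphabet, sum(!root_seq %in% aa_alphabet), replace = TRUE)
    root_seq <- rep_len(root_seq, n)
  }

  aln <- matrix(NA_character_, length(tips), n, dimnames = list(tips, NULL))
  for (k in seq_len(nrow(spec$rate_classes))) {
    cols <- which(class_of == k)
    if (!length(cols)) next
    rate <- spec$rate_classes$rate[k]
    root_k <- if (is.null(root_seq)) {
      sample(levels_aa, length(cols), replace = TRUE, prob = bf)
    } else root_seq[cols]
    if (rate == 0) {
      aln[, cols] <- matrix(root_k, length(tips), length(cols), byrow = TRUE)
    } else {
      sim <- phangorn::simSeq(tree, l = length(cols), Q = Q, bf = bf,
                              type = "AA", rate = rate, rootseq = root_k)
      m <- as.character(sim)
      aln[, cols] <- toupper(m[tips, , drop = FALSE])
    }
  }

  alignment <- tibble(
    id = tips, organism = tips,
    seq = apply(aln, 1, paste, collapse = "")
  )
  class(alignment) <- c("msa", class(alignment))
  list(alignment = alignment,
       column_rates = tibble(column = seq_len(n), class = class_of,
                             rate = spec$rate_classes$rate[class_of]))
}

#' Write an alignment to FASTA
#' @param aln an `msa` tibble (`id`, `seq`)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fasta_alignment <- function(aln, path) {
  x <- Biostrings::AAStringSet(setNames(aln$seq, aln$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA or Clustal alignment into an `msa` tibble
#' @param path alignment file
#' @param format `"fasta"` or `"clustal"`
#' @return tibble (`id`, `organism`, `seq`) of equal-length aligned rows
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  x <- Biostrings::readAAMultipleAlignment(path, format = format)
  s <- as.character(x)
  out <- tibble(id = names(s), organism = names(s), seq = unname(s))
  if (length(unique(nchar(out$seq))) > 1)
    stop_pc("alignment rows have unequal length")
  class(out) <- c("msa", class(out))
  out
}

msa_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seq, ""))
  rownames(m) <- aln$id
  m
}
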
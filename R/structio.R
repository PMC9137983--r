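# Superposition, pairwise RMSD and representative selection.

common_ca <- function(a, b) {
  ra <- residue_table(a); rb <- residue_table(b)
  ra <- ra[!is.na(ra$x), ]; rb <- rb[!is.na(rb$x), ]
  shared <- intersect(ra$resno, rb$resno)
  enough <- length(shared) >= max(3, 0.5 * min(nrow(ra), nrow(rb))) ||
    length(shared) >= 30
  if (!enough) {
    # numbering offset: fall back to sequence alignment of extracted sequences
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(paste(ra$aa, collapse = "")),
      Biostrings::AAString(paste(rb$aa, collapse = "")),
      type = "global", substitutionMatrix = blosum62(),
      gapOpening = 10, gapExtension = 0.5)
    pat <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    sub <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
    ia <- 0L; ib <- 0L; pa <- integer(0); pb <- integer(0)
    for (k in seq_along(pat)) {
      if (pat[k] != "-") ia <- ia + 1L
      if (sub[k] != "-") ib <- ib + 1L
      if (pat[k] != "-" && sub[k] != "-") { pa <- c(pa, ia); pb <- c(pb, ib) }
    }
  } else {
    pa <- match(shared, ra$resno); pb <- match(shared, rb$resno)
  }
  if (length(pa) < 3)
    stop_pc("fewer than 3 common alpha carbons between structures")
  list(a = as.matrix(ra[pa, c("x", "y", "z")]),
       b = as.matrix(rb[pb, c("x", "y", "z")]))
}

kabsch <- function(P, Q) {
  # least-squares rotation R and translation t with R %*% p + t ~ q
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- t(P - rep(cp, each = nrow(P))) %*% (Q - rep(cq, each = nrow(Q)))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t_vec <- cq - as.vector(R %*% cp)
  moved <- t(R %*% t(P)) + rep(t_vec, each = nrow(P))
  list(rotation = R, translation = t_vec,
       rmsd = sqrt(mean(rowSums((moved - Q)^2))))
}

#' Superpose two structures (Kabsch least squares on common alpha carbons)
#'
#' Alpha carbons are matched by author residue number; when the overlap is
#' too small (numbering offsets) matching falls back to a global sequence
#' alignment of the extracted sequences.
#'
#' @param a,b `protein_structure`s with >= 3 common alpha carbons
#' @return list with `rotation` (proper, det = +1), `translation` (maps
#'   `a` onto `b`), `rmsd` (Angstrom) and `n_atoms` used
#' @export
superpose <- function(a, b) {
  xy <- common_ca(a, b)
  fit <- kabsch(xy$a, xy$b)
  fit$n_atoms <- nrow(xy$a)
  fit
}

#' Pairwise best-fit RMSD matrix over an ensemble
#'
#' Every pair is superposed independently.
#'
#' @param structures named list of `protein_structure`s (>= 2)
#' @return symmetric labelled matrix of RMSD values (Angstrom)
#' @export
rmsd_matrix <- function(structures) {
  n <- length(structures)
  if (n < 2) stop_pc("need >= 2 structures")
  ids <- names(structures) %||% paste0("S", seq_len(n))
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- tryCatch(superpose(structures[[i]], structures[[j]])$rmsd,
                    error = function(e)
                      stop_pc("superposition failed for pair ", ids[i], " / ",
                              ids[j], ": ", conditionMessage(e)))
      m[i, j] <- m[j, i] <- r
    }
  }
  m
}

#' Cluster an ensemble and pick representatives
#'
#' k-means on a classical multidimensional-scaling embedding of the RMSD
#' matrix (up to `min(8, n - 1)` dimensions, 10 restarts, fixed seed).  The
#' representative of each cluster is chosen by best (lowest) resolution,
#' then fewest missing residues, then lowest mean B-factor, then
#' lexicographic id.
#'
#' @param m symmetric RMSD matrix from [rmsd_matrix()]
#' @param k target number of clusters (default 6); capped at the number of
#'   structures (and at the number of distinct embedded points)
#' @param metadata optional tibble (`id`, `resolution`, `n_missing`,
#'   `mean_b`) used for representative selection
#' @param seed integer seed for the k-means restarts
#' @return a `cluster_assignment`: list with `assignments` (tibble `id`,
#'   `cluster`), `representatives` (tibble `cluster`, `id`) and `k`
#' @export
cluster_representatives <- function(m, k = 6, metadata = NULL, seed = 1) {
  m <- as.matrix(m)
  if (any(!is.finite(m))) stop_pc("non-finite RMSD entries")
  if (k < 1) stop_pc("k must be >= 1")
  n <- nrow(m)
  ids <- rownames(m) %||% paste0("S", seq_len(n))
  k_eff <- as.integer(min(k, n))
  if (n == 1) {
    cl <- 1L
  } else {
    emb <- suppressWarnings(cmdscale(stats::as.dist(m), k = min(8, n - 1)))
    if (is.null(dim(emb))) emb <- matrix(emb, ncol = 1)
    if (ncol(emb) == 0 || nrow(emb) < n) emb <- matrix(0, n, 1)
    n_distinct <- nrow(unique(round(emb, 10)))
    if (n_distinct < k_eff) {
      warn(sprintf("only %d distinct conformations; reducing k from %d",
                   n_distinct, k_eff))
      k_eff <- n_distinct
    }
    if (k_eff == 1) {
      cl <- rep(1L, n)
    } else if (k_eff == n) {
      cl <- seq_len(n)  # every structure is its own cluster
    } else {
      set.seed(seed)
      km <- kmeans(emb, centers = k_eff, nstart = 10, iter.max = 100)
      cl <- km$cluster
    }
  }
  assignments <- tibble(id = ids, cluster = as.integer(cl))
  if (is.null(metadata)) {
    metadata <- tibble(id = ids, resolution = NA_real_,
                       n_missing = NA_integer_, mean_b = NA_real_)
  }
  reps <- assignments |>
    left_join(metadata, by = "id") |>
    group_by(.data$cluster) |>
    arrange(.data$resolution, .data$n_missing, .data$mean_b, .data$id,
            .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select("cluster", "id")
  structure(list(assignments = assignments, representatives = reps,
                 k = k_eff),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("<cluster_assignment>", nrow(x$assignments), "structures in", x$k,
      "clusters\n")
  print(x$representatives)
  invisible(x)
}
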
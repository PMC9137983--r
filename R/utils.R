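# Shared internal helpers: amino-acid tables, BLOSUM62 access, geometry.

.pc_env <- new.env(parent = emptyenv())

#' @noRd
aa_three_to_one <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V", MSE = "M"
)

#' Canonical amino-acid alphabet (Biostrings/BLOSUM row order)
#' @noRd
aa_alphabet <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

charged_residues <- c("D", "E", "K", "R")

#' BLOSUM62 substitution matrix (full, incl. X), cached from Biostrings
#' @noRd
blosum62 <- function() {
  if (is.null(.pc_env$B62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pc_env$B62 <- e$BLOSUM62
  }
  .pc_env$B62
}

#' BLOSUM62 restricted to the 20 canonical residues
#' @noRd
blosum62_20 <- function() {
  blosum62()[aa_alphabet, aa_alphabet]
}

#' Self-score-normalised BLOSUM62 similarity: b(a,b) = B(a,b)/sqrt(B(a,a)B(b,b)).
#' Equals 1 iff a == b (off-diagonal entries never reach the geometric mean of
#' the diagonals in BLOSUM62), so an invariant alignment column always attains
#' the maximal per-column similarity.
#' @noRd
blosum62_normalised <- function() {
  if (is.null(.pc_env$B62N)) {
    b <- blosum62_20()
    d <- sqrt(diag(b))
    .pc_env$B62N <- b / outer(d, d)
  }
  .pc_env$B62N
}

#' Bondi van der Waals radii by element (Angstrom)
#' @noRd
vdw_radius <- function(elem) {
  r <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
         SE = 1.90, MG = 1.73, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)
  out <- r[toupper(elem)]
  out[is.na(out)] <- 1.70
  unname(out)
}

#' Quasi-uniform unit vectors on the sphere (Fibonacci lattice)
#' @param n number of directions
#' @return n x 3 matrix of unit vectors
#' @noRd
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Largest-remainder apportionment of n items to fractional shares
#' @noRd
apportion <- function(fractions, n) {
  raw <- fractions * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

#' Minimum distance from each row of `x` to the rows of `y` (both n x 3),
#' computed in column chunks to bound memory.
#' @noRd
min_dist_to_set <- function(x, y, chunk = 5000L) {
  n <- nrow(x)
  out <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    d2 <- outer(rowSums(x[s:e, , drop = FALSE]^2), rowSums(y^2), "+") -
      2 * x[s:e, , drop = FALSE] %*% t(y)
    out[s:e] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' Pairwise squared distances between rows of x (m x 3) and y (n x 3)
#' @noRd
cross_dist2 <- function(x, y) {
  d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * x %*% t(y)
  pmax(d2, 0)
}

stop_pc <- function(...) abort(paste0(...), class = "pocketcons_error")
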
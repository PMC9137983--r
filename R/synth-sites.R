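# Candidate-site descriptor tables for filter testing.

#' Generate a candidate-site table straddling every filter threshold
#'
#' Produces a descriptor table (site points, enclosure, hydrophilic score,
#' charged fraction, conserved fraction, SiteScore, DScore) guaranteed to
#' contain rows on both sides of every default decision boundary: scores
#' 0.8, 50% conserved residues, 26.3% charged residues and the 15-site-point
#' minimum.
#'
#' @param n_rows number of rows (>= 1); the first rows are deterministic
#'   boundary-straddling anchors, the remainder randomised
#' @param seed integer seed
#' @return tibble with columns `site_id`, `n_points`, `enclosure`,
#'   `hydrophilic`, `charged_fraction`, `conserved_fraction`, `site_score`,
#'   `d_score`
#' @export
make_candidate_sites <- function(n_rows, seed = 1) {
  if (n_rows < 1) stop_pc("n_rows must be >= 1")
  set.seed(seed)
  # anchors: (n, e, p, charged, conserved) on both sides of each threshold
  anchors <- tibble(
    n_points = c(100L, 16L, 80L, 60L, 40L, 14L, 100L, 30L),
    enclosure = c(0.85, 0.30, 0.80, 0.75, 0.50, 0.90, 0.90, 0.40),
    hydrophilic = c(0.50, 1.20, 0.80, 1.00, 1.50, 0.60, 0.70, 1.10),
    charged_fraction = c(0.10, 0.30, 0.25, 0.40, 0.20, 0.05, 0.263, 0.35),
    conserved_fraction = c(0.80, 0.20, 0.55, 0.45, 0.50, 0.90, 0.60, 0.30)
  )
  extra <- max(0L, n_rows - nrow(anchors))
  if (extra > 0) {
    rnd <- tibble(
      n_points = sample(5:150, extra, replace = TRUE),
      enclosure = round(runif(extra, 0.1, 0.95), 3),
      hydrophilic = round(runif(extra, 0.2, 1.8), 3),
      charged_fraction = round(runif(extra, 0, 0.6), 3),
      conserved_fraction = round(runif(extra, 0, 1), 3)
    )
    out <- bind_rows(anchors, rnd)
  } else {
    out <- anchors
  }
  out <- out[seq_len(n_rows), ]
  out <- bind_cols(tibble(site_id = sprintf("S%04d", seq_len(n_rows))), out)
  out$site_score <- round(site_score(out$n_points, out$enclosure,
                                     out$hydrophilic), 6)
  out$d_score <- round(d_score(out$n_points, out$enclosure,
                               out$hydrophilic), 6)
  out
}

#' Write a candidate-site table to CSV
#' @param sites tibble from [make_candidate_sites()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_candidate_sites <- function(sites, path) {
  write.csv(sites, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a candidate-site table from CSV
#' @param path CSV path
#' @return tibble with the candidate-site columns
#' @export
read_candidate_sites <- function(path) {
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
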
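# The printed druggability equations and the reference submicromolar-site
# profile.
#
# Both scores combine the site-point count n (capped at 100), the enclosure
# e and the hydrophilic score p.  The site-point term is taken on
# sqrt(min(n, 100)): with the linear reading the reference profile would
# score about 7.3/9.4, an order of magnitude off the scores' own 0.8
# threshold and the published around-1 values, while the square-root
# reading reproduces them (1.0547 / 1.084).  A `n_transform = "linear"`
# switch preserves the literal form.

#' SiteScore: ligandability of a detected site
#'
#' `SiteScore = 0.0733 * sqrt(min(n, 100)) + 0.6688 * e - 0.20 * min(p, 1)`;
#' the hydrophilic score is capped at 1.0 to limit the impact of
#' hydrophilicity in charged and highly polar sites.  Sites at or above 0.8
#' are considered ligandable.
#'
#' @param n site-point count (capped at 100 internally)
#' @param e enclosure score in `[0, 1]`
#' @param p hydrophilic score
#' @param n_transform `"sqrt"` (default; reproduces the published score
#'   scale) or `"linear"` (the literal printed form)
#' @return numeric SiteScore, vectorised over the inputs
#' @export
site_score <- function(n, e, p, n_transform = c("sqrt", "linear")) {
  n_transform <- match.arg(n_transform)
  f <- if (n_transform == "sqrt") sqrt else identity
  0.0733 * f(pmin(n, 100)) + 0.6688 * e - 0.20 * pmin(p, 1.0)
}

#' DScore: druggability of a detected site
#'
#' `DScore = 0.094 * sqrt(min(n, 100)) + 0.60 * e - 0.324 * p`; unlike
#' SiteScore the hydrophilic penalty is not capped, so highly polar sites
#' are pushed below the 0.8 druggability threshold.
#'
#' @inheritParams site_score
#' @return numeric DScore, vectorised over the inputs
#' @export
d_score <- function(n, e, p, n_transform = c("sqrt", "linear")) {
  n_transform <- match.arg(n_transform)
  f <- if (n_transform == "sqrt") sqrt else identity
  0.094 * f(pmin(n, 100)) + 0.60 * e - 0.324 * p
}

#' Reference profile of the average submicromolar site
#'
#' The published property profile of an average submicromolar binding site,
#' used as the comparison baseline for detected pockets.
#'
#' @return one-row tibble: `n_points` 132, `site_score` 1 (threshold 0.8),
#'   `d_score` 1 (threshold 0.8), `exposure` 0.49, `enclosure` 0.78,
#'   `contact` 1.0, `phobic` 1.0, `philic` 1.0, `balance` 1.6, `donacc`
#'   0.76
#' @export
reference_profile <- function() {
  tibble(
    n_points = 132L, site_score = 1, d_score = 1, score_threshold = 0.8,
    exposure = 0.49, enclosure = 0.78, contact = 1.0, phobic = 1.0,
    philic = 1.0, balance = 1.6, donacc = 0.76
  )
}
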
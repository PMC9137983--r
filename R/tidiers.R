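# broom-style tidy()/glance() methods for pocketcons result objects.

#' @describeIn tidy one row per Mann-Whitney comparison
#' @param x a fitted pocketcons object
#' @param ... unused
#' @export
tidy.group_comparison <- function(x, ...) {
  tibble(statistic = x$u, p.value = x$p,
         method = if (x$exact) "Mann-Whitney U (exact)"
                  else "Mann-Whitney U (normal approximation)",
         alternative = "two.sided")
}

#' @describeIn glance group sizes, KS screen and significance flag
#' @param x a fitted pocketcons object
#' @param ... unused
#' @export
glance.group_comparison <- function(x, ...) {
  tibble(n1 = x$n1, n2 = x$n2,
         ks.p.a = x$ks_a$p, ks.p.b = x$ks_b$p,
         p.value = x$p, significant = x$significant)
}

#' @describeIn tidy per-site descriptor rows (list-columns flattened)
#' @export
tidy.site_set <- function(x, ...) {
  out <- as_tibble(x)
  if ("lining" %in% names(out))
    out$n_lining <- map_int(out$lining, length)
  out <- out[, setdiff(names(out), "lining")]
  out
}

#' @describeIn glance site count and the best scores
#' @export
glance.site_set <- function(x, ...) {
  tibble(n_sites = nrow(x),
         best_site_score = if (nrow(x)) max(x$site_score) else NA_real_,
         best_d_score = if (nrow(x)) max(x$d_score) else NA_real_,
         total_volume = if (nrow(x)) sum(x$volume) else 0)
}

#' @describeIn tidy per-column conservation rows
#' @export
tidy.conservation_profile <- function(x, ...) {
  as_tibble(x)[, intersect(c("column", "raw", "score", "grade", "flag"),
                           names(x))]
}

#' @describeIn glance column counts and grade coverage
#' @export
glance.conservation_profile <- function(x, ...) {
  tibble(n_columns = nrow(x),
         n_flagged = sum(x$flag != ""),
         n_grades = if (!"grade" %in% names(x)) NA_integer_
                    else length(unique(x$grade[x$flag == ""])),
         mean_score = mean(x$score, na.rm = TRUE),
         sd_score = sd(x$score, na.rm = TRUE))
}

#' @describeIn tidy retained assessment rows of a combined-filter result
#' @export
tidy.filter_result <- function(x, ...) {
  out <- as_tibble(x$retained)
  if ("lining" %in% names(out))
    out$lining <- map_chr(out$lining, ~ paste(.x, collapse = ";"))
  out
}

#' @describeIn glance stage counts of a combined-filter result
#' @export
glance.filter_result <- function(x, ...) {
  tibble(n_input = x$n_input, n_after_scores = x$n_after_scores,
         n_after_conservation = x$n_after_conservation,
         score_thr = x$score_thr, cons_thr = x$cons_thr)
}

#' @describeIn tidy per-structure cluster assignments
#' @export
tidy.cluster_assignment <- function(x, ...) x$assignments

#' @describeIn glance cluster count of an ensemble clustering
#' @export
glance.cluster_assignment <- function(x, ...) {
  tibble(k = x$k, n_structures = nrow(x$assignments))
}

#' @describeIn tidy the assessment table of a pipeline report
#' @export
tidy.assessment_report <- function(x, ...) {
  out <- as_tibble(x$assessments)
  if ("lining" %in% names(out))
    out$lining <- map_chr(out$lining, ~ paste(.x, collapse = ";"))
  out
}

#' @describeIn glance headline counts of a pipeline report
#' @export
glance.assessment_report <- function(x, ...) {
  tibble(n_sites = nrow(x$sites),
         n_clusters = nrow(x$clusters),
         n_retained = if (is.null(x$filter)) 0L
                      else x$filter$n_after_conservation,
         pct_conserved = if (is.null(x$summary)) NA_real_
                         else x$summary$pct_conserved)
}
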
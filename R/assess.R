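# Integration stage: site typing, conserved fractions, quadrant
# classification and the combined druggability-by-conservation filter.

#' Label sites as orthosteric, cofactor or other
#'
#' A site is orthosteric if any lining residue lies within `cutoff` of a
#' ligand atom, cofactor if within `cutoff` of a cofactor atom; a site near
#' both is orthosteric with a `merged` flag (colliding sites form one large
#' site).
#'
#' @param sites a `site_set` tibble with a `lining` list-column
#' @param s the `protein_structure` providing lining-residue coordinates
#' @param ligand_xyz optional n x 3 matrix of ligand atom coordinates
#' @param cofactor_xyz optional n x 3 matrix of cofactor atom coordinates
#' @param cutoff contact cutoff (Angstrom, default 4)
#' @return `sites` with `site_type` (`orthosteric`/`cofactor`/`other`) and
#'   `merged` columns added
#' @export
label_site_type <- function(sites, s, ligand_xyz = NULL, cofactor_xyz = NULL,
                            cutoff = 4.0) {
  sites <- as_tibble(sites)
  if (is.null(ligand_xyz) && is.null(cofactor_xyz)) {
    warn("no reference ligand/cofactor atoms supplied; all sites typed 'other'")
    sites$site_type <- if (nrow(sites)) "other" else character(0)
    sites$merged <- logical(nrow(sites))
    return(sites)
  }
  a <- s$atoms[!s$atoms$het, ]
  near_ref <- function(lining, ref) {
    if (is.null(ref) || !length(lining)) return(FALSE)
    ref <- matrix(as.numeric(ref), ncol = 3)
    sel <- a$resno %in% lining
    if (!any(sel)) return(FALSE)
    d <- sqrt(cross_dist2(as.matrix(a[sel, c("x", "y", "z")]), ref))
    min(d) <= cutoff
  }
  lig <- map_lgl_safe(sites$lining, near_ref, ligand_xyz)
  cof <- map_lgl_safe(sites$lining, near_ref, cofactor_xyz)
  sites$site_type <- dplyr::case_when(lig ~ "orthosteric",
                                      cof ~ "cofactor",
                                      TRUE ~ "other")
  sites$merged <- lig & cof
  sites
}

map_lgl_safe <- function(x, f, ...) vapply(x, f, logical(1), ...)

#' Conserved fraction of a site's lining
#'
#' Fraction of graded lining residues with conservation grade 8 or 9.
#'
#' @param lining integer vector of lining residue numbers
#' @param grades a `residue_grades` tibble from [map_to_structure()]
#' @param conserved_min lowest grade counted as conserved (default 8)
#' @return fraction in `[0, 1]`
#' @export
conserved_fraction <- function(lining, grades, conserved_min = 8) {
  g <- grades$grade[match(lining, grades$resno)]
  g <- g[!is.na(g)]
  if (!length(g)) stop_pc("no graded residues line this site")
  mean(g >= conserved_min)
}

#' Classify a score pair into a druggability quadrant
#'
#' The SiteScore/DScore plane is split at `threshold` into four regions:
#' `UR` (both scores at/above threshold: ligandable and druggable), `LR`
#' (SiteScore only: binds small molecules but hard to drug), `UL` (DScore
#' only) and `LL` (neither).  Boundaries are inclusive toward the
#' favourable side.
#'
#' @param sitescore,dscore finite numeric vectors
#' @param threshold decision threshold (default 0.8)
#' @return character vector of quadrant labels
#' @export
classify_quadrant <- function(sitescore, dscore, threshold = 0.8) {
  if (any(!is.finite(sitescore)) || any(!is.finite(dscore)))
    stop_pc("scores must be finite")
  dplyr::case_when(
    sitescore >= threshold & dscore >= threshold ~ "UR",
    sitescore >= threshold ~ "LR",
    dscore >= threshold ~ "UL",
    TRUE ~ "LL"
  )
}

#' Assemble site assessments
#'
#' Joins scores, conservation and charge into one assessment row per site,
#' with the standard flags: ligandable (SiteScore >= `score_thr`),
#' druggable (DScore >= `score_thr`), conserved (conserved fraction >=
#' `cons_thr`), charged_exceeds (charged fraction strictly above
#' `charged_thr`), and `retained` = ligandable & druggable & conserved.
#'
#' @param sites tibble with `site_score`, `d_score`, `charged_fraction` and
#'   either a `conserved_fraction` column or a `lining` list-column
#' @param grades optional `residue_grades` used to compute conserved
#'   fractions from `lining`
#' @param score_thr score threshold (default 0.8)
#' @param cons_thr conserved-fraction threshold (default 0.5)
#' @param charged_thr charged-fraction flag threshold (default 0.263)
#' @return a `site_assessment` tibble
#' @export
assess_sites <- function(sites, grades = NULL, score_thr = 0.8,
                         cons_thr = 0.5, charged_thr = 0.263) {
  out <- as_tibble(sites)
  if (!"conserved_fraction" %in% names(out)) {
    if (is.null(grades) || !"lining" %in% names(out))
      stop_pc("need either a conserved_fraction column or grades + lining")
    out$conserved_fraction <- map_dbl(out$lining, conserved_fraction, grades)
  }
  out$quadrant <- classify_quadrant(out$site_score, out$d_score, score_thr)
  out$ligandable <- out$site_score >= score_thr
  out$druggable <- out$d_score >= score_thr
  out$conserved <- out$conserved_fraction >= cons_thr
  out$charged_exceeds <- if ("charged_fraction" %in% names(out))
    out$charged_fraction > charged_thr else NA
  out$retained <- out$ligandable & out$druggable & out$conserved
  class(out) <- unique(c("site_assessment", class(out)))
  out
}

#' Apply the combined druggability-by-conservation filter
#'
#' Two stages: first both scores must reach `score_thr`, then the conserved
#' fraction must reach `cons_thr`.  Boundaries are inclusive.
#'
#' @param assessments a `site_assessment` tibble (see [assess_sites()]) or
#'   any tibble with `site_score`, `d_score` and `conserved_fraction`
#' @param score_thr score threshold (default 0.8)
#' @param cons_thr conserved-fraction threshold (default 0.5)
#' @return a `filter_result`: list with `retained` (surviving rows),
#'   `n_input`, `n_after_scores`, `n_after_conservation`
#' @export
apply_combined_filter <- function(assessments, score_thr = 0.8,
                                  cons_thr = 0.5) {
  a <- as_tibble(assessments)
  pass1 <- a$site_score >= score_thr & a$d_score >= score_thr
  pass2 <- pass1 & a$conserved_fraction >= cons_thr
  structure(list(retained = assessments[pass2, ],
                 n_input = nrow(a),
                 n_after_scores = sum(pass1),
                 n_after_conservation = sum(pass2),
                 score_thr = score_thr, cons_thr = cons_thr),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat("<filter_result>", x$n_input, "sites ->", x$n_after_scores,
      "after scores ->", x$n_after_conservation, "after conservation\n")
  invisible(x)
}

#' Summarise conservation over a structure
#'
#' Percentage of residues at conservation grade 8-9 and the distribution of
#' those residues over helix/sheet/loop (loop = neither HELIX nor SHEET
#' annotation).
#'
#' @param grades a `residue_grades` tibble
#' @param ss per-residue secondary structure: tibble (`resno`, `ss`) or a
#'   `protein_structure` (annotations are read from it)
#' @param conserved_min lowest grade counted as conserved (default 8)
#' @param per_site optional named list of lining residue-number vectors;
#'   adds per-site conserved percentages
#' @return a `conservation_summary`: list with `pct_conserved`, `ss_split`
#'   (fractions over helix/sheet/loop summing to 1 when any conserved
#'   residue exists) and `per_site`
#' @export
conservation_summary <- function(grades, ss, conserved_min = 8,
                                 per_site = NULL) {
  if (inherits(ss, "protein_structure")) {
    res <- residue_table(ss)
    ss <- tibble(resno = res$resno, ss = res$ss)
  }
  g <- grades[!is.na(grades$grade), ]
  conserved <- g$resno[g$grade >= conserved_min]
  pct <- if (nrow(g)) 100 * length(conserved) / nrow(g) else NA_real_
  cls <- ss$ss[match(conserved, ss$resno)]
  cls[is.na(cls)] <- "loop"
  split <- if (length(conserved)) {
    tab <- table(factor(cls, levels = c("helix", "sheet", "loop")))
    as.numeric(tab) / length(conserved)
  } else c(0, 0, 0)
  names(split) <- c("helix", "sheet", "loop")
  per_site_pct <- if (!is.null(per_site))
    map_dbl(per_site, ~ 100 * conserved_fraction(.x, grades, conserved_min))
  else NULL
  structure(list(pct_conserved = pct, ss_split = split,
                 per_site = per_site_pct),
            class = "conservation_summary")
}

#' @export
print.conservation_summary <- function(x, ...) {
  cat(sprintf("<conservation_summary> %.1f%% residues at grade 8-9\n",
              x$pct_conserved))
  cat(sprintf("  split: helix %.0f%% / sheet %.0f%% / loop %.0f%%\n",
              100 * x$ss_split[1], 100 * x$ss_split[2], 100 * x$ss_split[3]))
  invisible(x)
}

#' Compare pocket hydrogen-bonding character with known inhibitors
#'
#' Per enzyme: median inhibitor TPSA, median per-compound donor/acceptor
#' ratio, the pocket donor/acceptor descriptor, and the sign of the
#' mismatch (pocket minus inhibitors; positive = the pocket favours more
#' donors than the inhibitors provide).
#'
#' @param assessments tibble with `enzyme` and `donacc` columns (one or more
#'   site rows per enzyme)
#' @param inhibitors tibble with columns `enzyme`, `compound_id`, `tpsa`,
#'   `hbd`, `hba`
#' @return tibble per enzyme: `median_tpsa`, `median_donacc_inhibitors`,
#'   `pocket_donacc`, `mismatch_sign`; enzymes without inhibitors get
#'   missing-value markers
#' @export
compare_inhibitor_profile <- function(assessments, inhibitors) {
  a <- as_tibble(assessments)
  if (!"enzyme" %in% names(a)) stop_pc("assessments need an 'enzyme' column")
  inh <- as_tibble(inhibitors)
  pocket <- a |>
    group_by(.data$enzyme) |>
    summarise(pocket_donacc = median(.data$donacc, na.rm = TRUE),
              .groups = "drop")
  inh_sum <- if (nrow(inh)) {
    inh |>
      mutate(ratio = .data$hbd / .data$hba) |>
      group_by(.data$enzyme) |>
      summarise(median_tpsa = median(.data$tpsa),
                median_donacc_inhibitors = median(.data$ratio),
                .groups = "drop")
  } else {
    tibble(enzyme = character(0), median_tpsa = numeric(0),
           median_donacc_inhibitors = numeric(0))
  }
  out <- left_join(pocket, inh_sum, by = "enzyme")
  out$mismatch_sign <- sign(out$pocket_donacc -
                              out$median_donacc_inhibitors)
  out[, c("enzyme", "median_tpsa", "median_donacc_inhibitors",
          "pocket_donacc", "mismatch_sign")]
}

#' Read an inhibitor property table (CSV)
#'
#' Expected columns: `enzyme`, `compound_id`, `tpsa`, `hbd`, `hba`.
#'
#' @param path CSV path
#' @return validated tibble
#' @export
read_inhibitor_table <- function(path) {
  x <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  need <- c("enzyme", "compound_id", "tpsa", "hbd", "hba")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop_pc("inhibitor table lacks: ",
                            paste(miss, collapse = ", "))
  if (any(x$tpsa < 0) || any(x$hbd < 0) || any(x$hba < 0))
    stop_pc("TPSA and donor/acceptor counts must be >= 0")
  x
}
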
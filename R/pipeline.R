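# End-to-end pipeline: conservation -> structure -> pockets -> hotspots ->
# combined assessment, with a machine-readable run manifest.

#' Pipeline configuration
#'
#' Defaults follow the published workflow settings: 0.35 A grid, >= 15 site
#' points, <= 10 sites, 4 A lining cutoff, score threshold 0.8, conserved
#' fraction 0.5, charged fraction 0.263, k = 6 ensemble clusters, 3
#' predicted probe sites.
#'
#' @param structure a [structure_spec()], a `protein_structure`, or a PDB
#'   file path
#' @param alignment `NULL` (a synthetic alignment is evolved from the
#'   structure sequence), an [alignment_spec()], an `msa` tibble, or a
#'   FASTA path
#' @param chain chain to load when `structure` is a path
#' @param reference_row alignment row mapped onto the structure (default:
#'   first row)
#' @param spacing,min_points,max_sites,burial_min pocket-detection settings
#' @param score_thr,cons_thr,charged_thr assessment thresholds
#' @param lining_cutoff lining distance (Angstrom)
#' @param n_predicted probe-mapping predicted site count
#' @param seed master seed for all stochastic stages
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(structure = NULL, alignment = NULL, chain = "A",
                            reference_row = NULL, spacing = 0.35,
                            min_points = 15, max_sites = 10,
                            burial_min = 0.5, score_thr = 0.8,
                            cons_thr = 0.5, charged_thr = 0.263,
                            lining_cutoff = 4.0, n_predicted = 3, seed = 1) {
  structure(list(structure = structure, alignment = alignment, chain = chain,
                 reference_row = reference_row, spacing = spacing,
                 min_points = min_points, max_sites = max_sites,
                 burial_min = burial_min, score_thr = score_thr,
                 cons_thr = cons_thr, charged_thr = charged_thr,
                 lining_cutoff = lining_cutoff, n_predicted = n_predicted,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop_pc(stage, ": ", conditionMessage(e)))
}

default_pipeline_tree <- function(seed) {
  set.seed(seed)
  tr <- ape::rtree(8, br = NULL)
  tr$edge.length <- round(runif(nrow(tr$edge), 0.05, 0.3), 3)
  tr
}

#' Run the full assessment pipeline
#'
#' Executes conservation scoring, structure ingest, pocket detection,
#' probe mapping and the combined assessment, returning a single report.
#'
#' @param config a [pipeline_config()]
#' @return an `assessment_report`: list with the structure, conservation
#'   profile and residue grades, the ranked `sites`, probe `clusters` and
#'   `predicted` sites, the `assessments` table, the combined-`filter`
#'   result, a `summary` and a machine-readable `manifest`
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))

  s <- with_stage("structio", {
    st <- config$structure
    if (is.null(st)) stop_pc("no structure input configured")
    if (inherits(st, "protein_structure")) st
    else if (inherits(st, "structure_spec")) generate_structure(st)
    else load_structure(st, chain = config$chain, keep_ligands = TRUE)
  })

  aln_res <- with_stage("seqcons", {
    al <- config$alignment
    if (is.null(al)) {
      root <- extract_sequence(s)$seq
      spec <- alignment_spec(default_pipeline_tree(config$seed),
                             n_columns = nchar(root),
                             rate_classes = tibble(rate = c(0.1, 5),
                                                   prop = c(0.7, 0.3)),
                             seed = config$seed)
      ev <- evolve_alignment(spec, root_seq = root)
      ev$alignment
    } else if (inherits(al, "alignment_spec")) {
      evolve_alignment(al)$alignment
    } else if (is.data.frame(al)) {
      al
    } else {
      read_alignment(al)
    }
  })

  cons <- with_stage("seqcons", {
    d <- pairwise_distance(aln_res)
    tree <- build_nj_tree(d)
    profile <- assign_grades(score_conservation(aln_res, tree))
    row_id <- config$reference_row %||% aln_res$id[1]
    grades <- map_to_structure(profile, row_id, s)
    list(tree = tree, profile = profile, grades = grades, row = row_id)
  })

  sites <- with_stage("sitefind",
    find_sites(s, spacing = config$spacing, burial_min = config$burial_min,
               min_points = config$min_points,
               max_sites = config$max_sites))

  probes <- with_stage("probemap", {
    poses <- map_probes(s, seed = config$seed)
    clusters <- cluster_poses(poses)
    predicted <- predict_binding_sites(clusters, s,
                                       n_sites = config$n_predicted,
                                       lining_cutoff = config$lining_cutoff)
    list(poses = poses, clusters = clusters, predicted = predicted)
  })

  assessment <- with_stage("assess", {
    lig <- s$atoms[s$atoms$het & s$atoms$resid == "LIG", ]
    cof <- s$atoms[s$atoms$het & s$atoms$resid == "MG", ]
    lig_xyz <- if (nrow(lig)) as.matrix(lig[, c("x", "y", "z")]) else NULL
    cof_xyz <- if (nrow(cof)) as.matrix(cof[, c("x", "y", "z")]) else NULL
    typed <- if (nrow(sites)) {
      if (is.null(lig_xyz) && is.null(cof_xyz)) {
        tmp <- as_tibble(sites); tmp$site_type <- "other"
        tmp$merged <- FALSE; tmp
      } else label_site_type(sites, s, lig_xyz, cof_xyz,
                             cutoff = config$lining_cutoff)
    } else sites
    if (!nrow(typed)) {
      list(assessments = typed, filter = NULL, summary = NULL)
    } else {
      a <- assess_sites(typed, grades = cons$grades,
                        score_thr = config$score_thr,
                        cons_thr = config$cons_thr,
                        charged_thr = config$charged_thr)
      f <- apply_combined_filter(a, config$score_thr, config$cons_thr)
      lin <- setNames(a$lining, a$site_id)
      summ <- conservation_summary(cons$grades, s, per_site = lin)
      list(assessments = a, filter = f, summary = summ)
    }
  })

  manifest <- list(
    package = "pocketcons",
    version = as.character(utils::packageVersion("pocketcons")),
    thresholds = list(score = config$score_thr, conserved = config$cons_thr,
                      charged = config$charged_thr,
                      min_points = config$min_points,
                      max_sites = config$max_sites,
                      lining_cutoff = config$lining_cutoff,
                      spacing = config$spacing,
                      burial_min = config$burial_min),
    seeds = list(master = config$seed),
    reference_row = cons$row
  )
  structure(list(structure = s, alignment = aln_res, tree = cons$tree,
                 profile = cons$profile, grades = cons$grades,
                 sites = sites, poses = probes$poses,
                 clusters = probes$clusters, predicted = probes$predicted,
                 assessments = assessment$assessments,
                 filter = assessment$filter, summary = assessment$summary,
                 manifest = manifest),
            class = "assessment_report")
}

#' @export
print.assessment_report <- function(x, ...) {
  cat("<assessment_report>\n")
  cat("  sites detected:", nrow(x$sites), "\n")
  if (!is.null(x$filter))
    cat("  retained by combined filter:", x$filter$n_after_conservation,
        "\n")
  cat("  probe consensus clusters:", nrow(x$clusters), "\n")
  invisible(x)
}

#' Write an assessment report to a directory
#'
#' Emits the per-site CSV, the assessment CSV, the per-residue grades TSV,
#' the probe-cluster CSV, the retained-site list and the JSON summary and
#' manifest.  Output is byte-stable for an identical report.
#'
#' @param report an `assessment_report`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "assessment_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  num <- function(x) if (is.numeric(x)) round(x, 6) else x
  flatten_sites <- function(x) {
    x <- as_tibble(x)
    if ("lining" %in% names(x))
      x$lining <- map_chr(x$lining, ~ paste(.x, collapse = ";"))
    x <- x[, setdiff(names(x), "members")]
    mutate(x, across(dplyr::where(is.numeric), ~ round(.x, 6)))
  }
  if (!is.null(report$sites) && nrow(report$sites))
    write.csv(flatten_sites(report$sites), file.path(dir, "sites.csv"),
              row.names = FALSE, quote = FALSE)
  if (!is.null(report$assessments) && nrow(report$assessments))
    write.csv(flatten_sites(report$assessments),
              file.path(dir, "assessments.csv"), row.names = FALSE,
              quote = FALSE)
  if (!is.null(report$grades))
    write_grades_table(
      mutate(report$grades, score = round(.data$score, 6)),
      file.path(dir, "grades.tsv"))
  if (!is.null(report$clusters) && nrow(report$clusters))
    write.csv(flatten_sites(report$clusters),
              file.path(dir, "clusters.csv"), row.names = FALSE,
              quote = FALSE)
  if (!is.null(report$filter) && nrow(report$filter$retained))
    write.csv(flatten_sites(report$filter$retained),
              file.path(dir, "retained.csv"), row.names = FALSE,
              quote = FALSE)
  if (!is.null(report$summary))
    jsonlite::write_json(
      list(pct_conserved = num(report$summary$pct_conserved),
           ss_split = as.list(num(report$summary$ss_split)),
           per_site = as.list(num(report$summary$per_site))),
      file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
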
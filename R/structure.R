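# Single-chain protein structure container and PDB input/output.
#
# A `protein_structure` holds an atoms tibble (one row per heavy atom,
# author residue numbering preserved), optional secondary-structure
# annotations parsed from HELIX/SHEET records, and header metadata
# (resolution, mean B-factor, count of missing residues).

new_structure <- function(atoms, chain = "A", ss = NULL, metadata = list(),
                          source = NA_character_) {
  stopifnot(is.data.frame(atoms))
  atoms <- as_tibble(atoms)
  need <- c("eleno", "elety", "resid", "chain", "resno", "x", "y", "z",
            "b", "elem", "het")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop_pc("atoms table lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) && any(!is.finite(c(atoms$x, atoms$y, atoms$z))))
    stop_pc("non-finite atom coordinates")
  structure(
    list(atoms = atoms, chain = chain,
         ss = ss %||% tibble(resno = integer(), ss = character()),
         metadata = metadata, source = source),
    class = "protein_structure"
  )
}

#' @export
print.protein_structure <- function(x, ...) {
  prot <- x$atoms[!x$atoms$het, ]
  cat("<protein_structure> chain", x$chain, "|",
      length(unique(prot$resno)), "residues |",
      nrow(prot), "protein atoms |",
      sum(x$atoms$het), "kept heteroatoms\n")
  if (!is.null(x$metadata$resolution) && !is.na(x$metadata$resolution))
    cat("  resolution:", x$metadata$resolution, "A\n")
  invisible(x)
}

#' Number of residues in a structure
#' @param s a `protein_structure`
#' @return integer count of polymer residues
#' @export
n_residues <- function(s) {
  stopifnot(inherits(s, "protein_structure"))
  nrow(residue_table(s))
}

#' Per-residue table of a structure
#'
#' One row per polymer residue, in author order, with the alpha-carbon
#' coordinates (NA when the residue has no CA atom).
#'
#' @param s a `protein_structure`
#' @return tibble with `resno`, `resid`, `aa` (one-letter, `X` for
#'   nonstandard), `x`, `y`, `z` (CA position), and `ss`
#'   (helix/sheet/loop).
#' @export
residue_table <- function(s) {
  stopifnot(inherits(s, "protein_structure"))
  prot <- s$atoms[!s$atoms$het, ]
  if (!nrow(prot)) {
    return(tibble(resno = integer(), resid = character(), aa = character(),
                  x = numeric(), y = numeric(), z = numeric(), ss = character()))
  }
  res <- prot |>
    group_by(.data$resno) |>
    summarise(resid = .data$resid[1],
              x = .data$x[match("CA", .data$elety)],
              y = .data$y[match("CA", .data$elety)],
              z = .data$z[match("CA", .data$elety)],
              .groups = "drop") |>
    arrange(.data$resno)
  res$aa <- unname(aa_three_to_one[res$resid])
  res$aa[is.na(res$aa)] <- "X"
  res$ss <- ss_of_residues(s, res$resno)
  res[, c("resno", "resid", "aa", "x", "y", "z", "ss")]
}

ss_of_residues <- function(s, resno) {
  out <- rep("loop", length(resno))
  if (nrow(s$ss)) {
    out[resno %in% s$ss$resno[s$ss$ss == "helix"]] <- "helix"
    out[resno %in% s$ss$resno[s$ss$ss == "sheet"]] <- "sheet"
  }
  out
}

atom_xyz <- function(s, protein_only = TRUE) {
  a <- s$atoms
  if (protein_only) a <- a[!a$het, ]
  as.matrix(a[, c("x", "y", "z")])
}

#' Load and clean a single chain from a PDB file
#'
#' Retains the requested chain's polymer heavy atoms plus any magnesium
#' cofactor heteroatoms; drops waters, ligands and all other co-crystallised
#' molecules; keeps the first model and alternate location 'A' (or blank)
#' only; reads selenomethionine (MSE) as methionine. HELIX/SHEET records are
#' parsed into per-residue annotations and resolution / missing-residue
#' counts are taken from the header when present.
#'
#' @param path path to a PDB file
#' @param chain chain identifier to keep (default `"A"`)
#' @param keep_ligands if `TRUE`, non-water heteroatoms of the chain are kept
#'   and flagged (used by the synthetic fixtures to carry a planted ligand)
#' @return a `protein_structure`
#' @export
load_structure <- function(path, chain = "A", keep_ligands = FALSE) {
  if (!file.exists(path)) stop_pc("no such file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                  verbose = FALSE),
                  error = function(e) stop_pc("PDB parse error for ", path, ": ",
                                              conditionMessage(e)))
  at <- as_tibble(pdb$atom)
  at$chain[is.na(at$chain)] <- ""
  chains <- sort(unique(at$chain))
  if (!chain %in% chains)
    stop_pc("chain '", chain, "' not present; available chains: ",
            paste(chains, collapse = ", "))
  at <- at[at$chain == chain & (is.na(at$alt) | at$alt %in% c("", "A")), ]
  # selenomethionine is read as methionine
  mse <- at$resid == "MSE"
  at$resid[mse] <- "MET"
  at$type[mse] <- "ATOM"
  at$elety[mse & at$elety == "SE"] <- "SD"
  at$elesy[mse & toupper(at$elesy) == "SE"] <- "S"

  is_water <- at$resid %in% c("HOH", "WAT", "DOD")
  is_mg <- at$resid %in% c("MG") | toupper(at$elesy) %in% "MG"
  is_prot <- at$type == "ATOM" & at$resid %in% names(aa_three_to_one)
  keep_het <- (at$type == "HETATM" & !is_water & (is_mg | keep_ligands))
  at <- at[is_prot | keep_het, ]
  if (!nrow(at)) stop_pc("no atoms retained for chain ", chain)

  elem <- toupper(at$elesy)
  bad <- is.na(elem) | elem == ""
  elem[bad] <- toupper(substr(gsub("[0-9]", "", at$elety[bad]), 1, 1))
  atoms <- tibble(
    eleno = at$eleno, elety = at$elety, resid = at$resid, chain = at$chain,
    resno = at$resno, insert = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z, b = ifelse(is.na(at$b), 0, at$b),
    elem = elem, het = !(at$type == "ATOM" & at$resid %in% names(aa_three_to_one))
  )
  # drop hydrogens: descriptors are heavy-atom based
  atoms <- atoms[atoms$elem != "H", ]

  ss <- parse_ss(pdb, chain)
  lines <- readLines(path, warn = FALSE)
  metadata <- list(
    resolution = parse_resolution(lines),
    n_missing = parse_missing(lines, chain),
    mean_b = mean(atoms$b[!atoms$het])
  )
  new_structure(atoms, chain = chain, ss = ss, metadata = metadata,
                source = path)
}

parse_ss <- function(pdb, chain) {
  out <- list()
  h <- pdb$helix
  if (!is.null(h) && length(h$start)) {
    keep <- h$chain == chain
    if (any(keep))
      out$helix <- tibble(resno = unlist(Map(seq, h$start[keep], h$end[keep])),
                          ss = "helix")
  }
  sh <- pdb$sheet
  if (!is.null(sh) && length(sh$start)) {
    keep <- sh$chain == chain
    if (any(keep))
      out$sheet <- tibble(resno = unlist(Map(seq, sh$start[keep], sh$end[keep])),
                          ss = "sheet")
  }
  if (!length(out)) return(tibble(resno = integer(), ss = character()))
  bind_rows(out)
}

parse_resolution <- function(lines) {
  hit <- grep("^REMARK   2 RESOLUTION\\.", lines, value = TRUE)
  if (!length(hit)) return(NA_real_)
  num <- regmatches(hit[1], regexpr("[0-9]+\\.[0-9]+", hit[1]))
  if (!length(num)) NA_real_ else as.numeric(num)
}

parse_missing <- function(lines, chain) {
  rem <- grep("^REMARK 465", lines, value = TRUE)
  if (!length(rem)) return(0L)
  # REMARK 465   M RES C SSSEQI -> residue rows have a residue name in col 16-18
  rows <- rem[grepl("^REMARK 465\\s+[A-Z]{3}\\s+[A-Za-z0-9]\\s+-?[0-9]+\\s*$", rem)]
  if (!length(rows)) return(0L)
  ch <- sub("^REMARK 465\\s+[A-Z]{3}\\s+([A-Za-z0-9])\\s+-?[0-9]+\\s*$", "\\1", rows)
  sum(ch == chain)
}

#' Extract the one-letter sequence of a structure
#'
#' @param s a `protein_structure`
#' @param id identifier for the returned record
#' @return tibble with `id`, `organism` and `seq` (a sequence record);
#'   nonstandard residues appear as `X`
#' @export
extract_sequence <- function(s, id = s$source %||% "structure") {
  res <- residue_table(s)
  if (!nrow(res)) {
    warn("structure contains no polymer residues; returning empty sequence")
    return(tibble(id = id, organism = NA_character_, seq = ""))
  }
  tibble(id = as.character(id), organism = NA_character_,
         seq = paste(res$aa, collapse = ""))
}

#' Write a structure as a PDB v3.3 file
#'
#' Fixed-width ATOM/HETATM/TER/END records with optional HELIX/SHEET and
#' REMARK 2 resolution lines; output is byte-stable for identical input.
#'
#' @param s a `protein_structure`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_structure_pdb <- function(s, path) {
  stopifnot(inherits(s, "protein_structure"))
  lines <- character(0)
  if (!is.null(s$metadata$resolution) && !is.na(s$metadata$resolution))
    lines <- c(lines, sprintf("REMARK   2 RESOLUTION. %7.2f ANGSTROMS.",
                              s$metadata$resolution))
  ss <- s$ss
  if (nrow(ss)) {
    runs <- function(v) {
      v <- sort(unique(v))
      if (!length(v)) return(NULL)
      brk <- c(0, which(diff(v) > 1), length(v))
      map(seq_len(length(brk) - 1), ~ v[(brk[.x] + 1):brk[.x + 1]])
    }
    for (r in runs(ss$resno[ss$ss == "helix"]) %||% list()) {
      lines <- c(lines, sprintf(
        "HELIX    1   1 %3s %1s %4d  %3s %1s %4d  1%30s%6d",
        "ALA", s$chain, min(r), "ALA", s$chain, max(r), "", length(r)))
    }
    for (r in runs(ss$resno[ss$ss == "sheet"]) %||% list()) {
      lines <- c(lines, sprintf(
        "SHEET    1   A 1 %3s %1s%4d  %3s %1s%4d  0",
        "ALA", s$chain, min(r), "ALA", s$chain, max(r)))
    }
  }
  a <- s$atoms
  rec <- ifelse(a$het, "HETATM", "ATOM  ")
  name4 <- ifelse(nchar(a$elety) >= 4, substr(a$elety, 1, 4),
                  sprintf(" %-3s", a$elety))
  lines <- c(lines, sprintf(
    "%s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    rec, a$eleno %% 100000L, name4, "", a$resid, a$chain, a$resno %% 10000L,
    "", a$x, a$y, a$z, 1, a$b, a$elem))
  last <- a[nrow(a), ]
  lines <- c(lines,
             sprintf("TER   %5d      %3s %1s%4d",
                     (last$eleno + 1L) %% 100000L, last$resid, last$chain,
                     last$resno %% 10000L),
             "END")
  writeLines(lines, path)
  invisible(path)
}
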
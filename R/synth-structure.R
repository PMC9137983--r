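# Synthetic structures with engineered cavities.
#
# Pseudo-residues (an alpha carbon plus a one-atom side-chain proxy typed by
# residue class) are placed on concentric spherical shells around a cavity
# centroid at the origin.  The innermost shell lines the cavity; a mouth
# opening is carved by removing residues inside a spherical cap covering the
# requested fraction of the full solid angle.  The construction gives direct,
# monotone control over cavity volume, enclosure and lining polarity, which
# is all the downstream descriptors need — it makes no attempt at a
# physically realistic fold.

#' Specification of a synthetic cavity-bearing structure
#'
#' @param shell_radius outer radius of the pseudo-protein shell (Angstrom)
#' @param cavity_radius radius of the guaranteed empty void around the cavity
#'   centroid (Angstrom); must be smaller than `shell_radius`
#' @param mouth_fraction fraction in `[0,1]` of the full solid angle carved
#'   open around the +z axis (0 = fully enclosed cavity)
#' @param lining_composition named fractions over residue classes
#'   `hydrophobic`, `polar`, `charged` (D/E/K/R); must sum to 1
#' @param residue_count total number of pseudo-residues before the mouth is
#'   carved
#' @param plant_ligand place a one-atom HETATM ligand at the cavity centroid
#' @param seed integer seed; identical spec + seed gives byte-identical output
#' @param lining_count number of residues on the cavity-lining shell
#'   (default: scaled to the lining-shell surface area)
#' @return a `structure_spec` list
#' @export
structure_spec <- function(shell_radius = 18, cavity_radius = 6,
                           mouth_fraction = 0.1,
                           lining_composition = c(hydrophobic = 0.5,
                                                  polar = 0.3, charged = 0.2),
                           residue_count = 150, plant_ligand = FALSE,
                           seed = 1, lining_count = NULL) {
  if (cavity_radius >= shell_radius)
    stop_pc("invalid spec: cavity_radius must be < shell_radius")
  if (mouth_fraction < 0 || mouth_fraction > 1)
    stop_pc("invalid spec: mouth_fraction must lie in [0, 1]")
  need <- c("hydrophobic", "polar", "charged")
  if (!all(need %in% names(lining_composition)))
    stop_pc("lining_composition needs fractions named ",
            paste(need, collapse = ", "))
  lining_composition <- lining_composition[need]
  if (abs(sum(lining_composition) - 1) > 1e-9)
    stop_pc("invalid spec: lining_composition fractions must sum to 1")
  if (residue_count < 4) stop_pc("invalid spec: residue_count too small")
  structure(list(shell_radius = shell_radius, cavity_radius = cavity_radius,
                 mouth_fraction = mouth_fraction,
                 lining_composition = lining_composition,
                 residue_count = as.integer(residue_count),
                 plant_ligand = isTRUE(plant_ligand), seed = as.integer(seed),
                 lining_count = if (is.null(lining_count)) NULL
                                else as.integer(lining_count)),
            class = "structure_spec")
}

# residue templates per class: name, side-chain proxy atom name and element
.res_templates <- list(
  hydrophobic = list(c("LEU", "CG", "C"), c("VAL", "CB", "C"),
                     c("ILE", "CG1", "C"), c("PHE", "CG", "C")),
  polar = list(c("SER", "OG", "O"), c("THR", "OG1", "O"),
               c("ASN", "OD1", "O"), c("GLN", "NE2", "N")),
  charged = list(c("ASP", "OD1", "O"), c("GLU", "OE1", "O"),
                 c("LYS", "NZ", "N"), c("ARG", "NH1", "N"))
)

#' Generate a synthetic structure with an engineered cavity
#'
#' @param spec a [structure_spec()]
#' @param path optional file path; when given, the structure is also written
#'   as a PDB file
#' @return a `protein_structure`; the cavity centroid (the origin) is stored
#'   in `$metadata$cavity_centroid` and the lining residue numbers in
#'   `$metadata$lining_resno`
#' @export
generate_structure <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "structure_spec"))
  set.seed(spec$seed)
  r_inner <- spec$cavity_radius + 2.4  # keeps the void >= cavity_radius
  radii <- seq(r_inner, spec$shell_radius, by = 3.0)
  if (length(radii) == 0) radii <- r_inner

  # per-layer residue counts dense enough to seal the wall (lateral spacing
  # ~3.2 A < twice the vdW + probe exclusion), scaled up if the requested
  # residue_count asks for more
  n_per <- pmax(8L, as.integer(ceiling(4 * pi * radii^2 / (3.2^2 * 0.866))))
  if (sum(n_per) < spec$residue_count)
    n_per <- as.integer(ceiling(n_per * spec$residue_count / sum(n_per)))
  if (!is.null(spec$lining_count)) n_per[1] <- spec$lining_count

  placements <- purrr::map2(radii, n_per, function(r, n) {
    if (n == 0) return(NULL)
    fibonacci_sphere(n) * r
  })
  layer <- rep(seq_along(radii), vapply(placements, function(m)
    if (is.null(m)) 0L else nrow(m), integer(1)))
  ca <- do.call(rbind, placements)

  # carve the mouth: spherical cap of the stated solid-angle fraction (+z)
  if (spec$mouth_fraction > 0) {
    cos_alpha <- 1 - 2 * spec$mouth_fraction
    cosz <- ca[, 3] / sqrt(rowSums(ca^2))
    keep <- cosz < cos_alpha
    ca <- ca[keep, , drop = FALSE]
    layer <- layer[keep]
  }
  n_res <- nrow(ca)
  if (n_res < 4) stop_pc("mouth opening removed nearly all residues")

  # assign residue classes; exact counts on the lining shell
  assign_classes <- function(n) {
    counts <- apportion(spec$lining_composition, n)
    sample(rep(c("hydrophobic", "polar", "charged"), counts))
  }
  classes <- character(n_res)
  for (l in unique(layer)) {
    idx <- which(layer == l)
    classes[idx] <- assign_classes(length(idx))
  }
  pick <- function(cls) {
    tpl <- .res_templates[[cls]]
    tpl[[sample.int(length(tpl), 1)]]
  }
  tmpl <- t(vapply(classes, pick, character(3)))

  dirs <- ca / sqrt(rowSums(ca^2))
  side <- ca - dirs * 1.5  # side-chain proxy points toward the cavity
  resno <- seq_len(n_res)
  atoms <- tibble(
    eleno = integer(0), elety = character(0), resid = character(0),
    chain = character(0), resno = integer(0), x = numeric(0), y = numeric(0),
    z = numeric(0), b = numeric(0), elem = character(0), het = logical(0)
  )
  atoms <- tibble(
    eleno = seq_len(2L * n_res),
    elety = as.vector(rbind("CA", tmpl[, 2])),
    resid = rep(tmpl[, 1], each = 2),
    chain = "A",
    resno = rep(resno, each = 2),
    x = as.vector(rbind(ca[, 1], side[, 1])),
    y = as.vector(rbind(ca[, 2], side[, 2])),
    z = as.vector(rbind(ca[, 3], side[, 3])),
    b = 20,
    elem = as.vector(rbind("C", tmpl[, 3])),
    het = FALSE
  )
  if (spec$plant_ligand) {
    # a small tetrahedral ligand spanning the cavity so its atoms sit within
    # contact distance of the lining
    rl <- max(0, spec$cavity_radius - 1)
    lig <- rbind(c(0, 0, 0),
                 rl / sqrt(3) * rbind(c(1, 1, 1), c(1, -1, -1),
                                      c(-1, 1, -1), c(-1, -1, 1)))
    atoms <- bind_rows(atoms, tibble(
      eleno = max(atoms$eleno) + seq_len(5L), elety = paste0("C", 1:5),
      resid = "LIG", chain = "A", resno = max(resno) + 1L,
      x = lig[, 1], y = lig[, 2], z = lig[, 3], b = 20, elem = "C",
      het = TRUE))
  }
  atoms$x <- round(atoms$x, 3); atoms$y <- round(atoms$y, 3)
  atoms$z <- round(atoms$z, 3)

  s <- new_structure(atoms, chain = "A",
                     metadata = list(
                       cavity_centroid = c(0, 0, 0),
                       cavity_radius = spec$cavity_radius,
                       lining_resno = resno[layer == 1L],
                       resolution = 2.0, n_missing = 0L,
                       mean_b = 20, spec = spec),
                     source = "synthetic")
  if (!is.null(path)) write_structure_pdb(s, path)
  s
}

#' Generate a conformational ensemble with planted families
#'
#' Family centroids are independent whole-structure deformations of the base
#' structure scaled so that every pair of centroids is at least
#' `between_shift` apart in best-fit RMSD; members add iid Gaussian
#' coordinate noise with standard deviation `within_noise` per coordinate.
#'
#' @param base a [structure_spec()] for the common scaffold
#' @param families number of conformational families (>= 1)
#' @param members_per_family structures per family (>= 1)
#' @param within_noise per-coordinate Gaussian noise sd within a family
#'   (Angstrom)
#' @param between_shift minimum pairwise best-fit RMSD between family
#'   centroids (Angstrom)
#' @param seed integer seed
#' @return named list of `protein_structure`s; the true partition is in
#'   `attr(, "families")` (tibble `id`, `family`) and per-structure synthetic
#'   metadata in `attr(, "metadata")`
#' @export
generate_ensemble <- function(base, families, members_per_family,
                              within_noise = 0.1, between_shift = 3,
                              seed = 1) {
  stopifnot(inherits(base, "structure_spec"),
            families >= 1, members_per_family >= 1)
  base_s <- generate_structure(base)
  xyz <- atom_xyz(base_s, protein_only = FALSE)
  n_at <- nrow(xyz)
  set.seed(seed)

  defs <- map(seq_len(families), function(f) {
    if (families == 1) return(matrix(0, n_at, 3))
    d <- matrix(rnorm(n_at * 3), n_at, 3)
    d / sqrt(mean(rowSums(d^2))) * between_shift / sqrt(2)
  })
  if (families > 1) {
    # guarantee the minimum pairwise centroid RMSD by rescaling once
    cen_rmsd <- function(a, b) {
      d <- (xyz + a) - (xyz + b)
      sqrt(mean(rowSums(d^2)))
    }
    pairs <- combn(families, 2)
    min_r <- min(apply(pairs, 2, function(p) cen_rmsd(defs[[p[1]]], defs[[p[2]]])))
    if (min_r < between_shift && min_r > 0)
      defs <- map(defs, ~ .x * between_shift / min_r * 1.01)
  }

  out <- list()
  fam_tab <- list()
  meta <- list()
  k <- 0L
  for (f in seq_len(families)) {
    for (m in seq_len(members_per_family)) {
      k <- k + 1L
      id <- sprintf("F%02d_M%02d", f, m)
      noise <- if (within_noise > 0)
        matrix(rnorm(n_at * 3, sd = within_noise), n_at, 3)
      else matrix(0, n_at, 3)
      coords <- xyz + defs[[f]] + noise
      s <- base_s
      s$atoms$x <- round(coords[, 1], 3)
      s$atoms$y <- round(coords[, 2], 3)
      s$atoms$z <- round(coords[, 3], 3)
      s$metadata$resolution <- round(1.5 + 0.1 * ((k - 1L) %% 10L), 2)
      s$metadata$n_missing <- 0L
      s$source <- id
      out[[id]] <- s
      fam_tab[[k]] <- tibble(id = id, family = f)
      meta[[k]] <- tibble(id = id, resolution = s$metadata$resolution,
                          n_missing = 0L, mean_b = 20)
    }
  }
  attr(out, "families") <- bind_rows(fam_tab)
  attr(out, "metadata") <- bind_rows(meta)
  out
}
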
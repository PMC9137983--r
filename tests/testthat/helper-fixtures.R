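# Shared fixtures, all built in code at test time.

.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

# enclosed cavity structure used across sitefind/probemap tests
fx_cavity <- function(cavity = 4, mouth = 0, seed = 1, shell = cavity + 8,
                      lining = c(hydrophobic = 0.5, polar = 0.3,
                                 charged = 0.2), ligand = FALSE) {
  key <- paste("cav", cavity, mouth, seed, shell, ligand,
               paste(lining, collapse = "_"))
  memo(key, generate_structure(structure_spec(
    shell_radius = shell, cavity_radius = cavity, mouth_fraction = mouth,
    lining_composition = lining, residue_count = 50, plant_ligand = ligand,
    seed = seed)))
}

fx_sites <- function(cavity = 4, mouth = 0, seed = 1, spacing = 0.7, ...) {
  key <- paste("sites", cavity, mouth, seed, spacing)
  memo(key, find_sites(fx_cavity(cavity, mouth, seed, ...),
                       spacing = spacing))
}

# flat slab of carbon atoms filling z <= 0 (half-space burial oracle)
fx_halfspace <- function() {
  memo("halfspace", {
    g <- expand.grid(x = seq(-13.5, 13.5, 1.5), y = seq(-13.5, 13.5, 1.5),
                     z = seq(-6, 0, 1.5))
    atoms <- tibble::tibble(
      eleno = seq_len(nrow(g)), elety = "CA", resid = "ALA", chain = "A",
      resno = seq_len(nrow(g)), x = g$x, y = g$y, z = g$z, b = 20,
      elem = "C", het = FALSE)
    pocketcons:::new_structure(atoms)
  })
}

# random ultrametric-ish tree with branch lengths for alignment evolution
fx_tree <- function(n = 8, seed = 3) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 0.3)
  tr
}

# wrap a bare coordinate matrix as an all-CA structure
structure_from_xyz <- function(xyz, resid = "ALA") {
  xyz <- matrix(xyz, ncol = 3)
  atoms <- tibble::tibble(
    eleno = seq_len(nrow(xyz)), elety = "CA", resid = resid, chain = "A",
    resno = seq_len(nrow(xyz)), x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    b = 20, elem = "C", het = FALSE)
  pocketcons:::new_structure(atoms)
}

# hand-built multi-chain PDB file: chain A (ALA, MSE, GLY + altloc B atom),
# chain B (GLY), waters, an NAD fragment and an Mg ion
write_pdb_fixture <- function(path) {
  fmt <- function(rec, serial, name, alt, res, chain, resno, x, y, z,
                  elem) {
    sprintf("%-6s%5d %s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            rec, serial, sprintf(" %-3s", name), alt, res, chain, resno,
            x, y, z, 1, 20, elem)
  }
  lines <- c(
    "HEADER    TEST PROTEIN                            01-JAN-20   XXXX",
    "REMARK   2 RESOLUTION.    1.80 ANGSTROMS.",
    sprintf("HELIX    1   1 ALA A    1  MSE A    2  1%30s%6d", "", 2),
    sprintf("SHEET    1   A 1 GLY A   3  GLY A   3  0"),
    fmt("ATOM", 1, "N", "", "ALA", "A", 1, 0, 0, 0, "N"),
    fmt("ATOM", 2, "CA", "", "ALA", "A", 1, 1.5, 0, 0, "C"),
    fmt("ATOM", 3, "C", "", "ALA", "A", 1, 2.2, 1.3, 0, "C"),
    fmt("ATOM", 4, "O", "", "ALA", "A", 1, 1.6, 2.4, 0, "O"),
    fmt("ATOM", 5, "CB", "A", "ALA", "A", 1, 2.1, -1.2, 0.9, "C"),
    fmt("ATOM", 6, "CB", "B", "ALA", "A", 1, 2.3, -1.4, 1.1, "C"),
    fmt("HETATM", 7, "N", "", "MSE", "A", 2, 3.6, 1.4, 0.2, "N"),
    fmt("HETATM", 8, "CA", "", "MSE", "A", 2, 4.5, 2.5, 0.4, "C"),
    fmt("HETATM", 9, "SE", "", "MSE", "A", 2, 5.8, 2.3, 1.8, "SE"),
    fmt("ATOM", 10, "N", "", "GLY", "A", 3, 5.0, 3.6, -0.4, "N"),
    fmt("ATOM", 11, "CA", "", "GLY", "A", 3, 6.0, 4.7, -0.5, "C"),
    fmt("ATOM", 12, "N", "", "GLY", "B", 1, 10, 10, 10, "N"),
    fmt("ATOM", 13, "CA", "", "GLY", "B", 1, 11.5, 10, 10, "C"),
    fmt("HETATM", 14, "O", "", "HOH", "A", 101, 8, 8, 8, "O"),
    fmt("HETATM", 15, "O", "", "HOH", "B", 102, 9, 9, 9, "O"),
    fmt("HETATM", 16, "PA", "", "NAD", "A", 201, -3, -3, -3, "P"),
    fmt("HETATM", 17, "O1A", "", "NAD", "A", 201, -4, -3, -2, "O"),
    fmt("HETATM", 18, "MG", "", "MG", "A", 301, -1, 2, 3, "MG"),
    "TER      19      GLY A   3",
    "END")
  writeLines(lines, path)
  path
}

# hand-rolled site_points object: rectangular blobs of grid points
fake_site_points <- function(blob_specs, spacing = 1) {
  idx <- do.call(rbind, lapply(blob_specs, function(b) {
    g <- as.matrix(expand.grid(seq_len(b$dims[1]) - 1L,
                               seq_len(b$dims[2]) - 1L,
                               seq_len(b$dims[3]) - 1L))
    sweep(g, 2, -as.integer(b$origin))
  }))
  storage.mode(idx) <- "integer"
  n <- nrow(idx)
  structure(list(
    coords = idx * spacing,
    index = idx,
    burial = rep(0.8, n),
    open = matrix(FALSE, n, 110),
    rays = pocketcons:::fibonacci_sphere(110),
    grid = structure(list(origin = c(0, 0, 0), spacing = spacing,
                          dims = c(1000L, 1000L, 1000L)),
                     class = "pocket_grid")),
    class = "site_points")
}
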
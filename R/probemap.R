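# Simplified fragment-probe hotspot mapping and consensus-cluster ranking.
#
# Each probe is a single sphere with typed polar/apolar complementarity:
# candidate centres are surface grid points, scored by protein contact plus
# complementarity between the probe's donors/acceptors and nearby protein
# acceptors/donors (lower = better).  Consensus clusters of retained poses
# are ranked by the total number of nonbonded protein contacts of their
# member poses, mirroring the consensus-site ranking rule of probe-mapping
# servers.

#' The 16-probe fragment library
#'
#' The canonical 16 small organic probes of varying size, shape and
#' polarity, with effective radii, hydrogen-bond donor/acceptor counts and
#' an apolar flag.
#'
#' @return tibble with `name`, `radius` (Angstrom), `donors`, `acceptors`,
#'   `apolar`
#' @export
probe_library <- function() {
  tibble(
    name = c("acetamide", "acetonitrile", "acetone", "acetaldehyde",
             "methylamine", "benzaldehyde", "benzene", "isobutanol",
             "cyclohexane", "N,N-dimethylformamide", "dimethyl ether",
             "ethanol", "ethane", "phenol", "isopropanol", "urea"),
    radius = c(2.3, 2.2, 2.4, 2.2, 2.0, 2.9, 2.7, 2.6,
               2.8, 2.6, 2.3, 2.2, 2.0, 2.8, 2.4, 2.3),
    donors = c(2L, 0L, 0L, 0L, 2L, 0L, 0L, 1L,
               0L, 0L, 0L, 1L, 0L, 1L, 1L, 4L),
    acceptors = c(1L, 1L, 1L, 1L, 1L, 1L, 0L, 1L,
                  0L, 1L, 1L, 1L, 0L, 1L, 1L, 1L),
    apolar = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE,
               TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)
  )
}

CONTACT_CUTOFF <- 4.5  # heavy-atom nonbonded contact distance

#' Map probes over a structure's surface
#'
#' Candidate centres are points of a 2 A surface grid (outside the vdW
#' volume, near the surface).  The score of a pose is minus its protein
#' contact term minus the polar (or apolar) complementarity between probe
#' and protein atom types; the best `keep_per_probe` poses per probe are
#' retained.
#'
#' @param s a `protein_structure`
#' @param probes probe tibble (default [probe_library()])
#' @param keep_per_probe poses retained per probe type (default 50)
#' @param seed integer seed (grid-origin jitter; results are deterministic
#'   per seed)
#' @param grid_spacing candidate-centre spacing (Angstrom)
#' @return a `pose_set` tibble: `probe`, `x`, `y`, `z`, `score`
#'   (lower = better), `contacts` (protein heavy atoms within 4.5 A)
#' @export
map_probes <- function(s, probes = probe_library(), keep_per_probe = 50,
                       seed = 1, grid_spacing = 2) {
  a <- s$atoms[!s$atoms$het, ]
  if (!nrow(a)) stop_pc("empty structure")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  radii <- vdw_radius(a$elem)
  set.seed(seed)
  jitter <- runif(3, 0, grid_spacing / 4)
  lo <- apply(xyz, 2, min) - 4 + jitter
  hi <- apply(xyz, 2, max) + 4
  cand <- as.matrix(expand.grid(seq(lo[1], hi[1], by = grid_spacing),
                                seq(lo[2], hi[2], by = grid_spacing),
                                seq(lo[3], hi[3], by = grid_spacing)))
  colnames(cand) <- NULL

  d <- sqrt(cross_dist2(cand, xyz))
  gap <- sweep(d, 2, radii)           # distance to each atom's vdW surface
  min_gap <- apply(gap, 1, min)
  surface <- min_gap > 0 & min_gap <= 4   # outside vdW, near the surface
  if (!any(surface)) stop_pc("no surface points found")
  cand <- cand[surface, , drop = FALSE]
  d <- d[surface, , drop = FALSE]
  min_gap <- min_gap[surface]

  w <- proximity_weight(d)
  is_polar <- a$elem %in% c("N", "O")
  is_apolar <- a$elem %in% c("C", "S")
  contact_term <- rowSums(w)
  acc_term <- rowSums(w[, a$elem == "O", drop = FALSE])  # protein acceptors
  don_term <- rowSums(w[, a$elem == "N", drop = FALSE])  # protein donors
  apolar_term <- rowSums(w[, is_apolar, drop = FALSE])
  polar_term <- rowSums(w[, is_polar, drop = FALSE])
  contacts <- rowSums(d <= CONTACT_CUTOFF)

  poses <- map(seq_len(nrow(probes)), function(i) {
    p <- probes[i, ]
    clash <- min_gap < 0.6 * p$radius
    compl <- 0.4 * (p$donors * acc_term + p$acceptors * don_term)
    if (p$apolar) compl <- compl + 0.4 * apolar_term - 0.2 * polar_term
    score <- -contact_term - compl
    score[clash] <- Inf
    ord <- order(score, cand[, 1], cand[, 2], cand[, 3])
    keep <- head(ord[is.finite(score[ord])], keep_per_probe)
    tibble(probe = p$name, x = cand[keep, 1], y = cand[keep, 2],
           z = cand[keep, 3], score = score[keep],
           contacts = as.integer(contacts[keep]))
  })
  out <- bind_rows(poses)
  class(out) <- c("pose_set", class(out))
  out
}

#' Cluster probe poses into ranked consensus clusters
#'
#' Greedy centroid clustering: poses are visited best score first; a pose
#' joins the first existing cluster whose seed lies within `radius`,
#' otherwise it seeds a new cluster.  Clusters are ranked by the total
#' nonbonded contacts of all member poses (descending), ties broken by the
#' number of distinct probe types, then lexicographic centroid, so the
#' ranking is a total order.
#'
#' @param poses a `pose_set` tibble (>= 1 pose)
#' @param radius clustering radius (Angstrom, default 3)
#' @return a `consensus_clusters` tibble: `rank`, `n_poses`,
#'   `n_probe_types`, `total_contacts`, centroid `cx`,`cy`,`cz`, and a
#'   `members` list-column of pose rows
#' @export
cluster_poses <- function(poses, radius = 3.0) {
  poses <- as_tibble(poses)
  if (!nrow(poses)) stop_pc("need at least one pose")
  ord <- order(poses$score, poses$x, poses$y, poses$z, poses$probe)
  poses <- poses[ord, ]
  seeds <- matrix(numeric(0), 0, 3)
  member_of <- integer(nrow(poses))
  for (i in seq_len(nrow(poses))) {
    p <- c(poses$x[i], poses$y[i], poses$z[i])
    if (nrow(seeds)) {
      d2 <- colSums((t(seeds) - p)^2)
      hit <- which(d2 <= radius^2)
    } else hit <- integer(0)
    if (length(hit)) {
      member_of[i] <- hit[1]
    } else {
      seeds <- rbind(seeds, p)
      member_of[i] <- nrow(seeds)
    }
  }
  cl <- map(seq_len(nrow(seeds)), function(k) {
    mem <- poses[member_of == k, ]
    tibble(n_poses = nrow(mem),
           n_probe_types = length(unique(mem$probe)),
           total_contacts = sum(mem$contacts),
           cx = mean(mem$x), cy = mean(mem$y), cz = mean(mem$z),
           members = list(mem))
  }) |> bind_rows()
  ord <- order(-cl$total_contacts, -cl$n_probe_types, cl$cx, cl$cy, cl$cz)
  cl <- cl[ord, ]
  cl <- bind_cols(tibble(rank = seq_len(nrow(cl))), cl)
  class(cl) <- c("consensus_clusters", class(cl))
  cl
}

#' Predict the top binding sites from consensus clusters
#'
#' Clusters whose centroids lie within `merge_radius` are merged (best rank
#' wins), the merged clusters are re-ranked by total contacts, and the top
#' `n_sites` are returned as predicted binding sites.  When a structure is
#' supplied, each site lists the residues within `lining_cutoff` of any
#' member pose.
#'
#' @param clusters a `consensus_clusters` tibble
#' @param s optional `protein_structure` for lining-residue extraction
#' @param n_sites number of predicted sites (default 3)
#' @param lining_cutoff lining distance cutoff (Angstrom, default 4)
#' @param merge_radius centroid merge distance (Angstrom, default 5)
#' @return a `predicted_sites` tibble: `rank`, `total_contacts`,
#'   `n_probe_types`, centroid, `lining` (list of residue numbers)
#' @export
predict_binding_sites <- function(clusters, s = NULL, n_sites = 3,
                                  lining_cutoff = 4.0, merge_radius = 5.0) {
  clusters <- as_tibble(clusters)
  if (!nrow(clusters)) stop_pc("need at least one cluster")
  cen <- as.matrix(clusters[, c("cx", "cy", "cz")])
  group <- rep(NA_integer_, nrow(clusters))
  g <- 0L
  for (i in seq_len(nrow(clusters))) {     # rank order: best first
    if (!is.na(group[i])) next
    g <- g + 1L
    group[i] <- g
    d2 <- colSums((t(cen) - cen[i, ])^2)
    group[is.na(group) & d2 <= merge_radius^2] <- g
  }
  merged <- map(seq_len(g), function(k) {
    mem <- clusters[group == k, ]
    all_poses <- bind_rows(mem$members)
    tibble(total_contacts = sum(mem$total_contacts),
           n_probe_types = length(unique(all_poses$probe)),
           cx = sum(mem$cx * mem$n_poses) / sum(mem$n_poses),
           cy = sum(mem$cy * mem$n_poses) / sum(mem$n_poses),
           cz = sum(mem$cz * mem$n_poses) / sum(mem$n_poses),
           members = list(all_poses))
  }) |> bind_rows()
  merged <- merged[order(-merged$total_contacts, -merged$n_probe_types,
                         merged$cx, merged$cy, merged$cz), ]
  if (nrow(merged) < n_sites)
    warn(sprintf("only %d consensus sites available (%d requested)",
                 nrow(merged), n_sites))
  merged <- head(merged, n_sites)
  merged <- bind_cols(tibble(rank = seq_len(nrow(merged))), merged)

  merged$lining <- map(merged$members, function(mem) {
    if (is.null(s)) return(integer(0))
    a <- s$atoms[!s$atoms$het, ]
    d <- sqrt(cross_dist2(as.matrix(a[, c("x", "y", "z")]),
                          as.matrix(mem[, c("x", "y", "z")])))
    sort(unique(a$resno[apply(d, 1, min) <= lining_cutoff]))
  })
  class(merged) <- c("predicted_sites", class(merged))
  merged
}
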
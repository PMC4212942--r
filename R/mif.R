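# Probe interaction fields on pocket nodes. Four probes sense complementary
# site properties: H (shape), O (site H-bond donors; the probe is a
# carbonyl-like acceptor), N1 (site H-bond acceptors; the probe is an
# amide-NH-like donor) and DRY (hydrophobicity). The energy model is an
# openly parameterized 12-6 Lennard-Jones plus a directional H-bond well
# and a hydrophobic Gaussian kernel; all parameters are exposed in
# probe_params() and can be overridden.

PROBE_TYPES <- c("H", "O", "N1", "DRY")

# Donor/acceptor typing by residue and atom name. `root` is the bonded
# heavy-atom antecedent used to orient the H (donor) or lone-pair
# (acceptor) axis; "*" matches any standard residue.
DONOR_TABLE <- data.frame(
  resname = c("*", "SER", "THR", "TYR", "ASN", "GLN", "LYS", "ARG", "ARG",
              "ARG", "HIS", "HIS", "TRP", "CYS"),
  atom    = c("N", "OG", "OG1", "OH", "ND2", "NE2", "NZ", "NE", "NH1",
              "NH2", "ND1", "NE2", "NE1", "SG"),
  root    = c("CA", "CB", "CB", "CZ", "CG", "CD", "CE", "CD", "CZ",
              "CZ", "CG", "CD2", "CD1", "CB"),
  stringsAsFactors = FALSE)

ACCEPTOR_TABLE <- data.frame(
  resname = c("*", "*", "ASP", "ASP", "GLU", "GLU", "ASN", "GLN", "SER",
              "THR", "TYR", "HIS", "HIS", "MET"),
  atom    = c("O", "OXT", "OD1", "OD2", "OE1", "OE2", "OD1", "OE1", "OG",
              "OG1", "OH", "ND1", "NE2", "SD"),
  root    = c("C", "C", "CG", "CG", "CD", "CD", "CG", "CD", "CB",
              "CB", "CZ", "CG", "CD2", "CG"),
  stringsAsFactors = FALSE)

# Carbons bonded only to carbon/hydrogen (aliphatic/aromatic), by residue.
NONPOLAR_CARBONS <- list(
  ALA = "CB", VAL = c("CB", "CG1", "CG2"),
  LEU = c("CB", "CG", "CD1", "CD2"), ILE = c("CB", "CG1", "CG2", "CD1"),
  PRO = c("CB", "CG"), MET = "CB", LYS = c("CB", "CG", "CD"),
  ARG = c("CB", "CG"), GLU = c("CB", "CG"), GLN = c("CB", "CG"),
  ASP = "CB", ASN = "CB", HIS = "CB", SER = NULL, THR = "CG2",
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2"),
  TRP = c("CB", "CG", "CD2", "CE3", "CZ2", "CZ3", "CH2"))

#' Default probe parameters
#'
#' Per-probe energy-model parameters: Lennard-Jones well depth `eps`
#' (kcal/mol) and probe radius `r_probe` (added to the atomic van der Waals
#' radius to give the pair r_min); H-bond strength `e_hb` (kcal/mol,
#' negative = favorable), optimum `hb_dist`, well width `hb_sigma` and
#' cutoff `hb_max` (Angstrom); hydrophobic kernel weight `w_phobic`,
#' optimum `dry_dist` and width `dry_sigma`; pseudo-field kernel width
#' `sigma`; and `e_ref`, the characteristic interaction energy dividing the
#' pseudo-field weights so that electrostatic and hydrophobic fields are
#' mutually comparable despite their very different absolute energies.
#' `clamp` and `shape_cut` are shared. The implicit partial charges of the
#' O and N1 probes enter through the sign and magnitude of `e_hb`.
#'
#' @param ... Named overrides, either top-level (`clamp`, `shape_cut`) or
#'   per-probe lists merged over the defaults, e.g. `DRY = list(w_phobic = 1)`.
#' @return A `biogps_probe_params` list.
#' @export
probe_params <- function(...) {
  p <- list(
    H   = list(eps = 0.15, r_probe = 1.20, sigma = 1.0, e_ref = 0.5),
    O   = list(eps = 0.15, r_probe = 1.50, e_hb = -4.0, hb_dist = 2.9,
               hb_sigma = 0.45, hb_max = 4.0, sigma = 1.2, e_ref = 4.0),
    N1  = list(eps = 0.15, r_probe = 1.55, e_hb = -3.0, hb_dist = 2.9,
               hb_sigma = 0.45, hb_max = 4.0, sigma = 1.2, e_ref = 3.0),
    DRY = list(eps = 0.15, r_probe = 1.70, w_phobic = 0.6, dry_dist = 4.0,
               dry_sigma = 1.0, sigma = 1.2, e_ref = 0.6),
    clamp = c(-15, 5), shape_cut = -0.5)
  ov <- list(...)
  for (nm in names(ov)) {
    stopifnot(nm %in% names(p))
    if (is.list(ov[[nm]])) p[[nm]][names(ov[[nm]])] <- ov[[nm]]
    else p[[nm]] <- ov[[nm]]
  }
  for (pr in PROBE_TYPES)
    stopifnot(p[[pr]]$eps > 0, p[[pr]]$r_probe > 0,
              all(is.finite(unlist(p[[pr]]))))
  structure(p, class = "biogps_probe_params")
}

# rows of s$atoms matching a typing table, with the axis unit vector
# (root -> atom, i.e. pointing toward the interaction partner).
typed_atoms <- function(s, table) {
  a <- s$atoms
  out <- list()
  for (k in seq_len(nrow(table))) {
    hit <- which(a$name == table$atom[k] & a$type == "ATOM" &
                   (table$resname[k] == "*" | a$resname == table$resname[k]) &
                   (table$resname[k] != "*" | a$resname %in% AA3))
    if (table$atom[k] == "N") hit <- hit[a$resname[hit] != "PRO"]
    for (i in hit) {
      root <- which(a$resname == a$resname[i] & a$resno == a$resno[i] &
                      a$chain == a$chain[i] & a$name == table$root[k])
      out[[length(out) + 1L]] <- c(i, if (length(root)) root[1] else NA_integer_)
    }
  }
  if (!length(out))
    return(data.frame(idx = integer(0), ux = numeric(0), uy = numeric(0),
                      uz = numeric(0)))
  m <- do.call(rbind, out)
  m <- m[!duplicated(m[, 1]), , drop = FALSE]
  xyz <- coords(s)
  u <- matrix(NA_real_, nrow(m), 3)
  for (r in seq_len(nrow(m))) {
    if (is.na(m[r, 2])) next
    v <- xyz[m[r, 1], ] - xyz[m[r, 2], ]
    nv <- sqrt(sum(v^2))
    if (nv > 1e-6) u[r, ] <- v / nv
  }
  data.frame(idx = m[, 1], ux = u[, 1], uy = u[, 2], uz = u[, 3])
}

nonpolar_carbon_idx <- function(s) {
  a <- s$atoms
  which(a$type == "ATOM" & mapply(function(rn, nm)
    nm %in% (NONPOLAR_CARBONS[[rn]] %||% character(0)),
    a$resname, a$name))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

eligible_atoms <- function(s, probe, pocket = NULL) {
  switch(probe,
    O   = typed_atoms(s, DONOR_TABLE),      # probe accepts from site donors
    N1  = typed_atoms(s, ACCEPTOR_TABLE),   # probe donates to site acceptors
    DRY = data.frame(idx = nonpolar_carbon_idx(s), ux = NA_real_,
                     uy = NA_real_, uz = NA_real_),
    H   = {
      heavy <- which(s$atoms$element != "H")
      if (!is.null(pocket)) {
        xyz <- coords(s)[heavy, , drop = FALSE]
        keep <- vapply(seq_along(heavy), function(k) {
          min(rowSums(sweep(pocket$coords, 2, xyz[k, ])^2)) <= 4.5^2
        }, logical(1))
        heavy <- heavy[keep]
      }
      data.frame(idx = heavy, ux = NA_real_, uy = NA_real_, uz = NA_real_)
    })
}

#' Compute a probe interaction field on a pocket
#'
#' At every pocket node the probe energy is a sum over protein atoms of a
#' 12-6 Lennard-Jones term, plus for the O probe a directional H-bond well
#' over site donors, for the N1 probe the same over site acceptors, and for
#' the DRY probe a hydrophobic Gaussian kernel over nonpolar carbons. The
#' H-bond well is `e_hb * cos^2(theta) * exp(-(r - hb_dist)^2 / (2 hb_sigma^2))`
#' inside `hb_max`, with theta measured from the donor H (or acceptor
#' lone-pair) axis approximated by the bonded-neighbor direction. Energies
#' are clamped to `params$clamp`.
#'
#' @param s A `biogps_structure`.
#' @param pocket A `biogps_pocket` derived from `s`.
#' @param probe One of `"H"`, `"O"`, `"N1"`, `"DRY"`.
#' @param params A `biogps_probe_params`.
#' @return A `biogps_field`: list with `probe`, `pocket`, `energy`
#'   (kcal/mol per masked node, negative = favorable) and `structure_id`.
#' @export
compute_field <- function(s, pocket, probe, params = probe_params()) {
  probe <- match.arg(probe, PROBE_TYPES)
  stopifnot(inherits(params, "biogps_probe_params"),
            inherits(pocket, "biogps_pocket"))
  pp <- params[[probe]]
  nodes <- pocket$coords
  xyz <- coords(s)
  heavy <- which(s$atoms$element != "H")
  rmin <- vdw_radius(s$atoms$element[heavy]) + pp$r_probe
  e <- numeric(nrow(nodes))
  for (k in seq_along(heavy)) {          # Lennard-Jones over heavy atoms
    r <- sqrt(rowSums(sweep(nodes, 2, xyz[heavy[k], ])^2))
    r <- pmax(r, 0.3)
    sr6 <- (rmin[k] / r)^6
    e <- e + pp$eps * (sr6^2 - 2 * sr6)
  }
  if (probe %in% c("O", "N1")) {
    partners <- eligible_atoms(s, probe)
    for (k in seq_len(nrow(partners))) {
      i <- partners$idx[k]
      d <- sweep(nodes, 2, xyz[i, ])
      r <- sqrt(rowSums(d^2)); r <- pmax(r, 0.3)
      u <- c(partners$ux[k], partners$uy[k], partners$uz[k])
      cth <- if (any(is.na(u))) rep(1, length(r)) else
        pmax(0, (d %*% u)[, 1] / r)
      f <- exp(-(r - pp$hb_dist)^2 / (2 * pp$hb_sigma^2)) * (r <= pp$hb_max)
      e <- e + pp$e_hb * cth^2 * f
    }
  } else if (probe == "DRY") {
    for (i in nonpolar_carbon_idx(s)) {
      r <- sqrt(rowSums(sweep(nodes, 2, xyz[i, ])^2))
      e <- e - pp$w_phobic *
        exp(-(r - pp$dry_dist)^2 / (2 * pp$dry_sigma^2))
    }
  }
  e <- pmin(pmax(e, params$clamp[1]), params$clamp[2])
  structure(list(probe = probe, pocket = pocket, energy = e,
                 structure_id = s$id),
            class = "biogps_field")
}

#' Condense a field into an atom-centred pseudo-field
#'
#' The favorable part of the lattice field is re-expressed as a sum of
#' Gaussian kernels centred on chemically eligible atoms (O probe: site
#' donors; N1: site acceptors; DRY: nonpolar carbons; H: heavy atoms lining
#' the pocket). Each favorable node is attributed to its nearest eligible
#' atom; the atom's weight is the absolute sum of attributed energy, in
#' units of the probe's characteristic energy `e_ref` (`weight_mode =
#' "energy"`), or simply 1 for every atom that attracted favorable energy
#' (`weight_mode = "binary"`, the default used by the pipeline: presence
#' weights make the volume overlap robust to how unevenly the lattice field
#' distributes over the lining atoms). Kernel width is the per-probe
#' `sigma`.
#'
#' @param field A `biogps_field`.
#' @param s The structure the field was computed on.
#' @param params A `biogps_probe_params`.
#' @param weight_mode `"binary"` (default) or `"energy"`, see above.
#' @return A `biogps_pseudo_field`: `probe`, `sigma`, `centers` data frame
#'   (`x`, `y`, `z`, `weight`, `atom`), and the cached self-overlap volume.
#' @export
to_pseudo_field <- function(field, s, params = probe_params(),
                            weight_mode = c("binary", "energy")) {
  weight_mode <- match.arg(weight_mode)
  stopifnot(inherits(field, "biogps_field"))
  sigma <- params[[field$probe]]$sigma
  elig <- eligible_atoms(s, field$probe, field$pocket)
  fav <- which(field$energy < 0)
  if (nrow(elig) == 0L || length(fav) == 0L)
    return(new_pseudo_field(field$probe, sigma,
                            data.frame(x = numeric(0), y = numeric(0),
                                       z = numeric(0), weight = numeric(0),
                                       atom = integer(0))))
  xyz <- coords(s)[elig$idx, , drop = FALSE]
  nodes <- field$pocket$coords[fav, , drop = FALSE]
  nearest <- integer(length(fav))
  best <- rep(Inf, length(fav))
  for (k in seq_len(nrow(xyz))) {        # nearest-eligible-atom assignment
    d2 <- rowSums(sweep(nodes, 2, xyz[k, ])^2)
    hit <- d2 < best
    nearest[hit] <- k; best[hit] <- d2[hit]
  }
  # weights in units of the probe's characteristic interaction energy, so
  # that electrostatic and hydrophobic fields live on a common scale
  w <- vapply(seq_len(nrow(xyz)), function(k)
    abs(sum(field$energy[fav][nearest == k])), numeric(1)) /
    params[[field$probe]]$e_ref
  keep <- w > 0
  if (weight_mode == "binary") w <- as.numeric(w > 0)
  new_pseudo_field(field$probe, sigma,
                   data.frame(x = xyz[keep, 1], y = xyz[keep, 2],
                              z = xyz[keep, 3], weight = w[keep],
                              atom = elig$idx[keep]))
}

new_pseudo_field <- function(probe, sigma, centers) {
  pf <- structure(list(probe = probe, sigma = sigma, centers = centers),
                  class = "biogps_pseudo_field")
  pf$volume <- if (nrow(centers)) gaussian_overlap(pf, pf) else 0
  pf
}

# Analytic overlap integral of two Gaussian kernel sums; `xyzb` optionally
# supplies transformed positions for b's centers.
gaussian_overlap <- function(a, b, xyzb = NULL) {
  ca <- a$centers; cb <- b$centers
  if (nrow(ca) == 0L || nrow(cb) == 0L) return(0)
  if (is.null(xyzb)) xyzb <- as.matrix(cb[, c("x", "y", "z")])
  xyza <- as.matrix(ca[, c("x", "y", "z")])
  s2 <- a$sigma^2 + b$sigma^2
  pref <- (2 * pi * a$sigma^2 * b$sigma^2 / s2)^1.5
  d2 <- outer(rowSums(xyza^2), rowSums(xyzb^2), `+`) -
    2 * xyza %*% t(xyzb)
  sum(pref * outer(ca$weight, cb$weight) * exp(-pmax(d2, 0) / (2 * s2)))
}

#' Overlap volumes of two pseudo-fields under a rigid transform
#'
#' Analytic Gaussian-product integrals: `V_a` and `V_b` are the fields'
#' self-overlap volumes and `V_overlap` the cross integral after applying
#' `transform` to `b`'s centers, capped at `min(V_a, V_b)` so asymmetric
#' weights cannot overshoot the smaller field.
#'
#' @param a,b `biogps_pseudo_field` objects of the same probe.
#' @param transform A `biogps_transform` mapping `b` into `a`'s frame
#'   (default identity).
#' @return Named numeric `c(V_a, V_b, V_overlap)`.
#' @export
field_overlap <- function(a, b, transform = NULL) {
  stopifnot(inherits(a, "biogps_pseudo_field"),
            inherits(b, "biogps_pseudo_field"))
  if (!identical(a$probe, b$probe))
    stop("field_overlap: probe mismatch (", a$probe, " vs ", b$probe, ")")
  xyzb <- as.matrix(b$centers[, c("x", "y", "z")])
  if (!is.null(transform)) xyzb <- apply_transform(transform, xyzb)
  ov <- gaussian_overlap(a, b, xyzb)
  c(V_a = a$volume, V_b = b$volume,
    V_overlap = min(ov, a$volume, b$volume))
}

#' Select representative points from a field
#'
#' Greedy energy/space-coverage reduction: repeatedly accept the most
#' favorable remaining node and discard all nodes within `min_sep` of an
#' accepted point, until `k_max` points are kept or no node beats
#' `energy_cut`. Ties break on the lower node index, so the selection is
#' deterministic.
#'
#' @param field A `biogps_field`.
#' @param k_max Maximum number of points.
#' @param min_sep Minimum separation between accepted points, Angstrom.
#' @param energy_cut Only nodes at or below this energy are eligible
#'   (default -0.5 kcal/mol, the shape cutoff for the H probe).
#' @return Data frame of representative points: `x`, `y`, `z`, `probe`,
#'   `energy`.
#' @export
select_points <- function(field, k_max = 30L, min_sep = 1.5,
                          energy_cut = -0.5) {
  stopifnot(inherits(field, "biogps_field"), k_max >= 1L,
            min_sep >= field$pocket$grid$spacing - 1e-9)
  ord <- order(field$energy, seq_along(field$energy))
  ord <- ord[field$energy[ord] <= energy_cut]
  sel <- integer(0)
  xyz <- field$pocket$coords
  for (i in ord) {
    if (length(sel) >= k_max) break
    if (length(sel) == 0L ||
        min(rowSums(sweep(xyz[sel, , drop = FALSE], 2, xyz[i, ])^2)) >=
          min_sep^2)
      sel <- c(sel, i)
  }
  data.frame(x = xyz[sel, 1], y = xyz[sel, 2], z = xyz[sel, 3],
             probe = rep(field$probe, length(sel)),
             energy = field$energy[sel], stringsAsFactors = FALSE)
}
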
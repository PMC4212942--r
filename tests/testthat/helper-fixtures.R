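# Shared test fixtures and small independent oracles.

# memoised store for objects that are expensive to build
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# A minimal serine-hydrolase-like structure carrying the catalytic anchors
# (His general base, two oxyanion backbone amides, catalytic Ser) plus a few
# bystander residues. Geometry is fixed and chiral.
make_toy_enzyme <- function(id = "enzyme") {
  atoms <- rbind(
    data.frame(name = "N",   resname = "THR", resno = 40,
               x = 4.0, y = 0.0, z = 0.0, element = "N"),
    data.frame(name = "CA",  resname = "THR", resno = 40,
               x = 5.0, y = 1.0, z = 0.2, element = "C"),
    data.frame(name = "OG",  resname = "SER", resno = 105,
               x = 2.0, y = 2.0, z = 3.0, element = "O"),
    data.frame(name = "CB",  resname = "SER", resno = 105,
               x = 2.0, y = 2.0, z = 4.4, element = "C"),
    data.frame(name = "N",   resname = "GLN", resno = 106,
               x = 0.0, y = 5.0, z = 0.5, element = "N"),
    data.frame(name = "CA",  resname = "GLN", resno = 106,
               x = 1.0, y = 6.0, z = 0.7, element = "C"),
    data.frame(name = "NE2", resname = "HIS", resno = 224,
               x = 0.0, y = 0.0, z = 0.0, element = "N"),
    data.frame(name = "CD2", resname = "HIS", resno = 224,
               x = -1.2, y = -0.4, z = 0.0, element = "C"),
    data.frame(name = "CA",  resname = "GLY", resno = 300,
               x = -3.0, y = 4.0, z = -2.0, element = "C")
  )
  atoms$serial <- seq_len(nrow(atoms))
  atoms$chain <- "A"; atoms$insert <- ""; atoms$type <- "ATOM"
  biogps:::new_structure(id, atoms[, c("serial", "name", "resname", "chain",
                                       "resno", "insert", "x", "y", "z",
                                       "element", "type")])
}

toy_anchors <- function(s) {
  extract_anchors(s, "HIS 224", c("THR 40", "GLN 106"), serine = "SER 105")
}

# seeded random proper rotation (quaternion method)
random_rotation <- function(seed) {
  set.seed(seed)
  q <- rnorm(4)
  biogps:::quat_to_rot(q)
}

random_transform <- function(seed, trans_scale = 5) {
  set.seed(seed)
  q <- rnorm(4)
  biogps:::new_transform(biogps:::quat_to_rot(q),
                         rnorm(3, sd = trans_scale))
}

# apply a rigid motion to a characterized site at the descriptor level:
# representative points and pseudo-field centers move; the fingerprint is
# rebuilt from the moved points.
transform_site <- function(site, tr) {
  pts <- lapply(site$points, function(p) {
    if (nrow(p)) {
      xyz <- apply_transform(tr, as.matrix(p[, c("x", "y", "z")]))
      p$x <- xyz[, 1]; p$y <- xyz[, 2]; p$z <- xyz[, 3]
    }
    p
  })
  site$points <- pts
  site$fingerprint <- suppressWarnings(
    build_fingerprint(pts, site$id, site$fingerprint$params))
  for (pr in names(site$pseudo_fields)) {
    pf <- site$pseudo_fields[[pr]]
    if (nrow(pf$centers)) {
      xyz <- apply_transform(tr, as.matrix(pf$centers[, c("x", "y", "z")]))
      pf$centers$x <- xyz[, 1]; pf$centers$y <- xyz[, 2]
      pf$centers$z <- xyz[, 3]
      pf <- biogps:::new_pseudo_field(pf$probe, pf$sigma, pf$centers)
    }
    site$pseudo_fields[[pr]] <- pf
  }
  site
}

# brute-force RMSD oracle: best proper rotation over an Euler-angle grid
# (after centroid alignment); upper bound on the optimal RMSD.
grid_rmsd_oracle <- function(moving, fixed, step_deg = 10) {
  A <- sweep(moving, 2, colMeans(moving))
  B <- sweep(fixed, 2, colMeans(fixed))
  ang <- seq(0, 2 * pi - 1e-9, by = step_deg * pi / 180)
  bng <- seq(0, pi, by = step_deg * pi / 180)
  best <- Inf
  for (a in ang) for (b in bng) for (g in ang) {
    ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b)
    cg <- cos(g); sg <- sin(g)
    R <- matrix(c(ca * cb * cg - sa * sg, -ca * cb * sg - sa * cg, ca * sb,
                  sa * cb * cg + ca * sg, -sa * cb * sg + ca * cg, sa * sb,
                  -sb * cg, sb * sg, cb), 3, 3, byrow = TRUE)
    r <- sqrt(mean(rowSums((A %*% t(R) - B)^2)))
    if (r < best) best <- r
  }
  best
}

# small site cache for comparison tests
fixture_site <- function(seed, class = "donor", n_lining = 24, radius = 8) {
  key <- sprintf("site_%d_%s_%d_%g", seed, class, n_lining, radius)
  cached(key, {
    fr <- fixture_classes()[[class]]
    s <- make_toy_pocket(pocket_recipe(seed, n_lining = n_lining,
                                       fractions = fr, radius = radius),
                         id = sprintf("%s_s%d", class, seed))
    characterize_site(s)
  })
}
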
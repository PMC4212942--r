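# Active-site detection on a 3D lattice: a LIGSITE-style buriedness scan
# stands in for the unpublished cavity detector — a node belongs to the
# pocket when it is solvent-accessible yet enclosed by protein in most of
# the 26 lattice directions.

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20,
               F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)

vdw_radius <- function(element) {
  r <- VDW_RADII[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

#' Define a cubic lattice around a structure
#'
#' @param s A `biogps_structure` (or an n x 3 coordinate matrix).
#' @param spacing Node spacing, Angstrom (default 1.0).
#' @param margin Padding beyond the bounding box, Angstrom.
#' @return A `biogps_grid`: list with `origin`, `spacing`, `dim`.
#' @export
grid_spec <- function(s, spacing = 1.0, margin = 4.0) {
  stopifnot(spacing > 0, margin >= 0)
  xyz <- if (inherits(s, "biogps_structure")) coords(s) else as.matrix(s)
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  dim <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  structure(list(origin = lo, spacing = spacing, dim = dim),
            class = "biogps_grid")
}

grid_axes <- function(g) {
  lapply(1:3, function(k) g$origin[k] + (seq_len(g$dim[k]) - 1) * g$spacing)
}

# Coordinates of nodes given linear indices (x fastest, R array order).
node_coords <- function(g, idx) {
  ai <- arrayInd(idx, g$dim)
  sweep((ai - 1) * g$spacing, 2, g$origin, `+`)
}

# For every node: distance to the nearest atom surface (d - r_vdw), as a
# vector over the full lattice.
surface_distance <- function(g, xyz, radii) {
  ax <- grid_axes(g)
  nx <- g$dim[1]; ny <- g$dim[2]; nz <- g$dim[3]
  gx <- rep(ax[[1]], times = ny * nz)
  gy <- rep(rep(ax[[2]], each = nx), times = nz)
  gz <- rep(ax[[3]], each = nx * ny)
  dmin <- rep(Inf, nx * ny * nz)
  for (a in seq_len(nrow(xyz))) {
    d <- sqrt((gx - xyz[a, 1])^2 + (gy - xyz[a, 2])^2 + (gz - xyz[a, 3])^2)
    dmin <- pmin(dmin, d - radii[a])
  }
  dmin
}

# 26 lattice scan directions (all sign/axis combinations except 0,0,0).
scan_directions <- function() {
  d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d[rowSums(abs(d)) > 0, , drop = FALSE]
}

# Count, for every node, how many of the 26 directions hit protein within
# scan_range. `occ` is the logical occupancy array.
buriedness_counts <- function(occ, g, scan_range) {
  dims <- g$dim
  ms <- as.integer(ceiling(scan_range / g$spacing))
  pad <- array(FALSE, dims + 2L * ms)
  pad[ms + seq_len(dims[1]), ms + seq_len(dims[2]), ms + seq_len(dims[3])] <- occ
  dirs <- scan_directions()
  counts <- array(0L, dims)
  ix <- ms + seq_len(dims[1]); iy <- ms + seq_len(dims[2])
  iz <- ms + seq_len(dims[3])
  for (d in seq_len(nrow(dirs))) {
    v <- dirs[d, ]
    nstep <- floor(scan_range / (g$spacing * sqrt(sum(v^2))))
    hit <- array(FALSE, dims)
    for (m in seq_len(nstep))
      hit <- hit | pad[ix + m * v[1], iy + m * v[2], iz + m * v[3]]
    counts <- counts + hit
  }
  counts
}

# Largest 26-connected component among the masked linear indices; ties are
# broken by centroid distance to `ref_point`.
largest_component <- function(idx, g, ref_point) {
  if (length(idx) <= 1L) return(idx)
  dims <- g$dim
  inmask <- logical(prod(dims)); inmask[idx] <- TRUE
  dirs <- scan_directions()
  dirs <- dirs[order(dirs[, 3], dirs[, 2], dirs[, 1]), , drop = FALSE]
  half <- dirs[seq_len(13L), , drop = FALSE]    # one per +/- pair
  ai <- arrayInd(idx, dims)
  edges <- list()
  for (d in seq_len(nrow(half))) {
    nb <- sweep(ai, 2, half[d, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
    nbl <- nb[ok, 1] + (nb[ok, 2] - 1L) * dims[1] +
           (nb[ok, 3] - 1L) * dims[1] * dims[2]
    keep <- inmask[nbl]
    if (any(keep))
      edges[[length(edges) + 1L]] <- cbind(idx[ok][keep], nbl[keep])
  }
  verts <- as.character(idx)
  if (length(edges)) {
    e <- do.call(rbind, edges)
    gph <- igraph::graph_from_data_frame(
      data.frame(from = as.character(e[, 1]), to = as.character(e[, 2])),
      directed = FALSE, vertices = verts)
  } else {
    gph <- igraph::make_empty_graph(n = length(verts)) +
      igraph::vertices(verts)
  }
  comp <- igraph::components(gph)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    cds <- vapply(best, function(b) {
      members <- as.integer(names(comp$membership)[comp$membership == b])
      ctr <- colMeans(node_coords(g, members))
      sum((ctr - ref_point)^2)
    }, numeric(1))
    best <- best[which.min(cds)]
  } else best <- best[1]
  as.integer(names(comp$membership)[comp$membership == best])
}

new_pocket <- function(g, idx) {
  xyz <- node_coords(g, idx)
  structure(list(grid = g, idx = sort(idx),
                 coords = xyz[order(idx), , drop = FALSE],
                 centroid = colMeans(xyz)),
            class = "biogps_pocket")
}

#' @export
print.biogps_pocket <- function(x, ...) {
  cat(sprintf("<biogps_pocket> %d nodes (spacing %.2f A), centroid (%.1f, %.1f, %.1f)\n",
              length(x$idx), x$grid$spacing, x$centroid[1], x$centroid[2],
              x$centroid[3]))
  invisible(x)
}

#' Detect the buried active-site cavity of a structure
#'
#' Buriedness scan on a lattice: each solvent-accessible node (farther than
#' `probe_radius` from every van der Waals surface) sends rays along the 26
#' lattice directions; a node counts as pocket when at least `b_min` rays
#' hit protein within `scan_range`. The pocket seed is the largest
#' 26-connected component of such nodes; it is then grown by hysteresis
#' through adjacent accessible nodes with buriedness at least `b_min - 2`,
#' which keeps the mask boundary stable when the structure is re-gridded in
#' a rotated frame. The result is trimmed to `max_pocket_radius` of its
#' centroid. The default `b_min` of 14 keeps the contiguous cavity
#' interior; stricter thresholds retain only crevices between lining atoms
#' and fragment the mask.
#'
#' @param s A `biogps_structure` with at least 30 atoms (use
#'   [pocket_from_serine()] for smaller inputs).
#' @param spacing,margin Lattice geometry, Angstrom.
#' @param scan_range Ray length, Angstrom.
#' @param b_min Minimum number of blocked directions (of 26) for seed
#'   nodes; hysteresis growth accepts `b_min - 2`.
#' @param probe_radius Solvent probe radius, Angstrom.
#' @param max_pocket_radius Trim radius around the pocket centroid.
#' @return A `biogps_pocket`.
#' @export
detect_pocket <- function(s, spacing = 1.0, margin = 4.0, scan_range = 8.0,
                          b_min = 14L, probe_radius = 1.4,
                          max_pocket_radius = 15.0) {
  stopifnot(inherits(s, "biogps_structure"))
  if (nrow(s$atoms) < 30L)
    stop("detect_pocket: fewer than 30 atoms; use pocket_from_serine()")
  g <- grid_spec(s, spacing, margin)
  xyz <- coords(s)
  radii <- vdw_radius(s$atoms$element)
  sd <- surface_distance(g, xyz, radii)
  occ <- array(sd < 0, g$dim)              # inside some vdW sphere
  accessible <- sd >= probe_radius
  counts <- buriedness_counts(occ, g, scan_range)
  cand <- which(accessible & as.vector(counts) >= b_min)
  if (length(cand) == 0L) stop("no pocket found")
  comp <- largest_component(cand, g, colMeans(xyz))
  lo <- accessible & as.vector(counts) >= b_min - 2L
  comp <- grow_mask(comp, lo, g)
  ctr <- colMeans(node_coords(g, comp))
  keep <- comp[rowSums(sweep(node_coords(g, comp), 2, ctr)^2) <=
                 max_pocket_radius^2]
  if (length(keep) == 0L) stop("no pocket found")
  new_pocket(g, keep)
}

# Region growing: extend `seed` (linear indices) through 26-adjacent nodes
# flagged TRUE in the logical vector `lo` (hysteresis thresholding).
grow_mask <- function(seed, lo, g) {
  mask <- logical(prod(g$dim)); mask[seed] <- TRUE
  dirs <- scan_directions()
  frontier <- seed
  while (length(frontier)) {
    ai <- arrayInd(frontier, g$dim)
    new <- integer(0)
    for (d in seq_len(nrow(dirs))) {
      nb <- sweep(ai, 2, dirs[d, ], `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= g$dim[1] &
            nb[, 2] >= 1 & nb[, 2] <= g$dim[2] &
            nb[, 3] >= 1 & nb[, 3] <= g$dim[3]
      nbl <- nb[ok, 1] + (nb[ok, 2] - 1L) * g$dim[1] +
             (nb[ok, 3] - 1L) * g$dim[1] * g$dim[2]
      add <- nbl[lo[nbl] & !mask[nbl]]
      if (length(add)) { mask[add] <- TRUE; new <- c(new, add) }
    }
    frontier <- unique(new)
  }
  which(mask)
}

#' Pocket as an accessible ball around the catalytic serine
#'
#' Deterministic manual override: the pocket is every solvent-accessible
#' node within `radius` of the serine Oγ (or any other anchor atom). Useful
#' when cavity detection must not influence a mutant-projection study.
#'
#' @param s A `biogps_structure`.
#' @param serine Selector string (e.g. `"SER 105 OG"`), a parsed selector,
#'   or an atom row index.
#' @param radius Ball radius, Angstrom (default 10).
#' @param spacing,margin,probe_radius As in [detect_pocket()].
#' @return A `biogps_pocket`.
#' @export
pocket_from_serine <- function(s, serine, radius = 10.0, spacing = 1.0,
                               margin = 4.0, probe_radius = 1.4) {
  stopifnot(inherits(s, "biogps_structure"), radius > 0)
  i <- if (is.numeric(serine)) {
    if (serine < 1 || serine > nrow(s$atoms))
      stop("pocket_from_serine: atom index out of range")
    as.integer(serine)
  } else find_atom(s, serine, "OG")
  og <- as.numeric(coords(s)[i, ])
  g <- grid_spec(s, spacing, margin)
  xyz <- coords(s)
  radii <- vdw_radius(s$atoms$element)
  sd <- surface_distance(g, xyz, radii)
  nx <- g$dim[1]; ny <- g$dim[2]; nz <- g$dim[3]
  ax <- grid_axes(g)
  gx <- rep(ax[[1]], times = ny * nz)
  gy <- rep(rep(ax[[2]], each = nx), times = nz)
  gz <- rep(ax[[3]], each = nx * ny)
  inball <- (gx - og[1])^2 + (gy - og[2])^2 + (gz - og[3])^2 <= radius^2
  idx <- which(inball & sd >= probe_radius)
  if (length(idx) == 0L) stop("no pocket found")
  new_pocket(g, idx)
}

#' Write lattice values as an OpenDX scalar grid
#'
#' @param g A `biogps_grid`.
#' @param values Numeric vector over all lattice nodes (x fastest), or a
#'   `biogps_pocket` (written as a 0/1 mask).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dx <- function(g, values, path) {
  if (inherits(g, "biogps_pocket")) {
    p <- g; g <- p$grid
    values <- numeric(prod(g$dim)); values[p$idx] <- 1
  }
  stopifnot(length(values) == prod(g$dim))
  v <- aperm(array(values, g$dim), c(3, 2, 1))  # DX wants z fastest
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d",
            g$dim[1], g$dim[2], g$dim[3]),
    sprintf("origin %.4f %.4f %.4f", g$origin[1], g$origin[2], g$origin[3]),
    sprintf("delta %.4f 0 0", g$spacing),
    sprintf("delta 0 %.4f 0", g$spacing),
    sprintf("delta 0 0 %.4f", g$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            g$dim[1], g$dim[2], g$dim[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            length(values))), con)
  vals <- as.vector(v)  # z fastest after aperm
  pad <- ceiling(length(vals) / 3) * 3 - length(vals)
  m <- matrix(c(vals, rep(NA, pad)), ncol = 3, byrow = TRUE)
  lines <- apply(m, 1, function(r)
    paste(sprintf("%.6g", r[!is.na(r)]), collapse = " "))
  writeLines(lines, con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}
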
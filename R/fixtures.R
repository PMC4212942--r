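# Synthetic pocket fixtures: deterministic cup-shaped "active sites" with a
# controlled mix of H-bond donor, H-bond acceptor and hydrophobic lining
# groups. They exercise every pipeline stage offline, standing in for
# downloaded crystal structures.

# Run expr with a private RNG stream; the caller's .Random.seed is restored.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Evenly spread unit directions on the spherical cap z <= z_cut
# (cup interior opens toward +z), via a Fibonacci lattice.
cap_directions <- function(n, z_cut) {
  i <- seq_len(n) - 0.5
  z <- -1 + (z_cut + 1) * i / n       # from south pole up to the rim
  phi <- i * pi * (3 - sqrt(5))       # golden angle
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Recipe for a synthetic pocket
#'
#' @param seed Integer seed; the only source of randomness.
#' @param n_lining Number of chemically typed lining groups (>= 8).
#' @param fractions Named numeric `c(donor=, acceptor=, hydrophobic=)`
#'   summing to 1; group counts are the rounded fractions of `n_lining`.
#' @param radius Cup radius in Angstrom (lining sphere).
#' @param jitter Std. dev. of the per-group positional jitter, Angstrom.
#' @return A `biogps_recipe` list.
#' @export
pocket_recipe <- function(seed, n_lining = 24,
                          fractions = c(donor = 1/3, acceptor = 1/3,
                                        hydrophobic = 1/3),
                          radius = 8, jitter = 0.35) {
  stopifnot(n_lining >= 8, radius > 0, jitter >= 0,
            all(c("donor", "acceptor", "hydrophobic") %in% names(fractions)))
  fractions <- fractions[c("donor", "acceptor", "hydrophobic")]
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be non-negative and sum to 1")
  structure(list(seed = as.integer(seed), n_lining = as.integer(n_lining),
                 fractions = fractions, radius = radius, jitter = jitter),
            class = "biogps_recipe")
}

# integer counts per type, summing to n, largest-remainder rounding
type_counts <- function(fractions, n) {
  raw <- fractions * n
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    up <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[up] <- cnt[up] + 1
  }
  as.integer(cnt)
}

# Build atoms for one lining group. p: jittered anchor point on the lining
# sphere; u: inward unit normal. Returns a small data frame of atoms.
group_atoms <- function(type, p, u, resno) {
  back <- function(d) p - u * d   # outward along the normal
  mk <- function(name, resname, pos, element)
    data.frame(name = name, resname = resname, resno = resno,
               x = pos[1], y = pos[2], z = pos[3], element = element,
               stringsAsFactors = FALSE)
  switch(type,
    donor = rbind(                       # backbone-like amide N-H, H inward
      mk("N",  "GLY", p,          "N"),
      mk("CA", "GLY", back(1.45), "C")),
    acceptor = rbind(                    # carbonyl C=O, lone pairs inward
      mk("O",  "GLY", p,          "O"),
      mk("C",  "GLY", back(1.23), "C")),
    hydrophobic = rbind(                 # methyl-like CB
      mk("CB", "ALA", p,          "C"),
      mk("CA", "ALA", back(1.53), "C")),
    stop("unknown group type: ", type))
}

build_from_layout <- function(layout, recipe, id) {
  rows <- vector("list", nrow(layout) + 1L)
  for (g in seq_len(nrow(layout))) {
    p <- c(layout$px[g], layout$py[g], layout$pz[g])
    u <- c(layout$ux[g], layout$uy[g], layout$uz[g])
    rows[[g]] <- group_atoms(layout$type[g], p, u, g)
  }
  # dense shape-only wall behind the lining keeps the cup watertight for
  # the buriedness scan (GLY CA carbons: no donor/acceptor/DRY typing)
  r_wall <- recipe$radius + 2.5
  area <- 2 * pi * r_wall^2 * (1 + 0.65)
  wall_d <- cap_directions(ceiling(area / 5.5), 0.65)
  ng <- nrow(layout)
  rows[[ng + 1L]] <- data.frame(
    name = "CA", resname = "GLY", resno = ng + seq_len(nrow(wall_d)),
    x = wall_d[, 1] * r_wall, y = wall_d[, 2] * r_wall,
    z = wall_d[, 3] * r_wall, element = "C", stringsAsFactors = FALSE)
  a <- do.call(rbind, rows)
  atoms <- data.frame(serial = seq_len(nrow(a)), name = a$name,
                      resname = a$resname, chain = "A", resno = a$resno,
                      insert = "", x = round(a$x, 3), y = round(a$y, 3),
                      z = round(a$z, 3), element = a$element, type = "ATOM",
                      stringsAsFactors = FALSE)
  s <- new_structure(id, atoms)
  attr(s, "layout") <- layout
  attr(s, "recipe") <- recipe
  # designed focal point: deep interior of the cup, where buriedness and
  # solvent accessibility are both comfortable
  attr(s, "focal_point") <- c(0, 0, -recipe$radius / 2)
  s
}

#' Generate a synthetic cup-shaped pocket structure
#'
#' Builds a spherical-cap "cup" of rigid two-atom groups pointing inward:
#' amide-like N-H donors, carbonyl-like C=O acceptors and methyl-like
#' carbons, in the recipe's proportions, backed by a dense carbon wall that
#' closes the cavity for pocket detection. Atom and residue names are legal
#' PDB names (GLY/ALA fragments), so the standard readers and the
#' donor/acceptor typing tables apply unchanged. Identical recipes give
#' bit-identical structures.
#'
#' @param recipe A `biogps_recipe` from [pocket_recipe()].
#' @param id Structure id; default derived from the seed.
#' @return A `biogps_structure` (PDB-writable); the group layout is kept as
#'   an attribute so the pocket can be morphed later.
#' @export
make_toy_pocket <- function(recipe, id = NULL) {
  stopifnot(inherits(recipe, "biogps_recipe"))
  if (is.null(id)) id <- sprintf("pocket_s%03d", recipe$seed)
  with_seed(recipe$seed, {
    n <- recipe$n_lining
    d <- cap_directions(n, 0.5)          # lining stops below the wall rim
    cnt <- type_counts(recipe$fractions, n)
    types <- sample(rep(c("donor", "acceptor", "hydrophobic"), cnt))
    jit <- matrix(stats::rnorm(3 * n, sd = recipe$jitter), n, 3)
    p <- d * recipe$radius + jit
    u <- -d / sqrt(rowSums(d^2))         # inward normal
    layout <- data.frame(group = seq_len(n), type = types,
                         px = p[, 1], py = p[, 2], pz = p[, 3],
                         ux = u[, 1], uy = u[, 2], uz = u[, 3],
                         stringsAsFactors = FALSE)
    build_from_layout(layout, recipe, id)
  })
}

#' Morph a synthetic pocket toward a different lining chemistry
#'
#' Emulates stepwise mutagenesis with a controllable ground truth: a seeded
#' subset of lining groups is re-typed toward the target fractions, a few
#' more groups per step, keeping every group's position and orientation.
#' Step 0 is the input; the final step matches the target fractions to
#' within one group.
#'
#' @param s A structure produced by [make_toy_pocket()].
#' @param target Named fractions as in [pocket_recipe()].
#' @param steps Number of morph steps.
#' @param seed Seed selecting which groups convert.
#' @return List of `steps + 1` structures (step 0 = input).
#' @export
morph_pocket <- function(s, target, steps, seed) {
  layout <- attr(s, "layout"); recipe <- attr(s, "recipe")
  if (is.null(layout)) stop("morph_pocket: structure has no stored layout")
  stopifnot(steps >= 0)
  target <- target[c("donor", "acceptor", "hydrophobic")]
  n <- nrow(layout)
  want <- type_counts(target, n)
  names(want) <- c("donor", "acceptor", "hydrophobic")
  have <- table(factor(layout$type, names(want)))
  with_seed(seed, {
    excess <- lapply(names(want), function(ty) {
      k <- have[[ty]] - want[[ty]]
      if (k <= 0) return(integer(0))
      sample(which(layout$type == ty), k)
    })
    donors_from <- unlist(excess)             # groups that must change
    donors_from <- sample(donors_from)        # conversion order
    need <- pmax(want - as.integer(have), 0)
    new_types <- sample(rep(names(want), need))
    out <- vector("list", steps + 1L)
    out[[1]] <- s
    for (k in seq_len(steps)) {
      upto <- round(k / steps * length(donors_from))
      lay_k <- layout
      if (upto > 0) {
        idx <- donors_from[seq_len(upto)]
        lay_k$type[idx] <- new_types[seq_len(upto)]
      }
      out[[k + 1L]] <- build_from_layout(lay_k, recipe,
                                         sprintf("%s_m%02d", s$id, k))
    }
    out
  })
}

#' Mirror copy of a fixture structure
#'
#' Delegates to [reflect_structure()] and tags the id, emulating the
#' enantiomeric structures needed when active sites of opposite handedness
#' are superposed.
#'
#' @param s A `biogps_structure`.
#' @return The mirrored structure, id suffixed with `_mirror`.
#' @export
make_mirror <- function(s) {
  m <- reflect_structure(s)
  m$id <- paste0(s$id, "_mirror")
  lay <- attr(s, "layout")
  if (!is.null(lay)) {
    lay$px <- -lay$px; lay$ux <- -lay$ux
    attr(m, "layout") <- lay
    attr(m, "recipe") <- attr(s, "recipe")
  }
  m
}

#' Write a set of class-labelled fixture pockets
#'
#' Convenience generator for validation studies: `per_class` pockets for
#' each named recipe class, written as PDB files plus a manifest TSV.
#'
#' @param classes Named list of fraction vectors, e.g.
#'   `list(donor = c(donor=.7, acceptor=.15, hydrophobic=.15), ...)`.
#' @param per_class Pockets per class.
#' @param seed Base seed; pocket `i` of class `j` uses `seed + 100*j + i`.
#' @param out_dir Output directory (created if needed); `NULL` to skip
#'   writing and return structures only.
#' @param ... Passed to [pocket_recipe()] (n_lining, radius, jitter).
#' @return Invisibly, list of structures with a `manifest` attribute
#'   (data frame: id, class, seed, file).
#' @export
make_fixture_set <- function(classes, per_class = 8, seed = 7,
                             out_dir = NULL, ...) {
  out <- list(); man <- list()
  for (j in seq_along(classes)) {
    cls <- names(classes)[j]
    for (i in seq_len(per_class)) {
      sd <- seed + 100L * j + i
      id <- sprintf("%s_%02d", cls, i)
      s <- make_toy_pocket(pocket_recipe(sd, fractions = classes[[j]], ...),
                           id = id)
      file <- NA_character_
      if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        file <- file.path(out_dir, paste0(id, ".pdb"))
        write_pdb(s, file)
      }
      out[[id]] <- s
      man[[id]] <- data.frame(id = id, class = cls, seed = sd, file = file,
                              stringsAsFactors = FALSE)
    }
  }
  man <- do.call(rbind, man); rownames(man) <- NULL
  if (!is.null(out_dir))
    utils::write.table(man, file.path(out_dir, "manifest.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  attr(out, "manifest") <- man
  invisible(out)
}

#' Default fixture class recipes
#'
#' Three lining chemistries used throughout the validation studies:
#' donor-rich, acceptor-rich and hydrophobic pockets (0.70 of the lining in
#' the defining chemistry, 0.15 in each of the other two).
#' @return Named list of fraction vectors.
#' @export
fixture_classes <- function() {
  list(
    donor       = c(donor = 0.70, acceptor = 0.15, hydrophobic = 0.15),
    acceptor    = c(donor = 0.15, acceptor = 0.70, hydrophobic = 0.15),
    hydrophobic = c(donor = 0.15, acceptor = 0.15, hydrophobic = 0.70)
  )
}
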
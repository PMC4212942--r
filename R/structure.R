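#' @keywords internal
"_PACKAGE"

# Twenty standard amino-acid residue names; HETATM records never count as
# protein even when they carry one of these names.
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

#' Read a protein structure from PDB text or file
#'
#' Parses ATOM/HETATM records into a `biogps_structure`. Only the first
#' MODEL is kept and, where alternate locations exist, only the blank or
#' `A` altloc — mirroring the usual manual clean-up done before active-site
#' analysis. Record order, coordinates, names and residue identity are
#' preserved exactly.
#'
#' @param x Path to a PDB file, or a character scalar containing PDB text
#'   (recognized by embedded newlines).
#' @param id Structure identifier; defaults to the file base name.
#' @return A `biogps_structure`: list with `id` and an `atoms` data frame
#'   (`serial`, `name`, `resname`, `chain`, `resno`, `insert`, `x`, `y`,
#'   `z`, `element`, `type`).
#' @export
#' @examples
#' s <- read_pdb(paste(
#'   "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
#'   "ATOM      2  CA  GLY A   1       1.500   0.000   0.000  1.00  0.00           C",
#'   sep = "\n"))
#' nrow(s$atoms)
read_pdb <- function(x, id = NULL) {
  stopifnot(is.character(x), length(x) == 1L)
  path <- x
  if (grepl("\n", x, fixed = TRUE) || !file.exists(x)) {
    if (!grepl("\n", x, fixed = TRUE))
      stop("read_pdb: file not found: ", x)
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(strsplit(x, "\n", fixed = TRUE)[[1]], path)
    if (is.null(id)) id <- "structure"
  }
  if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(path))

  raw <- readLines(path, warn = FALSE)
  rec <- raw[startsWith(raw, "ATOM") | startsWith(raw, "HETATM")]
  if (length(rec) == 0L) {
    bad <- if (length(raw)) raw[1] else "<empty input>"
    stop("read_pdb: no ATOM/HETATM records; first line was: ", bad)
  }

  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = TRUE,
                                     verbose = FALSE)),
    error = function(e) stop("read_pdb: unparseable PDB input (",
                             conditionMessage(e), ")")
  )
  at <- pdb$atom
  elesy <- at$elesy
  # element symbol: fall back to the first letter of the atom name
  miss <- is.na(elesy) | !nzchar(trimws(elesy))
  elesy[miss] <- substr(gsub("[^A-Za-z].*$", "", trimws(at$elety[miss])), 1, 1)
  elesy <- toupper(trimws(elesy))
  if (any(!nzchar(elesy))) stop("read_pdb: atom with empty element symbol")

  atoms <- data.frame(
    serial  = as.integer(at$eleno),
    name    = trimws(at$elety),
    resname = trimws(at$resid),
    chain   = ifelse(is.na(at$chain), " ", at$chain),
    resno   = as.integer(at$resno),
    insert  = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    element = elesy,
    type    = at$type,
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("read_pdb: non-finite coordinates")
  new_structure(id, atoms)
}

new_structure <- function(id, atoms) {
  rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms), class = "biogps_structure")
}

#' @export
print.biogps_structure <- function(x, ...) {
  cat(sprintf("<biogps_structure> %s: %d atoms, %d residues\n", x$id,
              nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resno)))))
  invisible(x)
}

#' Coordinate matrix of a structure
#' @param s A `biogps_structure`.
#' @return Numeric n x 3 matrix of positions in Angstrom.
#' @export
coords <- function(s) {
  as.matrix(s$atoms[, c("x", "y", "z")])
}

#' Keep only standard protein atoms
#'
#' Removes waters, ions, ligands, glycosylation residues and every other
#' non-protein molecule: only ATOM records whose residue name is one of the
#' twenty standard amino acids survive, in their original order.
#'
#' @param s A `biogps_structure`.
#' @return The filtered structure.
#' @export
strip_non_protein <- function(s) {
  keep <- s$atoms$type == "ATOM" & s$atoms$resname %in% AA3
  if (!any(keep)) stop("strip_non_protein: no protein content in '", s$id, "'")
  new_structure(s$id, s$atoms[keep, , drop = FALSE])
}

#' Build the mirror image of a structure
#'
#' Negates the x coordinate of every atom, producing the enantiomeric
#' structure. Applying it twice returns the input bit-exactly.
#'
#' @param s A `biogps_structure`.
#' @return The reflected structure.
#' @export
reflect_structure <- function(s) {
  a <- s$atoms
  a$x <- -a$x
  new_structure(s$id, a)
}

# Parse "HIS 224 NE2" / "THR 40" (optionally "A/HIS 224 N") into a selector.
parse_selector <- function(txt) {
  chain <- NA_character_
  if (grepl("/", txt, fixed = TRUE)) {
    parts <- strsplit(txt, "/", fixed = TRUE)[[1]]
    chain <- trimws(parts[1])
    txt <- parts[2]
  }
  tok <- strsplit(trimws(txt), "[[:space:]]+")[[1]]
  if (length(tok) < 2L) stop("cannot parse residue selector: '", txt, "'")
  list(resname = toupper(tok[1]), resno = as.integer(tok[2]),
       atom = if (length(tok) >= 3L) toupper(tok[3]) else NA_character_,
       chain = chain)
}

find_atom <- function(s, sel, default_atom) {
  if (is.character(sel)) sel <- parse_selector(sel)
  atom <- if (is.na(sel$atom)) default_atom else sel$atom
  a <- s$atoms
  hit <- a$resname == sel$resname & a$resno == sel$resno & a$name == atom
  if (!is.na(sel$chain)) hit <- hit & a$chain == sel$chain
  i <- which(hit)
  if (length(i) == 0L)
    stop("selector '", sel$resname, " ", sel$resno, " ", atom,
         "' matches no atom in '", s$id, "'")
  i[1]
}

#' Locate the catalytic anchor atoms of a serine hydrolase
#'
#' Resolves the three functionalities used for catalytic-machinery
#' superposition: the general-base nitrogen (e.g. His Nε2), and the two
#' backbone amide nitrogens forming the oxyanion hole. The catalytic serine
#' Oγ may be supplied as a fourth, optional anchor; it enables the
#' signed-volume chirality test used for automatic mirror detection.
#'
#' Selectors are strings `"RESNAME RESNO [ATOM]"`; the atom defaults to
#' `NE2` for His base residues and to the backbone `N` for the oxyanion
#' residues, and may be overridden explicitly (e.g. `"TYR 473 OH"` for the
#' Tyr-oxyanion proteases).
#'
#' @param s A `biogps_structure`.
#' @param base Selector for the general-base residue.
#' @param oxyanion Character vector of exactly two selectors for the
#'   oxyanion-hole residues.
#' @param serine Optional selector for the catalytic serine (atom defaults
#'   to `OG`).
#' @return A `biogps_anchors` object: atom indices, positions and the
#'   signed volume of the anchor tetrahedron (NA without a serine).
#' @export
extract_anchors <- function(s, base, oxyanion, serine = NULL) {
  stopifnot(length(oxyanion) == 2L)
  bsel <- if (is.character(base)) parse_selector(base) else base
  bdef <- if (identical(bsel$resname, "HIS")) "NE2" else "N"
  idx <- c(
    find_atom(s, bsel, bdef),
    find_atom(s, oxyanion[[1]], "N"),
    find_atom(s, oxyanion[[2]], "N")
  )
  if (!is.null(serine)) {
    ssel <- if (is.character(serine)) parse_selector(serine) else serine
    idx <- c(idx, find_atom(s, ssel, "OG"))
  }
  if (anyDuplicated(idx)) stop("extract_anchors: anchor atoms not distinct")
  pos <- coords(s)[idx, , drop = FALSE]
  if (max(stats::dist(pos)) >= 20)
    stop("extract_anchors: anchors more than 20 A apart; wrong residues?")
  structure(list(idx = idx, pos = pos,
                 has_serine = length(idx) == 4L,
                 signed_volume = if (length(idx) == 4L)
                   signed_volume(pos) else NA_real_),
            class = "biogps_anchors")
}

# Signed volume of the tetrahedron spanned by 4 points (rows); sign encodes
# handedness and flips under reflection.
signed_volume <- function(p) {
  stopifnot(nrow(p) == 4L)
  det(rbind(p[2, ] - p[1, ], p[3, ] - p[1, ], p[4, ] - p[1, ])) / 6
}

#' Optimal rigid superposition of two point sets (Horn quaternion fit)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' `moving` (after transformation) and `fixed`, via the closed-form
#' quaternion solution: the optimal rotation is the eigenvector of the 4x4
#' cross-covariance matrix with the largest eigenvalue. Only proper
#' rotations (det = +1) are considered, so mirror-image point sets retain a
#' strictly positive residual.
#'
#' @param moving,fixed Numeric n x 3 matrices, n >= 3, matched row-wise.
#' @return A `biogps_transform`: list with `rotation` (3x3, acts on column
#'   vectors), `translation` (length 3) and `rmsd` after superposition.
#' @export
horn_fit <- function(moving, fixed) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (!identical(dim(moving), dim(fixed)))
    stop("horn_fit: point sets differ in size")
  n <- nrow(moving)
  if (n < 3L) stop("horn_fit: need at least 3 points")
  mc <- colMeans(moving); fc <- colMeans(fixed)
  A <- sweep(moving, 2, mc); B <- sweep(fixed, 2, fc)
  if (min(svd(A)$d[2], svd(B)$d[2]) < 1e-8)
    stop("horn_fit: degenerate (collinear) point set")
  M <- crossprod(A, B)  # sum over points of a_i b_i^T
  Sxx <- M[1,1]; Sxy <- M[1,2]; Sxz <- M[1,3]
  Syx <- M[2,1]; Syy <- M[2,2]; Syz <- M[2,3]
  Szx <- M[3,1]; Szy <- M[3,2]; Szz <- M[3,3]
  N <- matrix(c(
    Sxx+Syy+Szz,  Syz-Szy,      Szx-Sxz,      Sxy-Syx,
    Syz-Szy,      Sxx-Syy-Szz,  Sxy+Syx,      Szx+Sxz,
    Szx-Sxz,      Sxy+Syx,     -Sxx+Syy-Szz,  Syz+Szy,
    Sxy-Syx,      Szx+Sxz,      Syz+Szy,     -Sxx-Syy+Szz), 4, 4)
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  R <- quat_to_rot(q)
  t <- fc - as.vector(R %*% mc)
  moved <- sweep(moving %*% t(R), 2, t, `+`)
  rmsd <- sqrt(mean(rowSums((moved - fixed)^2)))
  new_transform(R, t, rmsd)
}

quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    w*w+x*x-y*y-z*z,  2*(x*y-w*z),      2*(x*z+w*y),
    2*(x*y+w*z),      w*w-x*x+y*y-z*z,  2*(y*z-w*x),
    2*(x*z-w*y),      2*(y*z+w*x),      w*w-x*x-y*y+z*z), 3, 3, byrow = TRUE)
}

new_transform <- function(R, t, rmsd = NA_real_) {
  structure(list(rotation = R, translation = as.numeric(t), rmsd = rmsd),
            class = "biogps_transform")
}

#' @export
print.biogps_transform <- function(x, ...) {
  ang <- rotation_angle(x$rotation) * 180 / pi
  cat(sprintf("<biogps_transform> rotation %.2f deg, |t| = %.3f A%s\n",
              ang, sqrt(sum(x$translation^2)),
              if (is.na(x$rmsd)) "" else sprintf(", rmsd %.4f A", x$rmsd)))
  invisible(x)
}

#' Apply a rigid transform
#' @param t A `biogps_transform`.
#' @param x A `biogps_structure` or an n x 3 coordinate matrix.
#' @return Object of the same kind with transformed coordinates.
#' @export
apply_transform <- function(t, x) {
  if (inherits(x, "biogps_structure")) {
    xyz <- sweep(coords(x) %*% t(t$rotation), 2, t$translation, `+`)
    a <- x$atoms
    a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
    return(new_structure(x$id, a))
  }
  sweep(as.matrix(x) %*% t(t$rotation), 2, t$translation, `+`)
}

#' Invert a rigid transform
#' @param t A `biogps_transform`.
#' @return The inverse transform.
#' @export
invert_transform <- function(t) {
  new_transform(t(t$rotation), -as.vector(t(t$rotation) %*% t$translation))
}

#' Compose rigid transforms (`a` after `b`)
#' @param a,b `biogps_transform` objects.
#' @return The composition applying `b` first, then `a`.
#' @export
compose_transforms <- function(a, b) {
  new_transform(a$rotation %*% b$rotation,
                as.vector(a$rotation %*% b$translation) + a$translation)
}

# Rotation angle (rad) of a proper rotation matrix.
rotation_angle <- function(R) {
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
}

#' Superpose structures on their catalytic machinery
#'
#' Generalized iterative superposition: in round 1 every structure is
#' Horn-fitted onto the anchors of the first (reference) structure; in each
#' later round every structure is refitted onto the arithmetic mean of the
#' current anchor positions. The anchor-RMSD trace is guaranteed
#' non-increasing. When `auto_reflect = TRUE` and all structures carry a
#' serine anchor, structures whose anchor tetrahedron has opposite
#' handedness to the reference are mirrored (x -> -x) before fitting, which
#' is what makes specular catalytic machineries superposable at all.
#'
#' @param structures List of `biogps_structure`.
#' @param anchors List of `biogps_anchors`, parallel to `structures`.
#' @param iterations Number of refinement rounds (default 15).
#' @param auto_reflect Mirror structures with inverted anchor handedness.
#' @return List with `structures` (superposed), `transforms`, `reflected`
#'   (logical per structure) and `trace` (mean anchor RMSD per round).
#' @export
superpose_on_anchors <- function(structures, anchors, iterations = 15,
                                 auto_reflect = FALSE) {
  n <- length(structures)
  stopifnot(n >= 2L, length(anchors) == n, iterations >= 1L)
  reflected <- logical(n)
  if (auto_reflect) {
    sv <- vapply(anchors, `[[`, numeric(1), "signed_volume")
    if (any(is.na(sv))) {
      warning("auto_reflect needs a serine anchor on every structure; skipped")
    } else {
      flip <- sign(sv) != sign(sv[1]) & sign(sv) != 0
      for (i in which(flip)) {
        structures[[i]] <- reflect_structure(structures[[i]])
        anchors[[i]]$pos[, 1] <- -anchors[[i]]$pos[, 1]
        anchors[[i]]$signed_volume <- -anchors[[i]]$signed_volume
      }
      reflected <- flip
    }
  }
  k <- min(vapply(anchors, function(a) nrow(a$pos), integer(1)))
  pos <- lapply(anchors, function(a) a$pos[seq_len(k), , drop = FALSE])

  transforms <- rep(list(new_transform(diag(3), c(0, 0, 0))), n)
  trace <- numeric(iterations)
  target <- pos[[1]]
  for (round in seq_len(iterations)) {
    for (i in seq_len(n)) {
      fit <- horn_fit(pos[[i]], target)
      pos[[i]] <- apply_transform(fit, pos[[i]])
      transforms[[i]] <- compose_transforms(fit, transforms[[i]])
    }
    target <- Reduce(`+`, pos) / n  # mean anchors become the next target
    trace[round] <- sqrt(mean(vapply(
      pos, function(p) mean(rowSums((p - target)^2)), numeric(1))))
  }
  out <- vector("list", n)
  for (i in seq_len(n)) out[[i]] <- apply_transform(transforms[[i]],
                                                    structures[[i]])
  list(structures = out, transforms = transforms, reflected = reflected,
       trace = trace)
}

#' Pairwise backbone RMSD matrix
#'
#' Crude whole-fold baseline: backbone atoms (N, CA, C, O) are paired by
#' residue rank after truncation to the shorter chain, each pair is
#' superposed with the Horn fit, and the residual RMSD is reported. This
#' deliberately ignores sequence correspondence — it serves as the
#' structure-similarity foil for the alignment-free site descriptors.
#'
#' @param structures List of `biogps_structure`.
#' @return Symmetric matrix of RMSD values (Angstrom), zero diagonal,
#'   dimnames set to structure ids.
#' @export
backbone_rmsd_matrix <- function(structures) {
  bb <- lapply(structures, function(s) {
    a <- s$atoms[s$atoms$name %in% c("N", "CA", "C", "O") &
                   s$atoms$type == "ATOM", , drop = FALSE]
    if (nrow(a) < 3L) stop("structure '", s$id, "' lacks backbone atoms")
    ord <- order(a$chain, a$resno, match(a$name, c("N", "CA", "C", "O")))
    as.matrix(a[ord, c("x", "y", "z")])
  })
  n <- length(structures)
  m <- matrix(0, n, n,
              dimnames = rep(list(vapply(structures, `[[`, "", "id")), 2))
  for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
    k <- min(nrow(bb[[i]]), nrow(bb[[j]]))
    fit <- horn_fit(bb[[j]][seq_len(k), ], bb[[i]][seq_len(k), ])
    m[i, j] <- m[j, i] <- fit$rmsd
  }
  m
}

#' Write a structure as PDB text
#' @param s A `biogps_structure`.
#' @param path Output file; if `NULL` the text is returned invisibly.
#' @return Character vector of PDB lines, invisibly.
#' @export
write_pdb <- function(s, path = NULL) {
  a <- s$atoms
  # atom names of <4 chars conventionally start in column 14
  nm <- ifelse(nchar(a$name) >= 4, substr(a$name, 1, 4),
               sprintf(" %-3s", a$name))
  lines <- sprintf("%-6s%5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   a$type, a$serial, nm, a$resname, a$chain, a$resno,
                   a$x, a$y, a$z, 1, 0, a$element)
  lines <- c(sprintf("REMARK   1 id %s", s$id), lines, "END")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
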
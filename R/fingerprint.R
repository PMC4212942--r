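# Four-point fingerprints. Every combination of four representative points
# ("quadruplet") is canonicalized and encoded as a discrete code combining
# the sorted probe-label multiset, the six binned inter-point distances and
# a chirality sign. The multiset of codes is the Common Reference
# Framework: rigid-motion invariant, reflection-sensitive, and directly
# comparable between sites without any prior alignment.

#' Fingerprint encoding parameters
#' @param bin_width Distance bin width, Angstrom.
#' @param max_dist Distances at or above this share the top bin, Angstrom.
#' @param chir_min_vol Absolute signed volume (cubic Angstrom) below which
#'   a quadruplet counts as planar and its chirality sign is zeroed.
#' @return Named list of encoding parameters.
#' @export
fingerprint_params <- function(bin_width = 2.0, max_dist = 16.0,
                               chir_min_vol = 0.5) {
  stopifnot(bin_width > 0, max_dist > bin_width, chir_min_vol >= 0)
  list(bin_width = bin_width, max_dist = max_dist,
       chir_min_vol = chir_min_vol)
}

# sort three parallel vectors elementwise: returns list(lo, mid, hi)
sort3 <- function(a, b, c) {
  lo <- pmin(a, b, c); hi <- pmax(a, b, c)
  list(lo = lo, mid = a + b + c - lo - hi, hi = hi)
}

#' Enumerate and encode all quadruplets of a point set
#'
#' Generates the `C(n, 4)` four-point combinations and canonicalizes each:
#' members are sorted by probe label, then by their sorted triple of
#' incident distances, then by energy, then by input index, making the
#' encoding invariant to any permutation of the input points. The six
#' pairwise distances are read in the fixed member-pair order (1-2, 1-3,
#' 1-4, 2-3, 2-4, 3-4) of that canonical ordering, binned, and joined with
#' the probe multiset and the chirality sign into the code string.
#'
#' @param points Data frame with `x`, `y`, `z`, `probe`, `energy` (as from
#'   [select_points()]).
#' @param params Encoding parameters from [fingerprint_params()].
#' @return A `biogps_quadruplets` data frame: canonical member indices
#'   `i1`..`i4` (rows of `points`), `code`, `chir`, signed `volume` and the
#'   summed absolute `energy`; `points` and `params` kept as attributes.
#'   Fewer than 4 points give zero rows.
#' @export
enumerate_quadruplets <- function(points, params = fingerprint_params()) {
  n <- nrow(points)
  empty <- data.frame(i1 = integer(0), i2 = integer(0), i3 = integer(0),
                      i4 = integer(0), code = character(0),
                      chir = integer(0), volume = numeric(0),
                      energy = numeric(0), stringsAsFactors = FALSE)
  attr(empty, "points") <- points; attr(empty, "params") <- params
  class(empty) <- c("biogps_quadruplets", "data.frame")
  if (n < 4L) return(empty)

  comb <- utils::combn(n, 4L)              # 4 x C
  C <- ncol(comb)
  xyz <- as.matrix(points[, c("x", "y", "z")])
  D <- as.matrix(stats::dist(xyz))
  probe_int <- match(points$probe, PROBE_TYPES)

  # canonical member order within each quadruplet
  qid <- rep(seq_len(C), each = 4L)
  pidx <- as.vector(comb)                  # point index per (quadruplet, slot)
  inc <- matrix(0, 4L * C, 3L)             # incident distances per member
  for (r in 1:4) {
    others <- comb[-r, , drop = FALSE]
    rows <- seq(r, by = 4L, length.out = C)
    for (k in 1:3)
      inc[rows, k] <- D[cbind(comb[r, ], others[k, ])]
  }
  s3 <- sort3(inc[, 1], inc[, 2], inc[, 3])
  ord <- order(qid, probe_int[pidx], s3$lo, s3$mid, s3$hi,
               points$energy[pidx], pidx)
  canon <- matrix(pidx[ord], nrow = 4L)    # canonical order, 4 x C

  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  nbin <- as.integer(floor(params$max_dist / params$bin_width))
  bins <- matrix(0L, C, 6L)
  for (k in 1:6)
    bins[, k] <- pmin(as.integer(D[cbind(canon[pairs[k, 1], ],
                                         canon[pairs[k, 2], ])] %/%
                                   params$bin_width), nbin)

  p1 <- xyz[canon[1, ], , drop = FALSE]
  e1 <- xyz[canon[2, ], , drop = FALSE] - p1
  e2 <- xyz[canon[3, ], , drop = FALSE] - p1
  e3 <- xyz[canon[4, ], , drop = FALSE] - p1
  vol <- (e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) -
          e1[, 2] * (e2[, 1] * e3[, 3] - e2[, 3] * e3[, 1]) +
          e1[, 3] * (e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])) / 6
  chir <- ifelse(abs(vol) < params$chir_min_vol, 0L, as.integer(sign(vol)))

  labels <- matrix(points$probe[canon], nrow = 4L)
  code <- paste0(labels[1, ], ".", labels[2, ], ".", labels[3, ], ".",
                 labels[4, ], "|",
                 bins[, 1], ".", bins[, 2], ".", bins[, 3], ".",
                 bins[, 4], ".", bins[, 5], ".", bins[, 6], "|", chir)
  energy <- abs(points$energy[canon[1, ]]) + abs(points$energy[canon[2, ]]) +
    abs(points$energy[canon[3, ]]) + abs(points$energy[canon[4, ]])

  out <- data.frame(i1 = canon[1, ], i2 = canon[2, ], i3 = canon[3, ],
                    i4 = canon[4, ], code = code, chir = chir,
                    volume = vol, energy = energy, stringsAsFactors = FALSE)
  out$code_rank <- code_rank(out$code, out$energy)
  attr(out, "points") <- points; attr(out, "params") <- params
  class(out) <- c("biogps_quadruplets", "data.frame")
  out
}

# rank of each quadruplet within its code group, by energy descending
# (deterministic tie-break on row order); used to cap match joins.
code_rank <- function(code, energy) {
  if (!length(code)) return(integer(0))
  o <- order(code, -energy, seq_along(code))
  rk <- integer(length(code))
  rk[o] <- sequence(rle(code[o])$lengths)
  rk
}

#' Encode a single quadruplet
#'
#' Canonicalizes and encodes exactly four representative points; any of the
#' 24 input permutations yields the same code.
#'
#' @param points4 Data frame of exactly 4 rows (`x`, `y`, `z`, `probe`,
#'   `energy`).
#' @param params Encoding parameters from [fingerprint_params()].
#' @return The code string.
#' @export
encode_quadruplet <- function(points4, params = fingerprint_params()) {
  stopifnot(nrow(points4) == 4L)
  enumerate_quadruplets(points4, params)$code
}

#' Build the fingerprint of a mapped active site
#'
#' Pools representative points across probes (mixed-probe quadruplets are
#' part of the Common Reference Framework), enumerates all quadruplets and
#' indexes them by code.
#'
#' @param points_by_probe A list of representative-point data frames (one
#'   per probe, as from [select_points()]) or a single pooled data frame.
#' @param structure_id Label for the fingerprinted site.
#' @param params Encoding parameters from [fingerprint_params()].
#' @return A `biogps_fingerprint`: list with `structure_id`, the pooled
#'   `points`, the `quads` table and `params`.
#' @export
build_fingerprint <- function(points_by_probe, structure_id,
                              params = fingerprint_params()) {
  points <- if (is.data.frame(points_by_probe)) points_by_probe
            else do.call(rbind, points_by_probe)
  if (is.null(points) || nrow(points) < 4L) {
    warning("fewer than 4 representative points; empty fingerprint for '",
            structure_id, "'")
    points <- points %||% data.frame(x = numeric(0), y = numeric(0),
                                     z = numeric(0), probe = character(0),
                                     energy = numeric(0))
  }
  rownames(points) <- NULL
  quads <- enumerate_quadruplets(points, params)
  structure(list(structure_id = structure_id, points = points,
                 pmat = as.matrix(points[, c("x", "y", "z")]),
                 quads = quads, params = params),
            class = "biogps_fingerprint")
}

#' @export
print.biogps_fingerprint <- function(x, ...) {
  cat(sprintf("<biogps_fingerprint> %s: %d points -> %d quadruplets (%d distinct codes)\n",
              x$structure_id, nrow(x$points), nrow(x$quads),
              length(unique(x$quads$code))))
  invisible(x)
}

#' Serialize a fingerprint to JSON
#' @param fp A `biogps_fingerprint`.
#' @param path Output file; `NULL` returns the JSON string.
#' @return The path (or JSON string), invisibly.
#' @export
write_fingerprint <- function(fp, path = NULL) {
  obj <- list(structure_id = fp$structure_id, params = fp$params,
              points = fp$points,
              quadruplets = as.data.frame(fp$quads))
  js <- jsonlite::toJSON(obj, dataframe = "columns", digits = NA,
                         auto_unbox = TRUE)
  if (is.null(path)) return(invisible(js))
  writeLines(js, path)
  invisible(path)
}
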
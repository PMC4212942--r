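# All-against-all site comparison. Matching quadruplet codes propose
# candidate superpositions (Horn fit of the four matched points); each
# candidate pose is scored by the Gaussian volume overlap of the
# pseudo-fields, probe by probe, and the pose maximizing the global
# Tanimoto is kept. One consistent pose per pair: per-probe scores are
# reported at the globally best superposition.

#' Match quadruplets of two fingerprints by code
#'
#' Exact-key join on the quadruplet codes. Within a shared code the
#' highest-energy instances of each side are paired (up to
#' `max_per_code` combinations); the joined list is sorted by combined
#' energy, descending, and truncated to the `m_max` strongest matches.
#'
#' @param fa,fb `biogps_fingerprint` objects.
#' @param m_max Match budget (default 500).
#' @param max_per_code Instance pairings kept per shared code.
#' @return Data frame with quadruplet row indices `qa`, `qb` (into
#'   `fa$quads` / `fb$quads`), the shared `code` and combined `energy`.
#' @export
match_quadruplets <- function(fa, fb, m_max = 500L, max_per_code = 9L) {
  qa <- fa$quads; qb <- fb$quads
  empty <- data.frame(qa = integer(0), qb = integer(0),
                      code = character(0), energy = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(qa) == 0L || nrow(qb) == 0L) return(empty)
  k <- max(1L, as.integer(floor(sqrt(max_per_code))))
  ka <- which(qa$code_rank <= k)
  kb <- which(qb$code_rank <= k)
  da <- data.frame(qa = ka, code = qa$code[ka], ea = qa$energy[ka],
                   stringsAsFactors = FALSE)
  db <- data.frame(qb = kb, code = qb$code[kb], eb = qb$energy[kb],
                   stringsAsFactors = FALSE)
  m <- merge(da, db, by = "code")
  if (nrow(m) == 0L) return(empty)
  m$energy <- m$ea + m$eb
  m <- m[order(-m$energy, m$qa, m$qb),
         c("qa", "qb", "code", "energy"), drop = FALSE]
  rownames(m) <- NULL
  utils::head(m, m_max)
}

#' Candidate pose from a quadruplet match
#'
#' Horn fit of the four canonical points of `fb`'s quadruplet onto those of
#' `fa`'s; proper rotation only. Nearly collinear quadruplets cannot anchor
#' a superposition and yield `NULL` (a skip signal).
#'
#' @param fa,fb The matched fingerprints.
#' @param match One row of [match_quadruplets()] output.
#' @return A `biogps_transform` mapping `fb`'s frame onto `fa`'s, or `NULL`.
#' @export
pose_from_match <- function(fa, fb, match) {
  ia <- match$qa[1]; ib <- match$qb[1]
  qa <- fa$quads; qb <- fb$quads
  pa <- fa$pmat[c(qa$i1[ia], qa$i2[ia], qa$i3[ia], qa$i4[ia]), ,
                drop = FALSE]
  pb <- fb$pmat[c(qb$i1[ib], qb$i2[ib], qb$i3[ib], qb$i4[ib]), ,
                drop = FALSE]
  tryCatch(horn_fit(pb, pa), error = function(e) NULL)
}

#' Score a superposition of two sites
#'
#' For every probe, the Tanimoto score
#' `T = V_overlap / (V_a + V_b - V_overlap)` of the pseudo-field volumes
#' under the pose; a probe with no field on either side is undefined (`NA`)
#' and excluded. The global score pools volumes over all defined probes
#' (volume-weighted pooling) rather than averaging the probe scores.
#'
#' @param a_fields,b_fields Named lists of `biogps_pseudo_field`, keyed by
#'   probe type.
#' @param t A `biogps_transform` mapping `b` onto `a` (default identity).
#' @param global_mode `"pooled"` (default) sums volumes over probes before
#'   the Tanimoto; `"mean"` averages the defined probe scores.
#' @return Named numeric of per-probe scores plus `global`, all in `[0, 1]`
#'   or `NA` where undefined.
#' @export
score_pose <- function(a_fields, b_fields, t = NULL,
                       global_mode = c("pooled", "mean")) {
  global_mode <- match.arg(global_mode)
  scores <- stats::setNames(rep(NA_real_, length(PROBE_TYPES)), PROBE_TYPES)
  va_tot <- vb_tot <- vo_tot <- 0
  for (pr in PROBE_TYPES) {
    pa <- a_fields[[pr]]; pb <- b_fields[[pr]]
    va <- if (is.null(pa)) 0 else pa$volume
    vb <- if (is.null(pb)) 0 else pb$volume
    if (va + vb == 0) next                       # absent on both sides
    vo <- if (va == 0 || vb == 0) 0 else
      unname(field_overlap(pa, pb, t)["V_overlap"])
    scores[pr] <- vo / (va + vb - vo)
    va_tot <- va_tot + va; vb_tot <- vb_tot + vb; vo_tot <- vo_tot + vo
  }
  glob <- if (global_mode == "pooled") {
    denom <- va_tot + vb_tot - vo_tot
    if (denom > 0) vo_tot / denom else 0
  } else {
    if (all(is.na(scores))) 0 else mean(scores, na.rm = TRUE)
  }
  c(scores, global = glob)
}

poses_distinct <- function(t1, t2, rot_tol = 2 * pi / 180, trans_tol = 0.25) {
  rotation_angle(crossprod(t1$rotation, t2$rotation)) > rot_tol ||
    sqrt(sum((t1$translation - t2$translation)^2)) > trans_tol
}

# unit quaternion (w,x,y,z) of a proper rotation; sign-normalized (w >= 0)
rot_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    j <- i %% 3L + 1L; k <- j %% 3L + 1L
    s <- sqrt(max(1e-12, R[i, i] - R[j, j] - R[k, k] + 1)) * 2
    q <- numeric(4)
    q[1] <- (R[k, j] - R[j, k]) / s
    q[i + 1L] <- 0.25 * s
    q[j + 1L] <- (R[j, i] + R[i, j]) / s
    q[k + 1L] <- (R[k, i] + R[i, k]) / s
  }
  q <- q / sqrt(sum(q^2))
  if (q[1] < 0) -q else q
}

# Minimal per-probe summaries of a pseudo-field set, for the inner loops.
field_summaries <- function(fields) {
  out <- list()
  for (pr in names(fields)) {
    pf <- fields[[pr]]
    if (is.null(pf) || nrow(pf$centers) == 0L) next
    out[[pr]] <- list(X = as.matrix(pf$centers[, c("x", "y", "z")]),
                      w = pf$centers$weight, sigma = pf$sigma,
                      volume = pf$volume)
  }
  out
}

# Overlap volumes per probe under rotation R, translation tv, using
# summaries; returns list(vo = named overlaps, scores implied by volumes).
summary_overlaps <- function(sa, sb, R, tv) {
  vo <- numeric(0)
  for (pr in union(names(sa), names(sb))) {
    a <- sa[[pr]]; b <- sb[[pr]]
    if (is.null(a) || is.null(b)) { vo[pr] <- 0; next }
    Bt <- sweep(b$X %*% t(R), 2, tv, `+`)
    s2 <- a$sigma^2 + b$sigma^2
    pref <- (2 * pi * a$sigma^2 * b$sigma^2 / s2)^1.5
    d2 <- outer(rowSums(a$X^2), rowSums(Bt^2), `+`) - 2 * a$X %*% t(Bt)
    ov <- pref * sum(outer(a$w, b$w) * exp(-pmax(d2, 0) / (2 * s2)))
    vo[pr] <- min(ov, a$volume, b$volume)
  }
  vo
}

score_from_summaries <- function(sa, sb, R, tv, global_mode) {
  scores <- stats::setNames(rep(NA_real_, length(PROBE_TYPES)), PROBE_TYPES)
  va_tot <- vb_tot <- vo_tot <- 0
  vo <- summary_overlaps(sa, sb, R, tv)
  for (pr in PROBE_TYPES) {
    va <- sa[[pr]]$volume %||% 0
    vb <- sb[[pr]]$volume %||% 0
    if (va + vb == 0) next
    v <- if (pr %in% names(vo)) vo[[pr]] else 0
    scores[pr] <- v / (va + vb - v)
    va_tot <- va_tot + va; vb_tot <- vb_tot + vb; vo_tot <- vo_tot + v
  }
  glob <- if (global_mode == "pooled") {
    denom <- va_tot + vb_tot - vo_tot
    if (denom > 0) vo_tot / denom else 0
  } else {
    if (all(is.na(scores))) 0 else mean(scores, na.rm = TRUE)
  }
  c(scores, global = glob)
}

# Coarse-to-fine kernel-correlation refinement: the kernel widths are
# inflated by each factor in `anneal` in turn (wide basins first), running
# `iters` EM updates per stage at that scale.
refine_from_summaries <- function(sa, sb, t, iters,
                                  anneal = c(2, 1)) {
  for (scale in anneal) {
    sa2 <- lapply(sa, function(a) { a$sigma <- a$sigma * scale; a })
    sb2 <- lapply(sb, function(b) { b$sigma <- b$sigma * scale; b })
    t <- refine_stage(sa2, sb2, t, iters)
  }
  t
}

refine_stage <- function(sa, sb, t, iters) {
  shared <- intersect(names(sa), names(sb))
  if (!length(shared)) return(t)
  for (it in seq_len(iters)) {
    cen_a <- cen_b <- c(0, 0, 0); tot <- 0
    Gs <- list()
    for (pr in shared) {
      a <- sa[[pr]]; b <- sb[[pr]]
      Bt <- sweep(b$X %*% t(t$rotation), 2, t$translation, `+`)
      s2 <- a$sigma^2 + b$sigma^2
      d2 <- outer(rowSums(a$X^2), rowSums(Bt^2), `+`) - 2 * a$X %*% t(Bt)
      G <- outer(a$w, b$w) * exp(-pmax(d2, 0) / (2 * s2))
      Gs[[pr]] <- G
      tot <- tot + sum(G)
      cen_a <- cen_a + colSums(rowSums(G) * a$X)
      cen_b <- cen_b + colSums(colSums(G) * b$X)
    }
    if (tot < 1e-12) return(t)
    cen_a <- cen_a / tot; cen_b <- cen_b / tot
    H <- matrix(0, 3, 3)
    for (pr in shared)
      H <- H + crossprod(sweep(sb[[pr]]$X, 2, cen_b),
                         t(Gs[[pr]]) %*% sweep(sa[[pr]]$X, 2, cen_a))
    sv <- svd(H)
    dsign <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, 1, dsign)) %*% t(sv$u)
    t <- new_transform(R, cen_a - as.vector(R %*% cen_b))
  }
  t
}

# Candidate poses from weighted principal axes of the pooled pseudo-field
# centers: align centroids and inertia axes in the four proper sign
# combinations. Complements the quadruplet poses with a global shape guess.
axis_poses <- function(a_fields, b_fields) {
  pool <- function(fs) {
    cs <- do.call(rbind, lapply(fs, function(pf)
      if (is.null(pf)) NULL else pf$centers[, c("x", "y", "z", "weight")]))
    if (is.null(cs)) cs <- data.frame(x = numeric(0), y = numeric(0),
                                      z = numeric(0), weight = numeric(0))
    cs[cs$weight > 0, , drop = FALSE]
  }
  ca <- pool(a_fields); cb <- pool(b_fields)
  if (nrow(ca) < 3L || nrow(cb) < 3L) return(list())
  frame <- function(cs) {
    w <- cs$weight / sum(cs$weight)
    xyz <- as.matrix(cs[, c("x", "y", "z")])
    m <- colSums(xyz * w)
    U <- eigen(crossprod(sweep(xyz, 2, m) * sqrt(w)), symmetric = TRUE)$vectors
    if (det(U) < 0) U[, 3] <- -U[, 3]
    list(m = m, U = U)
  }
  fa <- frame(ca); fb <- frame(cb)
  out <- list()
  for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
    R <- fa$U %*% diag(c(s1, s2, s1 * s2)) %*% t(fb$U)
    out[[length(out) + 1L]] <- new_transform(R, fa$m - as.vector(R %*% fb$m))
  }
  out
}

#' Locally refine a pose by kernel correlation
#'
#' EM-style refinement of the Gaussian volume overlap: soft
#' correspondences between same-probe centers are computed under the
#' current pose (Gaussian-weighted), then the weighted rigid fit updates
#' the pose; repeated for a fixed number of iterations. Converges to a
#' nearby local maximum of the overlap.
#'
#' @param a_fields,b_fields Named lists of `biogps_pseudo_field`.
#' @param t Starting `biogps_transform`.
#' @param iters Refinement iterations per annealing stage (default 6; the
#'   kernel widths are first doubled for a wide-basin pass, then restored).
#' @return The refined `biogps_transform`.
#' @export
refine_pose <- function(a_fields, b_fields, t, iters = 6L) {
  refine_from_summaries(field_summaries(a_fields),
                        field_summaries(b_fields), t, iters)
}

#' Compare two characterized sites
#'
#' Candidate superpositions come from the strongest quadruplet matches;
#' since a correct alignment is proposed independently by every truly
#' corresponding quadruplet while coincidental code collisions scatter, the
#' candidate poses are clustered (rotations within 8 degrees, translations
#' within 1.5 Angstrom join a cluster) and the cluster consensus poses are
#' scored in order of vote count. The pose maximizing the global Tanimoto
#' wins; ties keep the earlier pose in vote order. With no usable pose all
#' scores are zero and `pose_found` is `FALSE`.
#'
#' @param a,b Site descriptions from [characterize_site()] (lists with
#'   `fingerprint` and `pseudo_fields`).
#' @param m_max Match budget passed to [match_quadruplets()].
#' @param max_poses Cap on distinct pose clusters scored.
#' @param global_mode Passed to [score_pose()].
#' @param refine_iters Kernel-correlation iterations applied to each scored
#'   candidate (0 disables refinement).
#' @return A `biogps_scores`: list with `scores` (per-probe + global),
#'   `transform`, `pose_found`, `n_matches`, `n_poses`.
#' @export
compare_pair <- function(a, b, m_max = 500L, max_poses = 15L,
                         global_mode = c("pooled", "mean"),
                         refine_iters = 6L) {
  global_mode <- match.arg(global_mode)
  # canonical pair order makes the comparison exactly symmetric
  if (is.character(a$id) && is.character(b$id) && a$id > b$id) {
    res <- compare_pair(b, a, m_max, max_poses, global_mode, refine_iters)
    if (!is.null(res$transform)) res$transform <- invert_transform(res$transform)
    return(res)
  }
  matches <- match_quadruplets(a$fingerprint, b$fingerprint, m_max)
  best <- NULL; best_t <- NULL
  reps <- list()
  if (nrow(matches) > 0L) {
    # greedy pose clustering (voting): rotations compared through unit
    # quaternions (|dot| >= cos(tol/2)), translations by distance
    qmat <- matrix(numeric(0), 0, 4)
    tmat <- matrix(numeric(0), 0, 3)
    votes <- integer(0)
    cos_tol <- cos(8 * pi / 180 / 2)
    for (r in seq_len(nrow(matches))) {
      t <- pose_from_match(a$fingerprint, b$fingerprint,
                           list(qa = matches$qa[r], qb = matches$qb[r]))
      if (is.null(t)) next
      q <- rot_to_quat(t$rotation)
      if (nrow(qmat)) {
        close <- abs(qmat %*% q) >= cos_tol &
          rowSums(sweep(tmat, 2, t$translation)^2) <= 1.5^2
        ci <- which(close)[1]
      } else ci <- NA_integer_
      if (!is.na(ci)) {
        votes[ci] <- votes[ci] + 1L
      } else {
        reps[[length(reps) + 1L]] <- t
        qmat <- rbind(qmat, q)
        tmat <- rbind(tmat, t$translation)
        votes <- c(votes, 1L)
      }
    }
    reps <- reps[utils::head(order(-votes, seq_along(reps)), max_poses)]
  }
  cand <- c(reps, axis_poses(a$pseudo_fields, b$pseudo_fields))
  sa <- field_summaries(a$pseudo_fields)
  sb <- field_summaries(b$pseudo_fields)
  for (t in cand) {
    sc <- score_from_summaries(sa, sb, t$rotation, t$translation,
                               global_mode)
    if (is.null(best) || sc["global"] > best["global"] + 1e-12) {
      best <- sc; best_t <- t
    }
    if (refine_iters > 0L) {
      rt <- refine_from_summaries(sa, sb, t, refine_iters)
      rsc <- score_from_summaries(sa, sb, rt$rotation, rt$translation,
                                  global_mode)
      if (rsc["global"] > best["global"] + 1e-12) {
        best <- rsc; best_t <- rt
      }
    }
  }
  if (is.null(best)) {
    best <- stats::setNames(c(rep(0, length(PROBE_TYPES)), 0),
                            c(PROBE_TYPES, "global"))
    for (pr in PROBE_TYPES)   # keep probes undefined on both sides as NA
      if ((a$pseudo_fields[[pr]]$volume %||% 0) +
          (b$pseudo_fields[[pr]]$volume %||% 0) == 0)
        best[pr] <- NA_real_
  }
  structure(list(scores = best, transform = best_t,
                 pose_found = !is.null(best_t),
                 n_matches = nrow(matches), n_poses = length(cand)),
            class = "biogps_scores")
}

#' @export
print.biogps_scores <- function(x, ...) {
  cat("<biogps_scores>",
      paste(sprintf("%s=%.3f", names(x$scores), x$scores), collapse = " "),
      if (!x$pose_found) "(no pose)" else "", "\n")
  invisible(x)
}

#' All-against-all similarity matrices
#'
#' Compares every pair of sites (upper triangle plus the diagonal, which is
#' computed, not assumed) and assembles the five square Tanimoto matrices:
#' one per probe and the global score. Pairwise failures are flagged and
#' entered as zero, never aborting the batch.
#'
#' @param sites List of site descriptions from [characterize_site()].
#' @param m_max,max_poses Passed to [compare_pair()].
#' @param verbose Print one progress line per site.
#' @return A `biogps_simmat`: list with `ids` and matrices `H`, `O`, `N1`,
#'   `DRY`, `global`; failed pairs recorded in the `failures` attribute.
#' @export
all_against_all <- function(sites, m_max = 200L, max_poses = 50L,
                            global_mode = c("pooled", "mean"),
                            verbose = FALSE) {
  global_mode <- match.arg(global_mode)
  n <- length(sites)
  stopifnot(n >= 2L)
  ids <- vapply(sites, `[[`, "", "id")
  mats <- stats::setNames(rep(list(matrix(
    NA_real_, n, n, dimnames = list(ids, ids))), 5L),
    c(PROBE_TYPES, "global"))
  failures <- character(0)
  for (i in seq_len(n)) {
    for (j in i:n) {
      res <- tryCatch(compare_pair(sites[[i]], sites[[j]], m_max, max_poses,
                                   global_mode),
                      error = function(e) e)
      if (inherits(res, "error")) {
        failures <- c(failures, sprintf("%s vs %s: %s", ids[i], ids[j],
                                        conditionMessage(res)))
        sc <- stats::setNames(rep(0, 5L), c(PROBE_TYPES, "global"))
      } else sc <- res$scores
      for (m in names(mats)) {
        mats[[m]][i, j] <- sc[m]
        mats[[m]][j, i] <- sc[m]
      }
    }
    if (is.finite(mats$global[i, i]) &&
        abs(mats$global[i, i] - 1) > 1e-3)
      warning("self-similarity of '", ids[i], "' is ",
              format(mats$global[i, i]), ", expected 1")
    if (verbose)
      message(sprintf("compared %s (%d/%d)", ids[i], i, n))
  }
  out <- structure(c(list(ids = ids), mats), class = "biogps_simmat")
  attr(out, "failures") <- failures
  out
}

#' @export
print.biogps_simmat <- function(x, ...) {
  cat(sprintf("<biogps_simmat> %d sites; mean global similarity %.3f\n",
              length(x$ids),
              mean(x$global[upper.tri(x$global)], na.rm = TRUE)))
  invisible(x)
}

#' Write similarity matrices as TSV files
#' @param m A `biogps_simmat`.
#' @param dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_simmat <- function(m, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in c(PROBE_TYPES, "global")) {
    f <- file.path(dir, paste0("similarity_", nm, ".tsv"))
    utils::write.table(m[[nm]], f, sep = "\t", quote = FALSE,
                       col.names = NA)
    files <- c(files, f)
  }
  invisible(files)
}
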
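# Structure reading, cleaning, reflection and catalytic-machinery
# superposition.

pdb_line <- function(serial, name, resname, resno, x, y, z, element,
                     type = "ATOM", alt = " ") {
  nm <- if (nchar(name) >= 4) substr(name, 1, 4) else sprintf(" %-3s", name)
  sprintf("%-6s%5d %4s%s%-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          type, serial, nm, alt, resname, resno, x, y, z, element)
}

test_that("read_pdb preserves coordinates, names and order", {
  txt <- paste(pdb_line(1, "N", "GLY", 1, 0, 0, 0, "N"),
               pdb_line(2, "CA", "GLY", 1, 1.5, 0, 0, "C"), sep = "\n")
  s <- read_pdb(txt)
  expect_equal(nrow(s$atoms), 2L)
  expect_equal(s$atoms$name, c("N", "CA"))
  expect_equal(s$atoms$x, c(0, 1.5))
  expect_equal(s$atoms$element, c("N", "C"))
  expect_equal(s$atoms$resno, c(1L, 1L))
})

test_that("read_pdb keeps only blank/A altlocs and errors on empty input", {
  base <- c(pdb_line(1, "N", "GLY", 1, 0, 0, 0, "N"),
            pdb_line(2, "CA", "GLY", 2, 2, 0, 0, "C", alt = "A"),
            pdb_line(3, "CA", "GLY", 2, 2.2, 0, 0, "C", alt = "B"))
  s <- read_pdb(paste(base, collapse = "\n"))
  expect_equal(nrow(s$atoms), 2L)     # altloc B dropped
  expect_equal(s$atoms$x[2], 2)
  no_alt <- read_pdb(paste(base[1:2], collapse = "\n"))
  expect_equal(nrow(no_alt$atoms), 2L)
  expect_error(read_pdb("REMARK nothing here\nEND"), "no ATOM/HETATM")
})

test_that("strip_non_protein removes waters and ligands, keeps order", {
  lines <- c(
    vapply(1:10, function(i)
      pdb_line(i, "CA", "ALA", i, i, 0, 0, "C"), ""),
    pdb_line(11, "O", "HOH", 101, 9, 9, 9, "O", type = "HETATM"),
    pdb_line(12, "O", "HOH", 102, 9, 9, 8, "O", type = "HETATM"),
    pdb_line(13, "O", "HOH", 103, 9, 8, 9, "O", type = "HETATM"),
    pdb_line(14, "C1", "NAG", 201, 8, 8, 8, "C", type = "HETATM"))
  s <- read_pdb(paste(lines, collapse = "\n"))
  p <- strip_non_protein(s)
  expect_equal(nrow(p$atoms), 10L)
  expect_true(all(p$atoms$resname == "ALA"))
  expect_equal(p$atoms$serial, 1:10)

  expect_identical(strip_non_protein(p)$atoms, p$atoms)

  hoh <- read_pdb(paste(lines[11:13], collapse = "\n"))
  expect_error(strip_non_protein(hoh), "no protein")
})

test_that("reflection negates x, is an involution, and flips chirality", {
  s <- make_toy_enzyme()
  r <- reflect_structure(s)
  expect_equal(r$atoms$x, -s$atoms$x)
  expect_equal(r$atoms$y, s$atoms$y)
  expect_equal(r$atoms$z, s$atoms$z)
  expect_identical(reflect_structure(r), s)   # bit-exact involution

  v0 <- biogps:::signed_volume(coords(s)[c(1, 3, 5, 7), ])
  v1 <- biogps:::signed_volume(coords(r)[c(1, 3, 5, 7), ])
  expect_equal(v1, -v0)
  expect_gt(abs(v0), 1e-6)
})

test_that("extract_anchors resolves the catalytic machinery", {
  s <- make_toy_enzyme()
  a <- toy_anchors(s)
  expect_equal(s$atoms$name[a$idx], c("NE2", "N", "N", "OG"))
  expect_equal(s$atoms$resno[a$idx], c(224L, 40L, 106L, 105L))
  expect_true(a$has_serine)
  expect_true(is.finite(a$signed_volume))

  expect_error(extract_anchors(s, "HIS 999", c("THR 40", "GLN 106")),
               "999")
  # explicit atom override (Tyr-oxyanion variant)
  s2 <- s
  s2$atoms$resname[5] <- "TYR"; s2$atoms$name[5] <- "OH"
  s2$atoms$resno[5] <- 473; s2$atoms$element[5] <- "O"
  a2 <- extract_anchors(s2, "HIS 224", c("THR 40", "TYR 473 OH"))
  expect_equal(s2$atoms$name[a2$idx[3]], "OH")
})

test_that("horn_fit recovers exact transforms and validates input", {
  set.seed(11)
  pts <- matrix(rnorm(18), 6, 3)
  fit0 <- horn_fit(pts, pts)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-9)
  expect_equal(fit0$translation, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-9)

  for (seed in 1:5) {
    R0 <- random_rotation(seed)
    t0 <- c(1, -2, 3)
    moved <- sweep(pts %*% t(R0), 2, t0, `+`)
    fit <- horn_fit(pts, moved)
    expect_equal(fit$rotation, R0, tolerance = 1e-6)
    expect_equal(fit$translation, t0, tolerance = 1e-6)
    expect_lt(fit$rmsd, 1e-9)
  }

  expect_error(horn_fit(pts[1:4, ], pts), "size")
  expect_error(horn_fit(pts[1:2, ], pts[1:2, ]), "3 points")
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(horn_fit(line, line), "collinear")
})

test_that("horn_fit RMSD is invariant under a common rigid motion", {
  set.seed(21)
  a <- matrix(rnorm(15), 5, 3)
  b <- a + matrix(rnorm(15, sd = 0.3), 5, 3)
  r0 <- horn_fit(a, b)$rmsd
  for (seed in 1:5) {
    tr <- random_transform(seed)
    r1 <- horn_fit(apply_transform(tr, a), apply_transform(tr, b))$rmsd
    expect_equal(r1, r0, tolerance = 1e-9)
  }
})

test_that("iterative anchor superposition converges and is monotone", {
  s <- make_toy_enzyme("ref")
  copies <- lapply(1:3, function(i) {
    tr <- random_transform(100 + i)
    st <- apply_transform(tr, s); st$id <- paste0("copy", i); st
  })
  structures <- c(list(s), copies)
  anchors <- lapply(structures, toy_anchors)
  res <- superpose_on_anchors(structures, anchors, iterations = 15)
  expect_lt(res$trace[15], 1e-9)                 # identical machineries
  expect_true(all(diff(res$trace) <= 1e-9))      # non-increasing
  # all atoms coincide after superposition (identical structures)
  for (st in res$structures)
    expect_equal(coords(st), coords(res$structures[[1]]), tolerance = 1e-6)
})

test_that("one iteration reduces to the pairwise Horn fit", {
  s <- make_toy_enzyme("ref")
  tr <- random_transform(7)
  moved <- apply_transform(tr, s); moved$id <- "moved"
  anchors <- list(toy_anchors(s), toy_anchors(moved))
  res <- superpose_on_anchors(list(s, moved), anchors, iterations = 1)
  direct <- horn_fit(anchors[[2]]$pos, anchors[[1]]$pos)
  expect_equal(res$transforms[[2]]$rotation, direct$rotation,
               tolerance = 1e-9)
  expect_equal(res$transforms[[2]]$translation, direct$translation,
               tolerance = 1e-9)
})

test_that("auto-reflection lets a mirror-image machinery superpose", {
  s <- make_toy_enzyme("ref")
  m <- reflect_structure(s); m$id <- "mirror"
  anchors <- list(toy_anchors(s), toy_anchors(m))
  expect_equal(anchors[[2]]$signed_volume, -anchors[[1]]$signed_volume)

  with_refl <- superpose_on_anchors(list(s, m), anchors, iterations = 15,
                                    auto_reflect = TRUE)
  expect_true(with_refl$reflected[2])
  expect_lt(with_refl$trace[15], 1e-9)

  without <- superpose_on_anchors(list(s, m), anchors, iterations = 15,
                                  auto_reflect = FALSE)
  expect_gt(without$trace[15], 0.1)    # mirror cannot be superposed properly
})

test_that("backbone RMSD matrix has closed-form and invariance properties", {
  set.seed(31)
  n_res <- 6
  atoms <- do.call(rbind, lapply(seq_len(n_res), function(i) {
    data.frame(name = c("N", "CA", "C", "O"),
               resname = "ALA", resno = i,
               x = rnorm(4, i * 3), y = rnorm(4), z = rnorm(4),
               element = c("N", "C", "C", "O"))
  }))
  atoms$serial <- seq_len(nrow(atoms)); atoms$chain <- "A"
  atoms$insert <- ""; atoms$type <- "ATOM"
  s <- biogps:::new_structure("bb", atoms)

  m <- backbone_rmsd_matrix(list(s, s))
  expect_equal(m, matrix(0, 2, 2, dimnames = list(c("bb", "bb"),
                                                  c("bb", "bb"))))

  moved <- apply_transform(random_transform(5), s); moved$id <- "mv"
  m2 <- backbone_rmsd_matrix(list(s, moved))
  expect_lt(m2[1, 2], 1e-6)
  expect_equal(m2, t(m2))

  # one atom displaced by d: RMSD = d / sqrt(n) after optimal fit is
  # bounded above by that; verify against the direct closed form without
  # re-fitting by displacing along a direction and comparing to horn rmsd
  d <- 0.8
  shifted <- s
  shifted$atoms$x[1] <- shifted$atoms$x[1] + d
  shifted$id <- "sh"
  m3 <- backbone_rmsd_matrix(list(s, shifted))
  expect_lte(m3[1, 2], d / sqrt(nrow(atoms)) + 1e-9)
  expect_gt(m3[1, 2], 0)

  bad <- biogps:::new_structure("x", atoms[atoms$name == "CB", , drop = FALSE])
  expect_error(backbone_rmsd_matrix(list(s, bad)), "backbone")
})

test_that("PDB round trip preserves the atom table", {
  s <- make_toy_enzyme()
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, tf)
  s2 <- read_pdb(tf, id = s$id)
  expect_equal(s2$atoms$name, s$atoms$name)
  expect_equal(s2$atoms$resno, s$atoms$resno)
  expect_equal(coords(s2), coords(s), tolerance = 1e-3)
})
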
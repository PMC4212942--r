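# Probe fields, pseudo-fields and representative points.

# structure with a single backbone-like N-H donor pointing along +z
donor_structure <- function() {
  atoms <- data.frame(serial = 1:2, name = c("N", "CA"), resname = "GLY",
                      chain = "A", resno = 1, insert = "",
                      x = 0, y = 0, z = c(0, -1.45),
                      element = c("N", "C"), type = "ATOM")
  biogps:::new_structure("donor", atoms)
}

carbonyl_structure <- function(shift = c(0, 0, 0), id = "carbonyl") {
  atoms <- data.frame(serial = 1:2, name = c("O", "C"), resname = "GLY",
                      chain = "A", resno = 1, insert = "",
                      x = shift[1], y = shift[2],
                      z = c(0, -1.23) + shift[3],
                      element = c("O", "C"), type = "ATOM")
  biogps:::new_structure(id, atoms)
}

# a pocket whose mask is exactly the given nodes (test scaffold); node
# coordinates are honored verbatim so closed-form checks are exact
pocket_at <- function(nodes, spacing = 1) {
  nodes <- as.matrix(nodes)
  dimnames(nodes) <- NULL
  g <- structure(list(origin = apply(nodes, 2, min) - spacing,
                      spacing = spacing,
                      dim = rep(4L, 3)),
                 class = "biogps_grid")
  structure(list(grid = g, idx = seq_len(nrow(nodes)), coords = nodes,
                 centroid = colMeans(nodes)),
            class = "biogps_pocket")
}

synthetic_field <- function(pocket, energy, probe = "H") {
  structure(list(probe = probe, pocket = pocket, energy = energy,
                 structure_id = "synthetic"), class = "biogps_field")
}

test_that("O probe senses an N-H donor with the right sign and geometry", {
  s <- donor_structure()
  pk <- pocket_at(rbind(c(0, 0, 2.9),      # on-axis, optimal distance
                        c(2.9, 0, 0),      # orthogonal: cos(theta) = 0
                        c(0, 0, 0.5)))     # clash
  f <- compute_field(s, pk, "O")
  expect_lt(f$energy[1], -3)               # strongly favorable, near e_hb
  expect_gt(f$energy[1], -5)               # bounded by e_hb plus LJ tail
  expect_gt(f$energy[2], f$energy[1])      # off-axis much weaker
  expect_equal(f$energy[3], 5)             # clamped clash
})

test_that("clash nodes are clamped for every probe", {
  s <- donor_structure()
  pk <- pocket_at(rbind(c(0, 0, 0.5)))
  for (pr in c("H", "O", "N1", "DRY"))
    expect_equal(compute_field(s, pk, pr)$energy, 5)
})

test_that("DRY field matches the documented closed form on a lone carbon", {
  atoms <- data.frame(serial = 1:2, name = c("CB", "CA"), resname = "ALA",
                      chain = "A", resno = 1, insert = "",
                      x = c(0, 0), y = c(0, 0), z = c(0, -1.53),
                      element = "C", type = "ATOM")
  s <- biogps:::new_structure("methyl", atoms)
  node <- c(0, 0, 4)
  pk <- pocket_at(rbind(node))
  pp <- probe_params()
  f <- compute_field(s, pk, "DRY", pp)
  # hand-evaluated: LJ over both carbons + hydrophobic kernel on CB only
  lj <- function(r, rmin) pp$DRY$eps * ((rmin / r)^12 - 2 * (rmin / r)^6)
  rmin <- 1.70 + pp$DRY$r_probe
  expected <- lj(4, rmin) + lj(5.53, rmin) -
    pp$DRY$w_phobic * exp(-(4 - pp$DRY$dry_dist)^2 / (2 * pp$DRY$dry_sigma^2))
  expect_equal(f$energy, expected, tolerance = 1e-12)
})

test_that("field energies are clamped and finite on real pockets", {
  s <- cached("cup_1", make_toy_pocket(pocket_recipe(1,
    fractions = fixture_classes()$donor)))
  pk <- detect_pocket(s)
  for (pr in c("H", "O", "N1", "DRY")) {
    f <- compute_field(s, pk, pr)
    expect_true(all(is.finite(f$energy)))
    expect_true(all(f$energy >= -15 & f$energy <= 5))
  }
})

test_that("donor-rich and hydrophobic pockets order O and DRY fields oppositely", {
  sdon <- cached("cup_1", make_toy_pocket(pocket_recipe(1,
    fractions = fixture_classes()$donor)))
  sdry <- cached("cup_dry_2", make_toy_pocket(pocket_recipe(2,
    fractions = fixture_classes()$hydrophobic)))
  pd <- detect_pocket(sdon); ph <- detect_pocket(sdry)
  o_d <- mean(compute_field(sdon, pd, "O")$energy)
  o_h <- mean(compute_field(sdry, ph, "O")$energy)
  dry_d <- mean(compute_field(sdon, pd, "DRY")$energy)
  dry_h <- mean(compute_field(sdry, ph, "DRY")$energy)
  expect_lt(o_d, o_h)        # donors make the O probe happier
  expect_lt(dry_h, dry_d)    # hydrophobic lining favors DRY
})

test_that("pseudo-field centers land on the chemically eligible atoms", {
  s <- carbonyl_structure()
  pk <- pocket_at(rbind(c(0, 0, 2.9), c(0.5, 0.5, 2.9)))
  f <- compute_field(s, pk, "N1")
  pf <- to_pseudo_field(f, s)
  expect_equal(nrow(pf$centers), 1L)            # exactly the carbonyl O
  expect_equal(s$atoms$name[pf$centers$atom], "O")
  expect_equal(unname(unlist(pf$centers[1, c("x", "y", "z")])), c(0, 0, 0))

  # zero/unfavorable field -> empty pseudo-field
  zf <- synthetic_field(pk, c(0, 0), probe = "N1")
  expect_equal(nrow(to_pseudo_field(zf, s)$centers), 0L)
  expect_equal(to_pseudo_field(zf, s)$volume, 0)
})

test_that("two identical distant carbonyls get equal energy weights", {
  a1 <- carbonyl_structure()$atoms
  a2 <- carbonyl_structure(shift = c(12, 0, 0))$atoms
  a2$serial <- 3:4; a2$resno <- 2
  s <- biogps:::new_structure("two", rbind(a1, a2))
  pk <- pocket_at(rbind(c(0, 0, 2.9), c(12, 0, 2.9)))
  f <- compute_field(s, pk, "N1")
  pf <- to_pseudo_field(f, s, weight_mode = "energy")
  expect_equal(nrow(pf$centers), 2L)
  expect_equal(pf$centers$weight[1], pf$centers$weight[2], tolerance = 1e-6)
})

test_that("select_points takes separated minima greedily and deterministically", {
  nodes <- as.matrix(expand.grid(x = 0:10, y = 0, z = 0))
  pk <- pocket_at(nodes)
  e <- rep(0, nrow(nodes))
  e[nodes[, 1] == 0] <- -5; e[nodes[, 1] == 5] <- -3
  e[nodes[, 1] == 10] <- -4
  f <- synthetic_field(pk, e)
  pts <- select_points(f, k_max = 5, min_sep = 1.5)
  expect_equal(nrow(pts), 3L)
  expect_equal(pts$energy, c(-5, -4, -3))      # ranked by energy

  expect_equal(nrow(select_points(synthetic_field(pk, rep(0, nrow(nodes))),
                                  k_max = 5, min_sep = 1.5)), 0L)

  # two minima 1 A apart with min_sep 3: only the deeper survives
  e2 <- rep(0, nrow(nodes)); e2[nodes[, 1] == 4] <- -2
  e2[nodes[, 1] == 5] <- -6
  pts2 <- select_points(synthetic_field(pk, e2), k_max = 5, min_sep = 3)
  expect_equal(nrow(pts2), 1L)
  expect_equal(pts2$energy, -6)

  # k_max truncates
  e3 <- -(1:11)
  expect_equal(nrow(select_points(synthetic_field(pk, e3), k_max = 4,
                                  min_sep = 1.5)), 4L)
})

test_that("field_overlap obeys the Gaussian closed forms and symmetry", {
  mk <- function(x, w = 1, sigma = 1) biogps:::new_pseudo_field("H", sigma,
    data.frame(x = x, y = 0, z = 0, weight = w, atom = seq_along(x)))
  a <- mk(0)
  # self overlap equals volume
  self <- field_overlap(a, a)
  expect_equal(unname(self["V_overlap"]), unname(self["V_a"]),
               tolerance = 1e-12)
  expect_equal(unname(self["V_a"]), (2 * pi * 0.5)^1.5, tolerance = 1e-9)

  # offset Gaussians: closed-form product integral
  d <- 1.7
  b <- mk(d)
  ov <- field_overlap(a, b)
  expect_equal(unname(ov["V_overlap"]),
               (pi)^1.5 * exp(-d^2 / 4), tolerance = 1e-9)

  # far apart: negligible
  far <- field_overlap(a, mk(25))
  expect_lt(far["V_overlap"], 1e-6 * far["V_a"])

  # symmetry under swap with the inverse transform
  tr <- random_transform(3, trans_scale = 1)
  o1 <- field_overlap(a, b, tr)
  o2 <- field_overlap(b, a, invert_transform(tr))
  expect_equal(unname(o1["V_overlap"]), unname(o2["V_overlap"]),
               tolerance = 1e-9)

  expect_error(field_overlap(a, biogps:::new_pseudo_field("O", 1,
    a$centers)), "probe mismatch")
})

test_that("overlap never exceeds the smaller volume, even with uneven weights", {
  mk <- function(x, w) biogps:::new_pseudo_field("H", 1,
    data.frame(x = x, y = 0, z = 0, weight = w, atom = seq_along(x)))
  a <- mk(0, 2); b <- mk(0, 1)
  ov <- field_overlap(a, b)
  expect_lte(ov["V_overlap"], min(ov["V_a"], ov["V_b"]) * (1 + 1e-6))
})
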
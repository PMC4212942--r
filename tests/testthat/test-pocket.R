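# Lattice pocket detection: buriedness scan, manual serine override,
# invariances.

cup <- function(seed = 1) cached(sprintf("cup_%d", seed),
  make_toy_pocket(pocket_recipe(seed, fractions = fixture_classes()$donor)))

# independent naive buriedness/accessibility check for a single point
naive_node_status <- function(s, p, scan_range = 8, spacing = 1,
                              probe_radius = 1.4) {
  xyz <- coords(s)
  radii <- biogps:::vdw_radius(s$atoms$element)
  surf <- sqrt(rowSums(sweep(xyz, 2, p)^2)) - radii
  accessible <- min(surf) >= probe_radius
  dirs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  dirs <- dirs[rowSums(abs(dirs)) > 0, ]
  hits <- 0L
  for (d in seq_len(nrow(dirs))) {
    v <- dirs[d, ]
    nstep <- floor(scan_range / (spacing * sqrt(sum(v^2))))
    hit <- FALSE
    for (m in seq_len(nstep)) {
      q <- p + m * spacing * v
      if (any(sqrt(rowSums(sweep(xyz, 2, q)^2)) < radii)) { hit <- TRUE; break }
    }
    hits <- hits + hit
  }
  list(accessible = accessible, buried = hits)
}

test_that("detected cup pocket is buried, accessible and holds the focal point", {
  s <- cup()
  p <- detect_pocket(s)
  expect_s3_class(p, "biogps_pocket")
  expect_gt(length(p$idx), 10)
  focal <- attr(s, "focal_point")
  expect_lt(min(sqrt(rowSums(sweep(p$coords, 2, focal)^2))),
            p$grid$spacing)            # a mask node sits at the focal point
  # every node is outside the vdW volume; nodes stay below the wall rim
  rim_z <- 0.65 * (attr(s, "recipe")$radius + 2.5)
  expect_true(all(p$coords[, 3] <= rim_z + p$grid$spacing))
  # independent brute-force oracle on a sample of mask nodes
  set.seed(1)
  for (i in sample(length(p$idx), 8)) {
    st <- naive_node_status(s, p$coords[i, ])
    expect_true(st$accessible)
    expect_gte(st$buried, 12)   # hysteresis floor: b_min - 2
  }
})

test_that("a convex slab has no pocket", {
  g <- expand.grid(x = seq(0, 12, 2), y = seq(0, 12, 2), z = c(0, 2))
  atoms <- data.frame(serial = seq_len(nrow(g)), name = "CA",
                      resname = "GLY", chain = "A", resno = seq_len(nrow(g)),
                      insert = "", x = g$x, y = g$y, z = g$z,
                      element = "C", type = "ATOM")
  slab <- biogps:::new_structure("slab", atoms)
  expect_error(detect_pocket(slab), "no pocket")
})

test_that("a hollow sphere yields its interior void", {
  d <- biogps:::cap_directions(220, 1)   # full sphere
  r <- 6.5
  atoms <- data.frame(serial = seq_len(nrow(d)), name = "CA",
                      resname = "GLY", chain = "A", resno = seq_len(nrow(d)),
                      insert = "", x = r * d[, 1], y = r * d[, 2],
                      z = r * d[, 3], element = "C", type = "ATOM")
  sphere <- biogps:::new_structure("sphere", atoms)
  p <- detect_pocket(sphere)
  expect_true(all(sqrt(rowSums(p$coords^2)) < r))   # inside the shell
  expect_lt(min(sqrt(rowSums(p$coords^2))), p$grid$spacing)  # has the center
})

test_that("serine-ball pocket matches brute-force accessible-node count", {
  s <- cup()
  og <- attr(s, "focal_point")
  # use the nearest lining nitrogen as a stand-in anchor atom
  ni <- which(s$atoms$name == "N")[1]
  p <- pocket_from_serine(s, ni, radius = 6)
  # brute force: accessible grid nodes within the ball
  g <- p$grid
  xyz <- coords(s)
  radii <- biogps:::vdw_radius(s$atoms$element)
  axes <- biogps:::grid_axes(g)
  nodes <- as.matrix(expand.grid(axes[[1]], axes[[2]], axes[[3]]))
  anchor <- as.numeric(xyz[ni, ])
  inball <- rowSums(sweep(nodes, 2, anchor)^2) <= 36
  acc <- rep(TRUE, nrow(nodes))
  for (a in seq_len(nrow(xyz)))
    acc <- acc & sqrt(rowSums(sweep(nodes, 2, xyz[a, ])^2)) >= radii[a] + 1.4
  expect_equal(length(p$idx), sum(inball & acc))
})

test_that("serine-ball pocket grows monotonically with radius and errors when empty", {
  s <- cup()
  ni <- which(s$atoms$name == "N")[1]
  n1 <- length(pocket_from_serine(s, ni, radius = 5)$idx)
  n2 <- length(pocket_from_serine(s, ni, radius = 10)$idx)
  expect_gte(n2, n1)
  expect_error(pocket_from_serine(s, ni, radius = 0.4), "no pocket")
  expect_error(pocket_from_serine(s, "SER 999 OG"), "matches no atom")
})

test_that("pocket mask is stable under rigid motion of the structure", {
  s <- cup(3)
  p0 <- detect_pocket(s)
  tr <- random_transform(17, trans_scale = 3)
  sm <- apply_transform(tr, s)
  p1 <- detect_pocket(sm)
  # map moved mask back and count agreement within one spacing
  back <- apply_transform(invert_transform(tr), p1$coords)
  agree <- vapply(seq_len(nrow(back)), function(i)
    min(rowSums(sweep(p0$coords, 2, back[i, ])^2)) <= p0$grid$spacing^2,
    logical(1))
  expect_gte(mean(agree), 0.9)
  agree0 <- vapply(seq_len(nrow(p0$coords)), function(i)
    min(rowSums(sweep(back, 2, p0$coords[i, ])^2)) <= p0$grid$spacing^2,
    logical(1))
  expect_gte(mean(agree0), 0.9)
})

test_that("grid specification covers the structure with margin", {
  s <- cup()
  g <- grid_spec(s, spacing = 1, margin = 4)
  xyz <- coords(s)
  expect_true(all(g$origin <= apply(xyz, 2, min) - 4 + 1e-9))
  top <- g$origin + (g$dim - 1) * g$spacing
  expect_true(all(top >= apply(xyz, 2, max) + 4 - 1))
  expect_error(grid_spec(s, spacing = 0), "spacing")
})

test_that("DX export round-trips grid geometry", {
  s <- cup()
  p <- detect_pocket(s)
  tf <- tempfile(fileext = ".dx")
  on.exit(unlink(tf))
  write_dx(p, NULL, tf)
  lines <- readLines(tf)
  expect_match(lines[1], sprintf("counts %d %d %d", p$grid$dim[1],
                                 p$grid$dim[2], p$grid$dim[3]))
  nvals <- sum(vapply(lines[8:(length(lines) - 1)],
                      function(l) length(strsplit(trimws(l), " ")[[1]]),
                      integer(1)))
  expect_equal(nvals, prod(p$grid$dim))
  vals <- as.numeric(unlist(strsplit(trimws(
    lines[8:(length(lines) - 1)]), " ")))
  expect_equal(sum(vals), length(p$idx))   # 0/1 mask sums to node count
})
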
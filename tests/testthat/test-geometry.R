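# Hydrogen bonds, close contacts, mean planes, interplanar angles.

test_that("mean planes minimize perpendicular deviation and orient deterministically", {
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  pl <- mean_plane(pts)
  expect_equal(pl$rms, 0, tolerance = 1e-12)
  expect_equal(abs(pl$normal), c(0, 0, 1), tolerance = 1e-12)
  expect_gte(pl$normal[which(abs(pl$normal) > 1e-12)[1]], 0)
  expect_error(mean_plane(rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))),
               "collinear")
  # rms equals the smallest-eigenvalue oracle on random clouds
  for (seed in 1:50) {
    set.seed(seed)
    cloud <- matrix(rnorm(30), 10, 3) %*% diag(c(3, 2, 0.3))
    pl <- mean_plane(cloud)
    ev <- eigen(crossprod(sweep(cloud, 2, colMeans(cloud))),
                symmetric = TRUE)$values
    expect_equal(pl$rms, sqrt(min(ev) / nrow(cloud)), tolerance = 1e-9)
  }
})

test_that("interplanar angles are acute, symmetric and rigid-motion invariant", {
  p1 <- mean_plane(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  expect_equal(interplanar_angle(p1, p1), 0)
  p2 <- mean_plane(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1)))
  expect_equal(interplanar_angle(p1, p2), 90)
  for (seed in 1:10) {
    set.seed(seed)
    a <- matrix(rnorm(12), 4, 3)
    b <- matrix(rnorm(12), 4, 3)
    ang <- interplanar_angle(mean_plane(a), mean_plane(b))
    expect_equal(interplanar_angle(mean_plane(b), mean_plane(a)), ang)
    expect_gte(ang, 0); expect_lte(ang, 90)
    ar <- rigid_transform(a, seed + 100)
    br <- rigid_transform(rbind(a, b), seed + 100)[5:8, ]
    a2 <- rigid_transform(a, seed + 100)
    both <- rigid_transform(rbind(a, b), seed + 200)
    expect_equal(interplanar_angle(mean_plane(both[1:4, ]),
                                   mean_plane(both[5:8, ])), ang,
                 tolerance = 1e-6)
  }
})

test_that("the host template reproduces its designed interplanar angle", {
  host <- make_toy_molecule("host")
  core <- c("N1", "C2", "C3", "C3A", "C7A", "C4", "C5", "C6", "C7")
  aryl <- c("C9", "C10", "C11", "C12", "C13", "C14")
  p1 <- mean_plane(host$atoms[match(core, host$atoms$label), ])
  p2 <- mean_plane(host$atoms[match(aryl, host$atoms$label), ])
  expect_equal(interplanar_angle(p1, p2), 42, tolerance = 0.1 / 42)
})

test_that("constructed O-H...O geometries pass or fail the criteria as built", {
  # linear donor-H...acceptor at D...A = 2.80
  mk <- function(angle_dha) {
    t <- (180 - angle_dha) * pi / 180
    cell <- unit_cell(20, 21, 22)
    don <- c(5, 5, 5)
    h <- don + c(0.96, 0, 0)
    a <- h + 1.9 * c(cos(t), sin(t), 0)
    xyz <- rbind(don, h, a)
    f <- cart_to_frac(cell, xyz)
    ct <- cell_contents("hb", cell, list(parse_symop("x, y, z")),
                        tibble::tibble(label = c("O1", "H1", "O2"),
                                       element = c("O", "H", "O"),
                                       x = f[, 1], y = f[, 2], z = f[, 3],
                                       occupancy = 1))
    crystal_structure(ct)
  }
  hb <- find_hydrogen_bonds(mk(180))
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$angle_dha, 180, tolerance = 1e-6)
  expect_equal(nrow(find_hydrogen_bonds(mk(90))), 0L)
})

test_that("hydrogen-bond detection equals the all-images brute force", {
  for (kind in c("inversion_dimer", "hydrate_channel", "catamer")) {
    st <- crystal_structure(build_crystal(motif_spec(kind, seed = 2))$contents)
    hb <- find_hydrogen_bonds(st)
    got <- sort(unique(paste(hb$donor, hb$acceptor, round(hb$d_da, 3),
                             round(hb$angle_dha, 1))))
    expect_identical(got, oracle_hbond_keys(st), label = kind)
  }
  # dimer ground truth: one symmetry-distinct N-H...O at the target distance
  st <- crystal_structure(build_crystal(motif_spec("inversion_dimer"))$contents)
  hb <- find_hydrogen_bonds(st)
  no <- hb[hb$acceptor == "O1", ]
  expect_equal(nrow(no), 1L)
  expect_equal(no$d_da, 2.87, tolerance = 0.01 / 2.87)
})

test_that("unmodelled water hydrogens fall back to distance-only candidates", {
  cell <- unit_cell(15, 15, 15)
  xyz <- rbind(c(5, 5, 5), c(7.8, 5, 5))
  f <- cart_to_frac(cell, xyz)
  ct <- cell_contents("bare", cell, list(parse_symop("x, y, z")),
                      tibble::tibble(label = c("O1W", "O2W"),
                                     element = "O",
                                     x = f[, 1], y = f[, 2], z = f[, 3],
                                     occupancy = 1))
  hb <- find_hydrogen_bonds(crystal_structure(ct))
  expect_equal(nrow(hb), 0L)
  cand <- attr(hb, "da_only")
  expect_gte(nrow(cand), 1L)
  expect_equal(cand$d_da[1], 2.8, tolerance = 1e-6)
})

test_that("close contacts match table arithmetic and the brute-force oracle", {
  # C...H at 2.80 with vdW sum 2.90 -> one contact, gap -0.10
  cell <- unit_cell(18, 18, 18)
  xyz <- rbind(c(4, 4, 4), c(6.8, 4, 4))
  f <- cart_to_frac(cell, xyz)
  ct <- cell_contents("ch", cell, list(parse_symop("x, y, z")),
                      tibble::tibble(label = c("C1", "H1"),
                                     element = c("C", "H"),
                                     x = f[, 1], y = f[, 2], z = f[, 3],
                                     occupancy = 1))
  st <- crystal_structure(ct)
  cc <- find_close_contacts(st)
  expect_equal(nrow(cc), 1L)
  expect_equal(cc$gap, -0.10, tolerance = 1e-6)
  expect_equal(cc$vdw_sum, 2.90)
  # separated molecules give no contact at margin 0
  xyz2 <- rbind(c(4, 4, 4), c(4 + 2.9 + 0.5, 4, 4))
  f2 <- cart_to_frac(cell, xyz2)
  ct2 <- ct
  ct2$sites$x <- f2[, 1]
  expect_equal(nrow(find_close_contacts(crystal_structure(ct2))), 0L)
  # randomized fixtures against the brute force
  for (seed in 1:6) {
    st <- random_small_structure(seed)
    cc <- find_close_contacts(st, margin = 0.5)
    got <- sort(unique(paste(cc$label_i, cc$label_j, round(cc$distance, 3))))
    expect_identical(got, oracle_contact_keys(st, margin = 0.5),
                     label = paste("seed", seed))
  }
})

test_that("hydrogen-bond and contact detection agree with brute force on random fixtures", {
  for (seed in 7:20) {
    st <- random_small_structure(seed)
    hb <- find_hydrogen_bonds(st)
    got <- sort(unique(paste(hb$donor, hb$acceptor, round(hb$d_da, 3),
                             round(hb$angle_dha, 1))))
    expect_identical(got, oracle_hbond_keys(st), label = paste("hb seed", seed))
  }
})
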
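test_that("angle normalization is congruent, idempotent and half-open", {
  expect_equal(normalize_angle(540), 180)
  expect_equal(normalize_angle(-180), 180)
  expect_equal(normalize_angle(37.5), 37.5)
  x <- runif(200, -1000, 1000)
  n1 <- normalize_angle(x)
  expect_true(all(n1 > -180 & n1 <= 180))
  expect_equal(normalize_angle(n1), n1)
  expect_equal(normalize_angle(x + 360), n1)
  expect_true(all(abs((x - n1) %% 360) < 1e-9))
  expect_error(normalize_angle(NaN), "finite")
})

test_that("periodic angle distance is the shortest arc", {
  expect_equal(periodic_angle_distance(-179, 180), 1)
  expect_equal(periodic_angle_distance(42, 42), 0)
  expect_equal(periodic_angle_distance(90, -90), 180)
  a <- runif(300, -180, 180); b <- runif(300, -180, 180)
  expect_equal(periodic_angle_distance(a, b), periodic_angle_distance(b, a))
  expect_true(all(periodic_angle_distance(a, b) >= 0 &
                  periodic_angle_distance(a, b) <= 180))
})

test_that("torsion distance is a metric on the torus", {
  expect_equal(torsion_distance(-179, 180), 1)
  expect_equal(torsion_distance(c(0, 0), c(30, 40)), 50)
  p <- runif(4, -180, 180)
  expect_equal(torsion_distance(p, p), 0)
  expect_error(torsion_distance(c(0, 0), c(0, 0, 0)), "dimension")
  set.seed(7)
  for (i in 1:50) {
    n <- sample(1:4, 1)
    p <- runif(n, -180, 180); q <- runif(n, -180, 180); r <- runif(n, -180, 180)
    dpq <- torsion_distance(p, q)
    expect_gte(dpq, 0)
    expect_equal(dpq, torsion_distance(q, p))
    expect_lte(dpq, torsion_distance(p, r) + torsion_distance(r, q) + 1e-12)
  }
})

test_that("aggregate distance below a cutoff bounds every component", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(1:4, 1)
    p <- runif(n, -180, 180); q <- runif(n, -180, 180)
    if (torsion_distance(p, q) < 40)
      expect_true(all(periodic_angle_distance(p, q) < 40))
  }
})

test_that("circular statistics handle the wrap", {
  expect_equal(circular_mean(c(58, 62)), 60)
  expect_equal(circular_sd(c(58, 62)), 2)
  expect_equal(circular_mean(c(179, -179)), 180)
  expect_equal(circular_sd(c(179, -179)), 1)
  expect_error(circular_mean(c(0, 180)), "undefined")
})

test_that("dihedral angle follows the IUPAC sign convention", {
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)),
               180)
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
               0)
  set.seed(3)
  for (i in 1:20) {
    p <- matrix(rnorm(12), 4, 3)
    d <- tryCatch(dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ]),
                  error = function(e) NULL)
    if (is.null(d)) next
    pm <- p; pm[, 3] <- -pm[, 3]  # mirror image negates the angle
    expect_equal(dihedral_angle(pm[1, ], pm[2, ], pm[3, ], pm[4, ]),
                 -d, tolerance = 1e-9)
    # rigid motion invariance
    th <- runif(3, 0, 2 * pi)
    Rz <- matrix(c(cos(th[1]), -sin(th[1]), 0, sin(th[1]), cos(th[1]), 0,
                   0, 0, 1), 3, 3)
    Rx <- matrix(c(1, 0, 0, 0, cos(th[2]), -sin(th[2]),
                   0, sin(th[2]), cos(th[2])), 3, 3)
    pr <- p %*% (Rz %*% Rx) + matrix(rnorm(3), 4, 3, byrow = TRUE)
    expect_equal(dihedral_angle(pr[1, ], pr[2, ], pr[3, ], pr[4, ]), d,
                 tolerance = 1e-8)
  }
  expect_error(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "degenerate")
})

test_that("dihedral angles agree with an independent implementation", {
  set.seed(5)
  for (i in 1:25) {
    p <- matrix(rnorm(12, sd = 2), 4, 3)
    mine <- tryCatch(dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ]),
                     error = function(e) NULL)
    if (is.null(mine)) next
    ref <- bio3d::torsion.xyz(as.numeric(t(p)), atm.inc = 4)
    expect_equal(periodic_angle_distance(mine, ref[1]), 0, tolerance = 1e-6)
  }
})

test_that("rotating about a bond changes only that dihedral", {
  frag <- build_sidechain_fragment("LYS", c(-60, 180, 60, 180))
  chi0 <- extract_sidechain_torsions(frag, 1L)
  expect_equal(chi0, c(-60, 180, 60, 180), tolerance = 1e-8)
  # +60 about the chi1 bond moves chi1 only
  xyz <- rotate_about_bond(frag$xyz, 2L, 3L, 4:7, 60)
  rot <- conformation(xyz, frag$atoms)
  chi1 <- extract_sidechain_torsions(rot, 1L)
  expect_equal(chi1, c(0, 180, 60, 180), tolerance = 1e-8)
  # full turn is the identity
  xyz360 <- rotate_about_bond(frag$xyz, 2L, 3L, 4:7, 360)
  expect_equal(xyz360, frag$xyz, tolerance = 1e-9)
  # a rotation followed by its inverse restores the coordinates
  back <- rotate_about_bond(rotate_about_bond(frag$xyz, 2L, 3L, 4:7, 37.3),
                            2L, 3L, 4:7, -37.3)
  expect_equal(back, frag$xyz, tolerance = 1e-9)
})

test_that("side-chain torsion extraction is canonical and validated", {
  ser <- build_sidechain_fragment("SER", 180)
  expect_equal(extract_sidechain_torsions(ser, 1L), 180, tolerance = 1e-6)
  ala <- conformation(matrix(rnorm(9), 3, 3),
                      data.frame(resno = 1L, resid = "ALA",
                                 elety = c("N", "CA", "CB")))
  expect_error(extract_sidechain_torsions(ala, 1L), "no chi")
  # missing atom is named in the error
  ser_broken <- conformation(ser$xyz[-4, ], ser$atoms[-4, ])
  expect_error(extract_sidechain_torsions(ser_broken, 1L), "OG")
})
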
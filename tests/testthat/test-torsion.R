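test_that("wrap_angle maps to the half-open interval [-180, 180)", {
  expect_equal(wrap_angle(c(185, -180, 180, 540, 0, -185)),
               c(-175, -180, -180, -180, 0, 175))
  x <- seq(-1000, 1000, by = 7.3)
  w <- wrap_angle(x)
  expect_true(all(w >= -180 & w < 180))
  # wrapping preserves the angle modulo 360
  expect_equal((w - x) %% 360, rep(0, length(x)))
})

test_that("dihedral_angle reproduces cis = 0 and trans = -180", {
  # four points in a plane: eclipsed (cis) and anti (trans) butane-like chains
  p2 <- c(0, 0, 0); p3 <- c(1.5, 0, 0)
  cis <- dihedral_angle(c(-0.5, 1, 0), p2, p3, c(2.0, 1, 0))
  trans <- dihedral_angle(c(-0.5, 1, 0), p2, p3, c(2.0, -1, 0))
  expect_equal(cis, 0, tolerance = 1e-12)
  expect_equal(trans, -180, tolerance = 1e-12)
})

test_that("dihedral_angle matches the bio3d oracle on random geometries", {
  set.seed(42)
  for (i in 1:25) {
    pts <- matrix(rnorm(12, sd = 2), 4, 3)
    ours <- dihedral_angle(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    ref <- bio3d::torsion.xyz(as.vector(t(pts)), atm.inc = 4)
    expect_equal(ours, wrap_angle(ref[1]), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("dihedral_angle is invariant under rigid motion", {
  set.seed(7)
  for (i in 1:10) {
    pts <- matrix(rnorm(12, sd = 3), 4, 3)
    base <- dihedral_angle(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    move <- random_rigid(i)
    moved <- dihedral_angle(move(pts[1, ]), move(pts[2, ]),
                            move(pts[3, ]), move(pts[4, ]))
    # compare on the circle (wrap-around at -180/180)
    expect_lt(abs(wrap_angle(moved - base)), 1e-6)
  }
})

test_that("dihedral_angle rejects degenerate geometry", {
  p <- c(0, 0, 0)
  expect_error(dihedral_angle(c(1, 0, 0), p, p, c(0, 1, 0)), "degenerate")
  expect_error(dihedral_angle(c(2, 0, 0), c(1, 0, 0), c(0, 0, 0), c(-1, 0, 0)),
               "collinear")
})

test_that("torsion_trajectory validates its inputs", {
  expect_error(torsion_trajectory(array(0, c(3, 2, 3)), times = 1:3),
               "frames x residues x 2")
  expect_error(torsion_trajectory(array(0, c(3, 2, 2)), times = 1:2),
               "frames")
  a <- array(0, c(3, 2, 2)); a[2, 1, 1] <- NA
  expect_error(torsion_trajectory(a, times = 1:3), "non-finite")
  expect_error(torsion_trajectory(array(0, c(3, 2, 2)), times = c(0, 30, 30)),
               "strictly increasing")
  tr <- tiny_trajectory()
  expect_s3_class(tr, "torsion_trajectory")
  expect_identical(n_frames(tr), 3L)
  expect_identical(n_residues(tr), 2L)
  expect_true(all(tr$angles >= -180 & tr$angles < 180))
})

test_that("torsion tables round-trip through write/read", {
  tr <- simulate_trajectory(synthetic_spec(n_residues = 5, n_frames = 7,
                                           seed = 3),
                            "benign", seed = 11, variant_id = "rt")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_torsion_table(tr, path)
  back <- read_torsion_table(path, variant_id = "rt")
  expect_equal(back$angles, tr$angles, tolerance = 1e-6)
  expect_equal(back$times, tr$times)
  expect_identical(back$residue_ids, tr$residue_ids)
  expect_identical(back$variant_id, "rt")
})

test_that("single-frame and single-residue trajectories round-trip", {
  for (dims in list(c(1, 4), c(5, 1))) {
    a <- array(seq_len(dims[1] * dims[2] * 2) * 13 %% 360 - 180,
               c(dims[1], dims[2], 2))
    tr <- torsion_trajectory(a, times = (seq_len(dims[1]) - 1) * 30)
    path <- withr::local_tempfile(fileext = ".tsv")
    write_torsion_table(tr, path)
    back <- read_torsion_table(path)
    expect_equal(back$angles, tr$angles, tolerance = 1e-6)
  }
})

test_that("read_torsion_table rejects malformed tables with named offenders", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("frame\ttime_ps\tresidue\tphi\tpsi",
               "0\t0\t1\t10\t20", "0\t0\t1\t11\t21"), path)
  expect_error(read_torsion_table(path), "duplicated \\(frame, residue\\)")
  writeLines(c("frame\ttime_ps\tresidue\tphi\tpsi",
               "0\t0\t1\t10\t20", "0\t0\t2\t10\t20",
               "1\t30\t1\t10\t20"), path)
  expect_error(read_torsion_table(path), "frame 1 .* all 2 residues")
  writeLines(c("frame\ttime_ps\tresidue\tphi\tpsi",
               "0\t30\t1\t10\t20", "1\t30\t1\t10\t20"), path)
  expect_error(read_torsion_table(path), "strictly increasing")
  writeLines(c("frame\ttime_ps\tresidue\tphi", "0\t0\t1\t10"), path)
  expect_error(read_torsion_table(path), "missing column.*psi")
})

test_that("read_torsion_table wraps angles and skips comments", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# a comment", "frame\ttime_ps\tresidue\tphi\tpsi",
               "0\t0\t1\t185\t-180", "1\t30\t1\t360\t180"), path)
  tr <- read_torsion_table(path)
  expect_equal(tr$angles[1, 1, ], c(-175, -180))
  expect_equal(tr$angles[2, 1, ], c(0, -180))
})

test_that("select_window is half-open and counts 334 frames for the last 10 ns", {
  a <- array(0, c(1334, 1, 2))
  tr <- torsion_trajectory(a, times = (0:1333) * 30)
  win <- select_window(tr, 30000, 40000)
  expect_identical(n_frames(win), 334L)
  expect_true(all(win$times >= 30000 & win$times < 40000))
  # boundary frame at end_ps is excluded, at start_ps included
  one <- select_window(tr, 30000, 30030)
  expect_identical(n_frames(one), 1L)
  expect_equal(one$times, 30000)
  # composition: windowing twice equals the intersection window
  expect_equal(select_window(select_window(tr, 15000, 40000), 30000, 40000)$times,
               win$times)
  expect_error(select_window(tr, 100, 100), "start_ps")
  expect_error(select_window(tr, 50000, 60000), "no frames")
})

test_that("torsion_from_coords drops terminal residues and matches dihedral_angle", {
  set.seed(5)
  nf <- 2L; nr <- 5L
  coords <- array(rnorm(nf * nr * 9, sd = 3), c(nf, nr, 3, 3))
  # spread residues along x so geometries are far from degenerate
  for (r in seq_len(nr)) coords[, r, , 1] <- coords[, r, , 1] + 5 * r
  tr <- torsion_from_coords(coords, times = c(0, 30))
  expect_identical(n_residues(tr), nr - 2L)
  expect_identical(tr$residue_ids, 2:(nr - 1L))
  expect_identical(attr(tr, "dropped_residues"), c(1L, nr))
  f <- 1; i <- 3
  expect_equal(tr$angles[f, i - 1, 1],
               dihedral_angle(coords[f, i - 1, 3, ], coords[f, i, 1, ],
                              coords[f, i, 2, ], coords[f, i, 3, ]))
  expect_equal(tr$angles[f, i - 1, 2],
               dihedral_angle(coords[f, i, 1, ], coords[f, i, 2, ],
                              coords[f, i, 3, ], coords[f, i + 1, 1, ]))
})

test_that("variant manifests validate labels and round-trip as CSV", {
  m <- variant_manifest(c("A", "B"), "g1", c("benign", "pathogenic"))
  expect_s3_class(m, "variant_manifest")
  expect_error(variant_manifest("A", "g", "bad_label"), "class_label")
  expect_error(variant_manifest(c("A", "A"), "g", c("wt", "wt")), "unique")
  path <- withr::local_tempfile(fileext = ".csv")
  write_manifest(m, path)
  back <- read_manifest(path)
  expect_equal(back$variant_id, m$variant_id)
  expect_equal(back$class_label, m$class_label)
})
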
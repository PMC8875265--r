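test_that("xyz parser reads plain and extended frames", {
  path <- write_xyz_text(c(
    "3", "first frame",
    "O 0.0 0.0 0.0", "H 0.0 0.0 1.0", "N 0.0 0.0 2.8",
    "3", "second frame",
    "O 0.0 0.0 0.0", "H 0.0 0.0 1.7", "N 0.0 0.0 2.8"))
  tr <- read_xyz_trajectory(path, dt = 0.5)
  expect_equal(n_frames(tr), 2L)
  expect_equal(tr$symbols, c("O", "H", "N"))
  expect_equal(tr$coords[[2]][2, 3], 1.7)
  expect_null(tr$cell)

  ext <- write_xyz_text(c(
    "2",
    'Lattice="10.0 0.0 0.0 0.0 10.0 0.0 0.0 0.0 25.0" Properties=species:S:1:pos:R:3',
    "Si 1.0 1.0 1.0", "O 9.5 1.0 1.0"))
  tr2 <- read_xyz_trajectory(ext, dt = 0.5)
  expect_equal(tr2$cell, diag(c(10, 10, 25)))
})

test_that("xyz parser reports malformed input with the frame index", {
  bad <- write_xyz_text(c("3", "hdr", "O 0 0 0", "H 0 0 1", "N 0 0 2",
                          "x", "hdr", "O 0 0 0"))
  expect_error(read_xyz_trajectory(bad, dt = 0.5), "frame 2")
  short <- write_xyz_text(c("4", "hdr", "O 0 0 0", "H 0 0 1"))
  expect_error(read_xyz_trajectory(short, dt = 0.5), "truncated")
  swapped <- write_xyz_text(c("2", "a", "O 0 0 0", "H 0 0 1",
                              "2", "b", "H 0 0 0", "O 0 0 1"))
  expect_error(read_xyz_trajectory(swapped, dt = 0.5), "frame 2")
})

test_that("xyz write/read round-trips coordinates", {
  tr <- random_trajectory(n_atoms = 7, n_frames = 4,
                          cell = diag(c(12, 12, 25)), seed = 5)
  path <- tempfile(fileext = ".xyz")
  write_xyz_trajectory(tr, path)
  tr2 <- read_xyz_trajectory(path, dt = tr$dt)
  expect_equal(tr2$symbols, tr$symbols)
  expect_equal(tr2$cell, tr$cell, tolerance = 1e-8)
  for (f in seq_len(n_frames(tr))) {
    expect_equal(tr2$coords[[f]], tr$coords[[f]], tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("trajectory duration follows (n_frames - 1) * dt", {
  # 12 ps sampled at 0.5 fs -> 24001 frames
  n <- 12 * 1000 / 0.5 + 1
  coords <- rep(list(matrix(0, 1, 3)), n)
  tr <- trajectory("H", coords, dt = 0.5)
  expect_equal(n_frames(tr), 24001L)
  expect_equal(duration_ps(tr), 12)
})

test_that("rmsd matches a brute-force per-atom oracle on random inputs", {
  for (seed in 1:5) {
    tr <- random_trajectory(n_atoms = 10, n_frames = 5, seed = seed)
    rs <- rmsd_series(tr)
    for (f in 1:5) {
      expect_equal(rs$rmsd[f],
                   brute_rmsd(tr$coords[[f]], tr$coords[[1]]),
                   tolerance = 1e-12)
    }
    expect_identical(rs$rmsd[1], 0)
    expect_true(all(rs$rmsd >= 0))
  }
})

test_that("rmsd reproduces hand-evaluated displacement cases", {
  ref <- matrix(c(0, 0, 0, 1, 1, 1), ncol = 3, byrow = TRUE)
  moved <- ref
  moved[1, ] <- moved[1, ] + c(1, 0, 0)
  tr <- trajectory(c("C", "C"), list(ref, moved), dt = 1)
  expect_equal(rmsd_series(tr)$rmsd[2], sqrt(1 / 2), tolerance = 1e-12)

  # uniform translation with align off registers as |t|
  t_vec <- c(0.3, -1.2, 2.0)
  shifted <- sweep(ref, 2, -t_vec)
  tr2 <- trajectory(c("C", "C"), list(ref, shifted), dt = 1)
  expect_equal(rmsd_series(tr2)$rmsd[2], sqrt(sum(t_vec^2)),
               tolerance = 1e-12)
  # ... and vanishes under optimal superposition
  expect_equal(rmsd_series(tr2, align = TRUE)$rmsd[2], 0,
               tolerance = 1e-10)
})

test_that("rmsd selection by index and element works; empty selection errors", {
  tr <- random_trajectory(n_atoms = 6, n_frames = 3, seed = 9)
  rs_h <- rmsd_series(tr, selection = "H")
  sel <- which(tr$symbols == "H")
  expect_equal(rs_h$rmsd[3],
               brute_rmsd(tr$coords[[3]][sel, ], tr$coords[[1]][sel, ]),
               tolerance = 1e-12)
  expect_error(rmsd_series(tr, selection = integer(0)), "empty")
  expect_error(rmsd_series(tr, selection = 99), "out of range")
})

test_that("pair distances are symmetric and honour the minimum image", {
  tr <- trajectory(c("O", "N"),
                   list(matrix(c(0, 0, 0, 0, 0, 1.75), ncol = 3,
                               byrow = TRUE)), dt = 1)
  expect_equal(pair_distance_series(tr, 1, 2)$distance, 1.75)
  expect_equal(pair_distance_series(tr, 2, 1)$distance,
               pair_distance_series(tr, 1, 2)$distance)
  expect_error(pair_distance_series(tr, 1, 1), "distinct")

  cell <- diag(c(10, 10, 10))
  tr2 <- trajectory(c("O", "N"),
                    list(matrix(c(1, 0, 0, 9.5, 0, 0), ncol = 3,
                                byrow = TRUE)), dt = 1, cell = cell)
  expect_equal(pair_distance_series(tr2, 1, 2,
                                    minimum_image = TRUE)$distance, 1.5)
  # triclinic cells against the 27-image oracle
  set.seed(21)
  tricell <- matrix(c(9, 0, 0, 1.5, 8, 0, 0.5, 1.0, 11), ncol = 3,
                    byrow = TRUE)
  for (rep in 1:20) {
    p <- matrix(runif(6, -5, 15), ncol = 3, byrow = TRUE)
    tr3 <- trajectory(c("O", "N"), list(p), dt = 1, cell = tricell)
    expect_equal(
      pair_distance_series(tr3, 1, 2, minimum_image = TRUE)$distance,
      brute_mic_distance(p[1, ], p[2, ], tricell), tolerance = 1e-10)
  }
})

test_that("histogram conserves counts and the Gaussian fit recovers moments", {
  set.seed(2024)
  x <- rnorm(1e5, mean = 1.75, sd = 0.10)
  h <- hbond_histogram(x, bins = 80)
  expect_equal(sum(h$counts), length(x))
  expect_equal(h$fit_mean, 1.75, tolerance = 0.01)
  expect_equal(h$fit_sigma, 0.10, tolerance = 0.01)
  # count conservation for arbitrary binning
  for (nb in c(5, 17, 133)) {
    expect_equal(sum(hbond_histogram(x, bins = nb, fit = FALSE)$counts),
                 length(x))
  }
})

test_that("degenerate and bimodal series are handled sensibly", {
  expect_warning(h <- hbond_histogram(rep(1.75, 50)), "constant|degenerate")
  expect_true(is.na(h$fit_mean))
  expect_equal(sum(h$counts), 50)

  set.seed(7)
  mix <- c(rnorm(5e4, 1.75, 0.09), rnorm(5e4, 1.05, 0.05))
  hm <- hbond_histogram(mix, bins = 100)
  # a single Gaussian fitted to a well-separated two-state mixture stays
  # within the interval spanned by the state means (it may lock onto the
  # dominant mode)
  expect_gte(hm$fit_mean, 1.04)
  expect_lte(hm$fit_mean, 1.76)
})
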
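# Independent brute-force oracles and tiny fixture builders used across the
# suite. Oracles deliberately avoid the package's code paths.

# per-atom-loop RMSD, no vectorization
brute_rmsd <- function(frame, ref) {
  stopifnot(nrow(frame) == nrow(ref))
  acc <- 0
  for (i in seq_len(nrow(frame))) {
    d <- frame[i, ] - ref[i, ]
    acc <- acc + sum(d^2)
  }
  sqrt(acc / nrow(frame))
}

# minimum-image distance by enumerating periodic images; the +-3 range
# covers raw separations of a few cell lengths
brute_mic_distance <- function(p1, p2, cell) {
  best <- Inf
  for (a in -3:3) for (b in -3:3) for (cc in -3:3) {
    img <- p2 + a * cell[1, ] + b * cell[2, ] + cc * cell[3, ]
    best <- min(best, sqrt(sum((img - p1)^2)))
  }
  best
}

# random small trajectory (in memory)
random_trajectory <- function(n_atoms = 10, n_frames = 5, dt = 0.5,
                              cell = NULL, seed = 42) {
  set.seed(seed)
  coords <- lapply(seq_len(n_frames), function(f) {
    matrix(runif(n_atoms * 3, 0, 10), ncol = 3)
  })
  trajectory(rep(c("C", "H"), length.out = n_atoms), coords, dt = dt,
             cell = cell)
}

# write a small xyz text fixture; returns the path
write_xyz_text <- function(lines) {
  path <- tempfile(fileext = ".xyz")
  writeLines(lines, path)
  path
}
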
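# Independent brute-force oracles used to freeze expected values.

# Direct O(n^4) unitary 2-D DFT, written against the definition; never uses
# stats::fft so it can stand as an independent check of the propagation code.
dft2 <- function(x, inverse = FALSE) {
  d <- dim(x)
  sgn <- if (inverse) 1 else -1
  out <- matrix(0 + 0i, d[1], d[2])
  for (u in 0:(d[1] - 1)) for (v in 0:(d[2] - 1)) {
    acc <- 0 + 0i
    for (a in 0:(d[1] - 1)) for (b in 0:(d[2] - 1))
      acc <- acc + x[a + 1, b + 1] *
        exp(sgn * 2i * pi * (u * a / d[1] + v * b / d[2]))
    out[u + 1, v + 1] <- acc
  }
  out / sqrt(prod(d))
}

random_complex <- function(nr, nc, seed) {
  withr::with_seed(seed,
    matrix(complex(real = rnorm(nr * nc), imaginary = rnorm(nr * nc)),
           nr, nc))
}

# A tiny consistent ptychographic problem for engine tests.
tiny_problem <- function(seed = 1, noise = "clean", I0 = 1e6,
                         canvas = c(32, 32), window = c(12, 12),
                         rows = 3, cols = 3, step = 4, jitter = 0.4) {
  phantom <- make_particle_phantom(canvas, n_particles = 12,
                                   radius_range = c(1.5, 3), seed = seed)
  probe <- make_probe(window, diameter = 8, softness = 0.4, defocus = 0.2)
  scan <- make_scan(rows, cols, step = step, canvas = canvas,
                    window = window, jitter = jitter, seed = seed + 1)
  sim <- simulate_dataset(phantom, probe, scan, I0 = I0, noise = noise,
                          noise_seed = seed + 2)
  sim
}
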
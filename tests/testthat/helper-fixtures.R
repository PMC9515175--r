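# Shared fixtures and independent oracles, all built in code.

# logical disk mask: pixel centers within radius of (cr, cc)
disk_mask <- function(dim, center, radius) {
  rr <- matrix(seq_len(dim[1L]), dim[1L], dim[2L]) - center[1L]
  cc <- matrix(seq_len(dim[2L]), dim[1L], dim[2L], byrow = TRUE) - center[2L]
  rr^2 + cc^2 <= radius^2
}

# brute-force Otsu oracle: exhaustive between-class-variance maximizer over
# all 256 candidate bin boundaries (independent of the package's cumulative
# formulation)
otsu_bruteforce <- function(v, n_bins = 256L) {
  bin <- pmin(pmax(floor(v * n_bins), 0), n_bins - 1L)
  mids <- (seq_len(n_bins) - 0.5) / n_bins
  best <- -Inf
  best_k <- NA_integer_
  for (k in seq_len(n_bins - 1L)) {        # threshold = k / n_bins
    lo <- bin < k
    w0 <- mean(lo)
    if (w0 == 0 || w0 == 1) next
    m0 <- mean(mids[bin[lo] + 1L])
    m1 <- mean(mids[bin[!lo] + 1L])
    s <- w0 * (1 - w0) * (m0 - m1)^2
    if (s > best + 1e-15) {
      best <- s
      best_k <- k
    }
  }
  best_k / n_bins
}

# seeded bimodal intensity image (two-Gaussian mixture, clipped to [0, 1])
bimodal_image <- function(seed, n = 1e4, means = c(0.3, 0.7), sd = 0.05) {
  set.seed(seed)
  which_mode <- sample(1:2, n, replace = TRUE)
  v <- pmin(pmax(stats::rnorm(n, means[which_mode], sd), 0), 1)
  side <- ceiling(sqrt(n))
  matrix(c(v, rep(v[1L], side^2 - n)), side, side)
}

# points on an ellipse boundary (x = col, y = row), rotated by theta
ellipse_points <- function(n, center, a, b, theta = 0) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-1L]
  x <- a * cos(t); y <- b * sin(t)
  xr <- x * cos(theta) - y * sin(theta)
  yr <- x * sin(theta) + y * cos(theta)
  cbind(row = center[1L] + yr, col = center[2L] + xr)
}

# control-spec colony at reduced resolution for fast cohort tests
small_spec <- function(...) {
  sc <- study_cohort_specs(scale = 0.5)
  modifyList_spec(sc$specs$control, list(...))
}

modifyList_spec <- function(spec, changes) {
  for (nm in names(changes)) spec[[nm]] <- changes[[nm]]
  spec
}

# one-sided treated spec at reduced resolution: exposed factor f, source east
treated_spec <- function(f, seed = 1L, noise_sd = 0.02, gradient = 0,
                         scale = 0.5) {
  sc <- study_cohort_specs(scale = scale, noise_sd = noise_sd)
  sp <- sc$specs$`1cm`
  sp$r_exposed <- sp$r_unexposed * f
  sp$gradient <- gradient
  sp$seed <- as.integer(seed)
  sp
}

make_disk_scene <- function(dims = c(221, 221), center = c(111, 111),
                            r_per = 100, r_core = 40) {
  per <- colony_contour(ellipse_points(720, center, r_per, r_per))
  core <- colony_contour(ellipse_points(400, center, r_core, r_core))
  line <- separating_line(experiment_layout("d", center, c(center[1L], 600),
                                            1, 1, "1cm"))
  list(per = per, core = core, line = line, dims = dims, center = center)
}
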
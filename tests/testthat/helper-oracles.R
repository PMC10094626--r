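# Independent oracles and scene helpers shared across the suite. Each oracle
# deliberately takes a different computational route than the implementation
# it checks.

# --- brute-force Difference-of-Gaussians oracle -----------------------------
# Direct 2-D windowed sum over a reflect-padded image (no separability, no
# compiled code). Kernel definition matches the detector's documented one:
# truncation at 3.5 sigma, normalized.

oracle_kernel_1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3.5 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# half-sample symmetric reflection of 1-based indices into [1, n]
oracle_reflect <- function(i, n) {
  vapply(i, function(v) {
    while (v < 1 || v > n) {
      if (v < 1) v <- 1 - v
      if (v > n) v <- 2 * n + 1 - v
    }
    v
  }, numeric(1))
}

oracle_blur_2d <- function(img, sigma) {
  k1 <- oracle_kernel_1d(sigma)
  r <- (length(k1) - 1L) / 2L
  K <- outer(k1, k1)
  nr <- nrow(img); nc <- ncol(img)
  pad <- img[oracle_reflect((1 - r):(nr + r), nr),
             oracle_reflect((1 - r):(nc + r), nc)]
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc))
    out[i, j] <- sum(K * pad[i:(i + 2 * r), j:(j + 2 * r)])
  out
}

oracle_dog <- function(img, sigma_small, sigma_large) {
  oracle_blur_2d(img, sigma_small) - oracle_blur_2d(img, sigma_large)
}

# --- balanced two-way ANOVA sums-of-squares oracle --------------------------
# Classical cell-mean decomposition, computed from first principles.

oracle_balanced_anova_ss <- function(y, a, b) {
  a <- factor(a); b <- factor(b)
  grand <- mean(y)
  m_a <- tapply(y, a, mean)
  m_b <- tapply(y, b, mean)
  m_ab <- tapply(y, list(a, b), mean)
  n_cell <- table(a, b)
  stopifnot(length(unique(as.vector(n_cell))) == 1L)
  n <- n_cell[1, 1]
  J <- nlevels(b); I <- nlevels(a)
  ss_a <- n * J * sum((m_a - grand)^2)
  ss_b <- n * I * sum((m_b - grand)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, rep(1, J)) -
                      outer(rep(1, I), m_b) + grand)^2)
  cell_of <- m_ab[cbind(as.integer(a), as.integer(b))]
  ss_e <- sum((y - cell_of)^2)
  list(ss_a = ss_a, ss_b = ss_b, ss_ab = ss_ab, ss_e = ss_e,
       ss_total = sum((y - grand)^2))
}

# A balanced 2 x 3 factorial with genotype, age and interaction effects, the
# layout of the behavioral readouts.
balanced_fixture <- function(n = 4, seed = 101) {
  set.seed(seed)
  g <- expand.grid(genotype = c("WT", "KO"),
                   age_group = c("6m", "12m", "18m"),
                   rep = seq_len(n))
  effects <- c(WT = 0, KO = -2)
  ages <- c("6m" = 0, "12m" = 1, "18m" = 2.5)
  g$value <- 10 + effects[g$genotype] + ages[g$age_group] +
    ifelse(g$genotype == "KO", -0.8, 0) * ages[g$age_group] +
    rnorm(nrow(g), 0, 1)
  g
}

# --- Wilcoxon exact enumeration oracle --------------------------------------
# Full enumeration of all assignments of the pooled values to group a.

oracle_wilcoxon_exact <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n_a)])
  sets <- utils::combn(length(pooled), n_a)
  w_all <- apply(sets, 2, function(ix) sum(r[ix]))
  p <- 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs))
  min(1, p)
}

# --- scene helpers ----------------------------------------------------------

# A base_frame wrapping a constant background raster.
matrix_base <- function(h, w, bg = 0) {
  structure(list(raster = matrix(bg, h, w), mode = "index", origin_index = NULL),
            class = "base_frame")
}

# A frame with isotropic Gaussian blobs at the given (x, y) 0-based positions.
# Independent of the package's renderer.
blob_frame <- function(height, width, xs, ys, peak = 180, sigma = 3, bg = 0) {
  f <- matrix(bg, height, width)
  for (k in seq_along(xs)) {
    gy <- exp(-((seq_len(height) - 1 - ys[k])^2) / (2 * sigma^2))
    gx <- exp(-((seq_len(width) - 1 - xs[k])^2) / (2 * sigma^2))
    f <- f + peak * (gy %o% gx)
  }
  f
}

# Build a trajectory object directly from x/y vectors (fps-stamped), for
# metric unit tests that need exact positions.
xy_trajectory <- function(x, y, fps = 10, source = "detected") {
  noveltank::truth_as_trajectory(
    structure(data.frame(frame = seq_along(x) - 1L, x_px = x, y_px = y,
                         immobile = FALSE),
              class = c("behavior_truth", "data.frame"), fps = fps))
}

# The end-to-end scene used by the trajectory-recovery checks: reflection on,
# one static distractor appearing at frame 360 in a corner outside the walk
# bounds, a few dropout frames, optional noise. Dropouts are scheduled while
# the distractor is not yet visible: a dropout frame in which a distractor is
# the only detection makes the linking rules latch onto it by design (the
# nearest-to-last rule has no recovery heuristic, and at this image scale the
# 5000-px jump gate can never reject anything).
e2e_bounds <- function() list(xmin = 40, xmax = 280, ymin = 10, ymax = 150)

e2e_script <- function(seed, freeze_fraction = 0, fps = 10, duration_s = 60) {
  schedule <- switch(as.character(freeze_fraction),
    "0" = list(),
    "0.2" = list(c(10, 16), c(30, 36)),
    "0.5" = list(c(5, 15), c(25, 35), c(40, 50)),
    stop("unsupported freeze fraction"))
  noveltank::behavior_script(
    kind = "random-walk", speed_px_per_frame = 3, freeze_schedule = schedule,
    seed = seed, fps = fps, duration_s = duration_s,
    bounds = e2e_bounds(), midline_row_px = 120, start_xy = c(160, 135))
}

e2e_scene <- function(noise_sd = 0, noise_seed = 1L,
                      dropout_frames = c(120L, 121L, 300L, 340L)) {
  noveltank::scene_config(
    width_px = 320, height_px = 240, background = 30,
    blob_sigma_px = 3, blob_peak_intensity = 180,
    reflection = list(enabled = TRUE, gain = 0.4, floor_row = 160,
                      active_below_row = 140),
    dropout_frames = dropout_frames,
    distractors = data.frame(x = 15, y = 15, sigma = 3, intensity = 120,
                             from_frame = 360L),
    noise_sd = noise_sd, noise_seed = noise_seed)
}

# Toy 6-protein table for the proteomics filtering rules: 1 contaminant,
# 1 single-peptide, 1 partial detection, 1 KO-only, 2 complete in both.
toy_protein_table <- function() {
  data.frame(
    accession = c("P1", "P2", "P3", "P4", "P5", "P6"),
    gene = c("g1", "g2", "g3", "g4", "g5", "g6"),
    unique_peptide_count = c(5L, 1L, 4L, 3L, 6L, 2L),
    contaminant = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    ko1 = c(20.1, 21.0, 19.5, 22.0, 22.69, 20.54),
    ko2 = c(20.3, 21.2, NA, 22.1, 22.70, 20.60),
    ko3 = c(20.2, 21.1, 19.8, 21.9, 22.68, 20.48),
    wt1 = c(20.0, 20.9, NA, NA, 20.50, 17.87),
    wt2 = c(20.1, 21.0, NA, NA, 20.52, 17.90),
    wt3 = c(19.9, 20.8, NA, NA, 20.48, 17.84),
    stringsAsFactors = FALSE)
}
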
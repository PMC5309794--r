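# Independent oracles and fixture builders used across the suite.

# Exhaustive chord oracle: considers every pair of boundary pixels, tests
# whole-segment mask containment by fine sampling, and keeps the maximum --
# no sorting, no early exit. Conventions match the definition under test:
# chord length = Euclidean distance between pixel centres; if no
# perpendicular pair of positive length lies in the mask the minor axis is
# one pixel.
oracle_chords <- function(mask, angle_tol = 2) {
  mask <- unclass(mask) > 0
  h <- nrow(mask); w <- ncol(mask)
  px <- which(mask, arr.ind = TRUE)
  if (nrow(px) == 1L) return(list(major = 1, minor = 1, elongation = 1))
  is_b <- vapply(seq_len(nrow(px)), function(i) {
    r <- px[i, 1]; c <- px[i, 2]
    r == 1 || r == h || c == 1 || c == w ||
      !mask[r - 1, c] || !mask[r + 1, c] ||
      !mask[r, c - 1] || !mask[r, c + 1]
  }, TRUE)
  bp <- px[is_b, , drop = FALSE]
  nb <- nrow(bp)
  seg_ok <- function(p, q) {
    d <- sqrt(sum((p - q)^2))
    if (d == 0) return(TRUE)
    tt <- seq(0, 1, length.out = max(2L, ceiling(d * 4)))
    rr <- round(p[1] + tt * (q[1] - p[1]))
    cc <- round(p[2] + tt * (q[2] - p[2]))
    all(mask[cbind(rr, cc)])
  }
  major <- 0; major_ang <- 0
  for (i in seq_len(nb - 1L)) for (j in (i + 1L):nb) {
    d <- sqrt(sum((bp[i, ] - bp[j, ])^2))
    if (d > major && seg_ok(bp[i, ], bp[j, ])) {
      major <- d
      major_ang <- atan2(bp[j, 1] - bp[i, 1], bp[j, 2] - bp[i, 2])
    }
  }
  if (major == 0) return(list(major = 1, minor = 1, elongation = 1))
  minor <- 0
  for (i in seq_len(nb - 1L)) for (j in (i + 1L):nb) {
    d <- sqrt(sum((bp[i, ] - bp[j, ])^2))
    if (d <= minor || d == 0) next
    ang <- atan2(bp[j, 1] - bp[i, 1], bp[j, 2] - bp[i, 2])
    dev <- abs(((ang - major_ang) * 180 / pi) %% 180 - 90)
    if (dev <= angle_tol && seg_ok(bp[i, ], bp[j, ])) minor <- d
  }
  if (minor == 0) minor <- 1
  minor <- min(minor, major)
  list(major = major, minor = minor, elongation = minor / major)
}

# connected random blob: union of a few mutually overlapping ellipses
random_blob <- function(seed, size = 40L) {
  set.seed(seed)
  m <- matrix(FALSE, size, size)
  cx <- runif(1, size * 0.35, size * 0.65)
  cy <- runif(1, size * 0.35, size * 0.65)
  n_parts <- sample(2:4, 1)
  for (k in seq_len(n_parts)) {
    a <- runif(1, size * 0.12, size * 0.3)
    b <- runif(1, size * 0.08, a)
    th <- runif(1, 0, pi)
    px <- phenoscreen:::ellipse_pixels(size, size, cx, cy, a, b, th)
    m[px] <- TRUE
    # next component centred on a pixel of the current mask (stays connected)
    on <- which(m, arr.ind = TRUE)
    p <- on[sample(nrow(on), 1), ]
    cy <- p[1]; cx <- p[2]
  }
  m
}

disk_mask <- function(r, pad = 3L) rasterize_ellipse(r, r, 0, pad = pad)

small_cfg <- function(...) image_config(width = 512L, height = 512L, ...)

# minimal two-agent screen design used by scoring / reporting tests
demo_design <- function(agents = c("EDN3", "Dopamine"), serum = "low",
                        n_rep = 4L, n_ctrl = 6L, baseline_count = 60,
                        effects = NULL) {
  ag <- screen_agents()
  ag <- ag[ag$agent %in% agents, , drop = FALSE]
  list(agents = ag, effects = effects, n_replicates = n_rep, serum = serum,
       controls_per_stratum = n_ctrl, baseline_count = baseline_count,
       baseline_elong = 0.55)
}
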
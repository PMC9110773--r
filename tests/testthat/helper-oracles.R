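# Fixture builders and independent brute-force oracles shared across tests.
# Oracles are deliberately written as explicit loops / analytic formulas,
# independent of the package's code paths.

# --- contour builders -------------------------------------------------------

# Half-ellipse profile (apical-view style): apical semi-axis `a`, short
# semi-axis `b`, truncated `d` below the equator; base corners are the first
# and last vertices, the apex is an exact vertex. d = 0, a = b gives a
# semicircle on the x-axis.
half_ellipse_contour <- function(a, b, d = 0, n = 257L, view = "AP4CH") {
  if (n %% 2L == 0L) n <- n + 1L
  theta_b <- acos(-d / a)
  theta <- seq(theta_b, -theta_b, length.out = n)
  planar_contour(cbind(b * sin(theta), a * cos(theta)), view = view,
                 boundary = "endocardium", base_indices = c(1L, n))
}

circle_contour <- function(r, n = 360L, boundary = "endocardium",
                           cx = 0, cy = 0) {
  phi <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  planar_contour(cbind(cx + r * cos(phi), cy + r * sin(phi)),
                 view = "PSAX", boundary = boundary)
}

# --- analytic geometry oracles ---------------------------------------------

# Chord of the truncated-spheroid profile at axial distance u from the base
# plane (base at y = -d, equator at u = d, apex at u = a + d).
spheroid_chord <- function(u, a, b, d) {
  y <- u - d
  ifelse(abs(y) <= a, 2 * b * sqrt(pmax(0, 1 - (y / a)^2)), 0)
}

# Cavity volume of a truncated spheroid (closed form).
spheroid_cavity <- function(a, bx, by, d)
  pi * bx * by * ((2 / 3) * a + d - d^3 / (3 * a^2))

# Shell myocardial volume by 1D numerical quadrature of the cross-section
# areas (independent of the closed form).
shell_vmyo_numeric <- function(a, bx, by, d, t) {
  area_at <- function(y, a_, bx_, by_)
    pi * bx_ * by_ * pmax(0, 1 - (y / a_)^2)
  epi <- stats::integrate(area_at, -d, a + t, a_ = a + t, bx_ = bx + t,
                          by_ = by + t, rel.tol = 1e-10)$value
  endo <- stats::integrate(area_at, -d, a, a_ = a, bx_ = bx, by_ = by,
                           rel.tol = 1e-10)$value
  epi - endo
}

# Independent reconstruction of the wall-addition (novel) method from
# analytic chords: N disks, endo chords resampled at the absolute positions
# of the taller epi disks, diameters + 2t, apex extended by t.
oracle_novel_volume <- function(a, b, t, d, N = 20L) {
  L <- a + d
  edv_endo <- 0
  h <- L / N
  for (i in seq_len(N)) {
    u <- (i - 0.5) * h
    edv_endo <- edv_endo + (pi / 4) * spheroid_chord(u, a, b, d)^2 * h
  }
  he <- (L + t) / N
  edv_epi <- 0
  for (i in seq_len(N)) {
    u <- (i - 0.5) * he
    ce <- (if (u <= L) spheroid_chord(u, a, b, d) else 0) + 2 * t
    edv_epi <- edv_epi + (pi / 4) * ce^2 * he
  }
  edv_epi - edv_endo
}

# Midpoint-rule disk volume of a half spheroid from analytic chords (both
# views identical), for quadrature-convergence checks.
oracle_halfspheroid_disks <- function(a, b, N) {
  h <- a / N
  v <- 0
  for (i in seq_len(N)) {
    u <- (i - 0.5) * h
    v <- v + (pi / 4) * spheroid_chord(u, a, b, 0)^2 * h
  }
  v
}

# --- brute-force agreement statistics --------------------------------------

# All agreement quantities from their defining sums (explicit loops); p
# values via the t distribution function.
brute_stats <- function(pred, ref, loa_mult = 1.96) {
  n <- length(pred)
  d <- numeric(n)
  for (i in seq_len(n)) d[i] <- pred[i] - ref[i]
  m <- 0; for (i in seq_len(n)) m <- m + d[i]; m <- m / n
  v <- 0; for (i in seq_len(n)) v <- v + (d[i] - m)^2; v <- v / (n - 1)
  sd_d <- sqrt(v)
  mr <- 0; for (i in seq_len(n)) mr <- mr + ref[i]; mr <- mr / n
  mp <- 0; for (i in seq_len(n)) mp <- mp + pred[i]; mp <- mp / n
  sxx <- 0; sxy <- 0; syy <- 0
  for (i in seq_len(n)) {
    sxx <- sxx + (ref[i] - mr)^2
    syy <- syy + (pred[i] - mp)^2
    sxy <- sxy + (ref[i] - mr) * (pred[i] - mp)
  }
  b1 <- sxy / sxx; b0 <- mp - b1 * mr
  rss <- 0
  for (i in seq_len(n)) rss <- rss + (pred[i] - b0 - b1 * ref[i])^2
  see_val <- sqrt(rss / (n - 2))
  r <- sxy / sqrt(sxx * syy)
  t_r <- r * sqrt((n - 2) / (1 - r^2))
  r_p <- 2 * stats::pt(-abs(t_r), n - 2)
  t_t <- m / sqrt(v / n)
  t_p <- if (v == 0) (if (m == 0) 1 else 0) else 2 * stats::pt(-abs(t_t), n - 1)
  sdy <- 0
  for (i in seq_len(n)) sdy <- sdy + (ref[i] - mr) * (d[i] - m)
  s1 <- sdy / sxx; s0 <- m - s1 * mr
  rss2 <- 0
  for (i in seq_len(n)) rss2 <- rss2 + (d[i] - s0 - s1 * ref[i])^2
  se_s1 <- sqrt(rss2 / (n - 2) / sxx)
  s_p <- 2 * stats::pt(-abs(s1 / se_s1), n - 2)
  list(bias = m, sd_diff = sd_d, loa = loa_mult * sd_d,
       cv = 100 * sd_d / mr, see = see_val, r = r, r_p = r_p, t_p = t_p,
       slope = s1, slope_p = s_p)
}

# Random positive paired fixture of size n.
random_pairs <- function(n, bias = 10, noise = 15) {
  ref <- stats::runif(n, 90, 180)
  pred <- ref + bias + stats::rnorm(n, 0, noise)
  pred <- pmax(pred, 1)
  list(pred = pred, ref = ref)
}

# Representative calibrated shell (cohort-mean-like geometry).
pig_shell <- function() shell_spec(b_endo = 2.4, a_apex = 7, d_base = 1.19,
                                   t_wall = 0.97)
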
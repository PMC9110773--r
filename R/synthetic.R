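# Run expr with a temporarily seeded RNG, restoring the caller's stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# Truncated-normal draws by rejection; truncation at +/- `trunc` SDs keeps
# shells physical.
rtrunc_norm <- function(n, mean, sd, trunc = 3) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- stats::rnorm(1L, mean, sd)
      if (abs(x - mean) <= trunc * sd) break
    }
    out[i] <- x
  }
  out
}

#' Synthetic left-ventricular shell specification
#'
#' A truncated prolate-spheroid LV shell with uniform wall: the endocardial
#' surface is a spheroid with apical semi-axis `a_apex` and short semi-axes
#' `b_x`, `b_y` (equal for a solid of revolution), truncated by the mitral
#' (base) plane at height `d_base` on the basal side of the equator; the
#' epicardial surface is the concentric spheroid grown by `t_wall` in every
#' semi-axis. Its myocardial volume has a closed form, so the shell carries
#' analytic ground-truth mass.
#'
#' @param b_endo Endocardial short semi-axis in cm (used for both `b_x` and
#'   `b_y` unless given explicitly).
#' @param a_apex Endocardial apical semi-axis in cm.
#' @param d_base Basal truncation height in cm (`0 <= d_base <= a_apex`).
#' @param t_wall Uniform wall thickness in cm (> 0).
#' @param density Myocardial density in g/ml.
#' @param b_x,b_y Optional distinct short semi-axes for an elliptical
#'   cross-section (a non-revolution stress-test geometry).
#' @return An object of class `shell_spec`.
#' @export
shell_spec <- function(b_endo, a_apex, d_base, t_wall, density = 1.05,
                       b_x = b_endo, b_y = b_endo) {
  vals <- c(a_apex = a_apex, t_wall = t_wall, density = density,
            b_x = b_x, b_y = b_y)
  if (any(!is.finite(c(vals, d_base))) || any(vals <= 0) || d_base < 0)
    stop("shell parameters must be positive (d_base >= 0) and finite")
  if (d_base > a_apex)
    stop("geometry error: basal truncation d_base exceeds a_apex")
  structure(list(b_x = b_x, b_y = b_y, a_apex = a_apex, d_base = d_base,
                 t_wall = t_wall, density = density),
            class = "shell_spec")
}

#' @export
print.shell_spec <- function(x, ...) {
  cat(sprintf(
    "<shell_spec> a = %.2f, b = %.2f/%.2f, d = %.2f, t = %.2f cm; true mass %.1f g\n",
    x$a_apex, x$b_x, x$b_y, x$d_base, x$t_wall, shell_true_mass(x)))
  invisible(x)
}

# Cavity volume of a truncated spheroid: pi*bx*by*((2/3)a + d - d^3/(3a^2)).
truncated_spheroid_volume <- function(a, bx, by, d) {
  pi * bx * by * ((2 / 3) * a + d - d^3 / (3 * a^2))
}

#' Analytic myocardial volume of a shell
#'
#' Closed-form volume between the concentric truncated spheroids:
#' epicardial cavity (semi-axes grown by `t_wall`, same base plane) minus
#' endocardial cavity. By construction this is algebraically identical to
#' the Truncated Ellipsoid mass formula evaluated on the shell's exact
#' inputs.
#'
#' @param shell A [shell_spec].
#' @return Myocardial volume in ml.
#' @export
true_myocardial_volume <- function(shell) {
  if (!inherits(shell, "shell_spec")) stop("expected a shell_spec")
  t <- shell$t_wall
  truncated_spheroid_volume(shell$a_apex + t, shell$b_x + t, shell$b_y + t,
                            shell$d_base) -
    truncated_spheroid_volume(shell$a_apex, shell$b_x, shell$b_y,
                              shell$d_base)
}

#' @rdname true_myocardial_volume
#' @return `shell_true_mass()`: ground-truth mass in g
#'   (`density * true_myocardial_volume`).
#' @export
shell_true_mass <- function(shell) shell$density * true_myocardial_volume(shell)

#' @rdname true_myocardial_volume
#' @return `shell_true_edv()`: endocardial cavity volume in ml.
#' @export
shell_true_edv <- function(shell)
  truncated_spheroid_volume(shell$a_apex, shell$b_x, shell$b_y, shell$d_base)

#' Exact method inputs of a shell
#'
#' The Truncated Ellipsoid / Area-Length inputs implied analytically by the
#' shell, bypassing contour tracing: exact PSAX areas (`a1` epicardial,
#' `a2` endocardial), apical semi-axis `a`, truncation `d` and long-axis
#' length `l`. Feeding these to [lvm_truncated_ellipsoid()] reproduces
#' `density * true_myocardial_volume(shell)` exactly.
#'
#' @param shell A [shell_spec].
#' @return List with `a1`, `a2` (cm^2), `a`, `d`, `l` (cm).
#' @export
shell_te_inputs <- function(shell) {
  t <- shell$t_wall
  list(a1 = pi * (shell$b_x + t) * (shell$b_y + t),
       a2 = pi * shell$b_x * shell$b_y,
       a = shell$a_apex, d = shell$d_base,
       l = shell$a_apex + shell$d_base)
}

#' Render a shell to a traced view contour
#'
#' Produces the polygon a perfect reader would trace: apical views are the
#' profile of the (truncated) spheroid through the long axis — AP4CH in the
#' x-z plane (seeing `b_x`), AP2CH in the orthogonal y-z plane (seeing
#' `b_y`) — with base landmarks at the truncation-plane corners and a vertex
#' exactly at the apex; the PSAX view is the cross-section ellipse at the
#' widest (equator) level.
#'
#' @param shell A [shell_spec].
#' @param view `"AP4CH"`, `"AP2CH"` or `"PSAX"`.
#' @param boundary `"endocardium"` or `"epicardium"`.
#' @param n_points Number of polygon vertices (>= 16; apical contours are
#'   forced to an odd count so the apex is a vertex).
#' @return A [planar_contour].
#' @export
render_contours <- function(shell, view = c("AP4CH", "AP2CH", "PSAX"),
                            boundary = c("endocardium", "epicardium"),
                            n_points = 193L) {
  view <- match.arg(view)
  boundary <- match.arg(boundary)
  n_points <- as.integer(n_points)
  if (n_points < 16L) stop("n_points must be >= 16")
  t <- if (boundary == "epicardium") shell$t_wall else 0
  if (view == "PSAX") {
    phi <- seq(0, 2 * pi, length.out = n_points + 1L)[-(n_points + 1L)]
    pts <- cbind((shell$b_x + t) * cos(phi), (shell$b_y + t) * sin(phi))
    return(planar_contour(pts, view = "PSAX", boundary = boundary,
                          validate = FALSE))
  }
  if (n_points %% 2L == 0L) n_points <- n_points + 1L
  a_eff <- shell$a_apex + t
  b_eff <- (if (view == "AP4CH") shell$b_x else shell$b_y) + t
  theta_b <- acos(-shell$d_base / a_eff)  # base plane at y = -d_base
  theta <- seq(theta_b, -theta_b, length.out = n_points)
  pts <- cbind(b_eff * sin(theta), a_eff * cos(theta))
  planar_contour(pts, view = view, boundary = boundary,
                 base_indices = c(1L, n_points), validate = FALSE)
}

#' Tracing-noise and reader-effect model
#'
#' Models manual tracing variability: a smooth multiplicative radial jitter
#' of each contour (a low-order random harmonic field about the contour
#' centroid, normalised so the enclosed area is unbiased in expectation),
#' jitter of the base landmarks, calliper noise on the linear measures, and
#' an optional systematic outward placement of the epicardial border.
#' Endo- and epicardial borders traced on the same image share part of
#' their field (`border_corr`); epicardial apical borders — the hardest to
#' trace — get an inflated jitter (`epi_apical_mult`).
#'
#' @param point_jitter_sd Radial jitter SD as a fraction of the local
#'   radius (default 0.05).
#' @param thickness_bias Systematic outward displacement of epicardial
#'   borders in cm (default 0).
#' @param landmark_jitter_sd SD of the base-landmark jitter in cm.
#' @param linear_sd Calliper SD of the 1D measures in cm.
#' @param epi_apical_mult Jitter multiplier for epicardial apical borders.
#' @param border_corr Correlation of the endo/epi jitter fields within one
#'   view, in \[0, 1\].
#' @param n_harmonics Number of random harmonics in the jitter field
#'   (smoothness; the star-shaped construction keeps noised polygons
#'   simple).
#' @param seed Optional seed attached to the noise model.
#' @return An object of class `tracing_noise`.
#' @export
tracing_noise <- function(point_jitter_sd = 0.05, thickness_bias = 0,
                          landmark_jitter_sd = 0.08, linear_sd = 0.05,
                          epi_apical_mult = 2, border_corr = 0.7,
                          n_harmonics = 5L, seed = NULL) {
  sds <- c(point_jitter_sd, landmark_jitter_sd, linear_sd)
  if (any(!is.finite(sds)) || any(sds < 0)) stop("noise SDs must be >= 0")
  if (border_corr < 0 || border_corr > 1) stop("border_corr must be in [0, 1]")
  structure(list(point_jitter_sd = point_jitter_sd,
                 thickness_bias = thickness_bias,
                 landmark_jitter_sd = landmark_jitter_sd,
                 linear_sd = linear_sd, epi_apical_mult = epi_apical_mult,
                 border_corr = border_corr,
                 n_harmonics = as.integer(n_harmonics), seed = seed),
            class = "tracing_noise")
}

#' @rdname tracing_noise
#' @details `noiseless()` is shorthand for an all-zero noise model (exact
#'   tracings).
#' @export
noiseless <- function() tracing_noise(0, 0, 0, 0)

# Draw harmonic-field coefficients: DC term plus n_harmonics cosine/sine
# pairs, standard normal.
draw_field <- function(n_harmonics) {
  list(z0 = stats::rnorm(1L), a = stats::rnorm(n_harmonics),
       b = stats::rnorm(n_harmonics))
}

# Blend two fields with correlation rho (coefficient-wise).
blend_fields <- function(f1, f2, rho) {
  mix <- function(x, y) rho * x + sqrt(1 - rho^2) * y
  list(z0 = mix(f1$z0, f2$z0), a = mix(f1$a, f2$a), b = mix(f1$b, f2$b))
}

# Evaluate a unit-variance smooth field at vertex angles.
eval_field <- function(field, theta) {
  k <- seq_along(field$a)
  g <- field$z0 + drop(cos(outer(theta, k)) %*% field$a +
                       sin(outer(theta, k)) %*% field$b)
  g / sqrt(1 + length(k))
}

star_shaped <- function(p) {
  ctr <- colMeans(p)
  th <- atan2(p[, 2L] - ctr[2L], p[, 1L] - ctr[1L])
  d <- diff(th)
  d <- ((d + pi) %% (2 * pi)) - pi
  all(d > 0) || all(d < 0)
}

#' Apply tracing noise to a contour
#'
#' Radial multiplicative jitter about the contour centroid using a smooth
#' random harmonic field (so the noised polygon stays star-shaped, hence
#' simple), normalised to keep the enclosed area unbiased in expectation;
#' base landmarks are additionally jittered in the plane. If landmark
#' jitter breaks polygon simplicity the draw is retried (up to 5 times)
#' before erroring. Draws come from the current RNG stream.
#'
#' @param contour A [planar_contour].
#' @param noise A [tracing_noise]; all-zero noise returns the contour
#'   unchanged.
#' @param sd_mult Multiplier on `point_jitter_sd` for this contour.
#' @param radial_offset Systematic additive radial displacement in cm
#'   (used for the epicardial `thickness_bias`).
#' @param field Optional pre-drawn harmonic field (for correlated
#'   endo/epicardial borders); drawn fresh when `NULL`.
#' @return A noised [planar_contour].
#' @export
add_noise <- function(contour, noise, sd_mult = 1, radial_offset = 0,
                      field = NULL) {
  sd <- noise$point_jitter_sd * sd_mult
  if (sd == 0 && noise$landmark_jitter_sd == 0 && radial_offset == 0)
    return(contour)
  p0 <- contour$points
  ctr <- colMeans(p0)
  dx <- p0[, 1L] - ctr[1L]; dy <- p0[, 2L] - ctr[2L]
  r <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)
  if (is.null(field)) field <- draw_field(noise$n_harmonics)
  for (attempt in 1:5) {
    g <- if (sd > 0) sd * eval_field(field, theta) else 0
    fac <- pmax(1 + g, 0.2) / sqrt(1 + sd^2)
    r1 <- r * fac + radial_offset
    p <- cbind(ctr[1L] + r1 * cos(theta), ctr[2L] + r1 * sin(theta))
    if (noise$landmark_jitter_sd > 0 && !is.null(contour$base_indices)) {
      bi <- contour$base_indices
      p[bi, ] <- p[bi, ] +
        matrix(stats::rnorm(4L, 0, noise$landmark_jitter_sd), 2L, 2L)
      ok <- star_shaped(p) || is_simple_polygon(p)
    } else ok <- TRUE  # pure radial jitter preserves star shape
    if (ok) {
      out <- contour
      out$points <- p
      return(out)
    }
    field <- draw_field(noise$n_harmonics)
  }
  stop("tracing noise produced a self-intersecting contour after 5 retries")
}

#' Derive the linear measures a reader would take from a shell
#'
#' `IVSd = PWTd = t_wall` and `LVIDd = 2 * sqrt(b_x * b_y)` (the diameter of
#' the equivalent circular cross-section), plus calliper noise and the
#' epicardial thickness bias when configured. Draws come from the current
#' RNG stream.
#'
#' @param shell A [shell_spec].
#' @param noise A [tracing_noise] or `NULL` for exact values.
#' @return A [linear_measures].
#' @export
derive_linear_measures <- function(shell, noise = NULL) {
  t <- shell$t_wall
  d_iv <- 2 * sqrt(shell$b_x * shell$b_y)
  if (is.null(noise) || (noise$linear_sd == 0 && noise$thickness_bias == 0))
    return(linear_measures(ivsd = t, lvidd = d_iv, pwtd = t))
  sd <- noise$linear_sd
  linear_measures(
    ivsd = max(t + noise$thickness_bias + stats::rnorm(1L, 0, sd), 0.05),
    lvidd = max(d_iv + stats::rnorm(1L, 0, sd), 0.5),
    pwtd = max(t + noise$thickness_bias + stats::rnorm(1L, 0, sd), 0.05))
}

#' Simulate one traced study from a shell
#'
#' Renders the six view contours (endo- and epicardial AP4CH, AP2CH and
#' PSAX) and the linear measures, applies the tracing-noise model with
#' correlated endo/epicardial fields per view, and returns the study
#' together with its analytic ground truth.
#'
#' @param shell A [shell_spec].
#' @param noise A [tracing_noise]; use [noiseless()] for exact tracings.
#' @param study_id Identifier.
#' @param n_points_apical,n_points_psax Vertices per rendered contour.
#' @param seed Optional seed (isolated from the caller's RNG stream).
#' @return An object of class `synthetic_study`: list with `shell`, `study`
#'   (an [lv_study]), `true_mass_g` and `true_edv_ml`.
#' @export
simulate_study <- function(shell, noise = tracing_noise(),
                           study_id = "synthetic", n_points_apical = 193L,
                           n_points_psax = 180L, seed = NULL) {
  with_seed(seed, {
    rc <- function(view, boundary, n)
      render_contours(shell, view, boundary, n)
    noisy <- function(ct, mult = 1, offset = 0, field = NULL)
      add_noise(ct, noise, sd_mult = mult, radial_offset = offset,
                field = field)
    tb <- noise$thickness_bias
    contours <- list()
    for (view in c("AP4CH", "AP2CH", "PSAX")) {
      n <- if (view == "PSAX") n_points_psax else n_points_apical
      f_endo <- draw_field(noise$n_harmonics)
      f_epi <- blend_fields(f_endo, draw_field(noise$n_harmonics),
                            noise$border_corr)
      mult_epi <- if (view == "PSAX") 1 else noise$epi_apical_mult
      contours[[paste0(view, "_endo")]] <-
        noisy(rc(view, "endocardium", n), field = f_endo)
      contours[[paste0(view, "_epi")]] <-
        noisy(rc(view, "epicardium", n), mult = mult_epi, offset = tb,
              field = f_epi)
    }
    study <- lv_study(
      study_id = study_id,
      biplane = biplane_tracing(contours$AP4CH_endo, contours$AP2CH_endo,
                                contours$AP4CH_epi, contours$AP2CH_epi),
      psax = psax_tracing(contours$PSAX_endo, contours$PSAX_epi),
      linear = derive_linear_measures(shell, noise))
    structure(list(shell = shell, study = study,
                   true_mass_g = shell_true_mass(shell),
                   true_edv_ml = shell_true_edv(shell)),
              class = "synthetic_study")
  })
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %s: true mass %.1f g, true EDV %.1f ml\n",
              x$study$study_id, x$true_mass_g, x$true_edv_ml))
  invisible(x)
}

# Solve the apical semi-axis so the shell hits a target true mass, with
# d_base = d_frac * a_apex. Mass is strictly increasing in a.
solve_shell_for_mass <- function(target_mass, b, t, d_frac, density = 1.05) {
  f <- function(a) {
    sh <- shell_spec(b_endo = b, a_apex = a, d_base = d_frac * a, t_wall = t,
                     density = density)
    shell_true_mass(sh) - target_mass
  }
  lo <- 1.5; hi <- 30
  if (f(lo) > 0 || f(hi) < 0)
    stop("calibration error: target mass ", round(target_mass, 1),
         " g unreachable from the shape priors")
  a <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  shell_spec(b_endo = b, a_apex = a, d_base = d_frac * a, t_wall = t,
             density = density)
}

#' Simulate a calibrated synthetic cohort
#'
#' Draws `n` truncated-spheroid shells whose short semi-axis, wall
#' thickness and true mass follow truncated-normal distributions calibrated
#' to an end-diastolic porcine-like cohort (defaults: necropsy mass
#' 132 +/- 11 g, LVIDd 4.8 +/- 0.3 cm, PSAX mean wall 0.97 +/- 0.08 cm);
#' for each subject the apical semi-axis is solved so the shell's analytic
#' mass equals its drawn target exactly. Each study carries the noiseless
#' truth plus noised tracings.
#'
#' @param n Number of subjects (>= 3).
#' @param mass_mean,mass_sd Target true-mass distribution (g).
#' @param lvidd_mean,lvidd_sd Internal-diameter distribution (cm);
#'   `b_endo = LVIDd / 2`.
#' @param wall_mean,wall_sd Wall-thickness distribution (cm).
#' @param d_frac Basal truncation as a fraction of the apical semi-axis.
#' @param noise A [tracing_noise].
#' @param seed Seed for the whole cohort (all draws are taken from one
#'   seeded stream, so equal seeds give identical cohorts).
#' @param n_points_apical,n_points_psax Vertices per rendered contour.
#' @return An object of class `lv_cohort`: a list of `synthetic_study`.
#' @export
simulate_cohort <- function(n = 34L, mass_mean = 132, mass_sd = 11,
                            lvidd_mean = 4.8, lvidd_sd = 0.3,
                            wall_mean = 0.97, wall_sd = 0.08,
                            d_frac = 0.17, noise = tracing_noise(),
                            seed = NULL, n_points_apical = 129L,
                            n_points_psax = 120L) {
  n <- as.integer(n)
  if (n < 3L) stop("a cohort needs at least 3 subjects")
  with_seed(seed, {
    studies <- vector("list", n)
    for (i in seq_len(n)) {
      target <- rtrunc_norm(1L, mass_mean, mass_sd)
      b <- rtrunc_norm(1L, lvidd_mean, lvidd_sd) / 2
      t <- rtrunc_norm(1L, wall_mean, wall_sd)
      shell <- solve_shell_for_mass(target, b, t, d_frac)
      studies[[i]] <- simulate_study(shell, noise,
                                     study_id = sprintf("S%02d", i),
                                     n_points_apical = n_points_apical,
                                     n_points_psax = n_points_psax)
    }
    structure(studies, class = "lv_cohort",
              spec = list(n = n, mass_mean = mass_mean, mass_sd = mass_sd,
                          lvidd_mean = lvidd_mean, lvidd_sd = lvidd_sd,
                          wall_mean = wall_mean, wall_sd = wall_sd,
                          d_frac = d_frac, seed = seed))
  })
}

#' @export
print.lv_cohort <- function(x, ...) {
  tm <- vapply(x, function(s) s$true_mass_g, numeric(1L))
  cat(sprintf("<lv_cohort> %d synthetic studies; true mass %.1f +/- %.1f g\n",
              length(x), mean(tm), stats::sd(tm)))
  invisible(x)
}

#' Ground-truth table of a synthetic cohort
#'
#' @param cohort An `lv_cohort`.
#' @return Data frame with study id, true mass/EDV and shell parameters.
#' @export
cohort_truth <- function(cohort) {
  do.call(rbind, lapply(cohort, function(s) {
    data.frame(study_id = s$study$study_id, true_mass_g = s$true_mass_g,
               true_edv_ml = s$true_edv_ml, a_apex = s$shell$a_apex,
               b_x = s$shell$b_x, b_y = s$shell$b_y,
               d_base = s$shell$d_base, t_wall = s$shell$t_wall,
               density = s$shell$density, stringsAsFactors = FALSE)
  }))
}

#' Simulate two readings of the same study
#'
#' Two independent noised tracing sets of one underlying shell — the inputs
#' of an intra-reader analysis — optionally with a multiplicative length
#' scale applied to the second reading's tracings and calliper measures
#' (a systematic calibration difference between readers; a length scale `s`
#' shifts volumetric mass by a factor of about `s^3`).
#'
#' @param synth A `synthetic_study` (its shell is re-traced).
#' @param noise A [tracing_noise].
#' @param reader_scale Length-scale factor of the second reading.
#' @param seed Optional seed.
#' @return List with `baseline` and `repeated` [lv_study] readings.
#' @export
simulate_readers <- function(synth, noise = tracing_noise(),
                             reader_scale = 1, seed = NULL) {
  if (!inherits(synth, "synthetic_study")) stop("expected a synthetic_study")
  with_seed(seed, {
    baseline <- simulate_study(synth$shell, noise,
                               study_id = synth$study$study_id)$study
    repeated <- simulate_study(synth$shell, noise,
                               study_id = synth$study$study_id)$study
    if (reader_scale != 1) repeated <- scale_study(repeated, reader_scale)
    list(baseline = baseline, repeated = repeated)
  })
}

# Multiply every traced coordinate and linear measure by a length factor.
scale_study <- function(study, k) {
  sc <- function(ct) {
    if (is.null(ct)) return(NULL)
    ct$points <- ct$points * k
    ct
  }
  if (!is.null(study$biplane))
    study$biplane <- structure(lapply(study$biplane, sc),
                               class = "biplane_tracing")
  if (!is.null(study$psax))
    study$psax <- psax_tracing(sc(study$psax$endo), sc(study$psax$epi))
  if (!is.null(study$linear))
    study$linear <- linear_measures(study$linear$ivsd * k,
                                    study$linear$lvidd * k,
                                    study$linear$pwtd * k,
                                    if (!is.null(study$linear$lvids))
                                      study$linear$lvids * k)
  study
}
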
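#' Method configuration
#'
#' Shared knobs of the mass methods: the myocardial density converting
#' volume to mass, the disk count of the biplane decomposition, and the
#' disk-expansion rule of the wall-addition method.
#'
#' @param density Myocardial density in g/ml. Default 1.05, the standard
#'   value; configurable because infarct edema can change it.
#' @param n_disks Number of disks in the biplane decompositions (default 20,
#'   the guideline-standard count).
#' @param expansion How the wall-addition method builds the epicardial disk
#'   stack from the endocardial one. `"extend_apex"` (default): each disk's
#'   two diameters are the endocardial chords resampled at the disk's
#'   absolute axial position plus `2t`, and the axis is extended by `t`
#'   beyond the apex (the base plane is fixed; beyond the endocardial apex
#'   the disks are pure wall of diameter `2t`). `"stretch"`: the endocardial
#'   fraction-sampled chords are reused with the taller disks of the
#'   extended axis; kept for sensitivity analysis (it materially
#'   overestimates mass; see the methods vignette).
#' @return An object of class `method_config`.
#' @export
method_config <- function(density = 1.05, n_disks = 20L,
                          expansion = c("extend_apex", "stretch")) {
  if (!is.finite(density) || density <= 0) stop("density must be positive")
  n_disks <- as.integer(n_disks)
  if (n_disks < 1L) stop("n_disks must be >= 1")
  structure(list(density = density, n_disks = n_disks,
                 expansion = match.arg(expansion)),
            class = "method_config")
}

# Extract PSAX areas (A1 epi, A2 endo) from a psax_tracing or a named
# list/vector; tolerate the degenerate A1 == A2 zero-wall limit, reject
# inverted tracings.
psax_areas <- function(psax) {
  if (inherits(psax, "psax_tracing"))
    return(list(a1 = psax$area_epi, a2 = psax$area_endo))
  psax <- as.list(psax)
  nm <- names(psax)
  a1 <- if ("epi" %in% nm) psax$epi else psax$a1
  a2 <- if ("endo" %in% nm) psax$endo else psax$a2
  if (is.null(a1) || is.null(a2))
    stop("psax must be a psax_tracing or carry areas named epi/endo or a1/a2")
  if (!is.finite(a1) || !is.finite(a2) || a2 <= 0 || a1 < a2)
    stop("inverted or invalid PSAX areas: need A1 >= A2 > 0")
  list(a1 = a1, a2 = a2)
}

new_lvm_mass <- function(method, mass, intermediates = list()) {
  structure(list(method = method, mass_g = mass,
                 intermediates = intermediates),
            class = "lvm_mass")
}

#' @export
print.lvm_mass <- function(x, ...) {
  cat(sprintf("<lvm_mass> %s: %.1f g\n", x$method, x$mass_g))
  if (length(x$intermediates)) {
    iv <- unlist(x$intermediates)
    cat("  ", paste(sprintf("%s = %.3f", names(iv), iv), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Devereux cube-formula mass (1D)
#'
#' The guideline-corrected cube formula from linear end-diastolic measures:
#' `LVM = 0.8 * 1.04 * ((IVSd + LVIDd + PWTd)^3 - LVIDd^3) + 0.6` g.
#' The 1.04 g/ml density and the 0.8/+0.6 regression correction are part of
#' the formula itself, so `cfg$density` does not enter here.
#'
#' @param lm A [linear_measures] (or list with `ivsd`, `lvidd`, `pwtd`).
#' @param cfg A [method_config()] (unused by the formula; accepted for a
#'   uniform interface).
#' @return An `lvm_mass` result.
#' @export
lvm_devereux <- function(lm, cfg = method_config()) {
  lm <- as.list(lm)
  v <- c(lm$ivsd, lm$lvidd, lm$pwtd)
  if (length(v) != 3L || any(!is.finite(v)) || any(v <= 0))
    stop("Devereux mass requires positive ivsd, lvidd and pwtd")
  mass <- 0.8 * 1.04 * ((lm$ivsd + lm$lvidd + lm$pwtd)^3 - lm$lvidd^3) + 0.6
  new_lvm_mass("devereux", mass,
               list(ivsd_cm = lm$ivsd, lvidd_cm = lm$lvidd, pwtd_cm = lm$pwtd))
}

#' Area-Length mass (2D)
#'
#' `LVM = density * (5/6) * (A1 * (L + t) - A2 * L)` with the PSAX areas
#' A1 (epicardium), A2 (endocardium), the AP4CH long-axis length L and the
#' equivalent-circle mean wall thickness t.
#'
#' @param psax A [psax_tracing] (or named areas, see [psax_from_areas()]).
#' @param l Long-axis length L in cm (> 0), from the AP4CH view.
#' @param cfg A [method_config()].
#' @return An `lvm_mass` result.
#' @export
lvm_area_length <- function(psax, l, cfg = method_config()) {
  ar <- psax_areas(psax)
  if (!is.finite(l) || l <= 0) stop("long-axis length must be positive")
  t <- sqrt(ar$a1 / pi) - sqrt(ar$a2 / pi)
  mass <- cfg$density * (5 / 6) * (ar$a1 * (l + t) - ar$a2 * l)
  new_lvm_mass("area_length", mass,
               list(t_cm = t, a1_cm2 = ar$a1, a2_cm2 = ar$a2, l_cm = l,
                    myocardial_volume_ml = mass / cfg$density))
}

#' Truncated Ellipsoid mass (2D)
#'
#' Models the LV as a prolate spheroid truncated by the mitral plane at
#' distance `d` below the widest minor axis, with a uniform wall of the
#' PSAX-derived mean thickness `t`:
#' `LVM = density * pi * ((b+t)^2 * ((2/3)(a+t) + d - d^3/(3(a+t)^2))
#'                        - b^2 * ((2/3)a + d - d^3/(3a^2)))`,
#' where `b = sqrt(A2/pi)` is the equivalent endocardial minor radius.
#'
#' @param psax A [psax_tracing] (or named areas).
#' @param a Apical semi-axis (widest-chord plane to apex) in cm, > 0.
#' @param d Basal truncation (widest-chord plane to base) in cm, with
#'   `0 <= d <= a`.
#' @param cfg A [method_config()].
#' @return An `lvm_mass` result.
#' @export
lvm_truncated_ellipsoid <- function(psax, a, d, cfg = method_config()) {
  ar <- psax_areas(psax)
  if (!is.finite(a) || a <= 0) stop("apical semi-axis a must be positive")
  if (!is.finite(d) || d < 0) stop("basal truncation d must be >= 0")
  if (d > a) stop("geometry error: truncation d exceeds the apical semi-axis a")
  b <- sqrt(ar$a2 / pi)
  t <- sqrt(ar$a1 / pi) - b
  seg <- function(a_, r_) r_^2 * ((2 / 3) * a_ + d - d^3 / (3 * a_^2))
  vol <- pi * (seg(a + t, b + t) - seg(a, b))
  new_lvm_mass("truncated_ellipsoid", cfg$density * vol,
               list(t_cm = t, b_cm = b, a_cm = a, d_cm = d,
                    myocardial_volume_ml = vol))
}

#' Biplane endocardial/epicardial tracing mass (2D)
#'
#' Both borders are traced in both apical views; the myocardial volume is
#' the epicardial biplane disk volume minus the endocardial one.
#'
#' @param tr A [biplane_tracing] with all four contours.
#' @param cfg A [method_config()].
#' @return An `lvm_mass` result with EDV_ENDO and EDV_EPI intermediates.
#' @export
lvm_biplane_endo_epi <- function(tr, cfg = method_config()) {
  if (!inherits(tr, "biplane_tracing")) stop("expected a biplane_tracing")
  if (is.null(tr$ap4ch_epi) || is.null(tr$ap2ch_epi))
    stop("epicardial apical contours are missing; ",
         "the endo-/epicardial tracing method needs all four contours")
  v_endo <- biplane_disk_volume(
    biplane_stack(tr$ap4ch_endo, tr$ap2ch_endo, cfg$n_disks))
  v_epi <- biplane_disk_volume(
    biplane_stack(tr$ap4ch_epi, tr$ap2ch_epi, cfg$n_disks))
  if (v_epi <= v_endo)
    stop("tracing error: epicardial volume (", signif(v_epi, 6),
         " ml) does not exceed endocardial volume (", signif(v_endo, 6), " ml)")
  new_lvm_mass("biplane_endo_epi", cfg$density * (v_epi - v_endo),
               list(edv_endo_ml = v_endo, edv_epi_ml = v_epi,
                    myocardial_volume_ml = v_epi - v_endo))
}

#' Wall-addition (novel) biplane mass (2D)
#'
#' Adds the PSAX-derived mean wall thickness to the endocardial biplane disk
#' stack to reconstruct the epicardial volume, so no apical epicardial
#' tracing is needed. With the default `extend_apex` rule, each epicardial
#' disk diameter is the endocardial chord at the disk's absolute axial
#' position plus `2t` (wall on both margins), the long axis is extended by
#' `t` beyond the apex (pure-wall apex cap), and the base plane is fixed.
#' `LVM = density * (EDV_EPI - EDV_ENDO)`.
#'
#' @param tr A [biplane_tracing]; only the endocardial contours are used.
#' @param psax A [psax_tracing] (or named areas) giving the wall thickness.
#' @param cfg A [method_config()]; `cfg$expansion` selects the expansion
#'   rule.
#' @return An `lvm_mass` result with t, EDV_ENDO and EDV_EPI intermediates.
#' @export
lvm_novel <- function(tr, psax, cfg = method_config()) {
  if (!inherits(tr, "biplane_tracing")) stop("expected a biplane_tracing")
  ar <- psax_areas(psax)
  t <- sqrt(ar$a1 / pi) - sqrt(ar$a2 / pi)
  if (t < 0) stop("wall-thickness error: PSAX areas give a negative wall")
  n <- cfg$n_disks
  f <- (seq_len(n) - 0.5) / n
  ax4 <- long_axis(tr$ap4ch_endo)
  ax2 <- long_axis(tr$ap2ch_endo)
  len <- max(ax4$length, ax2$length)
  c4 <- chord_widths_at(tr$ap4ch_endo, ax4, f * ax4$length)
  c2 <- chord_widths_at(tr$ap2ch_endo, ax2, f * ax2$length)
  edv_endo <- (pi / 4) * (len / n) * sum(c4 * c2)
  if (cfg$expansion == "extend_apex") {
    # resample each view at the absolute positions of the taller epi disks;
    # beyond the endocardial apex the chord is 0 and the disk is pure wall
    e4 <- chord_widths_at(tr$ap4ch_endo, ax4, f * (ax4$length + t)) + 2 * t
    e2 <- chord_widths_at(tr$ap2ch_endo, ax2, f * (ax2$length + t)) + 2 * t
  } else {
    e4 <- c4 + 2 * t
    e2 <- c2 + 2 * t
  }
  edv_epi <- (pi / 4) * ((len + t) / n) * sum(e4 * e2)
  new_lvm_mass("novel", cfg$density * (edv_epi - edv_endo),
               list(t_cm = t, l_cm = len, edv_endo_ml = edv_endo,
                    edv_epi_ml = edv_epi,
                    myocardial_volume_ml = edv_epi - edv_endo))
}

#' Long-axis split of an apical contour at its widest chord
#'
#' Finds the plane of the widest chord perpendicular to the long axis and
#' splits the axis there: `a` = widest plane to apex (the spheroid's apical
#' semi-axis), `d` = widest plane to base (the basal truncation). These are
#' the Area-Length / Truncated Ellipsoid inputs. The maximum is located on a
#' midpoint scan and refined by a parabolic fit of the squared chord, which
#' is exact for (truncated) ellipse profiles.
#'
#' @param contour Apical [planar_contour] with base landmarks.
#' @param n_scan Number of scan positions along the axis.
#' @return List with `l` (axis length), `a`, `d` and `widest_cm` (the widest
#'   chord), all in cm.
#' @export
apical_axis_split <- function(contour, n_scan = 128L) {
  ax <- long_axis(contour)
  len <- ax$length
  u <- (seq_len(n_scan) - 0.5) * len / n_scan
  w <- chord_widths_at(contour, ax, u)
  i <- which.max(w)
  u_star <- u[i]
  if (i > 1L && i < n_scan) {
    # parabola through (u, w^2) around the maximum; w^2 is exactly quadratic
    # in u for an ellipse profile, so the vertex recovers the equator
    y0 <- w[i - 1L]^2; y1 <- w[i]^2; y2 <- w[i + 1L]^2
    denom <- y0 - 2 * y1 + y2
    if (denom < 0) u_star <- u[i] + (len / n_scan) * 0.5 * (y0 - y2) / denom
  }
  u_star <- min(max(u_star, 0), len)
  list(l = len, a = len - u_star, d = u_star,
       widest_cm = max(w))
}

#' Quantify LVM by every feasible method
#'
#' Runs all five mass methods on a study, reporting one row per method with
#' a feasibility flag: methods whose inputs are missing are reported as
#' infeasible rather than dropped, mirroring how incomplete subjects are
#' handled in method-comparison cohorts.
#'
#' @param study An [lv_study] (or a `synthetic_study`, whose traced study is
#'   used).
#' @param cfg A [method_config()].
#' @param methods Character vector of methods to attempt (default all five).
#' @return A data frame of class `lvm_results` with columns `study_id`,
#'   `method`, `mass_g`, `t_cm`, `edv_endo_ml`, `edv_epi_ml`, `feasible`.
#' @export
lvm_quantify <- function(study, cfg = method_config(),
                         methods = c("devereux", "area_length",
                                     "truncated_ellipsoid",
                                     "biplane_endo_epi", "novel")) {
  if (inherits(study, "synthetic_study")) study <- study$study
  if (!inherits(study, "lv_study")) stop("expected an lv_study")
  methods <- match.arg(methods, several.ok = TRUE)
  split4 <- NULL
  if (!is.null(study$biplane) &&
      any(c("area_length", "truncated_ellipsoid") %in% methods))
    split4 <- apical_axis_split(study$biplane$ap4ch_endo)
  one <- function(m) {
    res <- tryCatch(switch(m,
      devereux = if (!is.null(study$linear))
        lvm_devereux(study$linear, cfg),
      area_length = if (!is.null(study$psax) && !is.null(split4))
        lvm_area_length(study$psax, split4$l, cfg),
      truncated_ellipsoid = if (!is.null(study$psax) && !is.null(split4))
        lvm_truncated_ellipsoid(study$psax, split4$a, split4$d, cfg),
      biplane_endo_epi = if (!is.null(study$biplane) &&
                             !is.null(study$biplane$ap4ch_epi) &&
                             !is.null(study$biplane$ap2ch_epi))
        lvm_biplane_endo_epi(study$biplane, cfg),
      novel = if (!is.null(study$biplane) && !is.null(study$psax))
        lvm_novel(study$biplane, study$psax, cfg)),
      error = function(e) NULL)
    if (is.null(res))
      return(data.frame(study_id = study$study_id, method = m, mass_g = NA_real_,
                        t_cm = NA_real_, edv_endo_ml = NA_real_,
                        edv_epi_ml = NA_real_, feasible = FALSE,
                        stringsAsFactors = FALSE))
    iv <- res$intermediates
    grab <- function(k) if (!is.null(iv[[k]])) iv[[k]] else NA_real_
    data.frame(study_id = study$study_id, method = m, mass_g = res$mass_g,
               t_cm = grab("t_cm"), edv_endo_ml = grab("edv_endo_ml"),
               edv_epi_ml = grab("edv_epi_ml"), feasible = TRUE,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(methods, one))
  class(out) <- c("lvm_results", class(out))
  out
}

#' @export
print.lvm_results <- function(x, ...) {
  cat("LVM quantification results (g):\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
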
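#' Biplane disk stack
#'
#' The internal representation of the biplane method of disks: `n` elliptical
#' disks whose two orthogonal diameters come from the AP4CH and AP2CH views.
#' Construct directly from two diameter vectors, or from a pair of apical
#' contours with [biplane_stack()].
#'
#' @param diam_a,diam_b Disk diameters (cm) from the two views; equal length,
#'   all >= 0.
#' @param long_axis_length Common long-axis length (cm); the disk height is
#'   `long_axis_length / n`.
#' @return An object of class `disk_stack`.
#' @export
disk_stack <- function(diam_a, diam_b, long_axis_length) {
  if (length(diam_a) != length(diam_b))
    stop("diameter lists from the two views must have equal length")
  if (any(!is.finite(c(diam_a, diam_b))) || any(c(diam_a, diam_b) < 0))
    stop("disk diameters must be finite and >= 0")
  if (!is.finite(long_axis_length) || long_axis_length <= 0)
    stop("long-axis length must be positive")
  n <- length(diam_a)
  if (n < 1L) stop("a disk stack needs at least one disk")
  structure(list(diam_a = as.numeric(diam_a), diam_b = as.numeric(diam_b),
                 disk_height = long_axis_length / n, n_disks = n,
                 long_axis_length = long_axis_length),
            class = "disk_stack")
}

#' @rdname disk_stack
#' @param contour_a,contour_b Apical [planar_contour]s (typically AP4CH and
#'   AP2CH endocardium) with base landmarks.
#' @param n_disks Number of disks.
#' @details When the two views yield different long-axis lengths, the common
#'   disk height uses the longer of the two; each view's chords are sampled
#'   at the common slab fractions of its own axis length (the standard
#'   biplane convention).
#' @export
biplane_stack <- function(contour_a, contour_b, n_disks = 20L) {
  n_disks <- as.integer(n_disks)
  ax_a <- long_axis(contour_a)
  ax_b <- long_axis(contour_b)
  len <- max(ax_a$length, ax_b$length)
  f <- (seq_len(n_disks) - 0.5) / n_disks
  disk_stack(chord_widths_at(contour_a, ax_a, f * ax_a$length),
             chord_widths_at(contour_b, ax_b, f * ax_b$length),
             len)
}

#' Biplane method-of-disks volume
#'
#' Summed volume of `n` elliptical disks,
#' `V = (pi/4) * sum(a_i * b_i) * h`, in ml (1 cm^3 = 1 ml).
#'
#' @param stack A [disk_stack].
#' @return Volume in ml.
#' @export
biplane_disk_volume <- function(stack) {
  if (!inherits(stack, "disk_stack")) stop("expected a disk_stack")
  (pi / 4) * sum(stack$diam_a * stack$diam_b) * stack$disk_height
}

#' Mean wall thickness from the PSAX tracing
#'
#' Difference of the equivalent-circle radii of the epicardial (A1) and
#' endocardial (A2) short-axis areas: `t = sqrt(A1/pi) - sqrt(A2/pi)`.
#' For concentric circles this is exactly the anatomical wall thickness.
#'
#' @param psax A [psax_tracing].
#' @return Mean wall thickness t in cm (strictly positive).
#' @export
mean_wall_thickness_psax <- function(psax) {
  if (!inherits(psax, "psax_tracing")) stop("expected a psax_tracing")
  t <- sqrt(psax$area_epi / pi) - sqrt(psax$area_endo / pi)
  if (t <= 0)
    stop("inverted tracing: epicardial area must exceed endocardial area ",
         "(zero or negative wall thickness)")
  t
}

#' Teichholz left-ventricular volume
#'
#' The 1D cubed-diameter volume estimate with the Teichholz geometric
#' correction: `V = 7 d^3 / (2.4 + d)` ml for an internal diameter `d` in cm.
#'
#' @param d LV internal diameter in cm (> 0); vectorised.
#' @return Volume(s) in ml.
#' @export
teichholz_volume <- function(d) {
  if (any(!is.finite(d)) || any(d <= 0))
    stop("Teichholz volume requires a positive internal diameter")
  7 * d^3 / (2.4 + d)
}

#' Ejection fraction
#'
#' `100 * (EDV - ESV) / EDV` in percent.
#'
#' @param edv End-diastolic volume (ml), > 0.
#' @param esv End-systolic volume (ml), with `0 <= esv <= edv`.
#' @return Ejection fraction in percent, in \[0, 100\].
#' @export
ejection_fraction <- function(edv, esv) {
  if (any(!is.finite(c(edv, esv))) || any(edv <= 0) || any(esv < 0))
    stop("volumes must be finite with edv > 0 and esv >= 0")
  if (any(esv > edv))
    stop("esv exceeds edv")
  100 * (edv - esv) / edv
}
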
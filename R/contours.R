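#' Traced planar contour of a left-ventricular border
#'
#' An ordered polygon of tracing points from one echocardiographic view.
#' Coordinates are view-local 2D positions in centimetres; the polygon is
#' implicitly closed from the last point back to the first. Apical contours
#' (AP4CH, AP2CH) carry `base_indices`, the pair of vertices marking the
#' mitral-annulus endpoints, from which the long axis is derived.
#'
#' @param points Two-column numeric matrix (or object coercible to one) of
#'   (x, y) vertices in cm, at least 3 rows, implicitly closed.
#' @param view One of `"AP4CH"`, `"AP2CH"`, `"PSAX"`, `"PLAX"`.
#' @param boundary `"endocardium"` or `"epicardium"`.
#' @param phase `"end-diastole"` or `"end-systole"`.
#' @param base_indices Optional integer pair of distinct vertex indices
#'   marking the base (mitral annulus) endpoints; apical views only.
#' @param validate If `TRUE` (default) run the full validity check,
#'   including the O(n^2) simple-polygon test. Internal callers that
#'   construct contours guaranteed simple (e.g. star-shaped rendering)
#'   may skip it.
#' @return An object of class `planar_contour`.
#' @export
planar_contour <- function(points, view = c("AP4CH", "AP2CH", "PSAX", "PLAX"),
                           boundary = c("endocardium", "epicardium"),
                           phase = c("end-diastole", "end-systole"),
                           base_indices = NULL, validate = TRUE) {
  view <- match.arg(view)
  boundary <- match.arg(boundary)
  phase <- match.arg(phase)
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 2L)
    stop("contour `points` must be a two-column numeric matrix of (x, y) in cm")
  storage.mode(points) <- "double"
  dimnames(points) <- NULL
  x <- structure(
    list(points = points, view = view, boundary = boundary, phase = phase,
         base_indices = if (!is.null(base_indices)) as.integer(base_indices)),
    class = "planar_contour")
  if (validate) validate_contour(x)
  x
}

validate_contour <- function(contour) {
  p <- contour$points
  if (nrow(p) < 3L)
    stop("contour must have at least 3 points (got ", nrow(p), ")")
  if (!all(is.finite(p)))
    stop("contour contains non-finite coordinates")
  bi <- contour$base_indices
  if (!is.null(bi)) {
    if (length(bi) != 2L || anyNA(bi) || any(bi < 1L) || any(bi > nrow(p)))
      stop("base_indices must be two valid vertex indices")
    if (bi[1L] == bi[2L])
      stop("base_indices must mark two distinct vertices")
  }
  if (!is_simple_polygon(p))
    stop("contour polygon is self-intersecting (not simple)")
  invisible(contour)
}

#' @export
print.planar_contour <- function(x, ...) {
  cat(sprintf("<planar_contour> %s %s (%s), %d points%s\n",
              x$view, x$boundary, x$phase, nrow(x$points),
              if (!is.null(x$base_indices))
                sprintf(", base at vertices %d/%d",
                        x$base_indices[1L], x$base_indices[2L]) else ""))
  invisible(x)
}

# Simple-polygon test: no two non-adjacent edges intersect.
# Exact-arithmetic-free orientation test; touching at shared endpoints of
# adjacent edges is allowed. Vectorised over all edge pairs.
is_simple_polygon <- function(p) {
  n <- nrow(p)
  if (n < 3L) return(FALSE)
  j <- c(seq_len(n)[-1L], 1L)
  ax <- p[, 1L]; ay <- p[, 2L]
  bx <- p[j, 1L]; by <- p[j, 2L]
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  e1 <- idx[, 1L]; e2 <- idx[, 2L]
  # drop adjacent edge pairs (shared vertex), incl. the wrap-around pair
  adj <- (e2 - e1 == 1L) | (e1 == 1L & e2 == n)
  e1 <- e1[!adj]; e2 <- e2[!adj]
  if (!length(e1)) return(TRUE)
  o <- function(px, py, qx, qy, rx, ry) (qx - px) * (ry - py) - (qy - py) * (rx - px)
  d1 <- o(ax[e1], ay[e1], bx[e1], by[e1], ax[e2], ay[e2])
  d2 <- o(ax[e1], ay[e1], bx[e1], by[e1], bx[e2], by[e2])
  d3 <- o(ax[e2], ay[e2], bx[e2], by[e2], ax[e1], ay[e1])
  d4 <- o(ax[e2], ay[e2], bx[e2], by[e2], bx[e1], by[e1])
  crossing <- (d1 * d2 < 0) & (d3 * d4 < 0)
  if (any(crossing)) return(FALSE)
  # collinear overlap: a degenerate pair with all orientations zero
  degen <- (d1 == 0) & (d2 == 0) & (d3 == 0) & (d4 == 0)
  if (any(degen)) {
    for (k in which(degen)) {
      i1 <- e1[k]; i2 <- e2[k]
      r1x <- range(ax[i1], bx[i1]); r1y <- range(ay[i1], by[i1])
      r2x <- range(ax[i2], bx[i2]); r2y <- range(ay[i2], by[i2])
      if (r1x[1L] <= r2x[2L] && r2x[1L] <= r1x[2L] &&
          r1y[1L] <= r2y[2L] && r2y[1L] <= r1y[2L]) return(FALSE)
    }
  }
  TRUE
}

#' Enclosed area of a traced contour
#'
#' Absolute shoelace (Gauss) area of the closed polygon, independent of
#' tracing orientation. Used for the epicardial and endocardial short-axis
#' areas that define the mean wall thickness.
#'
#' @param contour A [planar_contour], or a two-column matrix of vertices.
#' @return Area in cm^2.
#' @export
polygon_area <- function(contour) {
  p <- if (inherits(contour, "planar_contour")) contour$points else as.matrix(contour)
  n <- nrow(p)
  if (n < 3L) stop("polygon area needs at least 3 vertices")
  j <- c(seq_len(n)[-1L], 1L)
  a <- abs(sum(p[, 1L] * p[j, 2L] - p[j, 1L] * p[, 2L])) / 2
  if (a <= 0) stop("degenerate (collinear) contour: zero enclosed area")
  a
}

#' Long axis of an apical contour
#'
#' The long axis runs from the midpoint of the base (mitral annulus) segment
#' to the contour vertex farthest from that midpoint (the apex). This is the
#' axis along which the method-of-disks decomposition slices the cavity.
#'
#' @param contour A [planar_contour] with `base_indices`.
#' @return List with `length` (cm), `base_mid`, `apex` (xy positions) and
#'   `axis` / `normal`, unit vectors along and perpendicular to the axis.
#' @details Distance ties (e.g. a circular-arc contour centred on the base
#'   midpoint, where every vertex is equidistant) are broken toward the
#'   vertex farthest from the base line, which recovers the symmetry apex.
#' @export
long_axis <- function(contour) {
  if (is.null(contour$base_indices))
    stop("long axis requires base landmarks (`base_indices`) on the contour")
  p <- contour$points
  b1 <- p[contour$base_indices[1L], ]
  b2 <- p[contour$base_indices[2L], ]
  base_mid <- (b1 + b2) / 2
  d2 <- (p[, 1L] - base_mid[1L])^2 + (p[, 2L] - base_mid[2L])^2
  apex_i <- which.max(d2)
  cand <- which(d2 >= d2[apex_i] * (1 - 1e-9))
  if (length(cand) > 1L) {
    bd <- b2 - b1
    nb <- sqrt(sum(bd^2))
    if (nb > 0) {
      bd <- bd / nb
      perp <- abs((p[cand, 1L] - base_mid[1L]) * (-bd[2L]) +
                  (p[cand, 2L] - base_mid[2L]) * bd[1L])
      apex_i <- cand[which.max(perp)]
    }
  }
  len <- sqrt(d2[apex_i])
  if (len <= 0) stop("zero-length long axis: apex coincides with base midpoint")
  u <- (p[apex_i, ] - base_mid) / len
  list(length = len, base_mid = base_mid, apex = p[apex_i, ],
       axis = u, normal = c(-u[2L], u[1L]), apex_index = apex_i)
}

# Total chord width of the polygon interior cut perpendicular to the axis at
# axial positions `at` (cm from the base midpoint towards the apex). Widths
# are the summed in-segment lengths (even-odd rule), robust to mild
# non-convexity; positions outside the contour return 0.
chord_widths_at <- function(contour, axis, at) {
  p <- contour$points
  du <- (p[, 1L] - axis$base_mid[1L]) * axis$axis[1L] +
        (p[, 2L] - axis$base_mid[2L]) * axis$axis[2L]
  dv <- (p[, 1L] - axis$base_mid[1L]) * axis$normal[1L] +
        (p[, 2L] - axis$base_mid[2L]) * axis$normal[2L]
  n <- length(du)
  j <- c(seq_len(n)[-1L], 1L)
  u1 <- du; u2 <- du[j]; v1 <- dv; v2 <- dv[j]
  vapply(at, function(u0) {
    cross <- (u1 <= u0) != (u2 <= u0)  # half-open rule: even crossing count
    if (!any(cross)) return(0)
    vv <- v1[cross] + (u0 - u1[cross]) * (v2[cross] - v1[cross]) / (u2[cross] - u1[cross])
    vv <- sort(vv)
    sum(vv[seq(2L, length(vv), by = 2L)] - vv[seq(1L, length(vv), by = 2L)])
  }, numeric(1L))
}

#' Disk chord widths along the long axis
#'
#' Slices the contour into `n_disks` slabs of equal height from base to apex
#' and returns the chord width perpendicular to the long axis at each slab
#' midpoint. Slabs beyond the traced contour return 0.
#'
#' @param contour A [planar_contour] with base landmarks.
#' @param axis Result of [long_axis()]; computed from `contour` if missing.
#' @param n_disks Number of disks (>= 1).
#' @return Numeric vector of `n_disks` chord widths in cm.
#' @export
disk_diameters <- function(contour, axis = long_axis(contour), n_disks = 20L) {
  n_disks <- as.integer(n_disks)
  if (n_disks < 1L) stop("n_disks must be >= 1")
  if (!is.finite(axis$length) || axis$length <= 0)
    stop("geometry error: long axis has zero length")
  at <- (seq_len(n_disks) - 0.5) * axis$length / n_disks
  chord_widths_at(contour, axis, at)
}

#' Parasternal short-axis tracing (endocardium and epicardium)
#'
#' Holds the two PSAX areas that define the mean wall thickness: the
#' epicardial area A1 and the endocardial area A2. Construct either from two
#' traced contours or, via [psax_from_areas()], from the areas directly.
#'
#' @param endo,epi [planar_contour]s of the endocardial and epicardial PSAX
#'   borders.
#' @return An object of class `psax_tracing` with elements `area_epi` (A1),
#'   `area_endo` (A2) and, when built from contours, `endo` and `epi`.
#' @export
psax_tracing <- function(endo, epi) {
  a2 <- polygon_area(endo)
  a1 <- polygon_area(epi)
  if (!(a1 > a2))
    stop("inverted PSAX tracing: epicardial area A1 (", signif(a1, 6),
         ") must exceed endocardial area A2 (", signif(a2, 6), ")")
  structure(list(area_epi = a1, area_endo = a2, endo = endo, epi = epi),
            class = "psax_tracing")
}

#' @rdname psax_tracing
#' @param area_epi,area_endo The PSAX areas A1 (epicardium) and A2
#'   (endocardium) in cm^2; `area_epi >= area_endo > 0` (equality is the
#'   degenerate zero-wall limit).
#' @export
psax_from_areas <- function(area_epi, area_endo) {
  if (!is.finite(area_epi) || !is.finite(area_endo) || area_endo <= 0)
    stop("PSAX areas must be finite with A2 > 0")
  if (area_epi < area_endo)
    stop("inverted PSAX tracing: epicardial area A1 must not be below A2")
  structure(list(area_epi = area_epi, area_endo = area_endo,
                 endo = NULL, epi = NULL),
            class = "psax_tracing")
}

#' @export
print.psax_tracing <- function(x, ...) {
  cat(sprintf("<psax_tracing> A1 (epi) = %.3f cm^2, A2 (endo) = %.3f cm^2\n",
              x$area_epi, x$area_endo))
  invisible(x)
}

#' Biplane apical tracing set
#'
#' The AP4CH and AP2CH contours feeding the biplane method of disks.
#' Endocardial contours are required and must carry base landmarks;
#' epicardial contours are optional (only the endo-/epicardial tracing
#' method needs them).
#'
#' @param ap4ch_endo,ap2ch_endo Endocardial [planar_contour]s with
#'   `base_indices`.
#' @param ap4ch_epi,ap2ch_epi Optional epicardial contours of the same views.
#' @return An object of class `biplane_tracing`.
#' @export
biplane_tracing <- function(ap4ch_endo, ap2ch_endo,
                            ap4ch_epi = NULL, ap2ch_epi = NULL) {
  for (ct in list(ap4ch_endo, ap2ch_endo))
    if (is.null(ct$base_indices))
      stop("endocardial apical contours must carry base landmarks")
  if (!is.null(ap4ch_epi) && polygon_area(ap4ch_epi) <= polygon_area(ap4ch_endo))
    stop("AP4CH epicardial area must exceed the endocardial area")
  if (!is.null(ap2ch_epi) && polygon_area(ap2ch_epi) <= polygon_area(ap2ch_endo))
    stop("AP2CH epicardial area must exceed the endocardial area")
  structure(list(ap4ch_endo = ap4ch_endo, ap2ch_endo = ap2ch_endo,
                 ap4ch_epi = ap4ch_epi, ap2ch_epi = ap2ch_epi),
            class = "biplane_tracing")
}

#' Linear end-diastolic measurements
#'
#' The 1D calliper measures consumed by the Devereux cube formula and the
#' Teichholz volume: septal and posterior wall thickness and internal
#' diameter at end-diastole (all cm), with an optional end-systolic diameter.
#'
#' @param ivsd Interventricular septal thickness, diastole (cm).
#' @param lvidd LV internal diameter, diastole (cm).
#' @param pwtd Posterior wall thickness, diastole (cm).
#' @param lvids Optional LV internal diameter, systole (cm); must be below
#'   `lvidd`.
#' @return An object of class `linear_measures`.
#' @export
linear_measures <- function(ivsd, lvidd, pwtd, lvids = NULL) {
  vals <- c(ivsd = ivsd, lvidd = lvidd, pwtd = pwtd)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("linear measures ivsd/lvidd/pwtd must all be positive and finite")
  if (!is.null(lvids)) {
    if (!is.finite(lvids) || lvids <= 0) stop("lvids must be positive")
    if (lvids >= lvidd) stop("lvids must be smaller than lvidd")
  }
  structure(list(ivsd = ivsd, lvidd = lvidd, pwtd = pwtd, lvids = lvids),
            class = "linear_measures")
}

#' Per-subject study container
#'
#' All tracings and linear measures for one subject at one cardiac phase.
#' At least one measurement group must be present; each mass method reports
#' itself infeasible when its inputs are missing.
#'
#' @param study_id Identifier (character scalar).
#' @param biplane Optional [biplane_tracing].
#' @param psax Optional [psax_tracing].
#' @param linear Optional [linear_measures].
#' @param phase Cardiac phase label.
#' @param metadata Free-form named list.
#' @return An object of class `lv_study`.
#' @export
lv_study <- function(study_id, biplane = NULL, psax = NULL, linear = NULL,
                     phase = "end-diastole", metadata = list()) {
  if (is.null(biplane) && is.null(psax) && is.null(linear))
    stop("study ", study_id, " has no measurement groups at all")
  structure(list(study_id = as.character(study_id), phase = phase,
                 biplane = biplane, psax = psax, linear = linear,
                 metadata = metadata),
            class = "lv_study")
}

#' @export
print.lv_study <- function(x, ...) {
  groups <- c(if (!is.null(x$biplane)) "biplane",
              if (!is.null(x$psax)) "psax",
              if (!is.null(x$linear)) "linear")
  cat(sprintf("<lv_study> %s (%s): %s\n", x$study_id, x$phase,
              paste(groups, collapse = " + ")))
  invisible(x)
}
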
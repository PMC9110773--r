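SCHEMA_ID <- "lvmass-contour/1"

contour_to_list <- function(ct) {
  out <- list(view = ct$view, boundary = ct$boundary,
              points = unname(ct$points))
  if (!is.null(ct$base_indices)) out$base_indices <- ct$base_indices
  out
}

#' Write a study to its JSON exchange document
#'
#' Serialises all contours and linear measures of a study to the versioned
#' JSON contour format (full numeric precision, so a write/read round trip
#' reproduces the study).
#'
#' @param study An [lv_study].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_study <- function(study, path) {
  if (!inherits(study, "lv_study")) stop("expected an lv_study")
  contours <- list()
  bp <- study$biplane
  if (!is.null(bp))
    for (ct in list(bp$ap4ch_endo, bp$ap2ch_endo, bp$ap4ch_epi, bp$ap2ch_epi))
      if (!is.null(ct)) contours[[length(contours) + 1L]] <- contour_to_list(ct)
  if (!is.null(study$psax) && !is.null(study$psax$endo))
    for (ct in list(study$psax$endo, study$psax$epi))
      contours[[length(contours) + 1L]] <- contour_to_list(ct)
  doc <- list(schema = SCHEMA_ID, study_id = study$study_id,
              phase = study$phase, contours = contours)
  if (!is.null(study$linear)) {
    lin <- study$linear
    doc$linear <- list(ivsd = lin$ivsd, lvidd = lin$lvidd, pwtd = lin$pwtd)
    if (!is.null(lin$lvids)) doc$linear$lvids <- lin$lvids
  }
  writeLines(jsonlite::toJSON(doc, digits = NA, auto_unbox = TRUE,
                              pretty = TRUE), path)
  invisible(path)
}

fail_parse <- function(path, ...) stop("parse error in ", path, ": ", ...,
                                       call. = FALSE)

#' Read a study from JSON
#'
#' Parses and validates the JSON contour document, with errors naming the
#' offending field or contour. The units are cm throughout, enforced by the
#' contour invariants at construction.
#'
#' @param path Path to a study JSON file.
#' @return An [lv_study].
#' @export
read_study <- function(path) {
  if (!file.exists(path)) stop("no such study file: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  if (is.null(doc$schema) || !identical(doc$schema, SCHEMA_ID))
    fail_parse(path, "missing or unsupported schema (expected '",
               SCHEMA_ID, "')")
  if (is.null(doc$study_id)) fail_parse(path, "missing study_id")
  cts <- list()
  for (i in seq_along(doc$contours)) {
    c_in <- doc$contours[[i]]
    for (fld in c("view", "boundary", "points"))
      if (is.null(c_in[[fld]]))
        fail_parse(path, "contour ", i, " lacks field '", fld, "'")
    pts <- c_in$points
    if (is.list(pts)) pts <- do.call(rbind, pts)
    if (!is.matrix(pts) || ncol(pts) != 2L || nrow(pts) < 3L)
      fail_parse(path, "contour ", i, " (", c_in$view, " ", c_in$boundary,
                 "): points must be an Nx2 array with N >= 3")
    ct <- tryCatch(
      planar_contour(pts, view = c_in$view, boundary = c_in$boundary,
                     phase = if (!is.null(doc$phase)) doc$phase
                             else "end-diastole",
                     base_indices = c_in$base_indices),
      error = function(e) fail_parse(path, "contour ", i, " (", c_in$view,
                                     " ", c_in$boundary, "): ",
                                     conditionMessage(e)))
    cts[[paste(c_in$view, c_in$boundary, sep = "_")]] <- ct
  }
  biplane <- NULL
  if (!is.null(cts$AP4CH_endocardium) && !is.null(cts$AP2CH_endocardium))
    biplane <- biplane_tracing(cts$AP4CH_endocardium, cts$AP2CH_endocardium,
                               cts$AP4CH_epicardium, cts$AP2CH_epicardium)
  psax <- NULL
  if (!is.null(cts$PSAX_endocardium) && !is.null(cts$PSAX_epicardium))
    psax <- psax_tracing(cts$PSAX_endocardium, cts$PSAX_epicardium)
  linear <- NULL
  if (!is.null(doc$linear)) {
    lin <- doc$linear
    for (fld in c("ivsd", "lvidd", "pwtd"))
      if (is.null(lin[[fld]]))
        fail_parse(path, "linear measures lack field '", fld, "'")
    linear <- tryCatch(
      linear_measures(lin$ivsd, lin$lvidd, lin$pwtd, lin$lvids),
      error = function(e) fail_parse(path, "linear measures: ",
                                     conditionMessage(e)))
  }
  tryCatch(
    lv_study(doc$study_id, biplane = biplane, psax = psax, linear = linear,
             phase = if (!is.null(doc$phase)) doc$phase else "end-diastole"),
    error = function(e) fail_parse(path, conditionMessage(e)))
}

#' Import contours from a CSV point list
#'
#' Reads a long-format point table with columns `view`, `boundary`, `x`,
#' `y` (cm) and an optional logical `base` column marking the two base
#' landmarks of each apical contour (defaulting to the first and last point
#' of the contour).
#'
#' @param path CSV file path.
#' @param study_id Identifier for the resulting study.
#' @param linear Optional [linear_measures] to attach.
#' @return An [lv_study].
#' @export
read_contours_csv <- function(path, study_id = basename(path),
                              linear = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("view", "boundary", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    fail_parse(path, "missing columns: ", paste(miss, collapse = ", "))
  cts <- list()
  for (key in unique(paste(df$view, df$boundary))) {
    sub <- df[paste(df$view, df$boundary) == key, , drop = FALSE]
    bi <- NULL
    if (toupper(sub$view[1L]) %in% c("AP4CH", "AP2CH")) {
      bi <- if ("base" %in% names(sub) && any(as.logical(sub$base)))
        which(as.logical(sub$base)) else c(1L, nrow(sub))
    }
    cts[[paste(toupper(sub$view[1L]), sub$boundary[1L], sep = "_")]] <-
      planar_contour(cbind(sub$x, sub$y), view = toupper(sub$view[1L]),
                     boundary = sub$boundary[1L], base_indices = bi)
  }
  biplane <- if (!is.null(cts$AP4CH_endocardium) &&
                 !is.null(cts$AP2CH_endocardium))
    biplane_tracing(cts$AP4CH_endocardium, cts$AP2CH_endocardium,
                    cts$AP4CH_epicardium, cts$AP2CH_epicardium)
  psax <- if (!is.null(cts$PSAX_endocardium) &&
              !is.null(cts$PSAX_epicardium))
    psax_tracing(cts$PSAX_endocardium, cts$PSAX_epicardium)
  lv_study(study_id, biplane = biplane, psax = psax, linear = linear)
}

#' Write a synthetic cohort to disk
#'
#' One JSON contour document per study plus a `truth.csv` ground-truth
#' table.
#'
#' @param cohort An `lv_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in cohort)
    write_study(s$study, file.path(dir, paste0(s$study$study_id, ".json")))
  utils::write.csv(cohort_truth(cohort), file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}

# One agreement row per method against the reference masses.
agreement_table <- function(results, truth, loa_multiplier = 1.96,
                            alpha = 0.05, subjects = NULL) {
  rows <- list()
  for (m in unique(results$method)) {
    sub <- results[results$method == m & results$feasible, , drop = FALSE]
    if (!is.null(subjects)) sub <- sub[sub$study_id %in% subjects, , drop = FALSE]
    idx <- match(sub$study_id, truth$study_id)
    ok <- !is.na(idx)
    if (sum(ok) < 3L) {
      rows[[m]] <- data.frame(method = m, n = sum(ok), mean_g = NA_real_,
                              sd_g = NA_real_, bias_g = NA_real_,
                              loa_g = NA_real_, cv_pct = NA_real_,
                              see_g = NA_real_, r = NA_real_, r_p = NA_real_,
                              paired_t_p = NA_real_,
                              prop_bias_slope = NA_real_,
                              prop_bias_p = NA_real_, stringsAsFactors = FALSE)
      next
    }
    ag <- lvm_agreement(sub$mass_g[ok], truth$true_mass_g[idx[ok]],
                        subject_ids = sub$study_id[ok],
                        loa_multiplier = loa_multiplier, alpha = alpha)
    rows[[m]] <- data.frame(method = m, n = ag$n, mean_g = ag$mean_predicted,
                            sd_g = ag$sd_predicted, bias_g = ag$bias,
                            loa_g = ag$loa_half_width, cv_pct = ag$cv_pct,
                            see_g = ag$see, r = ag$pearson_r,
                            r_p = ag$pearson_p, paired_t_p = ag$paired_t_p,
                            prop_bias_slope = ag$prop_bias_slope,
                            prop_bias_p = ag$prop_bias_p,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full quantification and agreement pipeline
#'
#' Quantifies every study by every method, then — when ground truth is
#' available — builds the method-agreement table (bias, LOA, CV, SEE,
#' Pearson r, paired t, proportional bias) for all subjects, repeats it for
#' the complete-case subgroup (subjects feasible for every method), and
#' ranks per-subject accuracy. The pipeline is deterministic: identical
#' inputs and configuration give byte-identical output files.
#'
#' @param cohort An `lv_cohort`, a list of [lv_study], or a directory of
#'   study JSON files.
#' @param truth Ground-truth table (data frame with `study_id`,
#'   `true_mass_g`) or path to a truth CSV; taken from the cohort itself
#'   when it is an `lv_cohort`.
#' @param cfg A [method_config()].
#' @param loa_multiplier,alpha Agreement-protocol constants.
#' @param out_dir Optional directory to write `results.csv`,
#'   `agreement.csv`, `agreement_complete_cases.csv` and `ranking.csv`.
#' @param quiet Suppress progress messages.
#' @return List with `results`, `agreement`, `agreement_complete`,
#'   `ranking` and the effective `config`.
#' @export
run_pipeline <- function(cohort, truth = NULL, cfg = method_config(),
                         loa_multiplier = 1.96, alpha = 0.05,
                         out_dir = NULL, quiet = FALSE) {
  if (is.character(cohort) && length(cohort) == 1L) {
    paths <- sort(list.files(cohort, pattern = "\\.json$", full.names = TRUE))
    if (is.null(truth)) {
      tp <- file.path(cohort, "truth.csv")
      if (file.exists(tp)) truth <- tp
    }
    cohort <- lapply(paths, read_study)
  }
  if (inherits(cohort, "lv_cohort") && is.null(truth)) truth <- cohort_truth(cohort)
  if (is.character(truth)) truth <- utils::read.csv(truth, stringsAsFactors = FALSE)
  if (length(cohort) < 3L) stop("analysis infeasible: fewer than 3 studies")
  if (!quiet)
    message("lvmass pipeline: ", length(cohort), " studies, density ",
            cfg$density, " g/ml, ", cfg$n_disks, " disks, expansion '",
            cfg$expansion, "', LOA x", loa_multiplier, ", alpha ", alpha)
  results <- do.call(rbind, lapply(cohort, lvm_quantify, cfg = cfg))
  agreement <- agreement_complete <- ranking <- NULL
  if (!is.null(truth)) {
    feas <- results[results$feasible, , drop = FALSE]
    complete_ids <- Reduce(intersect,
                           split(feas$study_id, feas$method))
    if (length(complete_ids) < 3L)
      stop("analysis infeasible: fewer than 3 complete cases")
    agreement <- agreement_table(results, truth, loa_multiplier, alpha)
    agreement_complete <- agreement_table(results, truth, loa_multiplier,
                                          alpha, subjects = complete_ids)
    series <- lapply(split(feas, feas$method), function(sub) {
      sub <- sub[sub$study_id %in% complete_ids, , drop = FALSE]
      idx <- match(sub$study_id, truth$study_id)
      paired_series(sub$mass_g, truth$true_mass_g[idx], sub$study_id)
    })
    ranking <- rank_accuracy(series, complete_cases_only = TRUE)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(results, file.path(out_dir, "results.csv"),
                     row.names = FALSE)
    if (!is.null(agreement)) {
      utils::write.csv(agreement, file.path(out_dir, "agreement.csv"),
                       row.names = FALSE)
      utils::write.csv(agreement_complete,
                       file.path(out_dir, "agreement_complete_cases.csv"),
                       row.names = FALSE)
      utils::write.csv(ranking, file.path(out_dir, "ranking.csv"),
                       row.names = FALSE)
    }
  }
  list(results = results, agreement = agreement,
       agreement_complete = agreement_complete, ranking = ranking,
       config = list(density = cfg$density, n_disks = cfg$n_disks,
                     expansion = cfg$expansion,
                     loa_multiplier = loa_multiplier, alpha = alpha))
}
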
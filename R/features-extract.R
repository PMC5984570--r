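#' Extract the 92-feature vector for every ROI and timepoint of a subject
#'
#' Normalizes each SPECT volume to the occipital reference, then, for each
#' of the six striatal ROIs keyed by structure + more/less-affected tag,
#' discretizes the in-mask uptake (fixed bin count) and computes the
#' first-order, morphological and texture feature families in registry
#' order. Features are computed in SPECT space on the supplied (propagated
#' or native) labels.
#'
#' @param subject a `synthetic_subject` (or any list with `id`, `spect_y0`,
#'   `spect_y1`).
#' @param labels label [vol3d()] on the SPECT lattice.
#' @param sides a [assign_affected_sides()] result.
#' @param registry the feature registry (see [feature_registry()]).
#' @param n_bins gray levels for discretization (default 64).
#' @return long-format data.frame: `subject`, `timepoint` (`y0`/`y1`),
#'   `roi` (structure), `side_tag` (`m`/`l`), `feature`, `value`; exactly
#'   92 rows per ROI per timepoint.
#' @export
extract_subject_features <- function(subject, labels, sides,
                                     registry = feature_registry(),
                                     n_bins = 64L) {
  codes <- label_codes()
  occ <- labels$data == codes[["occipital"]]
  tps <- list(y0 = subject$spect_y0, y1 = subject$spect_y1)
  out <- vector("list", 12)
  k <- 0L
  for (tp in names(tps)) {
    spect <- tps[[tp]]
    if (is.null(spect)) stop("subject ", subject$id, " has no ", tp,
                             " SPECT volume")
    stopifnot_same_lattice(spect, labels)
    norm <- normalize_to_reference(spect, occ)
    for (str in striatal_structures()) {
      for (tag in c("m", "l")) {
        side <- sides[[str]][[tag]]
        code <- codes[[paste0(str, "_", side)]]
        mask <- labels$data == code
        if (!any(mask)) {
          stop(sprintf("missing ROI for subject %s, timepoint %s: %s (%s)",
                       subject$id, tp, str, side))
        }
        contra <- labels$data ==
          codes[[paste0(str, "_", setdiff(c("left", "right"), side))]]
        vals <- roi_feature_vector(norm, mask, contra, registry, n_bins)
        k <- k + 1L
        out[[k]] <- data.frame(subject = subject$id, timepoint = tp,
                               roi = str, side_tag = tag,
                               feature = names(vals), value = unname(vals),
                               stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

# all 92 features of one ROI, ordered per registry
roi_feature_vector <- function(norm, mask, contra, registry, n_bins) {
  gl <- discretize(norm, mask, n_bins)
  vals <- c(first_order_features(norm, mask, n_bins = n_bins),
            morphology_features(mask, norm, contralateral_mask = contra),
            glcm_features(gl),
            glszm_features(gl),
            glrlm_features(gl))
  missing <- setdiff(registry$name, names(vals))
  if (length(missing)) {
    stop("extractor did not produce registry features: ",
         paste(missing, collapse = ", "))
  }
  vals[registry$name]
}

#' Extract features for a whole cohort
#'
#' Side assignment is made per subject from the year-0 SPECT (the putamen
#' rule, see [assign_affected_sides()]).
#'
#' @param cohort a `phantom_cohort`.
#' @param labels optional label volume on the SPECT lattice (defaults to
#'   the cohort's own).
#' @inheritParams extract_subject_features
#' @return long-format data.frame over all subjects, with an attribute
#'   `sides` (per-subject side assignments).
#' @export
extract_cohort_features <- function(cohort, labels = cohort$labels,
                                    registry = feature_registry(),
                                    n_bins = 64L) {
  sides <- lapply(cohort$subjects, function(s) {
    assign_affected_sides(s$spect_y0, labels)
  })
  names(sides) <- vapply(cohort$subjects, `[[`, "", "id")
  tabs <- mapply(function(s, sd) {
    extract_subject_features(s, labels, sd, registry, n_bins)
  }, cohort$subjects, sides, SIMPLIFY = FALSE)
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  attr(out, "sides") <- sides
  out
}

#' Write / read a long-format feature table
#'
#' The CSV header contract is `subject, timepoint, roi, side_tag, feature,
#' value`. The reader validates completeness: every (subject, timepoint,
#' roi, side_tag) cell must carry all 92 registry features, and missing
#' rows are reported by name.
#'
#' @param features long-format data.frame from [extract_cohort_features()].
#' @param path CSV path.
#' @return `write_feature_table`: `path` invisibly; `read_feature_table`:
#'   the validated data.frame.
#' @export
write_feature_table <- function(features, path) {
  need <- c("subject", "timepoint", "roi", "side_tag", "feature", "value")
  stopifnot(all(need %in% names(features)))
  utils::write.csv(features[, need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @param registry registry to validate against.
#' @export
read_feature_table <- function(path, registry = feature_registry()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "timepoint", "roi", "side_tag", "feature", "value")
  if (!all(need %in% names(df))) {
    stop("feature table lacks required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  key <- interaction(df$subject, df$timepoint, df$roi, df$side_tag,
                     drop = TRUE)
  gaps <- character(0)
  for (cell in levels(key)) {
    have <- df$feature[key == cell]
    miss <- setdiff(registry$name, have)
    if (length(miss)) {
      gaps <- c(gaps, paste0(cell, ": ", paste(miss, collapse = ", ")))
    }
  }
  if (length(gaps)) {
    stop("incomplete feature table; missing rows —\n",
         paste(utils::head(gaps, 20), collapse = "\n"))
  }
  df
}
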
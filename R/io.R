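#' Read a long-format cohort voxel table
#'
#' Expects a delimited table with columns `subject_id`, `region_id`,
#' `value` (one row per voxel). Values are validated as finite numbers and
#' the region universe can be checked against a parcellation manifest.
#'
#' @param path TSV/CSV file path.
#' @param manifest optional character vector of allowed region ids.
#' @return list of subject records (`subject_id`, `group = NA`,
#'   `region_values`), ordered by first appearance.
#' @export
read_cohort_table <- function(path, manifest = NULL) {
  dt <- data.table::fread(path, sep = "\t", colClasses = "character")
  required <- c("subject_id", "region_id", "value")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!nrow(dt)) return(list())
  val <- suppressWarnings(as.numeric(dt$value))
  bad <- which(!is.finite(val))
  if (length(bad)) {
    stop("non-numeric value(s) at data row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (!is.null(manifest)) {
    unk <- which(!dt$region_id %in% manifest)
    if (length(unk)) {
      stop("unknown region id(s) not in manifest at data row(s): ",
           paste(utils::head(unk, 5), collapse = ", "),
           " (e.g. ", dt$region_id[unk[1]], ")", call. = FALSE)
    }
  }
  sub_ids <- unique(dt$subject_id)
  subjects <- lapply(sub_ids, function(sid) {
    rows <- dt$subject_id == sid
    rv <- split(val[rows], dt$region_id[rows])
    # preserve manifest order where available, else sorted region ids
    ord <- if (!is.null(manifest)) intersect(manifest, names(rv))
           else sort(names(rv))
    list(subject_id = sid, group = NA_character_, region_values = rv[ord])
  })
  names(subjects) <- sub_ids
  subjects
}

#' Read a clinical table
#'
#' @param path TSV file with columns `subject_id`, `group`, `age`, `sex`,
#'   and optionally `onset`, `duration`, `hfmse`.
#' @return data.frame.
#' @export
read_clinical_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  required <- c("subject_id", "group", "age", "sex")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  as.data.frame(dt)
}

#' Extract regional value samples from a GM map and an atlas volume
#'
#' Region `k`'s sample is the set of GM values at voxels labeled `k` in the
#' atlas with GM value > 0. Both NIfTI volumes must share voxel
#' dimensions; atlas labels must be integers. Labels whose usable sample is
#' empty are dropped with a warning.
#'
#' @param gm_path NIfTI file with GM probability/volume values.
#' @param atlas_path NIfTI file with integer region labels (0 = background).
#' @param subject_id identifier attached to the record.
#' @return a subject record (`subject_id`, `group = NA`, `region_values`
#'   named by atlas label).
#' @export
read_nifti_pair <- function(gm_path, atlas_path, subject_id = gm_path) {
  gm <- as.array(RNifti::readNifti(gm_path))
  atlas <- as.array(RNifti::readNifti(atlas_path))
  if (!identical(dim(gm), dim(atlas))) {
    stop("voxel grid mismatch: GM ", paste(dim(gm), collapse = "x"),
         " vs atlas ", paste(dim(atlas), collapse = "x"), call. = FALSE)
  }
  if (max(abs(atlas - round(atlas))) > 1e-6) {
    stop("atlas labels are not integer-valued", call. = FALSE)
  }
  atlas <- as.integer(round(atlas))
  labels <- sort(unique(atlas[atlas > 0]))
  if (!length(labels) || !any(gm > 0)) {
    stop("no usable voxels (positive GM value within a labeled region)",
         call. = FALSE)
  }
  rv <- lapply(labels, function(k) gm[atlas == k & gm > 0])
  names(rv) <- as.character(labels)
  empty <- names(rv)[lengths(rv) == 0]
  if (length(empty)) {
    warning("region(s) with no usable voxels dropped: ",
            paste(empty, collapse = ", "))
    rv <- rv[lengths(rv) > 0]
  }
  if (!length(rv)) {
    stop("no usable voxels (positive GM value within a labeled region)",
         call. = FALSE)
  }
  list(subject_id = subject_id, group = NA_character_, region_values = rv)
}

#' Write a similarity matrix as delimited text plus a JSON sidecar
#'
#' @param W `similarity_matrix`.
#' @param path output TSV path; the sidecar is written next to it as
#'   `<path>.json` and records measure, bandwidth rule, grid spec and
#'   epsilon.
#' @return invisibly, `path`.
#' @export
write_similarity_matrix <- function(W, path) {
  utils::write.table(as.matrix(W), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  gs <- attr(W, "grid_spec")
  meta <- list(measure = attr(W, "measure"),
               bandwidth_rule = attr(W, "bandwidth_rule"),
               subject_id = attr(W, "subject_id"),
               n_points = gs$n_points, padding = gs$padding,
               epsilon = gs$epsilon)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
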
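#' Default ROI definitions of the default mode network
#'
#' The eight regions used as network nodes, each the union of automated
#' anatomical labelling (AAL) regions: PCC (posterior cingulate + precuneus,
#' bilateral), mPFC (superior medial frontal, bilateral), left/right
#' hippocampus + parahippocampus, left/right inferior parietal, and
#' left/right inferior temporal cortex. Integer atlas labels depend on the
#' user's atlas file and are attached via `labels`.
#'
#' @param labels Optional named list mapping ROI abbreviation to an integer
#'   vector of atlas labels whose union forms the ROI. Labels must be
#'   disjoint across ROIs.
#' @return Object of class `roi_spec_set`: a list of 8 ROI specs, each with
#'   `name`, `abbreviation`, `aal_regions` and (if supplied) `atlas_labels`.
#' @export
dmn_rois <- function(labels = NULL) {
  defs <- list(
    list(name = "Posterior cingulate cortex", abbreviation = "PCC",
         aal_regions = c("cingulum_post_L", "cingulum_post_R",
                         "precuneus_L", "precuneus_R")),
    list(name = "Medial prefrontal cortex", abbreviation = "mPFC",
         aal_regions = c("frontal_sup_medial_L", "frontal_sup_medial_R")),
    list(name = "Left hippocampus", abbreviation = "lHP",
         aal_regions = c("hippocampus_L", "parahippocampus_L")),
    list(name = "Right hippocampus", abbreviation = "rHP",
         aal_regions = c("hippocampus_R", "parahippocampus_R")),
    list(name = "Left inferior parietal cortex", abbreviation = "lIPC",
         aal_regions = "parietal_inf_L"),
    list(name = "Right inferior parietal cortex", abbreviation = "rIPC",
         aal_regions = "parietal_inf_R"),
    list(name = "Left inferior temporal cortex", abbreviation = "lITC",
         aal_regions = "temporal_inf_L"),
    list(name = "Right inferior temporal cortex", abbreviation = "rITC",
         aal_regions = "temporal_inf_R")
  )
  names(defs) <- vapply(defs, `[[`, character(1), "abbreviation")
  if (!is.null(labels)) {
    unknown <- setdiff(names(labels), names(defs))
    if (length(unknown)) {
      stop("labels given for unknown ROI(s): ", paste(unknown, collapse = ", "))
    }
    all_labels <- unlist(labels, use.names = FALSE)
    if (anyDuplicated(all_labels)) {
      stop("atlas labels must be disjoint across ROIs")
    }
    for (ab in names(labels)) {
      lab <- as.integer(labels[[ab]])
      if (!length(lab)) stop("empty label set for ROI ", ab)
      defs[[ab]]$atlas_labels <- lab
    }
  }
  structure(defs, class = "roi_spec_set")
}

#' Read ROI label definitions from a JSON file
#'
#' Expected schema: `{"PCC": {"labels": [35, 36, 67, 68]}, ...}` (or a bare
#' array of labels per ROI).
#'
#' @param path Path to a JSON file.
#' @return A `roi_spec_set` with atlas labels attached.
#' @export
read_roi_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  labels <- lapply(raw, function(x) {
    if (is.list(x) && !is.null(x$labels)) as.integer(x$labels) else as.integer(x)
  })
  dmn_rois(labels = labels)
}

#' Mean grey-matter volume inside a mask, above threshold
#'
#' Averages the voxel values that lie inside the mask AND strictly exceed
#' the threshold. Sub-threshold voxels are excluded from the mean (not
#' zero-filled): the threshold removes voxels that are not grey matter.
#'
#' @param image 3-D numeric array (or `niftiImage`) of grey-matter values.
#' @param mask Logical array of the same shape.
#' @param threshold Scalar; voxels must exceed it to contribute. Default 0.15.
#' @param roi ROI name used in error messages.
#' @return Scalar mean of supra-threshold voxels inside the mask.
#' @export
extract_roi_mean <- function(image, mask, threshold = 0.15, roi = "ROI") {
  img <- as.array(image)
  msk <- as.array(mask)
  if (!identical(dim(img), dim(msk))) {
    stop("image and mask shapes differ: ", paste(dim(img), collapse = "x"),
         " vs ", paste(dim(msk), collapse = "x"))
  }
  msk <- msk != 0
  if (!any(msk)) stop("empty mask for ", roi)
  vals <- img[msk]
  keep <- vals > threshold
  if (!any(keep)) {
    stop("empty ROI after threshold: no voxel in ", roi,
         " exceeds ", threshold, " (failed segmentation/registration?)")
  }
  mean(vals[keep])
}

#' Build the subject-by-ROI volume table from images and an atlas
#'
#' For each subject image and each ROI, averages the supra-threshold
#' grey-matter voxels over the union of the ROI's atlas labels.
#'
#' @param images List of subject entries, each a list with `subject_id`,
#'   `group` (one of `"NC"`, `"AD"`) and `image` (3-D array or `niftiImage`).
#' @param atlas Integer-labelled 3-D array (or `niftiImage`) on the same grid.
#' @param rois A `roi_spec_set` with atlas labels attached (see [dmn_rois()]).
#' @param threshold Grey-matter threshold passed to [extract_roi_mean()].
#' @return Volume table: data.frame with columns `subject_id`, `group` and
#'   one column per ROI abbreviation.
#' @export
build_volume_table <- function(images, atlas, rois, threshold = 0.15) {
  stopifnot(inherits(rois, "roi_spec_set"))
  atl <- as.array(atlas)
  has_labels <- vapply(rois, function(r) !is.null(r$atlas_labels), logical(1))
  if (!all(has_labels)) {
    stop("atlas labels missing for ROI(s): ",
         paste(names(rois)[!has_labels], collapse = ", "))
  }
  ids <- vapply(images, function(s) as.character(s$subject_id), character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate subject_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  masks <- lapply(rois, function(r) {
    m <- array(atl %in% r$atlas_labels, dim = dim(atl))
    if (!any(m)) stop("no atlas voxel carries a label of ROI ", r$abbreviation)
    m
  })
  rows <- lapply(images, function(s) {
    img <- as.array(s$image)
    if (!identical(dim(img), dim(atl))) {
      stop("subject ", s$subject_id, ": image shape ",
           paste(dim(img), collapse = "x"), " does not match atlas ",
           paste(dim(atl), collapse = "x"))
    }
    vols <- vapply(names(masks), function(ab) {
      extract_roi_mean(img, masks[[ab]], threshold = threshold, roi = ab)
    }, numeric(1))
    c(list(subject_id = as.character(s$subject_id),
           group = as.character(s$group)), as.list(vols))
  })
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  validate_volume_table(out, roi_names = names(rois))
  out
}

#' Validate a volume table
#'
#' Checks the column contract (`subject_id`, `group`, then the ROI columns),
#' group labels, absence of missing values and uniqueness of subject ids.
#'
#' @param table Data frame to validate.
#' @param roi_names Expected ROI column names (default the 8 DMN nodes).
#' @return The table, invisibly; errors on violation.
#' @export
validate_volume_table <- function(table, roi_names = dmn_nodes()) {
  stopifnot(is.data.frame(table))
  missing_cols <- setdiff(c("subject_id", "group", roi_names), names(table))
  if (length(missing_cols)) {
    stop("volume table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(table$subject_id)) stop("duplicate subject_id values")
  bad_group <- setdiff(unique(table$group), c("NC", "AD"))
  if (length(bad_group)) {
    stop("group labels must be 'NC' or 'AD'; found: ",
         paste(bad_group, collapse = ", "))
  }
  vals <- as.matrix(table[, roi_names, drop = FALSE])
  if (!is.numeric(vals) || any(!is.finite(vals))) {
    stop("ROI columns must be finite numeric values")
  }
  invisible(table)
}

#' Read / write a volume table as CSV
#'
#' Column order is `subject_id,group` followed by the ROI columns.
#'
#' @param path CSV file path.
#' @param table Volume table data.frame.
#' @param roi_names ROI column names for validation.
#' @return `read_volume_table` returns the validated data.frame;
#'   `write_volume_table` returns `path` invisibly.
#' @export
read_volume_table <- function(path, roi_names = dmn_nodes()) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_volume_table(tab, roi_names = roi_names)
  tab[, c("subject_id", "group", roi_names)]
}

#' @rdname read_volume_table
#' @export
write_volume_table <- function(table, path, roi_names = dmn_nodes()) {
  validate_volume_table(table, roi_names = roi_names)
  utils::write.csv(table[, c("subject_id", "group", roi_names)], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
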
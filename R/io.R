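#' Read and write dynamic images as NIfTI-1 plus a JSON timing sidecar
#'
#' NIfTI has no universally honoured frame-timing field, so the schedule is
#' serialized as a JSON sidecar next to the image:
#' `{"frame_starts_s": [...], "frame_durations_s": [...]}`. The sidecar path
#' is the image path with `.nii`/`.nii.gz` replaced by `.json`.
#'
#' @param image a [dynamic_image()]
#' @param path output path ending in `.nii` or `.nii.gz`
#' @return `write_dynamic` invisibly returns `path`; `read_dynamic` returns a
#'   `dynamic_image`.
#' @export
write_dynamic <- function(image, path) {
  ni <- set_sform(RNifti::asNifti(image$values), image$affine)
  RNifti::writeNifti(ni, path)
  jsonlite::write_json(
    list(frame_starts_s = image$schedule$starts,
         frame_durations_s = image$schedule$durations),
    sidecar_path(path), digits = NA)
  invisible(path)
}

set_sform <- function(ni, affine) {
  aff <- structure(affine, code = 2L)
  RNifti::sform(ni) <- aff
  ni
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' @rdname write_dynamic
#' @export
read_dynamic <- function(path) {
  ni <- RNifti::readNifti(path)
  vals <- array(as.numeric(ni), dim = dim(ni))
  if (length(dim(vals)) == 3L) dim(vals) <- c(dim(vals), 1L)
  side <- sidecar_path(path)
  if (!file.exists(side)) stop("missing schedule sidecar: ", side)
  js <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (length(js$frame_starts_s) != dim(vals)[4])
    stop(sprintf("schedule sidecar has %d frames but image has %d",
                 length(js$frame_starts_s), dim(vals)[4]))
  sched <- new_frame_schedule(js$frame_starts_s, js$frame_durations_s)
  aff <- nifti_affine(ni)
  dynamic_image(vals, sched, voxel_size = affine_voxel_size(aff), affine = aff)
}

nifti_affine <- function(ni) {
  x <- RNifti::xform(ni, useQuaternionFirst = FALSE)
  matrix(as.numeric(x), 4, 4)
}

affine_voxel_size <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

#' Read and write label maps (NIfTI + id/name TSV)
#'
#' Region names travel as a two-column TSV (`id`, `name`) next to the image,
#' with the same basename and extension `.tsv`.
#' @param lmap a [label_map()]
#' @param path output path ending in `.nii` or `.nii.gz`
#' @export
write_label_map <- function(lmap, path) {
  ni <- set_sform(RNifti::asNifti(array(as.integer(lmap$labels), dim(lmap$labels))),
                  lmap$affine)
  RNifti::writeNifti(ni, path)
  utils::write.table(
    data.frame(id = names(lmap$names), name = unname(lmap$names)),
    sub("\\.nii(\\.gz)?$", ".tsv", path),
    sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  ni <- RNifti::readNifti(path)
  labs <- array(as.integer(ni), dim = dim(ni))
  tsv <- sub("\\.nii(\\.gz)?$", ".tsv", path)
  if (!file.exists(tsv)) stop("missing label name TSV: ", tsv)
  tab <- utils::read.delim(tsv, colClasses = c("character", "character"))
  nm <- stats::setNames(tab$name, tab$id)
  aff <- nifti_affine(ni)
  label_map(labs, nm, voxel_size = affine_voxel_size(aff), affine = aff)
}

#' Write / read a subject metadata table
#'
#' Columns: id, group (control/anoxic/traumatic), genotype (HAB/MAB/LAB),
#' crs_r, state (VS_UWS/MCS/EMCS/deceased), outcome (favourable/unfavourable),
#' excluded_lab.
#' @param subjects data frame of subject records
#' @param path TSV path
#' @export
write_subjects <- function(subjects, path) {
  utils::write.table(subjects, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_subjects
#' @export
read_subjects <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Serialize an SVCA kinetic class set to JSON
#' @param classes a [kinetic_class_set()]
#' @param path JSON path
#' @export
write_classes <- function(classes, path) {
  jsonlite::write_json(list(
    affinity_group = classes$affinity_group,
    n_controls_used = classes$n_controls_used,
    frame_starts_s = classes$schedule$starts,
    frame_durations_s = classes$schedule$durations,
    blood = classes$blood$values,
    specific_gm = classes$specific_gm$values,
    nonspecific_gm = classes$nonspecific_gm$values,
    white_matter = classes$white_matter$values
  ), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_classes
#' @export
read_classes <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  sched <- new_frame_schedule(js$frame_starts_s, js$frame_durations_s)
  kinetic_class_set(
    blood = tac(js$blood, sched),
    specific_gm = tac(js$specific_gm, sched),
    nonspecific_gm = tac(js$nonspecific_gm, sched),
    white_matter = tac(js$white_matter, sched),
    affinity_group = js$affinity_group,
    n_controls_used = js$n_controls_used)
}
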
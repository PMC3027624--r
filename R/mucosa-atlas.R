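#' Construct an atlas bundle
#'
#' @param template [ImageVolume-class] atlas template.
#' @param mucosaLabel logical (or 0/1) 3D array on the template grid.
#' @param metadata free-text provenance.
#' @return an [AtlasBundle-class].
#' @export
AtlasBundle <- function(template, mucosaLabel, metadata = "") {
  if (!is.logical(mucosaLabel)) mucosaLabel <- mucosaLabel != 0
  new("AtlasBundle", template = template, mucosaLabel = mucosaLabel,
      metadata = metadata)
}

#' Read / write an atlas bundle directory
#'
#' An atlas bundle is a directory holding \code{template.nii.gz},
#' \code{mucosa_label.nii.gz} and a \code{metadata.txt}. The mucosa label must
#' share the template grid.
#'
#' @param dir bundle directory.
#' @return [readAtlas()] returns an [AtlasBundle-class]; [writeAtlas()]
#'   returns \code{dir} invisibly.
#' @export
readAtlas <- function(dir) {
  tpl <- readVolume(file.path(dir, "template.nii.gz"))
  lbl <- readMask(file.path(dir, "mucosa_label.nii.gz"), tpl)
  metaPath <- file.path(dir, "metadata.txt")
  meta <- if (file.exists(metaPath))
    paste(readLines(metaPath), collapse = "\n") else ""
  AtlasBundle(tpl, lbl, meta)
}

#' @rdname readAtlas
#' @param atlas an [AtlasBundle-class].
#' @export
writeAtlas <- function(atlas, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeVolume(atlas@template, file.path(dir, "template.nii.gz"))
  writeVolume(array(as.double(atlas@mucosaLabel), dim(atlas@mucosaLabel)),
              file.path(dir, "mucosa_label.nii.gz"),
              reference = atlas@template, datatype = "uint8")
  writeLines(atlas@metadata, file.path(dir, "metadata.txt"))
  invisible(dir)
}

#' Locate the nasal mucosa on a patient scan from the atlas
#'
#' Affine-registers the atlas template to the post-contrast scan and maps the
#' mucosa label with nearest-neighbour interpolation. If the user supplies a
#' manual mucosa region instead of an atlas, it is returned unchanged
#' (detection skipped).
#'
#' @param post post-contrast [ImageVolume-class] covering the nasal region.
#' @param atlas an [AtlasBundle-class], or a [RegionOfInterest-class] with
#'   role \code{"mucosa"} (manual override).
#' @return a [RegionOfInterest-class] with role \code{"mucosa"} and source
#'   \code{"atlas"} (or the override, unchanged).
#' @export
detectMucosa <- function(post, atlas) {
  if (is(atlas, "RegionOfInterest")) {
    if (roiRole(atlas) != "mucosa")
      stop("manual mucosa override must have role 'mucosa'")
    return(atlas)
  }
  stopifnot(is(atlas, "AtlasBundle"))
  t <- tryCatch(registerAffine(atlas@template, post), error = function(e)
    stop("atlas registration failed (", conditionMessage(e),
         "); supply a manual mucosa ROI", call. = FALSE))
  mask <- resampleMaskArray(atlas@mucosaLabel, atlas@template@affine, t, post)
  if (!any(mask))
    stop("atlas mucosa label mapped to an empty region; supply a manual mucosa ROI")
  new("RegionOfInterest", mask = mask, role = "mucosa", source = "atlas",
      refAffine = post@affine)
}
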
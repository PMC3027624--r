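# Geometric ground-truth phantoms emulating the situations the method has to
# handle: a dark resection cavity with a bright post-contrast enhancing rim,
# cavity collapse with rim growth, intrinsically bright "subacute blood"
# (bright on BOTH scans), adjacent thin meningeal enhancement, uniform normal
# parenchyma with a stable global pre/post brightness offset, a strongly
# enhancing nasal-mucosa slab in inferior slices, and Rician noise. No attempt
# at anatomical realism: the value of the phantom is that every voxel's
# noiseless pre/post difference is known exactly.

#' Construct a phantom specification
#'
#' Defaults describe the baseline study condition: a 64 x 64 x 44 grid at
#' 1 mm isotropic spacing, parenchyma 400, global post offset +7, a cavity of
#' radii (9, 8, 7) mm with a 2 mm rim enhancing at +100, mucosa contrast
#' +160 (so the default 25% threshold sits at 40, well below rim contrast),
#' and no noise. See [PhantomSpec-class] for every field.
#'
#' @param ... named [PhantomSpec-class] slot values overriding the defaults.
#' @return a [PhantomSpec-class].
#' @examples
#' spec <- phantomSpec(noise = "rician", sigma = 2, seed = 11L)
#' ph <- generatePhantom(spec)
#' ph$truth@enhancingCount
#' @export
phantomSpec <- function(...) {
  args <- list(...)
  if (!is.null(args$dim)) args$dim <- as.integer(args$dim)
  if (!is.null(args$seed)) args$seed <- as.integer(args$seed)
  do.call(new, c(list("PhantomSpec"), args))
}

# Ellipsoid membership: squared normalized distance <= 1.
.inEllipsoid <- function(X, Y, Z, center, radii) {
  ((X - center[1]) / radii[1])^2 + ((Y - center[2]) / radii[2])^2 +
    ((Z - center[3]) / radii[3])^2 <= 1
}

#' Generate a phantom scan pair with exact ground truth
#'
#' Builds the noiseless pre and post volumes so that \code{post - pre} equals
#' the specified contrast map exactly (global offset everywhere; offset + rim
#' contrast in the rim; offset + mucosa contrast in the mucosa slab; ...),
#' applies the requested noise model, and returns the scan pair together with
#' all ground-truth masks, the drawn-style regions of interest, and an atlas
#' bundle whose template is the phantom's own noiseless post volume.
#' Deterministic for a fixed seed.
#'
#' @param spec a [PhantomSpec-class].
#' @return list with elements \code{pre}, \code{post} ([ImageVolume-class]),
#'   \code{truth} ([PhantomTruth-class]) and \code{atlas}
#'   ([AtlasBundle-class]).
#' @export
generatePhantom <- function(spec) {
  validObject(spec)
  d <- spec@dim
  sp <- spec@spacing
  xs <- (seq_len(d[1]) - 1) * sp[1]
  ys <- (seq_len(d[2]) - 1) * sp[2]
  zs <- (seq_len(d[3]) - 1) * sp[3]
  X <- array(rep(xs, times = d[2] * d[3]), d)
  Y <- array(rep(rep(ys, each = d[1]), times = d[3]), d)
  Z <- array(rep(zs, each = d[1] * d[2]), d)

  fov <- (d - 1) * sp
  headCenter <- fov / 2 + spec@shift
  headRadii <- c(0.40, 0.45, 0.43) * fov
  cavCenter <- spec@cavityCenter + spec@shift
  outerRadii <- spec@cavityRadii + spec@rimThickness

  head <- .inEllipsoid(X, Y, Z, headCenter, headRadii)
  cavity <- .inEllipsoid(X, Y, Z, cavCenter, spec@cavityRadii) & head
  rim <- if (spec@rimThickness > 0 && spec@rimContrast > 0)
    .inEllipsoid(X, Y, Z, cavCenter, outerRadii) & !cavity & head
  else array(FALSE, d)

  # gross tumor region: generous ellipsoid around cavity + rim
  roiR <- if (anyNA(spec@roiRadii)) outerRadii + 2 else spec@roiRadii
  if (any(roiR < outerRadii))
    stop("tumor outline radii do not contain the enhancing rim")
  tumorMask <- .inEllipsoid(X, Y, Z, cavCenter, roiR) & head

  # thin meningeal arc on the head surface lateral to the cavity
  meninges <- array(FALSE, d)
  if (spec@meningesContrast > 0) {
    eHead <- ((X - headCenter[1]) / headRadii[1])^2 +
      ((Y - headCenter[2]) / headRadii[2])^2 +
      ((Z - headCenter[3]) / headRadii[3])^2
    meninges <- eHead > 0.86 & eHead <= 1 &
      X > cavCenter[1] & abs(Y - cavCenter[2]) < 14 &
      abs(Z - cavCenter[3]) < 9 & !tumorMask
    if (!any(meninges))
      stop("meningeal component lies outside the grid geometry")
  }
  tumorGenerous <- tumorMask | meninges

  # nasal mucosa slab, inferior and anterior, outside the head ellipsoid
  mcCenter <- c(fov[1] / 2, 10, 3) + spec@shift
  mucosa <- abs(X - mcCenter[1]) <= 4 & abs(Y - mcCenter[2]) <= 3 &
    abs(Z - mcCenter[3]) <= 1.5
  if (any(mucosa & head)) stop("mucosa slab overlaps the head ellipsoid")

  # normal parenchyma box in the contralateral hemisphere
  nmCenter <- headCenter + c(-14, 0, 0)
  normalBox <- abs(X - nmCenter[1]) <= 6 & abs(Y - nmCenter[2]) <= 8 &
    abs(Z - nmCenter[3]) <= 7
  normalBox <- normalBox & head
  if (any(normalBox & (tumorGenerous | cavity | rim)))
    stop("normal region overlaps tumor geometry")

  if (any(mucosa & tumorGenerous) || any(cavity & meninges))
    stop("phantom regions are not pairwise disjoint")

  pre <- array(0, d)
  pre[head] <- spec@parenchyma
  pre[cavity] <- spec@cavityIntensity
  pre[mucosa] <- 300
  blood <- array(FALSE, d)
  if (spec@bloodIntensity > 0) blood <- cavity

  contrast <- array(0, d)  # post - pre beyond the global offset
  contrast[rim] <- spec@rimContrast
  contrast[meninges] <- spec@meningesContrast
  contrast[mucosa] <- spec@mucosaContrast
  if (spec@bloodIntensity > 0) {
    if (spec@bloodMode == "both") {
      pre[blood] <- pre[blood] + spec@bloodIntensity
    } else {
      contrast[blood] <- contrast[blood] + spec@bloodIntensity
    }
  }
  post <- pre + contrast + spec@offset

  enhancing <- contrast > 0
  if (spec@noise != "none" && spec@sigma > 0) {
    set.seed(spec@seed)
    nvox <- prod(d)
    if (spec@noise == "gaussian") {
      pre <- pre + array(stats::rnorm(nvox, 0, spec@sigma), d)
      post <- post + array(stats::rnorm(nvox, 0, spec@sigma), d)
    } else {
      pre <- sqrt((pre + array(stats::rnorm(nvox, 0, spec@sigma), d))^2 +
                    array(stats::rnorm(nvox, 0, spec@sigma), d)^2)
      post <- sqrt((post + array(stats::rnorm(nvox, 0, spec@sigma), d))^2 +
                     array(stats::rnorm(nvox, 0, spec@sigma), d)^2)
    }
  }

  preVol <- ImageVolume(pre, spacing = sp)
  postVol <- ImageVolume(post, spacing = sp)
  rois <- list(
    tumor = roiFromMask(tumorMask, postVol, "tumor"),
    tumorGenerous = roiFromMask(tumorGenerous, postVol, "tumor"),
    normal = roiFromMask(normalBox, postVol, "normal"),
    mucosa = roiFromMask(mucosa, postVol, "mucosa"))
  truth <- new("PhantomTruth", enhancingMask = enhancing,
               enhancingCount = as.integer(sum(enhancing & tumorMask)),
               cavityMask = cavity, bloodMask = blood,
               meningesMask = meninges, rois = rois, offset = spec@offset)

  # atlas: the phantom's own noiseless post volume as template
  template <- ImageVolume(
    {
      tp <- array(0, d)
      tp[head] <- spec@parenchyma
      tp[cavity] <- spec@cavityIntensity
      tp[mucosa] <- 300
      if (spec@bloodIntensity > 0 && spec@bloodMode == "both")
        tp[blood] <- tp[blood] + spec@bloodIntensity
      tp + contrast + spec@offset
    }, spacing = sp)
  atlas <- AtlasBundle(template, mucosa,
                       metadata = "synthetic phantom self-atlas")
  list(pre = preVol, post = postVol, truth = truth, atlas = atlas)
}

#' Canned phantom scenarios
#'
#' Returns the specification list reproducing each studied situation:
#' \describe{
#'   \item{rim_baseline}{one scan pair with an enhancing rim (Rician noise,
#'     sigma 2 = 2\% of rim contrast).}
#'   \item{cavity_collapse}{two timepoints; the second has a collapsed cavity
#'     (smaller bounding extents) but a thicker rim with more enhancing
#'     voxels, the configuration that misleads diameter-based measures.}
#'   \item{subacute_blood}{two specs on the same cavity: blood added to both
#'     scans (true subacute blood, nothing should be measured) and the
#'     counterfactual with the same intensity added to the post scan only
#'     (genuine enhancement filling the cavity).}
#'   \item{meningeal_rim}{one pair with adjacent meningeal enhancement; the
#'     truth carries both the narrow and the generous tumor region.}
#'   \item{serial_series}{eight timepoints with a prescribed, non-monotonic
#'     true rim-volume trajectory, per-timepoint pose shifts and brightness
#'     offsets.}
#' }
#'
#' @param name scenario name.
#' @param seed integer seed; the same seed gives bit-identical volumes, a
#'   different seed changes only the noise, never the true trajectory.
#' @return list of [PhantomSpec-class] (one per timepoint).
#' @export
phantomScenario <- function(name = c("rim_baseline", "cavity_collapse",
                                     "subacute_blood", "meningeal_rim",
                                     "serial_series"), seed = 1L) {
  if (is.character(name) && length(name) == 1L &&
      !name %in% eval(formals(phantomScenario)$name))
    stop("unknown scenario '", name, "'; valid names: ",
         paste(eval(formals(phantomScenario)$name), collapse = ", "))
  name <- match.arg(name)
  seed <- as.integer(seed)
  base <- list(noise = "rician", sigma = 2, seed = seed)
  mk <- function(...) do.call(phantomSpec, utils::modifyList(base, list(...)))
  switch(name,
    rim_baseline = list(mk()),
    cavity_collapse = list(
      mk(cavityRadii = c(11, 10, 8), rimThickness = 1.5, offset = 7),
      mk(cavityRadii = c(6.6, 6, 4.8), rimThickness = 4, offset = 10,
         seed = seed + 1000L)),
    subacute_blood = list(
      mk(rimThickness = 0, rimContrast = 0, bloodIntensity = 350,
         bloodMode = "both"),
      mk(rimThickness = 0, rimContrast = 0, bloodIntensity = 350,
         bloodMode = "post", seed = seed + 1000L)),
    meningeal_rim = list(mk(meningesContrast = 80)),
    serial_series = {
      thickness <- c(1.5, 2.5, 2.25, 3.5, 3, 1.75, 4, 2.75)
      offsets <- c(7, 11, 5, 9, 13, 6, 8, 10)
      shifts <- list(c(0, 0, 0), c(2, -1, 1), c(-2, 1, 0), c(1, 2, -1),
                     c(-1, -2, 1), c(2, 1, -1), c(-2, -1, 0), c(1, -1, 1))
      lapply(seq_len(8L), function(i)
        mk(meningesContrast = 80, rimThickness = thickness[i],
           offset = offsets[i], shift = shifts[[i]],
           roiRadii = c(9, 8, 7) + 6.5,
           seed = seed + 1000L * (i - 1L)))
    })
}

#' Write a phantom fixture directory
#'
#' Writes, per timepoint, \code{pre.nii.gz}, \code{post.nii.gz} and
#' \code{rois/*.nii.gz}, plus one shared \code{atlas/} bundle (from the first
#' timepoint) and a \code{truth.json} with the true enhancing counts, cavity
#' sizes and applied offsets. Output is deterministic: repeating the call
#' reproduces identical files.
#'
#' @param specs a scenario name (see [phantomScenario()]) or a list of
#'   [PhantomSpec-class].
#' @param dir output directory.
#' @param seed seed used when \code{specs} is a scenario name.
#' @return \code{dir}, invisibly.
#' @export
writePhantomFixture <- function(specs, dir, seed = 1L) {
  if (is.character(specs)) specs <- phantomScenario(specs, seed = seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truthAll <- list()
  for (i in seq_along(specs)) {
    ph <- generatePhantom(specs[[i]])
    tdir <- file.path(dir, sprintf("timepoint_%02d", i))
    dir.create(file.path(tdir, "rois"), showWarnings = FALSE, recursive = TRUE)
    writeVolume(ph$pre, file.path(tdir, "pre.nii.gz"))
    writeVolume(ph$post, file.path(tdir, "post.nii.gz"))
    for (rn in names(ph$truth@rois)) {
      roi <- ph$truth@rois[[rn]]
      writeVolume(array(as.double(roi@mask), dim(roi@mask)),
                  file.path(tdir, "rois", paste0(rn, ".nii.gz")),
                  reference = ph$post, datatype = "uint8")
    }
    if (i == 1L) writeAtlas(ph$atlas, file.path(dir, "atlas"))
    truthAll[[sprintf("timepoint_%02d", i)]] <- list(
      enhancing_voxels = ph$truth@enhancingCount,
      enhancing_volume_cm3 = ph$truth@enhancingCount *
        voxelVolume(ph$post) / 1000,
      cavity_voxels = sum(ph$truth@cavityMask),
      blood_voxels = sum(ph$truth@bloodMask),
      offset = ph$truth@offset,
      seed = specs[[i]]@seed)
  }
  jsonlite::write_json(truthAll, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
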
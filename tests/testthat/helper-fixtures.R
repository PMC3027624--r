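# Shared fixtures, built once per test run and cached. All fixtures are
# generated in code; nothing binary lives in the repository.

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtureCache))
    assign(name, builder(), envir = .fixtureCache)
  get(name, envir = .fixtureCache)
}

# Noiseless baseline rim phantom.
fxNoiseless <- function() fixture("noiseless", function() {
  generatePhantom(phantomSpec(noise = "none"))
})

# Noiseless phantom plus its full quantification.
fxNoiselessResult <- function() fixture("noiselessResult", function() {
  ph <- fxNoiseless()
  res <- quantifyEnhancement(ph$pre, ph$post, ph$truth@rois$tumor,
                             ph$truth@rois$normal, ph$truth@rois$mucosa)
  list(ph = ph, res = res)
})

# A small SubtractionMap whose values can be set directly: both volumes share
# a flat background, the difference is planted into a normal-region box.
fxPlantedSubtraction <- function(values) {
  d <- c(12L, 12L, 8L)
  need <- prod(c(8, 8, 6))
  stopifnot(length(values) <= need)
  pre <- array(100, d)
  post <- array(100, d)
  box <- array(FALSE, d)
  box[3:10, 3:10, 2:7] <- TRUE
  vals <- rep_len(c(values, rep(values[length(values)],
                                need - length(values))), need)
  vals[seq_along(values)] <- values
  post[box] <- 100 + vals
  preVol <- ImageVolume(pre)
  postVol <- ImageVolume(post)
  list(sub = subtractVolumes(postVol, preVol),
       roi = roiFromMask(box, postVol, "normal"),
       post = postVol, box = box)
}
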
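#' Registration configuration constructor
#'
#' @param mode "3d" (trilinear warp, volumetric feature regions; the default,
#'   since the margin is a 3D quantity) or "2d" (slice-wise warp with the
#'   in-plane tent kernel, matching thick-slice acquisitions; the through-slice
#'   displacement component is held at zero)
#' @param controlSpacing control-point spacing in voxels (z, y, x); default 2
#'   slices through-plane, 8 voxels in-plane
#' @param featureLevels number of conv + max-pooling stages of the similarity
#'   network (default 5)
#' @param blockPartition regions per axis for the block-wise similarity;
#'   (z, y, x) in 3d mode — default 2 x 4 x 4 — or (y, x) per slice in 2d
#'   mode — default 4 x 4
#' @param maxIters optimisation budget (default 200)
#' @param tolerance relative loss-change stopping threshold (default 1e-4)
#' @param learningRate step size in voxels per iteration on the control
#'   lattice (default 0.1)
#' @param momentum heavy-ball momentum coefficient (default 0.9)
#' @param seed seed for the fixed random convolutional weights and any other
#'   randomness; identical config + seed gives bit-identical results
#' @param smoothnessWeight weight of the bending-energy penalty on the
#'   control lattice (default 0.01; 0 recovers the bare similarity objective)
#' @param channelsBase channels of the first conv level, doubling per level
#' @param translationInit fit a global translation (NCC grid search) before
#'   the non-rigid optimisation (default TRUE)
#' @param headInit "zero" (regression head zero-initialised, so the localizer
#'   proposes the identity field) or "random" (small seeded random head)
#' @param dropDegenerateBlocks how to treat zero-norm feature blocks from
#'   constant regions: drop them from the similarity sum (TRUE, default here
#'   so background-only regions do not abort a run) or raise an error (FALSE)
#' @return a \code{\linkS4class{RegistrationConfig}}
#' @export
registrationConfig <- function(mode = c("3d", "2d"),
                               controlSpacing = c(2, 8, 8),
                               featureLevels = 5L,
                               blockPartition = NULL,
                               maxIters = 200L,
                               tolerance = 1e-4,
                               learningRate = 0.1,
                               momentum = 0.9,
                               seed = 1L,
                               smoothnessWeight = 0.01,
                               channelsBase = 8L,
                               translationInit = TRUE,
                               headInit = c("zero", "random"),
                               dropDegenerateBlocks = TRUE) {
  mode <- match.arg(mode)
  headInit <- match.arg(headInit)
  if (is.null(blockPartition))
    blockPartition <- if (mode == "3d") c(2L, 4L, 4L) else c(4L, 4L)
  new("RegistrationConfig", mode = mode,
      controlSpacing = as.numeric(controlSpacing),
      featureLevels = as.integer(featureLevels),
      blockPartition = as.integer(blockPartition),
      maxIters = as.integer(maxIters), tolerance = tolerance,
      learningRate = learningRate, momentum = momentum,
      seed = as.integer(seed), smoothnessWeight = smoothnessWeight,
      channelsBase = as.integer(channelsBase),
      translationInit = translationInit, headInit = headInit,
      dropDegenerateBlocks = dropDegenerateBlocks)
}

# evaluate expr under a temporary seed without disturbing the global RNG
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Fixed random convolution weights, He-scaled, one (K*Cin x Cout) matrix per
# level. Deterministic in (seed, levels, channelsBase, dimensionality).
makeConvWeights <- function(seed, levels, channelsBase, is3d) {
  k <- if (is3d) 27L else 9L
  withSeed(seed, {
    lapply(seq_len(levels), function(l) {
      cin <- if (l == 1L) 1L else channelsBase * 2L^(l - 2L)
      cout <- channelsBase * 2L^(l - 1L)
      matrix(stats::rnorm(k * cin * cout, sd = sqrt(2 / (k * cin))),
             nrow = k * cin, ncol = cout)
    })
  })
}

# split 1..n into p near-equal contiguous chunks
splitIdx <- function(n, p) {
  bounds <- floor(seq(0, n, length.out = p + 1))
  lapply(seq_len(p), function(i) (bounds[i] + 1):bounds[i + 1])
}

# Region partition of a volume. 3d mode: blockPartition = (pz, py, px)
# volumetric tiles. 2d mode: blockPartition = (py, px) tiles on every slice.
regionPartition <- function(shape, config) {
  bp <- config@blockPartition
  if (config@mode == "3d") {
    zs <- splitIdx(shape[1], bp[1]); ys <- splitIdx(shape[2], bp[2])
    xs <- splitIdx(shape[3], bp[3])
    regions <- list()
    for (x in xs) for (y in ys) for (z in zs)
      regions[[length(regions) + 1L]] <- list(z = z, y = y, x = x)
  } else {
    ys <- splitIdx(shape[2], bp[1]); xs <- splitIdx(shape[3], bp[2])
    regions <- list()
    for (iz in seq_len(shape[1])) for (x in xs) for (y in ys)
      regions[[length(regions) + 1L]] <- list(z = iz, y = y, x = x)
  }
  regions
}

checkRegionSize <- function(regions, config) {
  is3d <- config@mode == "3d"
  minNeeded <- 2^config@featureLevels
  for (r in regions) {
    dims <- if (is3d) c(length(r$z), length(r$y), length(r$x))
            else c(length(r$y), length(r$x))
    if (any(dims < minNeeded))
      stop("configuration error: a ", paste(dims, collapse = "x"),
           " region cannot support ", config@featureLevels,
           " pooling levels (needs >= ", minNeeded, " per processed axis)")
  }
  invisible(TRUE)
}

regionArray <- function(a, r, is3d) {
  sub <- a[r$z, r$y, r$x, drop = FALSE]
  if (is3d) list(arr = as.numeric(sub), rdims = dim(sub))
  else list(arr = as.numeric(sub), rdims = c(dim(sub)[2], dim(sub)[3], 1L))
}

#' Extract block-wise multiscale deep features
#'
#' Partitions the image into regions and passes each region through a stack
#' of fixed random 3x3(x3) convolutions, each followed by ReLU and 2x
#' max-pooling; the global mean of every pooled map is concatenated across
#' levels into one feature vector per region. Max-pooling gives the features
#' local translation robustness; the fixed seeded weights make the extractor
#' deterministic.
#'
#' @param image a \code{\linkS4class{Volume}} (or 3D array); intensities are
#'   min-max normalised to [0, 1] first
#' @param config a \code{\linkS4class{RegistrationConfig}}
#' @return a \code{\linkS4class{FeatureBlocks}}
#' @export
extractFeatures <- function(image, config = registrationConfig()) {
  a <- if (is(image, "Volume")) image@data else image
  stopifnot(length(dim(a)) == 3L)
  a <- normalize01(a)
  regions <- regionPartition(dim(a), config)
  checkRegionSize(regions, config)
  is3d <- config@mode == "3d"
  w <- makeConvWeights(config@seed, config@featureLevels, config@channelsBase,
                       is3d)
  feats <- lapply(regions, function(r) {
    ra <- regionArray(a, r, is3d)
    cppRegionFeatures(ra$arr, as.integer(ra$rdims), w, is3d)
  })
  new("FeatureBlocks", blocks = do.call(cbind, feats),
      geometry = list(mode = config@mode, shape = dim(a), regions = regions))
}

normalize01 <- function(a) {
  rng <- range(a)
  if (rng[2] > rng[1]) (a - rng[1]) / (rng[2] - rng[1]) else a * 0
}
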
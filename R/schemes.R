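## Biopsy scheme planning: anatomically parameterised 12-core TRUS
## template and transperineal template-targeted cores optimised for
## total cancer core length.

#' Default 12-core TRUS scheme parameters
#'
#' The sextant-with-lateral template: left/right x base/mid/apex x
#' medial/lateral. Planned midpoints sit at fractions of the gland
#' semi-axes (x: +/-0.25 medial, +/-0.65 lateral; y: -0.5, the
#' posterior peripheral zone; z: +0.5 base, 0 mid, -0.5 apex), with
#' trajectories fanning from the anus reference point. Per-repetition
#' Gaussian jitter on each planned midpoint models probe/needle
#' insertion variability.
#'
#' @param xFractions medial/lateral placement fractions of the lateral semi-axis
#' @param yFraction antero-posterior placement fraction (negative = posterior)
#' @param zFractions base/mid/apex placement fractions of the base-apex semi-axis
#' @param jitterSd per-axis SD (mm) of anatomic placement jitter
#' @return a list of scheme parameters for [planTrus12()]
#' @export
defaultTrusScheme <- function(xFractions = c(medial = 0.25, lateral = 0.65),
                              yFraction = -0.5,
                              zFractions = c(base = 0.5, mid = 0, apex = -0.5),
                              jitterSd = 1.5) {
  stopifnot(all(abs(xFractions) <= 1), abs(yFraction) <= 1,
            all(abs(zFractions) <= 1), jitterSd >= 0)
  list(xFractions = xFractions, yFraction = yFraction,
       zFractions = zFractions, jitterSd = jitterSd)
}

#' Plan a systematic 12-core TRUS biopsy
#'
#' Core placement is driven purely by gland anatomy (capsule geometry
#' and the anus reference); lesion positions are never read, so the
#' scheme is blinded to the pathology. Jitter is drawn from the current
#' RNG state; set a seed (or use [runStrategy()]) for determinism.
#'
#' @param model a [ProstateModel-class]
#' @param scheme parameters from [defaultTrusScheme()]
#' @param effectiveLength sampling-notch length, mm
#' @param jitter apply anatomic placement jitter?
#' @return a [BiopsyPlan-class] with 12 cores
#' @export
planTrus12 <- function(model, scheme = defaultTrusScheme(),
                       effectiveLength = 17, jitter = TRUE) {
  stopifnot(is(model, "ProstateModel"))
  ax <- model@glandSemiAxes
  gc <- model@glandCentre
  slots <- expand.grid(side = c(-1, 1),
                       pos = names(scheme$xFractions),
                       level = names(scheme$zFractions),
                       stringsAsFactors = FALSE)
  mid <- cbind(
    gc[1] + slots$side * scheme$xFractions[slots$pos] * ax[1],
    gc[2] + scheme$yFraction * ax[2],
    gc[3] + scheme$zFractions[slots$level] * ax[3])
  if (jitter && scheme$jitterSd > 0)
    mid <- mid + matrix(rnorm(length(mid), 0, scheme$jitterSd), nrow(mid), 3)
  dirs <- mid - matrix(model@anusRef, nrow(mid), 3, byrow = TRUE)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  cores <- data.frame(
    slot = paste(ifelse(slots$side < 0, "L", "R"), slots$level, slots$pos,
                 sep = "-"),
    midX = mid[, 1], midY = mid[, 2], midZ = mid[, 3],
    dirX = dirs[, 1], dirY = dirs[, 2], dirZ = dirs[, 3],
    effectiveLength = effectiveLength, stringsAsFactors = FALSE)
  new("BiopsyPlan", strategy = "TRUS12", cores = cores,
      targetId = character(0))
}

#' Imaging-eligible targets of a model
#'
#' Any lesion (true or false-positive) whose volume is at least
#' \code{threshold} ml is an imaging target; returned sorted by volume
#' descending.
#'
#' @param model a [ProstateModel-class]
#' @param threshold minimum target volume, ml (default 0.2)
#' @return character vector of lesion ids (possibly empty, in which case
#'   the model reverts to TRUS-only analysis)
#' @export
eligibleTargets <- function(model, threshold = 0.2) {
  stopifnot(is(model, "ProstateModel"), threshold > 0)
  les <- model@lesions
  les <- les[les$volume >= threshold, , drop = FALSE]
  les$id[order(-les$volume)]
}

#' Plan a transperineal template-targeted biopsy
#'
#' Chooses \code{k} positions on the 5-mm template lattice maximising
#' the total cancer core length obtainable from the imaged target: at
#' each lattice position the needle (along the template direction) is
#' aimed at the deepest part of the lesion, i.e. the core's effective
#' segment is centred on its maximal chord through the target, and the
#' \code{k} distinct positions with the longest chords are taken
#' (greedy; for independent per-core lengths this equals the exhaustive
#' lattice optimum). Ties are broken by distance to the target centroid,
#' then lexicographic grid order. Planning uses the imaged target's
#' shape: for a false-positive target, the benign region's geometry.
#'
#' If fewer than \code{k} lattice positions intersect the target, the
#' remaining cores are stacked on the best position with a warning.
#'
#' @param model a [ProstateModel-class]
#' @param k number of targeted cores (1-5)
#' @param grid a [TemplateGrid-class]
#' @param effectiveLength sampling-notch length, mm
#' @param targetThreshold minimum target volume, ml
#' @return a [BiopsyPlan-class] with k cores
#' @export
planTargeted <- function(model, k, grid = templateGrid(),
                         effectiveLength = 17, targetThreshold = 0.2) {
  stopifnot(is(model, "ProstateModel"), k >= 1, k <= 5)
  targets <- eligibleTargets(model, targetThreshold)
  if (!length(targets))
    stop("no eligible target (no lesion >= ", targetThreshold,
         " ml); model reverts to TRUS-only analysis")
  les <- model@lesions[model@lesions$id == targets[1], , drop = FALSE]
  sp <- grid@spacing
  ct <- cos(les$theta); st <- sin(les$theta)
  extX <- sqrt((les$ax * ct)^2 + (les$ay * st)^2)
  extY <- sqrt((les$ax * st)^2 + (les$ay * ct)^2)
  is <- seq(ceiling((les$cx - extX - grid@anchor[1]) / sp),
            floor((les$cx + extX - grid@anchor[1]) / sp))
  js <- seq(ceiling((les$cy - extY - grid@anchor[2]) / sp),
            floor((les$cy + extY - grid@anchor[2]) / sp))
  cand <- expand.grid(i = is, j = js)
  if (!nrow(cand))
    cand <- data.frame(i = round((les$cx - grid@anchor[1]) / sp),
                       j = round((les$cy - grid@anchor[2]) / sp))
  x <- grid@anchor[1] + cand$i * sp
  y <- grid@anchor[2] + cand$j * sp
  ## long probe along the template direction through each lattice position
  probeMid <- cbind(x, y, rep(les$cz, length(x)))
  dirs <- matrix(grid@direction, length(x), 3, byrow = TRUE)
  iv <- .lesionIntervals(probeMid, dirs, 1e4, les)
  chord <- ifelse(is.na(iv[, 1]), 0, iv[, 2] - iv[, 1])
  midT <- (iv[, 1] + iv[, 2]) / 2
  dist <- sqrt((x - les$cx)^2 + (y - les$cy)^2)
  o <- order(-chord, dist, cand$i, cand$j)
  hits <- o[chord[o] > 0]
  if (!length(hits)) hits <- o[1]
  if (length(hits) < k) {
    warning("only ", length(hits), " lattice position(s) intersect the ",
            "target; stacking remaining core(s) on the best position")
    hits <- c(hits, rep(hits[1], k - length(hits)))
  }
  sel <- hits[seq_len(k)]
  ## centre the effective segment on the chord midpoint
  mid <- probeMid[sel, , drop = FALSE] +
    outer(ifelse(is.na(midT[sel]), 0, midT[sel]), grid@direction)
  cores <- data.frame(
    gridCol = cand$i[sel], gridRow = 2 + cand$j[sel],
    midX = mid[, 1], midY = mid[, 2], midZ = mid[, 3],
    dirX = grid@direction[1], dirY = grid@direction[2],
    dirZ = grid@direction[3],
    effectiveLength = effectiveLength,
    plannedChord = pmin(chord[sel], effectiveLength),
    stringsAsFactors = FALSE)
  new("BiopsyPlan", strategy = paste0("TARGETED_", k), cores = cores,
      targetId = targets[1])
}
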
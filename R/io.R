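## Plain-text I/O: the contour-stack interchange format and the flat
## YAML run configuration.

#' Write a contour stack to a text file
#'
#' Format (one file per model, whitespace-delimited, mm):
#' \preformatted{
#' contour-stack 1
#' slice_thickness <mm>
#' n_slices <n>
#' slice <index> <axial position mm> <n structures>
#' structure <label> <n vertices>
#' <x> <y>          # one vertex per line, counter-clockwise,
#' ...              # polygon implicitly closed
#' }
#' Structure labels are \code{capsule} or \code{lesion:<id>}; the slice
#' index times the thickness gives the axial coordinate.
#'
#' @param stack a [ContourStack-class]
#' @param path output file
#' @return \code{path}, invisibly
#' @export
writeContourStack <- function(stack, path) {
  stopifnot(is(stack, "ContourStack"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("contour-stack 1",
               paste("slice_thickness", format(stack@sliceThickness)),
               paste("n_slices", length(stack@slices))), con)
  for (i in seq_along(stack@slices)) {
    s <- stack@slices[[i]]
    writeLines(paste("slice", i, format(s$position, digits = 12),
                     length(s$structures)), con)
    for (label in names(s$structures)) {
      p <- s$structures[[label]]
      writeLines(paste("structure", label, nrow(p)), con)
      writeLines(paste(format(p[, 1], digits = 12),
                       format(p[, 2], digits = 12)), con)
    }
  }
  invisible(path)
}

.ioStop <- function(lineNo, msg) stop("contour stack, line ", lineNo, ": ", msg)

#' Read a contour stack from a text file
#'
#' Validates the format written by [writeContourStack()]: strictly
#' increasing, uniformly spaced axial positions; known structure labels
#' (\code{capsule}, \code{lesion:<id>}); simple closed polygons with at
#' least 3 vertices. Malformed files are rejected with line-level
#' diagnostics. Slices with an empty structure list are accepted (gap
#' slices) and flagged in the stack notes.
#'
#' @param path input file
#' @return a [ContourStack-class]
#' @export
readContourStack <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^contour-stack 1\\b", lines[1]))
    .ioStop(1, "missing 'contour-stack 1' header")
  tok <- function(i) strsplit(trimws(lines[i]), "\\s+")[[1]]
  t2 <- tok(2)
  if (length(t2) != 2L || t2[1] != "slice_thickness")
    .ioStop(2, "expected 'slice_thickness <mm>'")
  thickness <- as.numeric(t2[2])
  if (!is.finite(thickness) || thickness <= 0)
    .ioStop(2, "slice thickness must be a positive number")
  t3 <- tok(3)
  if (length(t3) != 2L || t3[1] != "n_slices")
    .ioStop(3, "expected 'n_slices <n>'")
  nSlices <- as.integer(t3[2])
  i <- 4L
  slices <- vector("list", nSlices)
  notes <- character(0)
  for (si in seq_len(nSlices)) {
    if (i > length(lines)) .ioStop(i, "unexpected end of file")
    t <- tok(i)
    if (length(t) != 4L || t[1] != "slice")
      .ioStop(i, "expected 'slice <index> <position> <n structures>'")
    pos <- as.numeric(t[3])
    nStruct <- as.integer(t[4])
    if (!is.finite(pos)) .ioStop(i, "bad axial position")
    if (is.na(nStruct) || nStruct < 0) .ioStop(i, "bad structure count")
    if (nStruct == 0L)
      notes <- c(notes, sprintf("slice %d has no structures (gap slice)", si))
    i <- i + 1L
    structures <- list()
    for (sj in seq_len(nStruct)) {
      t <- tok(i)
      if (length(t) != 3L || t[1] != "structure")
        .ioStop(i, "expected 'structure <label> <n vertices>'")
      label <- t[2]
      if (label != "capsule" && !grepl("^lesion:.+", label))
        .ioStop(i, paste0("unknown structure label '", label, "'"))
      nv <- as.integer(t[3])
      if (is.na(nv) || nv < 3L) .ioStop(i, "a polygon needs >= 3 vertices")
      i <- i + 1L
      if (i + nv - 1L > length(lines)) .ioStop(i, "truncated vertex list")
      xy <- do.call(rbind, lapply(lines[i:(i + nv - 1L)], function(l)
        as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
      if (ncol(xy) != 2L || anyNA(xy)) .ioStop(i, "bad vertex coordinates")
      structures[[label]] <- unname(xy)
      i <- i + nv
    }
    slices[[si]] <- list(position = pos, structures = structures)
  }
  pos <- vapply(slices, function(s) s$position, numeric(1))
  if (any(diff(pos) <= 0))
    stop("contour stack: axial positions must be strictly increasing")
  if (length(pos) > 1L && any(abs(diff(pos) - thickness) > 1e-6))
    stop("contour stack: non-uniform slice spacing")
  new("ContourStack", sliceThickness = thickness, slices = slices,
      notes = notes)
}

#' Write / read the flat run configuration
#'
#' The configuration is a flat YAML map (see [defaultRunConfig()]); it
#' round-trips losslessly through these functions.
#'
#' @param config a run configuration list
#' @param path file path
#' @return \code{readRunConfig} returns the configuration list;
#'   \code{writeRunConfig} returns \code{path} invisibly
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  .validateRunConfig(cfg)
  cfg
}
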
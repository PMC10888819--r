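# Readers and writers for the package's on-disk interfaces: PNG
# sections and label maps, GMT gene sets, ASCII PLY meshes, long-format
# expression tensors.

#' Write / read a section image as PNG
#'
#' @param section a [LabeledSection-class] or H x W x 3 array.
#' @param file output path.
#' @return The file path, invisibly.
#' @export
writeSectionPng <- function(section, file) {
  img <- if (methods::is(section, "LabeledSection")) section@image else section
  png::writePNG(clamp(img), file)
  invisible(file)
}

#' @rdname writeSectionPng
#' @export
readSectionPng <- function(file) {
  img <- png::readPNG(file)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}

#' Write / read an integer label map as single-channel PNG
#'
#' Labels (0..255) are stored in the 8-bit gray channel.
#'
#' @param labels integer matrix.
#' @param file path.
#' @return The file path (writer) or integer matrix (reader).
#' @export
writeLabelMapPng <- function(labels, file) {
  stopIfNot(max(labels) <= 255, "label values must fit 8 bits")
  png::writePNG(labels / 255, file)
  invisible(file)
}

#' @rdname writeLabelMapPng
#' @export
readLabelMapPng <- function(file) {
  m <- png::readPNG(file)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  out <- round(m * 255)
  storage.mode(out) <- "integer"
  out
}

#' Write / read gene sets in GMT format
#'
#' @param geneSets named list of character vectors.
#' @param file path.
#' @return File path (writer); named list (reader, via
#'   `fgsea::gmtPathways`).
#' @export
writeGmt <- function(geneSets, file) {
  lines <- vapply(names(geneSets), function(nm)
    paste(c(nm, "na", geneSets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, file)
  invisible(file)
}

#' @rdname writeGmt
#' @export
readGmt <- function(file) fgsea::gmtPathways(file)

#' Write a surface mesh as ASCII PLY
#'
#' @param vertices V x 3 matrix (mm).
#' @param faces F x 3 integer matrix (1-based).
#' @param file path.
#' @export
writeMeshPly <- function(vertices, faces, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  utils::write.table(format(vertices, trim = TRUE), con, col.names = FALSE,
                     row.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, faces - 1L), con, col.names = FALSE,
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Long-format export / import of an expression tensor
#'
#' One row per non-missing (gene, specimen, region, zone) cell.
#'
#' @param tensor an [ExpressionTensor-class].
#' @param file TSV path.
#' @return File path (writer); [ExpressionTensor-class] (reader; ages
#'   from the `agePcw` column).
#' @export
writeTensorTsv <- function(tensor, file) {
  d <- dimnames(tensor@values)
  grid <- expand.grid(gene = d[[1]], specimen = d[[2]], region = d[[3]],
                      zone = d[[4]], KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid$value <- as.numeric(tensor@values)
  grid$agePcw <- tensor@specimenAge[grid$specimen]
  writeTsv(grid[!is.na(grid$value), ], file)
}

#' @rdname writeTensorTsv
#' @export
readTensorTsv <- function(file) {
  df <- readTsv(file)
  gs <- unique(df$gene); sp <- unique(df$specimen)
  rg <- unique(df$region); zn <- unique(df$zone)
  vals <- array(NA_real_, c(length(gs), length(sp), length(rg), length(zn)),
                dimnames = list(gs, sp, rg, zn))
  vals[cbind(match(df$gene, gs), match(df$specimen, sp),
             match(df$region, rg), match(df$zone, zn))] <- df$value
  age <- tapply(df$agePcw, df$specimen, function(a) a[1])
  expressionTensor(vals, stats::setNames(as.numeric(age), names(age)))
}
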
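#' Read and write LAI cubes and masks as plain-text grids
#'
#' Rasters are serialized as plain CSV plus a JSON sidecar (`<path>.json`)
#' holding the composite day labels, affine geotransform, nodata sentinel
#' and array dimensions, so that artifacts are portable text. A cube is
#' written in long form (`composite,row,col,lai`); a mask as a plain
#' integer grid without headers.
#'
#' @param cube an `lai_cube` (see [make_lai_cube()]).
#' @param path output CSV path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_lai_cube <- function(cube, path) {
  a <- unclass(cube)
  dm <- dim(a)
  long <- data.frame(
    composite = rep(seq_len(dm[1]), times = dm[2] * dm[3]),
    row = rep(rep(seq_len(dm[2]), each = dm[1]), times = dm[3]),
    col = rep(seq_len(dm[3]), each = dm[1] * dm[2]),
    lai = as.vector(a)
  )
  utils::write.csv(long, path, row.names = FALSE)
  meta <- list(dim = dm, dates = attr(cube, "dates"),
               transform = attr(cube, "transform"),
               nodata = attr(cube, "nodata"),
               season = attr(cube, "season"))
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_lai_cube
#' @export
read_lai_cube <- function(path) {
  long <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  a <- array(NA_real_, dim = meta$dim)
  a[cbind(long$composite, long$row, long$col)] <- long$lai
  attr(a, "dates") <- meta$dates
  attr(a, "transform") <- meta$transform
  attr(a, "nodata") <- meta$nodata
  attr(a, "season") <- meta$season
  class(a) <- "lai_cube"
  a
}

#' @rdname write_lai_cube
#' @param mask byte raster matrix (1/0/NA).
#' @export
write_mask <- function(mask, path) {
  utils::write.table(mask, path, row.names = FALSE, col.names = FALSE,
                     sep = ",")
  meta <- list(dim = dim(mask), transform = attr(mask, "transform"))
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_lai_cube
#' @export
read_mask <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(m) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  storage.mode(m) <- "integer"
  attr(m, "transform") <- meta$transform
  m
}
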
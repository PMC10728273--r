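# Minimal NPY v1.0 reader/writer (one array per file). Arrays are written in
# Fortran (column-major) order, which the format records in its header, so
# files round-trip exactly and stay readable by any standard NPY consumer.

npyDescr <- c(float32 = "<f4", float64 = "<f8", int32 = "<i4", uint8 = "|u1")

#' Write an array to an NPY file
#'
#' @param x numeric/integer vector, matrix or array.
#' @param path output file path.
#' @param dtype one of `"float32"`, `"float64"`, `"int32"`, `"uint8"`.
#' @return `path`, invisibly.
#' @export
npyWrite <- function(x, path, dtype = c("float32", "float64", "int32", "uint8")) {
  dtype <- match.arg(dtype)
  shape <- if (is.null(dim(x))) length(x) else dim(x)
  shapeStr <- if (length(shape) == 1L) sprintf("(%d,)", shape)
    else sprintf("(%s)", paste(shape, collapse = ", "))
  header <- sprintf("{'descr': '%s', 'fortran_order': True, 'shape': %s, }",
                    npyDescr[[dtype]], shapeStr)
  # pad so magic(6) + version(2) + hlen(2) + header is a multiple of 64
  total <- 10L + nchar(header) + 1L
  pad <- (64L - total %% 64L) %% 64L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(0x93), charToRaw("NUMPY"), as.raw(c(1L, 0L))), con)
  writeBin(as.integer(nchar(header)), con, size = 2, endian = "little")
  writeChar(header, con, eos = NULL)
  v <- as.vector(x)
  switch(dtype,
    float32 = writeBin(as.numeric(v), con, size = 4, endian = "little"),
    float64 = writeBin(as.numeric(v), con, size = 8, endian = "little"),
    int32   = writeBin(as.integer(v), con, size = 4, endian = "little"),
    uint8   = writeBin(as.raw(as.integer(v)), con))
  invisible(path)
}

#' Read an NPY file written by [npyWrite()] (or any v1.x NPY file with a
#' supported dtype)
#'
#' @param path NPY file path.
#' @return An array with the stored shape (integer for int32/uint8 files).
#' @export
npyRead <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6)
  if (!identical(magic, c(as.raw(0x93), charToRaw("NUMPY"))))
    stop("not an NPY file: ", path)
  readBin(con, "raw", 2)  # version
  hlen <- readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE)
  header <- readChar(con, hlen, useBytes = TRUE)
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shapeStr <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("\\s", "", shapeStr), ",")[[1]])
  n <- prod(shape)
  v <- switch(descr,
    "<f4" = readBin(con, "numeric", n, size = 4, endian = "little"),
    "<f8" = readBin(con, "numeric", n, size = 8, endian = "little"),
    "<i4" = readBin(con, "integer", n, size = 4, endian = "little"),
    "|u1" = as.integer(readBin(con, "raw", n)),
    stop("unsupported NPY dtype: ", descr))
  if (length(shape) > 1L) {
    if (fortran) {
      dim(v) <- shape
    } else {
      dim(v) <- rev(shape)
      v <- aperm(v, rev(seq_along(shape)))
    }
  }
  v
}
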
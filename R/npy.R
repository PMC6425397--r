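#' Read and write NumPy .npy arrays
#'
#' Minimal serializer for the NumPy binary array format (version 1.0),
#' covering the dtypes that connectome releases and saved dynamics use:
#' little-endian float64 and int64/int32, 1- or 2-dimensional, C or Fortran
#' order. Matrices are written in C order as float64.
#'
#' @param path file path ending in \code{.npy}.
#' @return \code{read_npy} returns a numeric vector or matrix.
#' @export
read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 6L)
  if (!identical(magic, as.raw(c(0x93, utf8ToInt("N"), utf8ToInt("U"),
                                 utf8ToInt("M"), utf8ToInt("P"), utf8ToInt("Y"))))) {
    stop("not an npy file: ", path)
  }
  ver <- readBin(con, "raw", n = 2L)
  major <- as.integer(ver[1])
  hlen <- if (major == 1L) {
    readBin(con, "integer", n = 1L, size = 2L, endian = "little", signed = FALSE)
  } else {
    readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  }
  header <- rawToChar(readBin(con, "raw", n = hlen))

  descr <- sub(".*'descr'\\s*:\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order'\\s*:\\s*True", header)
  shape_str <- sub(".*'shape'\\s*:\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("\\s", "", shape_str), ",")[[1]])
  shape <- shape[!is.na(shape)]
  ntot <- if (length(shape) == 0L) 1L else prod(shape)

  data <- switch(descr,
    "<f8" = readBin(con, "double", n = ntot, size = 8L, endian = "little"),
    "<f4" = readBin(con, "double", n = ntot, size = 4L, endian = "little"),
    "<i8" = {
      w <- readBin(con, "integer", n = 2L * ntot, size = 4L, endian = "little")
      lo <- w[seq(1L, by = 2L, length.out = ntot)]
      hi <- w[seq(2L, by = 2L, length.out = ntot)]
      ifelse(lo < 0, lo + 2^32, as.double(lo)) + hi * 2^32
    },
    "<i4" = readBin(con, "integer", n = ntot, size = 4L, endian = "little"),
    "|b1" = as.integer(readBin(con, "raw", n = ntot)),
    stop("unsupported npy dtype: ", descr)
  )
  if (length(shape) <= 1L) return(data)
  if (length(shape) == 2L) {
    if (fortran) matrix(data, nrow = shape[1], ncol = shape[2])
    else matrix(data, nrow = shape[1], ncol = shape[2], byrow = TRUE)
  } else {
    stop("npy arrays with >2 dimensions are not supported")
  }
}

#' @param x numeric vector or matrix to write (stored as float64, C order).
#' @rdname read_npy
#' @export
write_npy <- function(x, path) {
  shape_str <- if (is.matrix(x)) {
    sprintf("(%d, %d)", nrow(x), ncol(x))
  } else {
    sprintf("(%d,)", length(x))
  }
  dict <- sprintf("{'descr': '<f8', 'fortran_order': False, 'shape': %s, }",
                  shape_str)
  # total header (magic 6 + version 2 + len 2 + dict + padding + \n) % 64 == 0
  base <- 10L + nchar(dict) + 1L
  pad <- (64L - base %% 64L) %% 64L
  header <- paste0(dict, strrep(" ", pad), "\n")

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, utf8ToInt("N"), utf8ToInt("U"), utf8ToInt("M"),
                    utf8ToInt("P"), utf8ToInt("Y"), 0x01, 0x00)), con)
  writeBin(as.raw(c(nchar(header) %% 256L, nchar(header) %/% 256L)), con)
  writeBin(charToRaw(header), con)
  vals <- if (is.matrix(x)) as.double(t(x)) else as.double(x)
  writeBin(vals, con, size = 8L, endian = "little")
  invisible(path)
}
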
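# Minimal NetCDF-3 (classic format, CDF-1) reader/writer.
#
# Scope: fixed-size (non-record) variables of type char, int, float, double;
# named dimensions; global and per-variable attributes. That is exactly what
# the package's gridded products need (CF-style lat/lon/time coordinate
# variables plus float32 data layers with _FillValue/units attributes).
# All multi-byte values are big-endian per the format; variable data are laid
# out row-major over the declared dimensions, so the R-side convention is
# that `data` arrays carry dim = rev(declared dimension lengths).

NC_TYPES <- c(byte = 1L, char = 2L, short = 3L, int = 4L,
              float = 5L, double = 6L)
NC_SIZE <- c(byte = 1L, char = 1L, short = 2L, int = 4L,
             float = 4L, double = 8L)

pad4 <- function(n) (4L - n %% 4L) %% 4L

nc3_write_name <- function(con, name) {
  raw <- charToRaw(name)
  writeBin(length(raw), con, size = 4L, endian = "big")
  writeBin(raw, con)
  if (pad4(length(raw)) > 0) writeBin(raw(pad4(length(raw))), con)
}

nc3_write_values <- function(con, type, values) {
  if (type == "char") {
    raw <- charToRaw(paste(values, collapse = ""))
    writeBin(raw, con)
    if (pad4(length(raw)) > 0) writeBin(raw(pad4(length(raw))), con)
    return(invisible(length(raw)))
  }
  sz <- NC_SIZE[[type]]
  if (type %in% c("int", "short", "byte")) {
    writeBin(as.integer(values), con, size = sz, endian = "big")
  } else {
    writeBin(as.numeric(values), con, size = sz, endian = "big")
  }
  nb <- length(values) * sz
  if (pad4(nb) > 0) writeBin(raw(pad4(nb)), con)
  invisible(nb)
}

att_nelems <- function(type, values) {
  if (type == "char") nchar(paste(values, collapse = "")) else length(values)
}

nc3_write_attlist <- function(con, atts) {
  if (length(atts) == 0) {
    writeBin(c(0L, 0L), con, size = 4L, endian = "big")  # ABSENT
    return(invisible())
  }
  writeBin(c(12L, length(atts)), con, size = 4L, endian = "big")  # NC_ATTRIBUTE
  for (nm in names(atts)) {
    a <- atts[[nm]]
    type <- if (is.character(a)) "char" else if (is.integer(a)) "int" else "double"
    nc3_write_name(con, nm)
    writeBin(NC_TYPES[[type]], con, size = 4L, endian = "big")
    writeBin(att_nelems(type, a), con, size = 4L, endian = "big")
    nc3_write_values(con, type, a)
  }
}

#' Write a NetCDF-3 classic file
#'
#' @param path output file path.
#' @param dims named integer vector of dimension lengths (declaration order).
#' @param vars list of variable descriptions: each a list with `name`,
#'   `dims` (character, names from `dims`, slowest-varying first), `type`
#'   (one of "char", "int", "float", "double"), `data` (R array with
#'   `dim = rev(lengths)`, written in declaration order) and optional `atts`.
#' @param gatts named list of global attributes (character or numeric).
#' @return `path`, invisibly.
#' @keywords internal
#' @export
nc3_write <- function(path, dims, vars, gatts = list()) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("CDF"), con)
  writeBin(as.raw(1L), con)
  writeBin(0L, con, size = 4L, endian = "big")  # numrecs

  # dim list
  writeBin(c(10L, length(dims)), con, size = 4L, endian = "big")  # NC_DIMENSION
  for (nm in names(dims)) {
    nc3_write_name(con, nm)
    writeBin(as.integer(dims[[nm]]), con, size = 4L, endian = "big")
  }
  nc3_write_attlist(con, gatts)

  # compute header size to assign offsets: write header to a scratch buffer
  # first, then data offsets follow sequentially.
  sizes <- vapply(vars, function(v) {
    n <- prod(unlist(dims[v$dims]))
    nb <- n * NC_SIZE[[v$type]]
    as.integer(nb + pad4(nb))
  }, integer(1))

  # serialize var metadata once to measure header length
  measure_var <- function(v) {
    nmlen <- nchar(v$name)
    hdr <- 4L + nmlen + pad4(nmlen) +      # name
      4L + 4L * length(v$dims)             # rank + dimids
    atts <- v$atts %||% list()
    if (length(atts) == 0) hdr <- hdr + 8L else {
      hdr <- hdr + 8L
      for (nm in names(atts)) {
        a <- atts[[nm]]
        type <- if (is.character(a)) "char" else if (is.integer(a)) "int" else "double"
        alen <- nchar(nm); nel <- att_nelems(type, a)
        nb <- nel * NC_SIZE[[type]]
        hdr <- hdr + 4L + alen + pad4(alen) + 8L + nb + pad4(nb)
      }
    }
    hdr + 12L  # nc_type + vsize + begin (CDF-1: 4 bytes each)
  }
  header_len <- seek(con)  # bytes written so far
  header_len <- header_len + 8L +  # NC_VARIABLE tag + count
    sum(vapply(vars, measure_var, numeric(1)))
  begins <- cumsum(c(header_len, head(sizes, -1L)))

  writeBin(c(11L, length(vars)), con, size = 4L, endian = "big")  # NC_VARIABLE
  dimids <- setNames(seq_along(dims) - 1L, names(dims))
  for (i in seq_along(vars)) {
    v <- vars[[i]]
    nc3_write_name(con, v$name)
    writeBin(length(v$dims), con, size = 4L, endian = "big")
    writeBin(as.integer(dimids[v$dims]), con, size = 4L, endian = "big")
    nc3_write_attlist(con, v$atts %||% list())
    writeBin(NC_TYPES[[v$type]], con, size = 4L, endian = "big")
    writeBin(sizes[i], con, size = 4L, endian = "big")
    writeBin(as.integer(begins[i]), con, size = 4L, endian = "big")
  }
  stopifnot(seek(con) == header_len)
  for (v in vars) nc3_write_values(con, v$type, as.vector(v$data))
  invisible(path)
}

# ---- reader ----

nc3_read_name <- function(con) {
  n <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  nm <- rawToChar(readBin(con, "raw", n))
  if (pad4(n) > 0) readBin(con, "raw", pad4(n))
  nm
}

nc3_read_values <- function(con, typeid, nelems) {
  type <- names(NC_TYPES)[match(typeid, NC_TYPES)]
  sz <- NC_SIZE[[type]]
  out <- switch(type,
    char = rawToChar(readBin(con, "raw", nelems)),
    byte = ,
    short = ,
    int = readBin(con, "integer", nelems, size = sz, endian = "big"),
    float = ,
    double = readBin(con, "numeric", nelems, size = sz, endian = "big"))
  nb <- nelems * sz
  if (pad4(nb) > 0) readBin(con, "raw", pad4(nb))
  out
}

nc3_read_attlist <- function(con) {
  tag <- readBin(con, "integer", 2L, size = 4L, endian = "big")
  if (tag[2] == 0L) return(list())
  atts <- list()
  for (i in seq_len(tag[2])) {
    nm <- nc3_read_name(con)
    typeid <- readBin(con, "integer", 1L, size = 4L, endian = "big")
    nel <- readBin(con, "integer", 1L, size = 4L, endian = "big")
    atts[[nm]] <- nc3_read_values(con, typeid, nel)
  }
  atts
}

#' Read a NetCDF-3 classic file
#'
#' Supports the same subset as [nc3_write()] (fixed-size variables). Record
#' variables written by other tools are read as well, provided `numrecs`
#' describes them (the record dimension is materialized).
#'
#' @param path file path.
#' @return list with `dims` (named lengths), `gatts`, and `vars`: per
#'   variable `dims`, `type`, `atts` and `data` (dim = rev(lengths)).
#' @keywords internal
#' @export
nc3_read <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4L)
  if (!identical(magic[1:3], charToRaw("CDF")) || !magic[4] %in% as.raw(1:2))
    abort(sprintf("'%s' is not a classic NetCDF file", path),
          class = "lcspp_format_error")
  offsize <- if (magic[4] == as.raw(2)) 8L else 4L
  numrecs <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  tag <- readBin(con, "integer", 2L, size = 4L, endian = "big")
  dims <- integer(0)
  if (tag[2] > 0) {
    for (i in seq_len(tag[2])) {
      nm <- nc3_read_name(con)
      dims[nm] <- readBin(con, "integer", 1L, size = 4L, endian = "big")
    }
  }
  rec_dim <- which(dims == 0L)
  gatts <- nc3_read_attlist(con)
  tag <- readBin(con, "integer", 2L, size = 4L, endian = "big")
  vars <- list()
  meta <- list()
  if (tag[2] > 0) {
    for (i in seq_len(tag[2])) {
      nm <- nc3_read_name(con)
      rank <- readBin(con, "integer", 1L, size = 4L, endian = "big")
      dimids <- readBin(con, "integer", rank, size = 4L, endian = "big")
      atts <- nc3_read_attlist(con)
      typeid <- readBin(con, "integer", 1L, size = 4L, endian = "big")
      readBin(con, "integer", 1L, size = 4L, endian = "big")  # vsize
      begin <- if (offsize == 8L) {
        hi <- readBin(con, "integer", 1L, size = 4L, endian = "big")
        lo <- readBin(con, "integer", 1L, size = 4L, endian = "big")
        hi * 2^32 + (lo %% 2^32 + 2^32) %% 2^32
      } else readBin(con, "integer", 1L, size = 4L, endian = "big")
      meta[[nm]] <- list(dimids = dimids + 1L, atts = atts,
                         typeid = typeid, begin = begin)
    }
  }
  for (nm in names(meta)) {
    m <- meta[[nm]]
    dlen <- dims[m$dimids]
    if (length(rec_dim) == 1L && rec_dim %in% m$dimids)
      dlen[m$dimids == rec_dim] <- numrecs
    seek(con, m$begin)
    n <- prod(pmax(dlen, 1L))
    data <- nc3_read_values(con, m$typeid, n)
    if (m$typeid != NC_TYPES[["char"]] && length(dlen) > 1L)
      dim(data) <- rev(unname(dlen))
    vars[[nm]] <- list(
      dims = names(dims)[m$dimids],
      type = names(NC_TYPES)[match(m$typeid, NC_TYPES)],
      atts = m$atts, data = data)
  }
  list(dims = dims, gatts = gatts, vars = vars)
}
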
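## Minimal MAT v5 reader.
##
## No MAT-file reader ships with the R stack this package targets, and the
## profilometer exports records as MATLAB binary containers, so a small
## parser is provided.  Scope: top-level numeric and character arrays
## (classes double/single/int8..uint32/char), uncompressed or
## zlib-compressed elements, either byte order.  Cell arrays, structs,
## sparse and complex matrices are out of scope and raise an error.

MI_TYPES <- c(miINT8 = 1, miUINT8 = 2, miINT16 = 3, miUINT16 = 4,
              miINT32 = 5, miUINT32 = 6, miSINGLE = 7, miDOUBLE = 9,
              miINT64 = 12, miUINT64 = 13, miMATRIX = 14, miCOMPRESSED = 15,
              miUTF8 = 16, miUTF16 = 17)

MX_NUMERIC <- c(6, 7, 8, 9, 10, 11, 12, 13, 14, 15)  # double..uint64
MX_CHAR <- 4

#' Read a MAT v5 container
#'
#' Parses top-level numeric and character arrays from a MATLAB Level-5
#' binary container (the format profilometer software exports).  Matrices
#' are returned in their stored shape; character arrays as strings.
#'
#' @param path path to a `.mat` file.
#' @return named list of matrices / strings.
#' @export
read_mat5 <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  l3d_assert(length(raw) > 128, "schema_mismatch", "file too short for MAT v5")
  magic <- rawToChar(raw[1:4])
  l3d_assert(identical(magic, "MATL"), "schema_mismatch",
             "not a MAT v5 container (missing MATLAB header)")
  endian_tag <- rawToChar(raw[127:128])
  endian <- if (endian_tag == "IM") "little" else "big"
  pos <- 129L
  out <- list()
  while (pos + 7L <= length(raw)) {
    el <- mat5_element(raw, pos, endian)
    pos <- el$next_pos
    if (is.null(el$value)) next
    out[[el$name]] <- el$value
  }
  out
}

rb <- function(raw, what, n, size, endian, signed = TRUE) {
  readBin(raw, what, n = n, size = size, endian = endian, signed = signed)
}

## parse one top-level data element starting at pos; returns value+name
mat5_element <- function(raw, pos, endian) {
  tag <- rb(raw[pos:(pos + 7L)], "integer", 2, 4, endian)
  type <- tag[1]; nbytes <- tag[2]
  if (type == MI_TYPES[["miCOMPRESSED"]]) {
    payload <- raw[(pos + 8L):(pos + 7L + nbytes)]
    inflated <- memDecompress(payload, type = "gzip")
    el <- mat5_element(inflated, 1L, endian)
    el$next_pos <- pos + 8L + nbytes
    return(el)
  }
  l3d_assert(type == MI_TYPES[["miMATRIX"]], "schema_mismatch",
             paste("unsupported top-level element type", type))
  body <- raw[(pos + 8L):(pos + 7L + nbytes)]
  parsed <- mat5_matrix(body, endian)
  parsed$next_pos <- pos + 8L + nbytes + pad8(nbytes)
  parsed
}

pad8 <- function(n) (8L - n %% 8L) %% 8L

## read the sub-element at cursor `at` inside `body`; small-element format
## packs type and length into the first 4 bytes
mat5_sub <- function(body, at, endian) {
  t4 <- rb(body[at:(at + 3L)], "integer", 1, 4, endian)
  small_len <- bitwAnd(bitwShiftR(t4, 16), 0xFFFFL)
  if (small_len > 0L) {
    type <- bitwAnd(t4, 0xFFFFL)
    list(type = type, data = body[(at + 4L):(at + 3L + small_len)],
         next_at = at + 8L)
  } else {
    len <- rb(body[(at + 4L):(at + 7L)], "integer", 1, 4, endian)
    data <- if (len > 0) body[(at + 8L):(at + 7L + len)] else raw(0)
    list(type = t4, data = data, next_at = at + 8L + len + pad8(len))
  }
}

decode_numeric <- function(sub, endian) {
  d <- sub$data
  switch(as.character(sub$type),
         "1" = as.numeric(rb(d, "integer", length(d), 1, endian)),
         "2" = as.numeric(rb(d, "integer", length(d), 1, endian, signed = FALSE)),
         "3" = as.numeric(rb(d, "integer", length(d) / 2, 2, endian)),
         "4" = as.numeric(rb(d, "integer", length(d) / 2, 2, endian, signed = FALSE)),
         "5" = as.numeric(rb(d, "integer", length(d) / 4, 4, endian)),
         "6" = { v <- rb(d, "integer", length(d) / 4, 4, endian)
                 ifelse(v < 0, v + 2^32, as.numeric(v)) },
         "7" = as.numeric(rb(d, "double", length(d) / 4, 4, endian)),
         "9" = rb(d, "double", length(d) / 8, 8, endian),
         "12" = ,
         "13" = decode_int64(d, endian, signed = sub$type == 12),
         l3d_error("schema_mismatch",
                   paste("unsupported data type", sub$type)))
}

## 64-bit integers assembled from 32-bit halves (exact up to 2^53)
decode_int64 <- function(d, endian, signed = TRUE) {
  halves <- rb(d, "integer", length(d) / 4, 4, endian)
  lo_first <- endian == "little"
  lo <- halves[seq(if (lo_first) 1 else 2, length(halves), by = 2)]
  hi <- halves[seq(if (lo_first) 2 else 1, length(halves), by = 2)]
  lo <- ifelse(lo < 0, lo + 2^32, as.numeric(lo))
  hi_val <- if (signed) as.numeric(hi) else ifelse(hi < 0, hi + 2^32, as.numeric(hi))
  hi_val * 2^32 + lo
}

mat5_matrix <- function(body, endian) {
  at <- 1L
  flags <- mat5_sub(body, at, endian); at <- flags$next_at
  fl <- rb(flags$data, "integer", 2, 4, endian)
  class_id <- bitwAnd(fl[1], 0xFFL)
  complex <- bitwAnd(fl[1], bitwShiftL(1L, 11)) != 0
  l3d_assert(!complex, "schema_mismatch", "complex arrays unsupported")
  dims_sub <- mat5_sub(body, at, endian); at <- dims_sub$next_at
  dims <- rb(dims_sub$data, "integer", length(dims_sub$data) / 4, 4, endian)
  name_sub <- mat5_sub(body, at, endian); at <- name_sub$next_at
  name <- rawToChar(name_sub$data[name_sub$data != as.raw(0)])
  if (class_id %in% MX_NUMERIC) {
    pr <- mat5_sub(body, at, endian)
    vals <- decode_numeric(pr, endian)
    value <- if (length(dims) == 2) {
      matrix(vals, dims[1], dims[2])
    } else array(vals, dims)
    if (all(dim(value) == 1)) value <- as.numeric(value)
  } else if (class_id == MX_CHAR) {
    pr <- mat5_sub(body, at, endian)
    value <- if (pr$type %in% c(4, 17)) {  # miUINT16 / miUTF16
      codes <- rb(pr$data, "integer", length(pr$data) / 2, 2, endian,
                  signed = FALSE)
      intToUtf8(codes)
    } else rawToChar(pr$data[pr$data != as.raw(0)])
  } else {
    l3d_error("schema_mismatch",
              paste("unsupported array class", class_id, "for variable", name))
  }
  list(name = name, value = value)
}
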
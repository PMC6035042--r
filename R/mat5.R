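# Minimal MAT-file (level 5) reader/writer.
#
# Scope: little-endian files; numeric, logical, char, cell, and struct
# arrays; compressed (zlib) top-level elements on read. This is all the
# published single-molecule "intervals" containers need, and all the
# package's own container writer produces. Sparse arrays and MATLAB objects
# are skipped with a warning.

MI_INT8 <- 1L
MI_UINT8 <- 2L
MI_INT16 <- 3L
MI_UINT16 <- 4L
MI_INT32 <- 5L
MI_UINT32 <- 6L
MI_SINGLE <- 7L
MI_DOUBLE <- 9L
MI_INT64 <- 12L
MI_UINT64 <- 13L
MI_MATRIX <- 14L
MI_COMPRESSED <- 15L
MI_UTF8 <- 16L
MI_UTF16 <- 17L

MX_CELL <- 1L
MX_STRUCT <- 2L
MX_OBJECT <- 3L
MX_CHAR <- 4L
MX_SPARSE <- 5L
MX_DOUBLE <- 6L
MX_SINGLE <- 7L

#' Read a MAT v5 file into a named list
#'
#' Supports the subset of the format used by single-molecule analysis
#' containers: numeric/logical/char matrices, cell arrays, and (nested)
#' structs, with zlib-compressed elements. Char row vectors become R
#' strings, cell arrays become lists, structs become named lists.
#'
#' @param path Path to a `.mat` file.
#' @return Named list of top-level variables.
#' @export
read_mat5 <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 128) {
    stop("unsupported format: file too short for a MAT v5 header", call. = FALSE)
  }
  header_txt <- tryCatch(rawToChar(raw[1:19]), error = function(e) "")
  if (!identical(header_txt, "MATLAB 5.0 MAT-file")) {
    stop("unsupported format: not a MAT v5 container", call. = FALSE)
  }
  endian <- rawToChar(raw[127:128])
  if (endian != "IM") {
    stop("unsupported format: big-endian MAT files are not handled", call. = FALSE)
  }
  pos <- 129L
  vars <- list()
  while (pos + 8L <= length(raw) + 1L) {
    tag <- parse_tag(raw, pos)
    if (tag$type == MI_COMPRESSED) {
      payload <- raw[(pos + 8L):(pos + 7L + tag$nbytes)]
      inner <- tryCatch(
        memDecompress(payload, type = "gzip"),
        error = function(e) {
          stop("unsupported format: cannot decompress MAT element (", conditionMessage(e), ")",
            call. = FALSE
          )
        }
      )
      el <- parse_element(inner, 1L)
    } else {
      el <- parse_element(raw, pos)
    }
    if (!is.null(el$value)) vars[[el$name %||% sprintf("var%d", length(vars) + 1L)]] <- el$value
    # compressed elements are not padded to the 8-byte boundary
    step <- if (tag$type == MI_COMPRESSED) tag$nbytes else pad8(tag$nbytes)
    pos <- pos + 8L + step
  }
  vars
}

pad8 <- function(n) as.integer(ceiling(n / 8) * 8)

parse_tag <- function(raw, pos) {
  b <- raw[pos:(pos + 3L)]
  type_full <- readBin(b, "integer", size = 4, endian = "little")
  small_bytes <- bitwAnd(bitwShiftR(type_full, 16L), 0xFFFFL)
  if (small_bytes != 0L) {
    list(
      type = bitwAnd(type_full, 0xFFFFL), nbytes = small_bytes,
      small = TRUE, data_offset = 4L, total = 8L
    )
  } else {
    nb <- readBin(raw[(pos + 4L):(pos + 7L)], "integer", size = 4, endian = "little")
    list(type = type_full, nbytes = nb, small = FALSE, data_offset = 8L, total = 8L + pad8(nb))
  }
}

read_numeric_payload <- function(raw, pos, tag) {
  data <- raw[(pos + tag$data_offset):(pos + tag$data_offset + tag$nbytes - 1L)]
  switch(as.character(tag$type),
    "1" = as.numeric(readBin(data, "integer", n = tag$nbytes, size = 1, signed = TRUE)),
    "2" = as.numeric(readBin(data, "integer", n = tag$nbytes, size = 1, signed = FALSE)),
    "3" = as.numeric(readBin(data, "integer", n = tag$nbytes %/% 2, size = 2, signed = TRUE, endian = "little")),
    "4" = as.numeric(readBin(data, "integer", n = tag$nbytes %/% 2, size = 2, signed = FALSE, endian = "little")),
    "5" = as.numeric(readBin(data, "integer", n = tag$nbytes %/% 4, size = 4, endian = "little")),
    "6" = {
      v <- readBin(data, "integer", n = tag$nbytes %/% 4, size = 4, endian = "little")
      ifelse(v < 0, v + 2^32, as.numeric(v))
    },
    "7" = as.numeric(readBin(data, "double", n = tag$nbytes %/% 4, size = 4, endian = "little")),
    "9" = readBin(data, "double", n = tag$nbytes %/% 8, size = 8, endian = "little"),
    "12" = as.numeric(readBin(data, "double", n = tag$nbytes %/% 8, size = 8, endian = "little")),
    "13" = as.numeric(readBin(data, "double", n = tag$nbytes %/% 8, size = 8, endian = "little")),
    "16" = rawToChar(data),
    "17" = intToUtf8(readBin(data, "integer", n = tag$nbytes %/% 2, size = 2, signed = FALSE, endian = "little"), multiple = FALSE),
    stop("unsupported format: MAT data type ", tag$type, call. = FALSE)
  )
}

# Parse one element starting at pos; returns list(name, value, total_bytes).
parse_element <- function(raw, pos) {
  tag <- parse_tag(raw, pos)
  if (tag$type != MI_MATRIX) {
    # non-matrix top-level data: expose as plain numeric
    return(list(name = NULL, value = read_numeric_payload(raw, pos, tag), total = tag$total))
  }
  end <- pos + tag$total - 1L
  cur <- pos + 8L

  # array flags
  ftag <- parse_tag(raw, cur)
  flags <- raw[(cur + ftag$data_offset):(cur + ftag$data_offset + 7L)]
  class_id <- as.integer(flags[1])
  is_logical <- bitwAnd(as.integer(flags[2]), 2L) != 0L
  cur <- cur + (if (ftag$small) 8L else ftag$total)

  # dimensions
  dtag <- parse_tag(raw, cur)
  dims <- readBin(
    raw[(cur + dtag$data_offset):(cur + dtag$data_offset + dtag$nbytes - 1L)],
    "integer",
    n = dtag$nbytes %/% 4, size = 4, endian = "little"
  )
  cur <- cur + (if (dtag$small) 8L else dtag$total)

  # name
  ntag <- parse_tag(raw, cur)
  name <- if (ntag$nbytes > 0) {
    rawToChar(raw[(cur + ntag$data_offset):(cur + ntag$data_offset + ntag$nbytes - 1L)])
  } else {
    NULL
  }
  cur <- cur + (if (ntag$small) 8L else ntag$total)

  value <- NULL
  if (class_id %in% c(MX_DOUBLE, MX_SINGLE, 8L, 9L, 10L, 11L, 12L, 13L, 14L, 15L)) {
    if (prod(dims) == 0) {
      value <- matrix(numeric(0), nrow = dims[1], ncol = if (length(dims) > 1) dims[2] else 0)
    } else {
      ptag <- parse_tag(raw, cur)
      v <- read_numeric_payload(raw, cur, ptag)
      if (is_logical) v <- v != 0
      value <- array(v, dim = dims)
      if (length(dims) == 2 && dims[1] == 1 && dims[2] == 1) value <- v[1]
    }
  } else if (class_id == MX_CHAR) {
    if (prod(dims) == 0) {
      value <- ""
    } else {
      ptag <- parse_tag(raw, cur)
      v <- read_numeric_payload(raw, cur, ptag)
      if (is.character(v)) {
        value <- v
      } else {
        codes <- as.integer(v)
        ch <- ifelse(codes == 0L, "", intToUtf8(codes, multiple = TRUE))
        m <- matrix(ch, nrow = dims[1], ncol = dims[2])
        # MATLAB pads char matrices with trailing spaces
        value <- apply(m, 1, function(r) sub(" +$", "", paste(r, collapse = "")))
      }
      if (length(value) == 1) value <- value[[1]]
    }
  } else if (class_id == MX_CELL) {
    n <- prod(dims)
    value <- vector("list", n)
    for (i in seq_len(n)) {
      el <- parse_element(raw, cur)
      value[[i]] <- el$value
      cur <- cur + el$total
    }
  } else if (class_id == MX_STRUCT) {
    fltag <- parse_tag(raw, cur)
    flen <- readBin(
      raw[(cur + fltag$data_offset):(cur + fltag$data_offset + 3L)],
      "integer",
      size = 4, endian = "little"
    )
    cur <- cur + (if (fltag$small) 8L else fltag$total)
    fntag <- parse_tag(raw, cur)
    nfields <- fntag$nbytes %/% flen
    fnames <- vapply(seq_len(nfields), function(i) {
      b <- raw[(cur + fntag$data_offset + (i - 1L) * flen):(cur + fntag$data_offset + i * flen - 1L)]
      rawToChar(b[b != as.raw(0)])
    }, character(1))
    cur <- cur + (if (fntag$small) 8L else fntag$total)
    n_el <- prod(dims)
    structs <- vector("list", n_el)
    for (e in seq_len(n_el)) {
      fields <- vector("list", nfields)
      for (fi in seq_len(nfields)) {
        el <- parse_element(raw, cur)
        fields[[fi]] <- el$value
        cur <- cur + el$total
      }
      names(fields) <- fnames
      structs[[e]] <- fields
    }
    value <- if (n_el == 1) structs[[1]] else structs
  } else {
    warning("skipping unsupported MAT array class ", class_id)
    value <- NULL
  }
  list(name = name, value = value, total = tag$total)
}

# ---------------------------------------------------------------------------
# Writer (uncompressed, little-endian)

mat5_tag <- function(type, nbytes) {
  c(
    writeBin(as.integer(type), raw(), size = 4, endian = "little"),
    writeBin(as.integer(nbytes), raw(), size = 4, endian = "little")
  )
}

mat5_pad <- function(bytes) {
  n <- length(bytes)
  c(bytes, raw(pad8(n) - n))
}

mat5_data_element <- function(type, bytes) {
  mat5_pad(c(mat5_tag(type, length(bytes)), bytes))
}

mat5_numeric_array <- function(x, name = "") {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  flags <- mat5_data_element(MI_UINT32, c(
    writeBin(as.integer(MX_DOUBLE), raw(), size = 4, endian = "little"),
    writeBin(0L, raw(), size = 4, endian = "little")
  ))
  dims <- mat5_data_element(MI_INT32, writeBin(as.integer(dim(x)), raw(), size = 4, endian = "little"))
  nm <- mat5_data_element(MI_INT8, if (nzchar(name)) charToRaw(name) else raw(0))
  dat <- mat5_data_element(MI_DOUBLE, writeBin(as.vector(x), raw(), size = 8, endian = "little"))
  body <- c(flags, dims, nm, dat)
  c(mat5_tag(MI_MATRIX, length(body)), body)
}

mat5_char_array <- function(s, name = "") {
  codes <- utf8ToInt(s)
  flags <- mat5_data_element(MI_UINT32, c(
    writeBin(as.integer(MX_CHAR), raw(), size = 4, endian = "little"),
    writeBin(0L, raw(), size = 4, endian = "little")
  ))
  dims <- mat5_data_element(MI_INT32, writeBin(c(1L, length(codes)), raw(), size = 4, endian = "little"))
  nm <- mat5_data_element(MI_INT8, if (nzchar(name)) charToRaw(name) else raw(0))
  dat <- mat5_data_element(MI_UINT16, writeBin(as.integer(codes), raw(), size = 2, endian = "little"))
  body <- c(flags, dims, nm, dat)
  c(mat5_tag(MI_MATRIX, length(body)), body)
}

mat5_cell_array <- function(items, name = "") {
  flags <- mat5_data_element(MI_UINT32, c(
    writeBin(as.integer(MX_CELL), raw(), size = 4, endian = "little"),
    writeBin(0L, raw(), size = 4, endian = "little")
  ))
  dims <- mat5_data_element(MI_INT32, writeBin(c(length(items), 1L), raw(), size = 4, endian = "little"))
  nm <- mat5_data_element(MI_INT8, if (nzchar(name)) charToRaw(name) else raw(0))
  cells <- do.call(c, c(list(raw(0)), lapply(items, mat5_value)))
  body <- c(flags, dims, nm, cells)
  c(mat5_tag(MI_MATRIX, length(body)), body)
}

mat5_struct <- function(fields, name = "") {
  stopifnot(!is.null(names(fields)), all(nzchar(names(fields))))
  flen <- 32L
  flags <- mat5_data_element(MI_UINT32, c(
    writeBin(as.integer(MX_STRUCT), raw(), size = 4, endian = "little"),
    writeBin(0L, raw(), size = 4, endian = "little")
  ))
  dims <- mat5_data_element(MI_INT32, writeBin(c(1L, 1L), raw(), size = 4, endian = "little"))
  nm <- mat5_data_element(MI_INT8, if (nzchar(name)) charToRaw(name) else raw(0))
  fl <- mat5_data_element(MI_INT32, writeBin(flen, raw(), size = 4, endian = "little"))
  fn_bytes <- do.call(c, lapply(names(fields), function(f) {
    b <- charToRaw(substr(f, 1, flen - 1L))
    c(b, raw(flen - length(b)))
  }))
  fn <- mat5_data_element(MI_INT8, fn_bytes)
  vals <- do.call(c, c(list(raw(0)), lapply(fields, mat5_value)))
  body <- c(flags, dims, nm, fl, fn, vals)
  c(mat5_tag(MI_MATRIX, length(body)), body)
}

# Dispatch an R value to its MAT representation (unnamed element).
mat5_value <- function(x) {
  if (is.character(x) && length(x) == 1) {
    mat5_char_array(x)
  } else if (is.character(x)) {
    mat5_cell_array(as.list(x))
  } else if (is.numeric(x) || is.logical(x)) {
    mat5_numeric_array(x)
  } else if (is.list(x) && !is.null(names(x)) && all(nzchar(names(x)))) {
    mat5_struct(x)
  } else if (is.list(x)) {
    mat5_cell_array(x)
  } else {
    stop("cannot serialize value of class ", class(x)[1], " to MAT", call. = FALSE)
  }
}

#' Write variables to a MAT v5 file
#'
#' Companion writer to [read_mat5()]: numeric matrices, strings, character
#' vectors (as cell arrays of strings), lists (cell arrays) and named lists
#' (structs). Written uncompressed, little-endian.
#'
#' @param vars Named list of variables.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mat5 <- function(vars, path) {
  stopifnot(is.list(vars))
  if (length(vars) > 0) stopifnot(!is.null(names(vars)), all(nzchar(names(vars))))
  desc <- sprintf(
    "MATLAB 5.0 MAT-file, Platform: R cosmoskit, Created on: %s",
    format(Sys.time(), "%a %b %d %H:%M:%S %Y")
  )
  hdr <- charToRaw(desc)
  hdr <- c(hdr, charToRaw(strrep(" ", 116 - length(hdr))))
  hdr <- c(hdr, raw(8)) # subsystem offset
  hdr <- c(hdr, writeBin(c(0x00L, 0x01L), raw(), size = 1)) # version 0x0100
  hdr <- c(hdr, charToRaw("IM"))
  body <- raw(0)
  for (nm in names(vars)) {
    x <- vars[[nm]]
    el <- if (is.character(x) && length(x) == 1) {
      mat5_char_array(x, nm)
    } else if (is.character(x)) {
      el2 <- mat5_cell_array(as.list(x), nm)
      el2
    } else if (is.numeric(x) || is.logical(x)) {
      mat5_numeric_array(x, nm)
    } else if (is.list(x) && !is.null(names(x)) && all(nzchar(names(x)))) {
      mat5_struct(x, nm)
    } else if (is.list(x)) {
      mat5_cell_array(x, nm)
    } else {
      stop("cannot serialize variable ", nm, call. = FALSE)
    }
    body <- c(body, el)
  }
  writeBin(c(hdr, body), path)
  invisible(path)
}
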
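# Minimal NRRD (.nrrd) reader/writer: attached-data files, raw or gzip
# encoding, standard scalar types, 3-D only. Covers what structure masks and
# dose grids need; detached headers, block types and text encodings are out.

nrrd_type_table <- list(
  "signed char" = list(what = "integer", size = 1L, signed = TRUE),
  "int8"        = list(what = "integer", size = 1L, signed = TRUE),
  "uchar"       = list(what = "integer", size = 1L, signed = FALSE),
  "uint8"       = list(what = "integer", size = 1L, signed = FALSE),
  "short"       = list(what = "integer", size = 2L, signed = TRUE),
  "int16"       = list(what = "integer", size = 2L, signed = TRUE),
  "ushort"      = list(what = "integer", size = 2L, signed = FALSE),
  "uint16"      = list(what = "integer", size = 2L, signed = FALSE),
  "int"         = list(what = "integer", size = 4L, signed = TRUE),
  "int32"       = list(what = "integer", size = 4L, signed = TRUE),
  "uint"        = list(what = "double",  size = 4L, signed = FALSE, uint32 = TRUE),
  "uint32"      = list(what = "double",  size = 4L, signed = FALSE, uint32 = TRUE),
  "float"       = list(what = "double",  size = 4L, signed = TRUE),
  "double"      = list(what = "double",  size = 8L, signed = TRUE)
)

nrrd_parse_vector <- function(s) {
  as.numeric(strsplit(gsub("[()]", "", trimws(s)), ",")[[1]])
}

nrrd_read <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- readLines(con, n = 1L, warn = FALSE)
  if (!grepl("^NRRD000[0-9]$", magic))
    stop(sprintf("'%s' is not an NRRD file (bad magic '%s')", path, magic),
         call. = FALSE)
  fields <- list()
  hdr_bytes <- nchar(magic, type = "bytes") + 1L
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L)
      stop(sprintf("'%s': NRRD header ended without a blank line", path),
           call. = FALSE)
    hdr_bytes <- hdr_bytes + nchar(line, type = "bytes") + 1L
    if (line == "") break
    if (startsWith(line, "#")) next
    kv <- regmatches(line, regexpr("^[^:]+:=?", line))
    key <- tolower(trimws(sub(":=?$", "", kv)))
    val <- trimws(sub("^[^:]+:=?", "", line))
    fields[[key]] <- val
  }
  need <- function(k) {
    if (is.null(fields[[k]]))
      stop(sprintf("'%s': NRRD header missing required field '%s'", path, k),
           call. = FALSE)
    fields[[k]]
  }
  if (as.integer(need("dimension")) != 3L)
    stop(sprintf("'%s': only 3-D NRRD volumes are supported", path), call. = FALSE)
  sizes <- as.integer(strsplit(need("sizes"), "[[:space:]]+")[[1]])
  type <- nrrd_type_table[[tolower(need("type"))]]
  if (is.null(type))
    stop(sprintf("'%s': unsupported NRRD type '%s'", path, fields$type),
         call. = FALSE)
  encoding <- tolower(need("encoding"))
  endian <- if (!is.null(fields$endian)) tolower(fields$endian) else "little"
  n <- prod(sizes)
  if (encoding == "raw") {
    vals <- readBin(con, what = type$what, n = n, size = type$size,
                    signed = type$signed, endian = endian)
  } else if (encoding %in% c("gzip", "gz")) {
    close(con); on.exit(NULL)
    all_bytes <- readBin(path, "raw", n = file.info(path)$size)
    comp <- all_bytes[(hdr_bytes + 1L):length(all_bytes)]
    rawvals <- memDecompress(comp, type = "gzip")
    vals <- readBin(rawvals, what = type$what, n = n, size = type$size,
                    signed = type$signed, endian = endian)
  } else {
    stop(sprintf("'%s': unsupported NRRD encoding '%s'", path, encoding),
         call. = FALSE)
  }
  if (length(vals) < n)
    stop(sprintf("'%s': NRRD data truncated (%d of %d values)", path,
                 length(vals), n), call. = FALSE)

  spacing <- c(1, 1, 1)
  if (!is.null(fields[["space directions"]])) {
    dirs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    m <- vapply(dirs, nrrd_parse_vector, numeric(3))
    spacing <- sqrt(colSums(m^2))
  } else if (!is.null(fields$spacings)) {
    spacing <- as.numeric(strsplit(fields$spacings, "[[:space:]]+")[[1]])
  }
  # NRRD's space origin is the center of the first voxel; internally the grid
  # corner is stored, with centers at corner + (i - 0.5) * spacing.
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]]))
    origin <- nrrd_parse_vector(fields[["space origin"]])
  origin <- origin - spacing / 2
  list(values = array(vals, dim = sizes),
       geometry = grid_geometry(sizes, spacing, origin))
}

nrrd_write <- function(values, geometry, path, type = c("double", "uint8"),
                       encoding = c("raw", "gzip")) {
  type <- match.arg(type)
  encoding <- match.arg(encoding)
  first_center <- geometry$origin + geometry$spacing / 2
  hdr <- c(
    "NRRD0004",
    sprintf("type: %s", type),
    "dimension: 3",
    sprintf("sizes: %d %d %d", geometry$shape[1], geometry$shape[2],
            geometry$shape[3]),
    sprintf("encoding: %s", encoding),
    "endian: little",
    "space dimension: 3",
    sprintf("space directions: (%.10g,0,0) (0,%.10g,0) (0,0,%.10g)",
            geometry$spacing[1], geometry$spacing[2], geometry$spacing[3]),
    sprintf("space origin: (%.10g,%.10g,%.10g)",
            first_center[1], first_center[2], first_center[3]),
    ""
  )
  payload <- if (type == "uint8") {
    writeBin_raw <- as.raw(as.integer(values != 0))
    writeBin_raw
  } else {
    raw_con <- rawConnection(raw(0), "wb")
    writeBin(as.numeric(values), raw_con, size = 8L, endian = "little")
    on.exit(close(raw_con), add = TRUE)
    rawConnectionValue(raw_con)
  }
  if (encoding == "gzip") payload <- memCompress(payload, type = "gzip")
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con, sep = "\n")
  writeBin(payload, con)
  invisible(path)
}
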
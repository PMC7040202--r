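# Minimal NRRD (teem) support: 3D volumes, raw encoding, little endian.
# Header is plain text; data follow after a blank line. The x index runs
# fastest on disk, matching R's column-major array layout directly.

nrrd_types <- list(
  "double" = list(what = "double", size = 8L),
  "float"  = list(what = "double", size = 4L),
  "int"    = list(what = "integer", size = 4L),
  "short"  = list(what = "integer", size = 2L),
  "uchar"  = list(what = "integer", size = 1L),
  "unsigned char" = list(what = "integer", size = 1L)
)

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L, warn = FALSE)
  if (!grepl("^NRRD000[1-5]$", magic)) stop("not an NRRD file (bad magic)")
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("truncated NRRD header")
    if (line == "") break
    if (startsWith(line, "#")) next
    kv <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(kv) != 3L) stop(sprintf("malformed NRRD header line: %s", line))
    fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  type <- fields[["type"]]
  if (is.null(type) || is.null(nrrd_types[[type]])) {
    stop(sprintf("unsupported NRRD type '%s'", type))
  }
  if (!identical(as.integer(fields[["dimension"]]), 3L)) {
    stop("only 3-dimensional NRRD volumes are supported")
  }
  enc <- fields[["encoding"]]
  if (is.null(enc) || enc != "raw") stop("only raw NRRD encoding is supported")
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  if (length(sizes) != 3L || any(sizes < 1L)) stop("bad NRRD sizes field")
  spacing <- nrrd_spacing(fields)
  if (is.null(spacing)) stop("NRRD header carries no voxel spacing")
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]])) {
    origin <- parse_nrrd_vector(fields[["space origin"]])
  }
  tinfo <- nrrd_types[[type]]
  endian <- fields[["endian"]]
  endian <- if (is.null(endian)) "little" else endian
  n <- prod(sizes)
  vals <- readBin(con, what = tinfo$what, n = n, size = tinfo$size,
                  endian = endian,
                  signed = !(type %in% c("uchar", "unsigned char")))
  if (length(vals) != n) {
    stop(sprintf("truncated NRRD data: expected %d values, got %d", n,
                 length(vals)))
  }
  image_volume(array(as.double(vals), dim = sizes), spacing = spacing,
               origin = origin)
}

nrrd_spacing <- function(fields) {
  if (!is.null(fields[["spacings"]])) {
    sp <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
    if (length(sp) == 3L && all(is.finite(sp)) && all(sp > 0)) return(sp)
    return(NULL)
  }
  if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    if (length(vecs) != 3L) return(NULL)
    m <- vapply(vecs, parse_nrrd_vector, numeric(3))
    # only axis-aligned grids supported: spacing = row norms of a diagonal
    if (any(abs(m[row(m) != col(m)]) > 1e-12)) {
      stop("oblique NRRD space directions are not supported")
    }
    sp <- abs(diag(m))
    if (all(sp > 0)) return(sp)
    return(NULL)
  }
  NULL
}

parse_nrrd_vector <- function(s) {
  s <- gsub("[()]", "", s)
  as.numeric(strsplit(trimws(s), "\\s*,\\s*")[[1]])
}

write_nrrd <- function(vol, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "NRRD0004",
    "# generated by the radsig package",
    "type: double",
    "dimension: 3",
    "space: left-posterior-superior",
    sprintf("sizes: %s", paste(dim(vol$voxels), collapse = " ")),
    sprintf("space directions: (%.10g,0,0) (0,%.10g,0) (0,0,%.10g)",
            vol$spacing[1], vol$spacing[2], vol$spacing[3]),
    "endian: little",
    "encoding: raw",
    sprintf("space origin: (%.10g,%.10g,%.10g)",
            vol$origin[1], vol$origin[2], vol$origin[3]),
    ""
  )
  writeLines(hdr, con, sep = "\n")
  writeBin(as.vector(vol$voxels), con, size = 8L, endian = "little")
  invisible(path)
}
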
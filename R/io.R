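#' Read and write volumetric images
#'
#' Supported formats, chosen by file extension: MetaImage (`.mhd` header +
#' `.raw` data), NIfTI-1 (`.nii`, `.nii.gz`), NRRD (`.nrrd`, raw or gzip
#' encodings), and multi-page TIFF (`.tif`, `.tiff`). Spacing is taken from
#' file metadata where the format stores it (MHD, NIfTI, NRRD) and must be
#' supplied by the caller for TIFF. All spacings are interpreted as
#' micrometres per voxel. Label images are read and written without any value
#' interpolation; integer data round-trip bit-exactly in every format.
#'
#' @param path file path.
#' @param spacing optional numeric length-3 override (required for TIFF).
#' @param label logical; read as a `label_volume` (integer IDs)?
#' @param ontology optional ontology `data.frame` attached to label volumes.
#' @return `read_volume` returns a `volume` or `label_volume`;
#'   `write_volume` returns `path` invisibly.
#' @examples
#' p <- tempfile(fileext = ".mhd")
#' v <- label_volume(array(1:8, c(2, 2, 2)), spacing = c(20, 1, 1))
#' write_volume(v, p)
#' identical(read_volume(p, label = TRUE)$data, v$data)
#' @export
read_volume <- function(path, spacing = NULL, label = FALSE, ontology = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(file_ext2(path))
  res <- switch(ext,
    mhd = read_mhd(path),
    nii = read_nifti_file(path),
    "nii.gz" = read_nifti_file(path),
    nrrd = read_nrrd(path),
    tif = ,
    tiff = read_tiff_stack(path),
    stop("unsupported volume format: .", ext)
  )
  sp <- if (!is.null(spacing)) spacing else res$spacing
  if (is.null(sp)) {
    stop("no spacing metadata in ", basename(path),
         "; supply `spacing` explicitly")
  }
  if (label) {
    label_volume(res$data, spacing = sp, origin = res$origin %||% c(0, 0, 0),
                 ontology = ontology)
  } else {
    volume(res$data, spacing = sp, origin = res$origin %||% c(0, 0, 0))
  }
}

#' @param x a `volume` or `label_volume`.
#' @rdname read_volume
#' @export
write_volume <- function(x, path) {
  stopifnot(inherits(x, "volume"))
  ext <- tolower(file_ext2(path))
  switch(ext,
    mhd = write_mhd(x, path),
    nii = ,
    "nii.gz" = write_nifti_file(x, path),
    nrrd = write_nrrd(x, path),
    tif = ,
    tiff = write_tiff_stack(x, path),
    stop("unsupported volume format: .", ext)
  )
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

file_ext2 <- function(path) {
  if (grepl("\\.nii\\.gz$", path, ignore.case = TRUE)) return("nii.gz")
  tools::file_ext(path)
}

## ---- MetaImage -------------------------------------------------------------

mhd_types <- c(MET_UCHAR = "uint8", MET_CHAR = "int8", MET_USHORT = "uint16",
               MET_SHORT = "int16", MET_INT = "int32", MET_UINT = "uint32",
               MET_FLOAT = "float32", MET_DOUBLE = "float64")

read_mhd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = " = "), "")
  get <- function(k) vals[match(k, keys)]
  dims <- as.integer(strsplit(trimws(get("DimSize")), "\\s+")[[1]])
  sp <- get("ElementSpacing")
  spacing <- if (is.na(sp)) NULL else as.numeric(strsplit(trimws(sp), "\\s+")[[1]])
  off <- get("Offset")
  origin <- if (is.na(off)) c(0, 0, 0) else as.numeric(strsplit(trimws(off), "\\s+")[[1]])
  type <- trimws(get("ElementType"))
  if (!type %in% names(mhd_types)) stop("unsupported MHD ElementType: ", type)
  datafile <- trimws(get("ElementDataFile"))
  if (is.na(datafile)) stop("MHD header lacks ElementDataFile")
  rawpath <- file.path(dirname(path), datafile)
  if (!file.exists(rawpath)) stop("raw data file not found: ", rawpath)
  msb <- identical(toupper(trimws(get("ElementByteOrderMSB"))), "TRUE")
  n <- prod(dims)
  info <- type_info(mhd_types[[type]])
  if (file.info(rawpath)$size < n * info$bytes) {
    stop("raw file shorter than DimSize implies (truncated?): ", rawpath)
  }
  con <- file(rawpath, "rb")
  on.exit(close(con))
  data <- readBin(con, what = info$what, n = n, size = info$bytes,
                  signed = info$signed, endian = if (msb) "big" else "little")
  data <- decode_unsigned(data, mhd_types[[type]])
  dim(data) <- dims
  list(data = data, spacing = spacing, origin = origin)
}

write_mhd <- function(x, path) {
  is_lab <- is_label_volume(x)
  type <- if (is_lab) "MET_INT" else "MET_DOUBLE"
  rawname <- paste0(tools::file_path_sans_ext(basename(path)), ".raw")
  header <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "ElementByteOrderMSB = False",
    paste("DimSize =", paste(dim(x$data), collapse = " ")),
    paste("ElementSpacing =", paste(format(x$spacing, scientific = FALSE), collapse = " ")),
    paste("Offset =", paste(format(x$origin, scientific = FALSE), collapse = " ")),
    paste("ElementType =", type),
    paste("ElementDataFile =", rawname)
  )
  writeLines(header, path)
  con <- file(file.path(dirname(path), rawname), "wb")
  on.exit(close(con))
  if (is_lab) {
    writeBin(as.integer(x$data), con, size = 4L, endian = "little")
  } else {
    writeBin(as.double(x$data), con, size = 8L, endian = "little")
  }
}

type_info <- function(t) {
  switch(t,
    uint8 = list(what = "integer", bytes = 1L, signed = FALSE),
    int8 = list(what = "integer", bytes = 1L, signed = TRUE),
    uint16 = list(what = "integer", bytes = 2L, signed = FALSE),
    int16 = list(what = "integer", bytes = 2L, signed = TRUE),
    int32 = list(what = "integer", bytes = 4L, signed = TRUE),
    uint32 = list(what = "integer", bytes = 4L, signed = TRUE),  # reinterpreted below
    float32 = list(what = "numeric", bytes = 4L, signed = TRUE),
    float64 = list(what = "numeric", bytes = 8L, signed = TRUE)
  )
}

decode_unsigned <- function(data, t) {
  if (t == "uint32" && any(data < 0)) data[data < 0] <- data[data < 0] + 2^32
  data
}

## ---- NIfTI -----------------------------------------------------------------

read_nifti_file <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  spacing <- if (is.null(pd)) NULL else as.numeric(pd[1:3])
  d <- dim(img)
  if (length(d) > 3L) d <- d[1:3]
  data <- array(as.vector(img)[seq_len(prod(d))], d)  # strip image attributes
  list(data = data, spacing = spacing, origin = c(0, 0, 0))
}

write_nifti_file <- function(x, path) {
  datatype <- if (is_label_volume(x)) "int32" else "double"
  img <- RNifti::asNifti(x$data)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path, datatype = datatype)
}

## ---- NRRD ------------------------------------------------------------------

nrrd_types <- c("signed char" = "int8", int8 = "int8", uchar = "uint8",
                "unsigned char" = "uint8", uint8 = "uint8",
                short = "int16", int16 = "int16", ushort = "uint16",
                uint16 = "uint16", int = "int32", int32 = "int32",
                uint = "uint32", uint32 = "uint32",
                float = "float32", double = "float64")

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("unexpected end of NRRD header")
    if (line == "") break
    header <- c(header, line)
  }
  fields <- header[grepl(":", header, fixed = TRUE)]
  kv <- strsplit(fields, ":\\s*")
  keys <- tolower(vapply(kv, `[`, "", 1L))
  vals <- vapply(kv, function(x) paste(x[-1], collapse = ": "), "")
  get <- function(k) vals[match(k, keys)]
  sizes <- as.integer(strsplit(trimws(get("sizes")), "\\s+")[[1]])
  type <- trimws(get("type"))
  if (!type %in% names(nrrd_types)) stop("unsupported NRRD type: ", type)
  t <- nrrd_types[[type]]
  spacing <- NULL
  if (!is.na(get("spacings"))) {
    spacing <- as.numeric(strsplit(trimws(get("spacings")), "\\s+")[[1]])
  } else if (!is.na(get("space directions"))) {
    dirs <- regmatches(get("space directions"),
                       gregexpr("\\(([^)]*)\\)", get("space directions")))[[1]]
    spacing <- vapply(dirs, function(d) {
      v <- as.numeric(strsplit(gsub("[()]", "", d), ",")[[1]])
      sqrt(sum(v^2))
    }, 0)
  }
  encoding <- trimws(get("encoding"))
  endian <- trimws(get("endian"))
  if (is.na(endian)) endian <- "little"
  n <- prod(sizes)
  info <- type_info(t)
  payload <- readBin(con, "raw", n = file.info(path)$size)
  if (encoding %in% c("gzip", "gz")) {
    payload <- memDecompress(payload, type = "gzip")
  } else if (encoding != "raw") {
    stop("unsupported NRRD encoding: ", encoding)
  }
  if (length(payload) < n * info$bytes) stop("NRRD data shorter than sizes imply")
  data <- readBin(payload, what = info$what, n = n, size = info$bytes,
                  signed = info$signed, endian = endian)
  data <- decode_unsigned(data, t)
  dim(data) <- sizes
  list(data = data, spacing = spacing, origin = c(0, 0, 0))
}

write_nrrd <- function(x, path) {
  is_lab <- is_label_volume(x)
  header <- c(
    "NRRD0004",
    paste0("type: ", if (is_lab) "int32" else "double"),
    "dimension: 3",
    paste("sizes:", paste(dim(x$data), collapse = " ")),
    paste("spacings:", paste(format(x$spacing, scientific = FALSE), collapse = " ")),
    "endian: little",
    "encoding: raw",
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  if (is_lab) {
    writeBin(as.integer(x$data), con, size = 4L, endian = "little")
  } else {
    writeBin(as.double(x$data), con, size = 8L, endian = "little")
  }
}

## ---- TIFF stacks -----------------------------------------------------------

# Pages run along axis 1 (the plane axis); each page is a (row, column)
# matrix. TIFF carries no z spacing, so read_volume() requires `spacing`.
read_tiff_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d23 <- dim(pages[[1]])[1:2]
  data <- array(0, c(length(pages), d23))
  for (p in seq_along(pages)) data[p, , ] <- pages[[p]][, , drop = TRUE]
  list(data = data, spacing = NULL, origin = c(0, 0, 0))
}

write_tiff_stack <- function(x, path) {
  d <- dim(x$data)
  mx <- max(x$data)
  if (any(x$data < 0)) stop("TIFF writer supports non-negative data only")
  if (is_label_volume(x) || all(x$data == round(x$data))) {
    if (mx > 65535) stop("integer TIFF limited to 16-bit values")
    pages <- lapply(seq_len(d[1]), function(p) {
      m <- matrix(x$data[p, , ] / 65535, d[2], d[3])
      m
    })
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else {
    scale <- if (mx > 0) mx else 1
    pages <- lapply(seq_len(d[1]), function(p) matrix(x$data[p, , ] / scale, d[2], d[3]))
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  }
}

#' Read a label ontology table
#'
#' @param path CSV or TSV file with columns `id`, `name`, and optionally
#'   `parent_id`, `level`.
#' @return a `data.frame`.
#' @export
read_ontology <- function(path) {
  sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  ont <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE)
  if (!all(c("id", "name") %in% names(ont))) {
    stop("ontology needs at least `id` and `name` columns")
  }
  ont
}
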
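## Readers/writers for the point-cloud formats the pipeline touches:
## PLY (ascii + binary_little_endian), PCD v0.7 (ascii + binary) and
## whitespace-separated XYZ[+labels]. Per-point label attributes are named
## "semantic" and "instance" in every format; the synthetic noise flag is
## stored as a uchar property "noise_mask" where the format permits.
## Coordinates are written as 64-bit floats in the binary formats so a
## write -> read round trip is bit-identical.

.ply_type_size <- c(char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
                    short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
                    int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
                    float = 4L, float32 = 4L, double = 8L, float64 = 8L)

## interleave per-field little-endian byte blocks into one record stream
.interleave_raw <- function(parts, sizes, n) {
  stride <- sum(sizes)
  out <- raw(stride * n)
  offs <- cumsum(c(0L, sizes))
  base <- stride * (seq_len(n) - 1L)
  for (j in seq_along(parts)) {
    idx <- rep(base + offs[j], each = sizes[j]) + seq_len(sizes[j])
    out[idx] <- parts[[j]]
  }
  out
}

.guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("ply", "pcd", "xyz")) return(ext)
  if (ext %in% c("txt", "asc")) return("xyz")
  stop("cannot infer point-cloud format from extension: ", path)
}

#' Read a point cloud
#'
#' Reads PLY (ascii or binary little-endian), PCD v0.7 (ascii or binary) or
#' whitespace-separated XYZ files into a [labeled_cloud()]. Per-point integer
#' attributes named `semantic` and `instance`, and a `noise_mask` flag, are
#' recognised where present. Point order is preserved exactly as stored.
#'
#' @param path file path.
#' @param format `"ply"`, `"pcd"` or `"xyz"`; inferred from the extension by
#'   default.
#' @return a [labeled_cloud()] in the sensor frame.
#' @export
read_cloud <- function(path, format = c("auto", "ply", "pcd", "xyz")) {
  format <- match.arg(format)
  if (format == "auto") format <- .guess_format(path)
  if (!file.exists(path)) stop("cannot read point cloud file: ", path)
  switch(format,
         ply = .read_ply(path),
         pcd = .read_pcd(path),
         xyz = .read_xyz(path))
}

#' Write a point cloud
#'
#' Inverse of [read_cloud()]. Binary variants store coordinates as 64-bit
#' floats, so re-reading reproduces them bit for bit; the ascii variants
#' round-trip within 1e-6. Label attributes that the target format cannot
#' represent raise an error rather than being dropped silently.
#'
#' @param cloud a [labeled_cloud()].
#' @param path output path.
#' @param format `"ply"`, `"pcd"` or `"xyz"` (inferred from extension).
#' @param binary write the binary variant (PLY/PCD only).
#' @return `invisible(path)`.
#' @export
write_cloud <- function(cloud, path, format = c("auto", "ply", "pcd", "xyz"),
                        binary = FALSE) {
  format <- match.arg(format)
  if (format == "auto") format <- .guess_format(path)
  stopifnot(inherits(cloud, "labeled_cloud"))
  switch(format,
         ply = .write_ply(cloud, path, binary),
         pcd = .write_pcd(cloud, path, binary),
         xyz = .write_xyz(cloud, path))
  invisible(path)
}

.finish_cloud <- function(cols) {
  pts <- cbind(cols$x, cols$y, cols$z)
  bad <- which(!is.finite(pts))
  if (length(bad))
    stop(sprintf("non-finite coordinate at row %d",
                 ((bad[1L] - 1L) %% nrow(pts)) + 1L))
  normals <- NULL
  if (!is.null(cols$nx)) {
    normals <- cbind(cols$nx, cols$ny, cols$nz)
    len <- sqrt(rowSums(normals^2))
    len[len == 0] <- 1
    normals <- normals / len
  }
  labeled_cloud(pts,
                semantic = cols$semantic,
                instance = cols$instance,
                noise_mask = if (is.null(cols$noise_mask)) NULL else
                  cols$noise_mask != 0,
                normals = normals,
                frame = "sensor")
}

## ---------------------------------------------------------------- PLY ----

.read_ply <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  m <- grepRaw("end_header\r\n", raw, fixed = TRUE)
  mlen <- 12L
  if (!length(m)) {
    m <- grepRaw("end_header\n", raw, fixed = TRUE)
    mlen <- 11L
  }
  if (!length(m)) stop("not a PLY file (no end_header): ", path)
  body_off <- m[1L] + mlen
  hdr <- strsplit(rawToChar(raw[seq_len(m[1L] - 1L)]), "\r?\n")[[1L]]
  hdr <- trimws(hdr)
  if (!identical(hdr[1L], "ply")) stop("not a PLY file: ", path)
  fmt_line <- grep("^format ", hdr, value = TRUE)[1L]
  fmt <- strsplit(fmt_line, "\\s+")[[1L]][2L]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format: ", fmt)

  props <- character(0); types <- character(0); n_vertex <- NA_integer_
  in_vertex <- FALSE
  for (line in hdr) {
    tok <- strsplit(line, "\\s+")[[1L]]
    if (tok[1L] == "element") {
      in_vertex <- identical(tok[2L], "vertex")
      if (in_vertex) n_vertex <- as.integer(tok[3L])
    } else if (tok[1L] == "property" && in_vertex) {
      if (identical(tok[2L], "list")) stop("list properties unsupported")
      types <- c(types, tok[2L])
      props <- c(props, tok[3L])
    }
  }
  if (is.na(n_vertex)) stop("PLY file has no vertex element")

  if (fmt == "ascii") {
    body <- rawToChar(raw[body_off:length(raw)])
    vals <- scan(text = body, what = numeric(), n = n_vertex * length(props),
                 quiet = TRUE)
    m <- matrix(vals, nrow = n_vertex, ncol = length(props), byrow = TRUE)
    cols <- stats::setNames(lapply(seq_along(props), function(j) m[, j]), props)
  } else {
    sizes <- .ply_type_size[types]
    if (anyNA(sizes)) stop("unknown PLY property type")
    stride <- sum(sizes)
    offs <- cumsum(c(0L, sizes))[seq_along(props)]
    base <- body_off - 1L + stride * (seq_len(n_vertex) - 1L)
    cols <- stats::setNames(vector("list", length(props)), props)
    for (j in seq_along(props)) {
      sz <- sizes[j]
      idx <- rep(base + offs[j], each = sz) + seq_len(sz)
      bytes <- raw[idx]
      ty <- types[j]
      cols[[j]] <- if (ty %in% c("float", "float32"))
        readBin(bytes, "numeric", n_vertex, size = 4L, endian = "little")
      else if (ty %in% c("double", "float64"))
        readBin(bytes, "numeric", n_vertex, size = 8L, endian = "little")
      else if (ty %in% c("uchar", "uint8"))
        readBin(bytes, "integer", n_vertex, size = 1L, signed = FALSE,
                endian = "little")
      else
        readBin(bytes, "integer", n_vertex, size = sz, endian = "little")
    }
  }
  for (nm in c("x", "y", "z"))
    if (is.null(cols[[nm]])) stop("PLY vertex element lacks property ", nm)
  .finish_cloud(cols)
}

.ply_fields <- function(cloud) {
  fields <- list(x = cloud$points[, 1L], y = cloud$points[, 2L],
                 z = cloud$points[, 3L])
  ftypes <- c("double", "double", "double")
  if (!is.null(cloud$normals)) {
    fields$nx <- cloud$normals[, 1L]; fields$ny <- cloud$normals[, 2L]
    fields$nz <- cloud$normals[, 3L]
    ftypes <- c(ftypes, "double", "double", "double")
  }
  if (!is.null(cloud$semantic)) {
    fields$semantic <- cloud$semantic; ftypes <- c(ftypes, "int")
  }
  if (!is.null(cloud$instance)) {
    fields$instance <- cloud$instance; ftypes <- c(ftypes, "int")
  }
  if (!is.null(cloud$noise_mask)) {
    fields$noise_mask <- as.integer(cloud$noise_mask)
    ftypes <- c(ftypes, "uchar")
  }
  list(fields = fields, types = ftypes)
}

.write_ply <- function(cloud, path, binary) {
  ff <- .ply_fields(cloud)
  n <- n_points(cloud)
  hdr <- c("ply",
           sprintf("format %s 1.0",
                   if (binary) "binary_little_endian" else "ascii"),
           sprintf("element vertex %d", n),
           sprintf("property %s %s", ff$types, names(ff$fields)),
           "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (binary) {
    sizes <- ifelse(ff$types == "double", 8L,
                    ifelse(ff$types == "uchar", 1L, 4L))
    parts <- lapply(seq_along(ff$fields), function(j) {
      if (ff$types[j] == "double")
        writeBin(as.double(ff$fields[[j]]), raw(), size = 8L,
                 endian = "little")
      else
        writeBin(as.integer(ff$fields[[j]]), raw(), size = sizes[j],
                 endian = "little")
    })
    writeBin(.interleave_raw(parts, sizes, n), con)
  } else {
    cells <- vapply(seq_along(ff$fields), function(j) {
      if (ff$types[j] == "double") sprintf("%.9g", ff$fields[[j]])
      else sprintf("%d", as.integer(ff$fields[[j]]))
    }, character(n))
    if (n == 1L) cells <- matrix(cells, nrow = 1L)
    writeLines(apply(cells, 1L, paste, collapse = " "), con, sep = "\n")
  }
}

## ---------------------------------------------------------------- PCD ----

.read_pcd <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  m <- grepRaw("DATA [a-z_]+\r?\n", raw)
  if (!length(m)) stop("not a PCD file (no DATA line): ", path)
  mtxt <- rawToChar(grepRaw("DATA [a-z_]+\r?\n", raw, value = TRUE))
  body_off <- m[1L] + nchar(mtxt, type = "bytes")
  hdr <- strsplit(rawToChar(raw[seq_len(body_off - 1L)]), "\r?\n")[[1L]]
  get <- function(key) {
    line <- grep(paste0("^", key, "\\b"), hdr, value = TRUE)
    if (!length(line)) return(NULL)
    strsplit(trimws(line[1L]), "\\s+")[[1L]][-1L]
  }
  fields <- get("FIELDS")
  size <- as.integer(get("SIZE"))
  type <- get("TYPE")
  count <- get("COUNT")
  if (!is.null(count) && any(as.integer(count) != 1L))
    stop("PCD COUNT > 1 unsupported")
  n <- as.integer(get("POINTS")[1L])
  data_mode <- tolower(strsplit(trimws(grep("^DATA", hdr, value = TRUE)[1L]),
                                "\\s+")[[1L]][2L])
  if (data_mode == "ascii") {
    body <- rawToChar(raw[body_off:length(raw)])
    vals <- scan(text = body, what = numeric(), n = n * length(fields),
                 quiet = TRUE)
    mx <- matrix(vals, nrow = n, ncol = length(fields), byrow = TRUE)
    cols <- stats::setNames(lapply(seq_along(fields), function(j) mx[, j]),
                            fields)
  } else if (data_mode == "binary") {
    stride <- sum(size)
    offs <- cumsum(c(0L, size))[seq_along(fields)]
    base <- body_off - 1L + stride * (seq_len(n) - 1L)
    cols <- stats::setNames(vector("list", length(fields)), fields)
    for (j in seq_along(fields)) {
      sz <- size[j]
      idx <- rep(base + offs[j], each = sz) + seq_len(sz)
      bytes <- raw[idx]
      cols[[j]] <- if (type[j] == "F")
        readBin(bytes, "numeric", n, size = sz, endian = "little")
      else if (sz == 1L)
        readBin(bytes, "integer", n, size = 1L,
                signed = (type[j] == "I"), endian = "little")
      else
        readBin(bytes, "integer", n, size = sz, endian = "little")
    }
  } else stop("unsupported PCD DATA mode: ", data_mode)
  .finish_cloud(cols)
}

.write_pcd <- function(cloud, path, binary) {
  if (!is.null(cloud$normals))
    stop("PCD writer does not represent normals; use PLY")
  fields <- list(x = cloud$points[, 1L], y = cloud$points[, 2L],
                 z = cloud$points[, 3L])
  type <- c("F", "F", "F"); size <- c(8L, 8L, 8L)
  if (!is.null(cloud$semantic)) {
    fields$semantic <- cloud$semantic; type <- c(type, "I"); size <- c(size, 4L)
  }
  if (!is.null(cloud$instance)) {
    fields$instance <- cloud$instance; type <- c(type, "I"); size <- c(size, 4L)
  }
  if (!is.null(cloud$noise_mask)) {
    fields$noise_mask <- as.integer(cloud$noise_mask)
    type <- c(type, "U"); size <- c(size, 1L)
  }
  n <- n_points(cloud)
  hdr <- c("# .PCD v0.7 - Point Cloud Data file format",
           "VERSION 0.7",
           paste("FIELDS", paste(names(fields), collapse = " ")),
           paste("SIZE", paste(size, collapse = " ")),
           paste("TYPE", paste(type, collapse = " ")),
           paste("COUNT", paste(rep(1L, length(fields)), collapse = " ")),
           sprintf("WIDTH %d", n),
           "HEIGHT 1",
           "VIEWPOINT 0 0 0 1 0 0 0",
           sprintf("POINTS %d", n),
           sprintf("DATA %s", if (binary) "binary" else "ascii"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (binary) {
    parts <- lapply(seq_along(fields), function(j) {
      if (type[j] == "F")
        writeBin(as.double(fields[[j]]), raw(), size = 8L, endian = "little")
      else
        writeBin(as.integer(fields[[j]]), raw(), size = size[j],
                 endian = "little")
    })
    writeBin(.interleave_raw(parts, size, n), con)
  } else {
    cells <- vapply(seq_along(fields), function(j) {
      if (type[j] == "F") sprintf("%.9g", fields[[j]])
      else sprintf("%d", as.integer(fields[[j]]))
    }, character(n))
    if (n == 1L) cells <- matrix(cells, nrow = 1L)
    writeLines(apply(cells, 1L, paste, collapse = " "), con, sep = "\n")
  }
}

## ---------------------------------------------------------------- XYZ ----

.read_xyz <- function(path) {
  m <- as.matrix(utils::read.table(path))
  if (ncol(m) < 3L) stop("XYZ file needs at least 3 columns")
  cols <- list(x = m[, 1L], y = m[, 2L], z = m[, 3L])
  if (ncol(m) >= 4L) cols$semantic <- as.integer(m[, 4L])
  if (ncol(m) >= 5L) cols$instance <- as.integer(m[, 5L])
  .finish_cloud(cols)
}

.write_xyz <- function(cloud, path) {
  if (!is.null(cloud$noise_mask) || !is.null(cloud$normals))
    stop("XYZ format cannot represent noise_mask/normals; use PLY")
  cols <- lapply(1:3, function(j) sprintf("%.9g", cloud$points[, j]))
  if (!is.null(cloud$instance) && is.null(cloud$semantic))
    stop("XYZ format stores instance only alongside semantic")
  if (!is.null(cloud$semantic)) cols <- c(cols, list(sprintf("%d", cloud$semantic)))
  if (!is.null(cloud$instance)) cols <- c(cols, list(sprintf("%d", cloud$instance)))
  writeLines(do.call(paste, cols), path)
}
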
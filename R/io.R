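# On-disk vertex indices are 0-based in every supported format (GIFTI, OFF,
# PLY triangle records, plain index lists, sulcal-line JSON), matching
# neuroimaging conventions; internal indices are 1-based R indices.
# Converters live entirely in this file.

gifti_dtype <- function(dt) {
  switch(dt,
         NIFTI_TYPE_FLOAT32 = list(what = "double", size = 4L),
         NIFTI_TYPE_FLOAT64 = list(what = "double", size = 8L),
         NIFTI_TYPE_INT32 = list(what = "integer", size = 4L),
         NIFTI_TYPE_UINT8 = list(what = "integer", size = 1L),
         stop("unsupported GIFTI DataType: ", dt))
}

read_gifti_arrays <- function(path) {
  doc <- xml2::read_xml(path)
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  out <- lapply(arrays, function(a) {
    at <- xml2::xml_attrs(a)
    dims <- as.integer(at[grep("^Dim[0-9]$", names(at))])
    n <- prod(dims)
    enc <- at[["Encoding"]]
    txt <- xml2::xml_text(xml2::xml_find_first(a, ".//Data"))
    dt <- gifti_dtype(at[["DataType"]])
    vals <- if (enc == "ASCII") {
      as.numeric(scan(text = txt, quiet = TRUE))
    } else if (enc %in% c("Base64Binary", "GZipBase64Binary")) {
      raw <- jsonlite::base64_dec(gsub("\\s", "", txt))
      if (enc == "GZipBase64Binary") raw <- memDecompress(raw, type = "gzip")
      endian <- if (identical(at[["Endian"]], "BigEndian")) "big" else "little"
      readBin(raw, what = dt$what, n = n, size = dt$size, endian = endian)
    } else stop("unsupported GIFTI Encoding: ", enc)
    if (length(vals) != n)
      stop("GIFTI data length ", length(vals), " does not match dims ",
           paste(dims, collapse = "x"))
    mat <- if (length(dims) == 2L) {
      if (identical(at[["ArrayIndexingOrder"]], "ColumnMajorOrder"))
        matrix(vals, nrow = dims[1L]) else
          matrix(vals, ncol = dims[2L], byrow = TRUE)
    } else matrix(vals, ncol = 1L)
    list(intent = at[["Intent"]], data = mat)
  })
  labels <- xml2::xml_find_all(doc, ".//LabelTable/Label")
  label_table <- if (length(labels)) {
    data.frame(key = as.integer(xml2::xml_attr(labels, "Key")),
               name = xml2::xml_text(labels))
  } else NULL
  list(arrays = out, label_table = label_table)
}

gifti_data_array <- function(intent, dtype, mat, fmt) {
  dims <- dim(mat)
  vals <- as.vector(t(mat))  # RowMajorOrder
  paste0(
    sprintf(paste0('<DataArray Intent="%s" DataType="%s" ',
                   'ArrayIndexingOrder="RowMajorOrder" Dimensionality="2" ',
                   'Dim0="%d" Dim1="%d" Encoding="ASCII" ',
                   'Endian="LittleEndian" ExternalFileName="" ',
                   'ExternalFileOffset="">\n'),
            intent, dtype, dims[1L], dims[2L]),
    "<Data>", paste(sprintf(fmt, vals), collapse = " "), "</Data>\n",
    "</DataArray>\n")
}

write_gifti <- function(path, body, n_arrays) {
  txt <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<!DOCTYPE GIFTI SYSTEM "http://www.nitrc.org/frs/download.php/115/gifti.dtd">\n',
    sprintf('<GIFTI Version="1.0" NumberOfDataArrays="%d">\n', n_arrays),
    body, "</GIFTI>\n")
  writeLines(txt, path)
}

#' Read a triangle surface mesh
#'
#' Reads GIFTI (`.gii`, pointset + triangle arrays; ASCII, Base64Binary and
#' GZipBase64Binary encodings), OFF (`.off`) or ASCII PLY (`.ply`)
#' surfaces.  Triangle indices are converted from the formats' 0-based to
#' internal 1-based indexing.
#'
#' @param path file path; the format is taken from the extension unless
#'   `format` is given.
#' @param format `"gifti"`, `"off"` or `"ply"`.
#' @return a [triangle_mesh].
#' @export
read_surface <- function(path, format = NULL) {
  format <- surface_format(path, format)
  if (format == "gifti") {
    g <- read_gifti_arrays(path)
    intents <- vapply(g$arrays, `[[`, "", "intent")
    vi <- match("NIFTI_INTENT_POINTSET", intents)
    ti <- match("NIFTI_INTENT_TRIANGLE", intents)
    if (is.na(vi) || is.na(ti))
      stop("GIFTI surface needs POINTSET and TRIANGLE arrays")
    return(triangle_mesh(g$arrays[[vi]]$data, g$arrays[[ti]]$data + 1L,
                         name = sub("\\.[^.]*$", "", basename(path))))
  }
  lines <- readLines(path)
  if (format == "off") {
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    if (!grepl("^OFF", lines[1L])) stop("not an OFF file")
    counts <- scan(text = lines[2L], quiet = TRUE)
    nv <- counts[1L]; nf <- counts[2L]
    v <- matrix(scan(text = paste(lines[3:(2 + nv)], collapse = "\n"),
                     quiet = TRUE), ncol = 3L, byrow = TRUE)
    f <- matrix(scan(text = paste(lines[(3 + nv):(2 + nv + nf)],
                                  collapse = "\n"), quiet = TRUE),
                ncol = 4L, byrow = TRUE)
    if (any(f[, 1L] != 3L)) stop("only triangle faces are supported")
    return(triangle_mesh(v, f[, 2:4] + 1L,
                         name = sub("\\.[^.]*$", "", basename(path))))
  }
  # ascii ply
  hdr_end <- which(lines == "end_header")[1L]
  if (is.na(hdr_end)) stop("not an ASCII PLY file")
  hdr <- lines[seq_len(hdr_end)]
  if (!any(grepl("^format ascii", hdr)))
    stop("only ASCII PLY is supported")
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", hdr, value = TRUE)))
  v <- matrix(scan(text = paste(lines[hdr_end + seq_len(nv)], collapse = "\n"),
                   quiet = TRUE), nrow = nv, byrow = TRUE)[, 1:3, drop = FALSE]
  f <- matrix(scan(text = paste(lines[hdr_end + nv + seq_len(nf)],
                                collapse = "\n"), quiet = TRUE),
              nrow = nf, byrow = TRUE)
  if (any(f[, 1L] != 3L)) stop("only triangle faces are supported")
  triangle_mesh(v, f[, 2:4] + 1L, name = sub("\\.[^.]*$", "", basename(path)))
}

surface_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("gifti", "off", "ply")))
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext, gii = "gifti", off = "off", ply = "ply",
         stop("cannot infer surface format from extension '.", ext, "'"))
}

#' Write a triangle surface mesh
#'
#' @param mesh a [triangle_mesh].
#' @param path output path (`.gii`, `.off` or `.ply`).
#' @param format optional explicit format.
#' @return `path`, invisibly.
#' @export
write_surface <- function(mesh, path, format = NULL) {
  format <- surface_format(path, format)
  v <- mesh$vertices
  tr0 <- mesh$triangles - 1L
  if (format == "gifti") {
    body <- paste0(
      gifti_data_array("NIFTI_INTENT_POINTSET", "NIFTI_TYPE_FLOAT32", v,
                       "%.9g"),
      gifti_data_array("NIFTI_INTENT_TRIANGLE", "NIFTI_TYPE_INT32", tr0,
                       "%d"))
    write_gifti(path, body, 2L)
  } else if (format == "off") {
    writeLines(c("OFF",
                 sprintf("%d %d 0", nrow(v), nrow(tr0)),
                 sprintf("%.9g %.9g %.9g", v[, 1L], v[, 2L], v[, 3L]),
                 sprintf("3 %d %d %d", tr0[, 1L], tr0[, 2L], tr0[, 3L])),
               path)
  } else {
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(v)),
                 "property float x", "property float y", "property float z",
                 sprintf("element face %d", nrow(tr0)),
                 "property list uchar int vertex_indices", "end_header",
                 sprintf("%.9g %.9g %.9g", v[, 1L], v[, 2L], v[, 3L]),
                 sprintf("3 %d %d %d", tr0[, 1L], tr0[, 2L], tr0[, 3L])),
               path)
  }
  invisible(path)
}

#' Read a spherical parameterization
#'
#' Reads a sphere surface (any format of [read_surface()]) whose vertices
#' are index-aligned with a subject mesh, and normalizes the vertex rows to
#' unit length (FreeSurfer-style spheres have radius 100).
#'
#' @param path sphere surface file.
#' @return a [spherical_param].
#' @export
read_sphere <- function(path) {
  m <- read_surface(path)
  v <- m$vertices
  spherical_param(v / sqrt(rowSums(v^2)))
}

#' Read / write per-vertex labels as GIFTI label files
#'
#' `write_labels_gifti()` stores a [parcellation] as a
#' `NIFTI_INTENT_LABEL` data array with a label table (key 0 named
#' `"constraint"` when present); `read_labels_gifti()` reads it back.
#'
#' @param path file path (`.label.gii` conventionally).
#' @param map a [parcellation].
#' @return `read_labels_gifti()`: a [parcellation]; `write_labels_gifti()`:
#'   the path, invisibly.
#' @export
read_labels_gifti <- function(path) {
  g <- read_gifti_arrays(path)
  intents <- vapply(g$arrays, `[[`, "", "intent")
  li <- match("NIFTI_INTENT_LABEL", intents)
  if (is.na(li)) li <- 1L
  labels <- as.integer(g$arrays[[li]]$data[, 1L])
  parcellation(labels)
}

#' @rdname read_labels_gifti
#' @export
write_labels_gifti <- function(map, path) {
  stopifnot(inherits(map, "parcellation"))
  keys <- sort(unique(map$labels))
  lt <- paste0(
    "<LabelTable>\n",
    paste(sprintf('<Label Key="%d"><![CDATA[%s]]></Label>', keys,
                  ifelse(keys == 0L, "constraint", paste0("region_", keys))),
          collapse = "\n"),
    "\n</LabelTable>\n")
  body <- paste0(lt, gifti_data_array("NIFTI_INTENT_LABEL", "NIFTI_TYPE_INT32",
                                      matrix(map$labels, ncol = 1L), "%d"))
  write_gifti(path, body, 1L)
  invisible(path)
}

#' Read / write plain-text vertex index lists
#'
#' One 0-based vertex index per line; used for constraint regions
#' (cingulate-pole analogues).  Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @param region a [constraint_region].
#' @param n_vertices optional mesh vertex count for range checking on read.
#' @return `read_index_list()`: a [constraint_region].
#' @export
read_index_list <- function(path, n_vertices = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  constraint_region(as.integer(lines) + 1L, n_vertices = n_vertices)
}

#' @rdname read_index_list
#' @export
write_index_list <- function(region, path) {
  stopifnot(inherits(region, "constraint_region"))
  writeLines(as.character(region$vertex_indices - 1L), path)
  invisible(path)
}

#' Read / write sulcal lines as JSON
#'
#' Schema: `{"label": str, "vertices": [int, ...]}` with 0-based vertex
#' indices.
#'
#' @param path file path.
#' @param line a [sulcal_line].
#' @param mesh optional [triangle_mesh] for adjacency checking on read.
#' @return `read_sulcal_line()`: a [sulcal_line].
#' @export
read_sulcal_line <- function(path, mesh = NULL) {
  x <- jsonlite::fromJSON(path)
  sulcal_line(as.integer(x$vertices) + 1L, label = x$label, mesh = mesh)
}

#' @rdname read_sulcal_line
#' @export
write_sulcal_line <- function(line, path) {
  stopifnot(inherits(line, "sulcal_line"))
  jsonlite::write_json(list(label = line$label,
                            vertices = line$vertex_indices - 1L),
                       path, auto_unbox = TRUE)
  invisible(path)
}
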
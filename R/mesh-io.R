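# Triangle-mesh readers and writers.
#
# PLY is the canonical interchange dialect: ASCII and binary little-endian are
# read; binary little-endian is written by default, with vertex coordinates as
# doubles so round-trips preserve millimetre coordinates to well below 1e-6.
# Per-vertex scalars (distance heatmaps) travel as a PLY vertex property
# "quality". STL (ASCII + binary) and OBJ are supported for geometry only.

ply_type_size <- c(char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
                   short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
                   int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_read_prop <- function(raw_block, type, offset, stride, n) {
  size <- ply_type_size[[type]]
  idx <- as.vector(outer(seq_len(size), (seq_len(n) - 1L) * stride, "+") + offset)
  bytes <- raw_block[idx]
  what <- if (type %in% c("float", "float32", "double", "float64")) "double" else "integer"
  signed <- !(type %in% c("uchar", "uint8", "ushort", "uint16"))
  readBin(bytes, what = what, n = n, size = size, signed = signed,
          endian = "little")
}

detect_format <- function(path, format) {
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("ply", "stl", "obj")) return(ext)
  stop("cannot infer mesh format from extension '", ext,
       "'; pass format = \"ply\", \"stl\" or \"obj\"")
}

#' Load a surface mesh from PLY, STL or OBJ
#'
#' Coordinates are taken to be millimetres (no unit metadata is read;
#' CT-derived bone meshes are conventionally stored in mm). Duplicate
#' vertices are merged within 1e-6 mm, which restores shared connectivity for
#' STL files that repeat vertices per facet.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"ply"`, `"stl"` or `"obj"`.
#' @param merge_tol duplicate-vertex merge tolerance in mm.
#' @return A [tri_surface()]. If the file carried a per-vertex `quality`
#'   property (PLY), it is attached as attribute `"quality"`.
#' @export
load_mesh <- function(path, format = c("auto", "ply", "stl", "obj"),
                      merge_tol = 1e-6) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  format <- detect_format(path, format)
  mesh <- switch(format,
                 ply = read_ply(path),
                 stl = read_stl(path),
                 obj = read_obj(path))
  if (n_faces(mesh) == 0L) stop("empty mesh: ", path)
  q <- attr(mesh, "quality")
  mesh <- merge_duplicate_vertices(mesh, tol = merge_tol)
  if (!is.null(q) && length(q) == n_vertices(mesh)) attr(mesh, "quality") <- q
  mesh
}

read_ply <- function(path) {
  blob <- readBin(path, "raw", file.size(path))
  # header is ASCII terminated by "end_header\n"
  marker <- charToRaw("end_header")
  hdr_end <- NA_integer_
  limit <- min(length(blob), 65536L)
  for (i in seq_len(limit - length(marker))) {
    if (blob[i] == marker[1] && all(blob[i + seq_along(marker) - 1L] == marker)) {
      j <- i + length(marker)
      while (j <= length(blob) && blob[j] != as.raw(10L)) j <- j + 1L
      hdr_end <- j
      break
    }
  }
  if (is.na(hdr_end)) stop("PLY format error: missing end_header")
  hdr <- strsplit(rawToChar(blob[1:hdr_end]), "\r?\n")[[1]]
  if (!identical(hdr[1], "ply")) stop("PLY format error: missing 'ply' magic (line 1)")
  fmt_line <- grep("^format ", hdr, value = TRUE)
  if (!length(fmt_line)) stop("PLY format error: missing format line")
  fmt <- strsplit(fmt_line[1], "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("PLY format error: unsupported format '", fmt, "'")

  elements <- list(); cur <- NULL
  for (ln in hdr) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (!length(tok)) next
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list")
        cur$props[[length(cur$props) + 1L]] <- list(name = tok[5], list = TRUE,
                                                    count_type = tok[3], type = tok[4])
      else
        cur$props[[length(cur$props) + 1L]] <- list(name = tok[3], list = FALSE,
                                                    type = tok[2])
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex) || is.null(elements$face))
    stop("PLY format error: vertex and face elements required")

  if (fmt == "ascii") {
    body <- strsplit(rawToChar(blob[(hdr_end + 1L):length(blob)]), "\r?\n")[[1]]
    body <- body[nzchar(trimws(body))]
    out <- ply_parse_ascii(elements, body, length(hdr))
  } else {
    out <- ply_parse_binary(elements, blob[(hdr_end + 1L):length(blob)])
  }
  mesh <- tri_surface(out$vertices, out$faces)
  if (!is.null(out$quality)) attr(mesh, "quality") <- out$quality
  mesh
}

ply_parse_ascii <- function(elements, body, hdr_lines) {
  pos <- 0L
  vertices <- faces <- quality <- NULL
  for (el in elements) {
    if (pos + el$count > length(body))
      stop(sprintf("PLY format error: element '%s' declares %d records but only %d found (after line %d)",
                   el$name, el$count, length(body) - pos, hdr_lines + pos))
    lines <- body[pos + seq_len(el$count)]
    pos <- pos + el$count
    if (el$name == "vertex") {
      pnames <- vapply(el$props, `[[`, "", "name")
      vals <- matrix(scan(text = lines, quiet = TRUE), nrow = el$count,
                     byrow = TRUE)
      if (ncol(vals) != length(pnames))
        stop("PLY format error: vertex record width mismatch")
      vertices <- vals[, match(c("x", "y", "z"), pnames), drop = FALSE]
      if ("quality" %in% pnames) quality <- vals[, match("quality", pnames)]
    } else if (el$name == "face") {
      toks <- strsplit(trimws(lines), "\\s+")
      counts <- vapply(toks, function(t) as.integer(t[1]), 1L)
      if (any(counts != 3L))
        stop("PLY format error: only triangular faces are supported (record ",
             which(counts != 3L)[1], ")")
      faces <- matrix(as.integer(unlist(lapply(toks, `[`, 2:4))), ncol = 3L,
                      byrow = TRUE) + 1L
    }
  }
  list(vertices = vertices, faces = faces, quality = quality)
}

ply_parse_binary <- function(elements, body) {
  offset <- 0L
  vertices <- faces <- quality <- NULL
  for (el in elements) {
    if (el$name == "vertex") {
      sizes <- vapply(el$props, function(p) ply_type_size[[p$type]], 1L)
      stride <- sum(sizes)
      need <- stride * el$count
      if (offset + need > length(body))
        stop(sprintf("PLY format error: vertex element declares %d records but data is truncated",
                     el$count))
      block <- body[offset + seq_len(need)]
      offset <- offset + need
      offs <- cumsum(c(0L, sizes))[seq_along(sizes)]
      pnames <- vapply(el$props, `[[`, "", "name")
      grab <- function(nm) {
        k <- match(nm, pnames)
        ply_read_prop(block, el$props[[k]]$type, offs[k], stride, el$count)
      }
      vertices <- cbind(grab("x"), grab("y"), grab("z"))
      if ("quality" %in% pnames) quality <- grab("quality")
    } else if (el$name == "face") {
      p <- el$props[[1]]
      if (!p$list) stop("PLY format error: face element must carry a list property")
      csize <- ply_type_size[[p$count_type]]
      isize <- ply_type_size[[p$type]]
      stride <- csize + 3L * isize
      need <- stride * el$count
      if (offset + need > length(body))
        stop(sprintf("PLY format error: face element declares %d records but data is truncated",
                     el$count))
      block <- body[offset + seq_len(need)]
      counts <- ply_read_prop(block, p$count_type, 0L, stride, el$count)
      if (any(counts != 3L))
        stop("PLY format error: only triangular faces are supported")
      offset <- offset + need
      idx <- vapply(0:2, function(k)
        ply_read_prop(block, p$type, csize + k * isize, stride, el$count),
        numeric(el$count))
      faces <- matrix(as.integer(idx), ncol = 3L) + 1L
    } else {
      # skip unknown fixed-width element
      sizes <- vapply(el$props, function(p) ply_type_size[[p$type]], 1L)
      offset <- offset + sum(sizes) * el$count
    }
  }
  list(vertices = vertices, faces = faces, quality = quality)
}

read_stl <- function(path) {
  size <- file.size(path)
  blob <- readBin(path, "raw", size)
  n_bin <- if (size >= 84L) readBin(blob[81:84], "integer", 1L, 4L,
                                    endian = "little") else -1L
  is_binary <- !is.na(n_bin) && n_bin > 0 && size == 84 + 50 * as.numeric(n_bin)
  if (is_binary) {
    stride <- 50L
    body <- blob[85:size]
    tri <- vapply(0:8, function(k)
      ply_read_prop(body, "float", 12L + 4L * k, stride, n_bin),
      numeric(n_bin))
    if (n_bin == 1L) tri <- matrix(tri, nrow = 1L)
    v <- rbind(tri[, 1:3, drop = FALSE], tri[, 4:6, drop = FALSE],
               tri[, 7:9, drop = FALSE])
    ord <- as.vector(t(matrix(seq_len(3L * n_bin), ncol = 3L)))
    v <- v[ord, , drop = FALSE]
  } else {
    lines <- readLines(path, warn = FALSE)
    vt <- grep("^\\s*vertex\\s", lines, value = TRUE)
    if (!length(vt)) stop("STL format error: no vertex records found")
    v <- matrix(scan(text = sub("^\\s*vertex\\s+", "", vt), quiet = TRUE),
                ncol = 3L, byrow = TRUE)
    if (nrow(v) %% 3L != 0L)
      stop("STL format error: vertex count ", nrow(v),
           " is not a multiple of 3 (truncated facet)")
  }
  faces <- matrix(seq_len(nrow(v)), ncol = 3L, byrow = TRUE)
  tri_surface(v, faces, validate = FALSE)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vt <- grep("^v\\s", lines, value = TRUE)
  ft <- grep("^f\\s", lines, value = TRUE)
  if (!length(vt)) stop("OBJ format error: no vertex records")
  v <- matrix(scan(text = sub("^v\\s+", "", vt), quiet = TRUE), ncol = 3L,
              byrow = TRUE)
  tris <- list()
  for (k in seq_along(ft)) {
    tok <- strsplit(trimws(sub("^f\\s+", "", ft[k])), "\\s+")[[1]]
    idx <- as.integer(vapply(strsplit(tok, "/"), `[[`, "", 1L))
    if (any(is.na(idx)) || any(idx < 0L))
      stop("OBJ format error: unsupported face record '", ft[k], "' (record ", k, ")")
    if (length(idx) < 3L)
      stop("OBJ format error: face with fewer than 3 vertices (record ", k, ")")
    for (j in 2:(length(idx) - 1L))  # fan-triangulate polygons
      tris[[length(tris) + 1L]] <- idx[c(1L, j, j + 1L)]
  }
  if (!length(tris)) stop("OBJ format error: no face records")
  tri_surface(v, do.call(rbind, tris), validate = FALSE)
}

#' Save a surface mesh to PLY, STL or OBJ
#'
#' PLY (the canonical dialect) is written binary little-endian by default with
#' double-precision coordinates, so `load_mesh(save_mesh(m))` reproduces
#' vertices exactly to well within 1e-6 mm. An optional per-vertex scalar
#' (e.g. correspondence distances for a heatmap) is stored as PLY vertex
#' property `quality`; STL and OBJ cannot carry it and drop it with a
#' warning. STL is written ASCII (binary STL is single-precision by format).
#'
#' @param mesh a [tri_surface()].
#' @param path output path.
#' @param format `"auto"` (by extension), `"ply"`, `"stl"` or `"obj"`.
#' @param per_vertex_scalar optional numeric vector, one value per vertex.
#' @param binary write binary PLY (default) or ASCII.
#' @return Invisibly, `path`.
#' @export
save_mesh <- function(mesh, path, format = c("auto", "ply", "stl", "obj"),
                      per_vertex_scalar = NULL, binary = TRUE) {
  format <- match.arg(format)
  format <- detect_format(path, format)
  if (!is.null(per_vertex_scalar)) {
    if (length(per_vertex_scalar) != n_vertices(mesh))
      stop("per_vertex_scalar must have one value per vertex (",
           length(per_vertex_scalar), " != ", n_vertices(mesh), ")")
    if (format != "ply") {
      warning(toupper(format), " cannot carry per-vertex scalars; dropped")
      per_vertex_scalar <- NULL
    }
  }
  switch(format,
         ply = write_ply(mesh, path, per_vertex_scalar, binary),
         stl = write_stl(mesh, path),
         obj = write_obj(mesh, path))
  invisible(path)
}

write_ply <- function(mesh, path, quality = NULL, binary = TRUE) {
  v <- mesh$vertices
  f <- mesh$faces
  hdr <- c("ply",
           if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
           sprintf("element vertex %d", nrow(v)),
           "property double x", "property double y", "property double z",
           if (!is.null(quality)) "property double quality",
           sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices",
           "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  vm <- if (is.null(quality)) v else cbind(v, as.numeric(quality))
  if (binary) {
    writeBin(as.vector(t(vm)), con, size = 8L, endian = "little")
    idx_raw <- writeBin(as.integer(t(f) - 1L), raw(), size = 4L, endian = "little")
    out <- raw(13L * nrow(f))
    rec0 <- (seq_len(nrow(f)) - 1L) * 13L
    out[rec0 + 1L] <- as.raw(3L)
    body_pos <- as.vector(outer(2:13, rec0, "+"))
    out[body_pos] <- idx_raw
    writeBin(out, con)
  } else {
    writeLines(apply(vm, 1L, function(r) paste(sprintf("%.17g", r), collapse = " ")), con)
    writeLines(paste(3L, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  }
}

write_stl <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  fn <- face_cross(mesh)
  len <- row_norms(fn)
  fn <- fn / pmax(len, 1e-300)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid bisym", con)
  for (i in seq_len(nrow(f))) {
    writeLines(c(sprintf("  facet normal %.9g %.9g %.9g", fn[i, 1], fn[i, 2], fn[i, 3]),
                 "    outer loop",
                 sprintf("      vertex %.17g %.17g %.17g",
                         v[f[i, ], 1], v[f[i, ], 2], v[f[i, ], 3]),
                 "    endloop", "  endfacet"), con)
  }
  writeLines("endsolid bisym", con)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(apply(mesh$vertices, 1L,
                   function(r) paste("v", paste(sprintf("%.17g", r), collapse = " "))), con)
  writeLines(paste("f", mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]), con)
}
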
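#' Read a triangle mesh from STL, PLY or OBJ
#'
#' Reads the mesh file and, when present, the landmark/region sidecar
#' `<path>.landmarks.json` (0-based vertex indexing in the sidecar). STL files
#' store one vertex triple per triangle, so shared vertices are reconstructed
#' by exact-coordinate matching in order of first appearance.
#'
#' @param path Path to the mesh file.
#' @param format `"stl"`, `"ply"`, `"obj"` or `"auto"` (from the extension).
#' @return A [tri_mesh()].
#' @export
read_mesh <- function(path, format = c("auto", "stl", "ply", "obj")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("stl", "ply", "obj")) {
      stop("cannot infer mesh format from extension of ", path, call. = FALSE)
    }
  }
  mesh <- switch(format,
    stl = read_stl(path),
    ply = read_ply(path),
    obj = read_obj(path)
  )
  sidecar <- sidecar_path(path)
  if (file.exists(sidecar)) {
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    lm <- NULL
    if (!is.null(sc$landmarks) && length(sc$landmarks)) {
      lm <- do.call(rbind, sc$landmarks)
      rownames(lm) <- names(sc$landmarks)
    }
    region <- sc$region_labels
    if (!is.null(region) && length(region) == 0L) region <- NULL
    mesh <- tri_mesh(mesh$vertices, mesh$faces, landmarks = lm, region = region)
  }
  mesh
}

#' Write a triangle mesh to STL, PLY or OBJ
#'
#' STL carries no attributes; PLY/OBJ here store geometry only as well.
#' Landmarks and region labels, when present, are written to the JSON sidecar
#' `<path>.landmarks.json` with 0-based vertex indexing, which [read_mesh()]
#' picks up automatically.
#'
#' @param mesh A [tri_mesh()].
#' @param path Output path.
#' @param format `"stl"` (ASCII), `"ply"` (ASCII), `"obj"` or `"auto"`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "stl", "ply", "obj")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("stl", "ply", "obj")) {
      stop("cannot infer mesh format from extension of ", path, call. = FALSE)
    }
  }
  switch(format,
    stl = write_stl(mesh, path),
    ply = write_ply(mesh, path),
    obj = write_obj(mesh, path)
  )
  if (!is.null(mesh$landmarks) || !is.null(mesh$region)) {
    sc <- list(
      vertex_indexing = "0-based",
      landmarks = if (is.null(mesh$landmarks)) NULL else
        stats::setNames(
          lapply(seq_len(nrow(mesh$landmarks)),
                 function(i) unname(mesh$landmarks[i, ])),
          rownames(mesh$landmarks)
        ),
      region_labels = mesh$region
    )
    jsonlite::write_json(sc[!vapply(sc, is.null, logical(1))],
                         sidecar_path(path), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".landmarks.json")

fmt_num <- function(x) formatC(x, format = "g", digits = 9)

## ---- PLY (ASCII) ----

write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0", "comment auriclass mesh",
    paste("element vertex", n_vertices(mesh)),
    "property float x", "property float y", "property float z",
    paste("element face", n_faces(mesh)),
    "property list uchar int vertex_indices", "end_header"
  ), con)
  v <- mesh$vertices
  writeLines(paste(fmt_num(v[, 1]), fmt_num(v[, 2]), fmt_num(v[, 3])), con)
  if (n_faces(mesh) > 0L) {
    f <- mesh$faces - 1L
    writeLines(paste(3L, f[, 1], f[, 2], f[, 3]), con)
  }
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr_end <- match("end_header", trimws(lines))
  if (is.na(hdr_end)) stop("not a valid PLY file: ", path, call. = FALSE)
  hdr <- lines[seq_len(hdr_end)]
  if (!any(grepl("^format ascii", hdr))) {
    stop("only ASCII PLY is supported: ", path, call. = FALSE)
  }
  nv <- as.integer(sub("^element vertex\\s+", "", grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("^element face\\s+", "", grep("^element face", hdr, value = TRUE)))
  body <- lines[(hdr_end + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  vl <- body[seq_len(nv)]
  v <- matrix(as.numeric(unlist(strsplit(trimws(vl), "\\s+"))),
              ncol = length(strsplit(trimws(vl[1]), "\\s+")[[1]]), byrow = TRUE)
  v <- v[, 1:3, drop = FALSE]
  f <- matrix(integer(0), ncol = 3)
  if (nf > 0L) {
    fl <- body[nv + seq_len(nf)]
    fm <- matrix(as.integer(unlist(strsplit(trimws(fl), "\\s+"))),
                 ncol = 4, byrow = TRUE)
    if (any(fm[, 1] != 3L)) stop("non-triangular PLY face", call. = FALSE)
    f <- fm[, 2:4, drop = FALSE] + 1L
  }
  tri_mesh(v, f)
}

## ---- OBJ ----

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh$vertices
  writeLines(paste("v", fmt_num(v[, 1]), fmt_num(v[, 2]), fmt_num(v[, 3])), con)
  if (n_faces(mesh) > 0L) {
    f <- mesh$faces
    writeLines(paste("f", f[, 1], f[, 2], f[, 3]), con)
  }
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (!length(vl)) stop("degenerate mesh: 0 vertices in ", path, call. = FALSE)
  v <- matrix(as.numeric(unlist(strsplit(sub("^v\\s+", "", trimws(vl)), "\\s+"))),
              ncol = 3, byrow = TRUE)
  f <- matrix(integer(0), ncol = 3)
  if (length(fl)) {
    toks <- strsplit(sub("^f\\s+", "", trimws(fl)), "\\s+")
    idx <- lapply(toks, function(t) as.integer(sub("/.*$", "", t)))
    if (any(lengths(idx) != 3L)) stop("non-triangular OBJ face", call. = FALSE)
    f <- do.call(rbind, idx)
  }
  tri_mesh(v, f)
}

## ---- STL (ASCII and binary) ----

write_stl <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid auriclass", con)
  v <- mesh$vertices
  f <- mesh$faces
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; c3 <- v[f[i, 3], ]
    n <- pracma_cross(b - a, c3 - a)
    nn <- sqrt(sum(n^2))
    if (nn > 0) n <- n / nn
    writeLines(c(
      paste("  facet normal", fmt_num(n[1]), fmt_num(n[2]), fmt_num(n[3])),
      "    outer loop",
      paste("      vertex", fmt_num(a[1]), fmt_num(a[2]), fmt_num(a[3])),
      paste("      vertex", fmt_num(b[1]), fmt_num(b[2]), fmt_num(b[3])),
      paste("      vertex", fmt_num(c3[1]), fmt_num(c3[2]), fmt_num(c3[3])),
      "    endloop",
      "  endfacet"
    ), con)
  }
  writeLines("endsolid auriclass", con)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

read_stl <- function(path) {
  # binary STL: 80-byte header then uint32 facet count matching file size
  sz <- file.info(path)$size
  con <- file(path, "rb")
  head <- readBin(con, "raw", n = min(80, sz))
  is_binary <- FALSE
  if (sz >= 84) {
    nt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    if (!is.na(nt) && sz == 84 + 50 * as.numeric(nt)) is_binary <- TRUE
  }
  close(con)
  tris <- if (is_binary) read_stl_binary(path) else read_stl_ascii(path)
  if (nrow(tris) == 0L) stop("degenerate mesh: 0 vertices in ", path, call. = FALSE)
  # merge shared vertices exactly, first-appearance order
  key <- paste(tris[, 1], tris[, 2], tris[, 3], sep = "|")
  first <- !duplicated(key)
  verts <- tris[first, , drop = FALSE]
  idx <- match(key, key[first])
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  tri_mesh(verts, faces)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (!length(vl)) return(matrix(numeric(0), ncol = 3))
  matrix(as.numeric(unlist(strsplit(sub("^\\s*vertex\\s+", "", vl), "\\s+"))),
         ncol = 3, byrow = TRUE)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  nt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  out <- matrix(NA_real_, nrow = 3 * nt, ncol = 3)
  for (i in seq_len(nt)) {
    vals <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
    out[(3 * i - 2):(3 * i), ] <- matrix(vals[4:12], ncol = 3, byrow = TRUE)
    readBin(con, "raw", n = 2)
  }
  out
}
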
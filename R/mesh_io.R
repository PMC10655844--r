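#' Read a surface mesh from PLY, STL or OFF
#'
#' ASCII variants of the three formats; the format is chosen by file
#' extension.
#'
#' @param path file path ending in .ply, .stl or .off.
#' @return a `seeg_mesh`.
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = read_ply(path),
         off = read_off(path),
         stl = read_stl(path),
         stop("unsupported mesh format: .", ext))
}

#' Write a surface mesh as ASCII PLY, STL or OFF
#'
#' @param mesh a `seeg_mesh`.
#' @param path output path; extension selects the format.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = write_ply(mesh, path),
         off = write_off(mesh, path),
         stl = write_stl(mesh, path),
         stop("unsupported mesh format: .", ext))
  invisible(path)
}

read_ply <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "ply")) stop("not a PLY file: ", path)
  end <- match("end_header", trimws(lines))
  if (is.na(end)) stop("PLY header not terminated")
  header <- lines[seq_len(end)]
  if (any(grepl("^format\\s+binary", header)))
    stop("binary PLY not supported")
  nv <- as.integer(sub(".*vertex\\s+", "", grep("^element vertex", header, value = TRUE)[1]))
  nf <- as.integer(sub(".*face\\s+", "", grep("^element face", header, value = TRUE)[1]))
  body <- lines[(end + 1):length(lines)]
  vl <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  V <- matrix(as.numeric(unlist(lapply(vl, `[`, 1:3))), ncol = 3, byrow = TRUE)
  fl <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  F <- t(vapply(fl, function(x) {
    if (as.integer(x[1]) != 3L) stop("non-triangular PLY face")
    as.integer(x[2:4]) + 1L
  }, integer(3)))
  surface_mesh(V, F)
}

write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(mesh$triangles)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(mesh$vertices, 1, paste, collapse = " "), con)
  writeLines(paste(3, mesh$triangles[, 1] - 1L, mesh$triangles[, 2] - 1L,
                   mesh$triangles[, 3] - 1L), con)
}

read_off <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (lines[1] != "OFF") stop("not an OFF file: ", path)
  counts <- as.integer(strsplit(lines[2], "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  vl <- strsplit(lines[2 + seq_len(nv)], "\\s+")
  V <- matrix(as.numeric(unlist(lapply(vl, `[`, 1:3))), ncol = 3, byrow = TRUE)
  fl <- strsplit(lines[2 + nv + seq_len(nf)], "\\s+")
  F <- t(vapply(fl, function(x) as.integer(x[2:4]) + 1L, integer(3)))
  surface_mesh(V, F)
}

write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("OFF", sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$triangles))), con)
  writeLines(apply(mesh$vertices, 1, paste, collapse = " "), con)
  writeLines(paste(3, mesh$triangles[, 1] - 1L, mesh$triangles[, 2] - 1L,
                   mesh$triangles[, 3] - 1L), con)
}

# ASCII STL carries no vertex sharing; vertices are re-welded exactly on read.
read_stl <- function(path) {
  lines <- trimws(readLines(path))
  vx <- grep("^vertex\\s", lines, value = TRUE)
  coords <- matrix(as.numeric(unlist(lapply(strsplit(vx, "\\s+"), `[`, 2:4))),
                   ncol = 3, byrow = TRUE)
  if (nrow(coords) %% 3 != 0) stop("malformed STL: vertex count not a multiple of 3")
  key <- apply(coords, 1, paste, collapse = ",")
  uk <- unique(key)
  V <- coords[match(uk, key), , drop = FALSE]
  F <- matrix(match(key, uk), ncol = 3, byrow = TRUE)
  surface_mesh(V, F)
}

write_stl <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid seegrs", con)
  V <- mesh$vertices
  F <- mesh$triangles
  N <- mesh$normals
  for (i in seq_len(nrow(F))) {
    writeLines(sprintf("facet normal %.9g %.9g %.9g", N[i, 1], N[i, 2], N[i, 3]), con)
    writeLines("  outer loop", con)
    for (k in 1:3)
      writeLines(sprintf("    vertex %.17g %.17g %.17g",
                         V[F[i, k], 1], V[F[i, k], 2], V[F[i, k], 3]), con)
    writeLines("  endloop", con)
    writeLines("endfacet", con)
  }
  writeLines("endsolid seegrs", con)
}
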
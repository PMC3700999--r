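# Minimal ASCII OFF / PLY mesh exchange. Only the plain triangle-mesh
# subset of either format is supported.

#' Write a mesh as ASCII OFF
#' @param mesh a `tri_mesh`.
#' @param path output file path.
#' @export
write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$faces)), con)
  writeLines(apply(mesh$vertices, 1, function(r)
    sprintf("%.10g %.10g %.10g", r[1], r[2], r[3])), con)
  writeLines(apply(mesh$faces - 1L, 1, function(r)
    sprintf("3 %d %d %d", r[1], r[2], r[3])), con)
  invisible(path)
}

#' Read an ASCII OFF mesh
#' @param path input file path.
#' @return A `tri_mesh`.
#' @export
read_off <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (lines[1] != "OFF") stop("not an OFF file")
  counts <- as.integer(strsplit(lines[2], "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  vtx <- matrix(as.numeric(unlist(strsplit(lines[3:(2 + nv)], "\\s+"))),
                nv, 3, byrow = TRUE)
  fl <- strsplit(lines[(3 + nv):(2 + nv + nf)], "\\s+")
  fc <- t(vapply(fl, function(x) as.integer(x[2:4]), integer(3))) + 1L
  tri_mesh(vtx, fc)
}

#' Write a mesh as ASCII PLY
#' @param mesh a `tri_mesh`.
#' @param path output file path.
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(apply(mesh$vertices, 1, function(r)
    sprintf("%.10g %.10g %.10g", r[1], r[2], r[3])), con)
  writeLines(apply(mesh$faces - 1L, 1, function(r)
    sprintf("3 %d %d %d", r[1], r[2], r[3])), con)
  invisible(path)
}

#' Read an ASCII PLY triangle mesh
#' @param path input file path.
#' @return A `tri_mesh`.
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (trimws(lines[1]) != "ply") stop("not a PLY file")
  hend <- which(trimws(lines) == "end_header")[1]
  header <- trimws(lines[1:hend])
  if (!any(grepl("^format ascii", header)))
    stop("only ASCII PLY is supported")
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", header, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", header, value = TRUE)))
  body <- trimws(lines[-(1:hend)])
  body <- body[nzchar(body)]
  vtx <- matrix(as.numeric(unlist(strsplit(body[1:nv], "\\s+"))),
                nv, 3, byrow = TRUE)
  fl <- strsplit(body[(nv + 1):(nv + nf)], "\\s+")
  fc <- t(vapply(fl, function(x) as.integer(x[2:4]), integer(3))) + 1L
  tri_mesh(vtx, fc)
}

#' Serialize a cortical surface (two PLY lobes + JSON metadata)
#' @param cortex a `cortical_surface`.
#' @param dir output directory (created if needed).
#' @export
write_cortex <- function(cortex, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ply(cortex$left, file.path(dir, "cortex_left.ply"))
  write_ply(cortex$right, file.path(dir, "cortex_right.ply"))
  meta <- cortex[c("level", "base_radius", "fold_amplitude", "wavenumber",
                   "seed", "hemisphere_offset", "brain_radius")]
  writeLines(to_json(meta), file.path(dir, "cortex_meta.json"))
  invisible(dir)
}

# tiny JSON emitter for flat named lists of scalars (avoids a hard
# dependency for serialization metadata)
to_json <- function(x) {
  item <- function(v) {
    if (is.character(v)) sprintf('"%s"', v) else sprintf("%.10g", v)
  }
  paste0("{", paste(sprintf('"%s": %s', names(x),
                            vapply(x, item, character(1))), collapse = ", "),
         "}")
}
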
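#' Read a Wavefront OBJ phantom
#'
#' Parses OBJ text into a [polygon_phantom()].  One region is created per
#' `g`/`o` group.  The region id is resolved through `group_to_region`, or,
#' failing that, parsed from a trailing `_<id>` in the group name (the same
#' convention [write_obj_phantom()] emits, mirrored in `usemtl m<id>`).
#' Faces with more than three vertices are fan-triangulated (vertex 1 with
#' each successive pair), preserving vertex order.
#'
#' @param path file path, connection, or a character vector of OBJ lines.
#' @param group_to_region optional named integer vector mapping group names
#'   to region ids.
#' @param sex,source metadata passed to [polygon_phantom()].
#' @return a [polygon_phantom()].
#' @export
read_obj_phantom <- function(path, group_to_region = NULL,
                             sex = "n/a", source = "obj") {
  lines <- if (is.character(path) && length(path) > 1) path else readLines(path)
  lines <- trimws(lines)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lines <- lines[keep]
  lineno <- which(keep)

  tok1 <- sub("[ \t].*$", "", lines)
  vidx <- tok1 == "v"
  verts <- matrix(0, sum(vidx), 3)
  if (any(vidx)) {
    vparts <- strsplit(sub("^v[ \t]+", "", lines[vidx]), "[ \t]+")
    verts <- do.call(rbind, lapply(vparts, function(p) as.numeric(p[1:3])))
  }
  n_total_v <- nrow(verts)

  groups <- list()
  cur_group <- NA_character_
  cur_faces <- list()
  vmap_start <- integer(0)  # not used: OBJ indexes the global vertex list
  flush <- function() {
    if (!is.na(cur_group) && length(cur_faces)) {
      groups[[length(groups) + 1L]] <<- list(name = cur_group,
                                             faces = cur_faces)
    }
  }
  for (i in seq_along(lines)) {
    t1 <- tok1[i]
    if (t1 == "g" || t1 == "o") {
      flush()
      cur_group <- sub("^[go][ \t]+", "", lines[i])
      cur_faces <- list()
    } else if (t1 == "f") {
      p <- strsplit(sub("^f[ \t]+", "", lines[i]), "[ \t]+")[[1]]
      idx <- as.integer(sub("/.*$", "", p))   # drop texture/normal refs
      if (anyNA(idx)) stop("unparseable face at line ", lineno[i])
      idx[idx < 0] <- n_total_v + 1L + idx[idx < 0]
      if (any(idx < 1L | idx > n_total_v)) {
        stop("face references missing vertex at line ", lineno[i])
      }
      if (length(idx) < 3L) stop("face with <3 vertices at line ", lineno[i])
      # fan triangulation for n-gons
      tris <- lapply(seq_len(length(idx) - 2L), function(k) {
        c(idx[1L], idx[k + 1L], idx[k + 2L])
      })
      if (is.na(cur_group)) cur_group <- "default_0"
      cur_faces <- c(cur_faces, tris)
    }
  }
  flush()
  if (!length(groups)) stop("OBJ contains no faces")

  resolve_id <- function(name) {
    if (!is.null(group_to_region) && name %in% names(group_to_region)) {
      return(as.integer(group_to_region[[name]]))
    }
    m <- regmatches(name, regexec("_([0-9]+)$", name))[[1]]
    if (length(m) == 2L) return(as.integer(m[2]))
    stop("cannot resolve region id for OBJ group '", name,
         "'; supply group_to_region or name groups '<name>_<id>'")
  }

  regions <- lapply(groups, function(g) {
    f <- do.call(rbind, g$faces)
    used <- sort(unique(as.vector(f)))
    remap <- match(f, used)
    dim(remap) <- dim(f)
    list(region_id = resolve_id(g$name),
         name = sub("_[0-9]+$", "", g$name),
         vertices = verts[used, , drop = FALSE],
         faces = remap)
  })
  polygon_phantom(regions, sex = sex, source = source)
}

#' Write a phantom as Wavefront OBJ
#'
#' Emits one `g`/`usemtl` pair per region; the region id is carried as the
#' group-name suffix `_<id>` and mirrored as `usemtl m<id>`, so the output is
#' re-readable by [read_obj_phantom()] with no mapping.  Vertex coordinates
#' are written with full double precision (17 significant digits) so a text
#' round-trip is bit-exact.
#'
#' @param phantom a [polygon_phantom()].
#' @param path file path or connection; if `NULL`, the lines are returned.
#' @return invisibly, the character vector of OBJ lines.
#' @export
write_obj_phantom <- function(phantom, path = NULL) {
  stopifnot(inherits(phantom, "polygon_phantom"))
  if (!length(phantom$regions)) stop("phantom has no regions to write")
  out <- c("# phantomdose OBJ export")
  offset <- 0L
  for (r in phantom$regions) {
    if (nrow(r$faces) == 0L) stop("region ", r$region_id, " has zero faces")
    out <- c(out,
             sprintf("g %s_%d", r$name, r$region_id),
             sprintf("usemtl m%d", r$region_id),
             sprintf("v %.17g %.17g %.17g",
                     r$vertices[, 1], r$vertices[, 2], r$vertices[, 3]),
             sprintf("f %d %d %d",
                     r$faces[, 1] + offset, r$faces[, 2] + offset,
                     r$faces[, 3] + offset))
    offset <- offset + nrow(r$vertices)
  }
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}
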
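#' Read a TetGen-dialect tetrahedral phantom
#'
#' The NODE file starts with a header line `<n_nodes> 3 0 0` followed by
#' `<index> <x> <y> <z>` records; the ELE file starts with
#' `<n_elements> 4 1` followed by `<index> <n1> <n2> <n3> <n4> <region_id>`
#' records.  Indices are 1-based on disk.  Degenerate (near-zero-volume)
#' elements are kept and flagged, not dropped.
#'
#' @param ele_path,node_path file paths or connections.
#' @return a [tet_phantom()].
#' @export
read_tet_phantom <- function(ele_path, node_path) {
  nl <- read_records(node_path)
  nh <- nl$header
  n_nodes <- nh[1]
  if (length(nl$records) != n_nodes) {
    stop("NODE header declares ", n_nodes, " nodes but file has ",
         length(nl$records), " records")
  }
  node_rec <- do.call(rbind, lapply(nl$records, as.numeric))
  node_index <- as.integer(node_rec[, 1])
  nodes <- node_rec[order(node_index), 2:4, drop = FALSE]
  base <- min(node_index)                      # tolerate 0-based exports
  if (!base %in% c(0L, 1L)) stop("NODE indices must start at 0 or 1")

  el <- read_records(ele_path)
  n_ele <- el$header[1]
  if (length(el$records) != n_ele) {
    stop("ELE header declares ", n_ele, " elements but file has ",
         length(el$records), " records")
  }
  ele_rec <- do.call(rbind, lapply(el$records, as.numeric))
  if (ncol(ele_rec) < 6L) {
    stop("ELE records need index, 4 node indices and a region attribute")
  }
  elements <- matrix(as.integer(ele_rec[, 2:5]), ncol = 4) - base + 1L
  if (any(elements < 1L) || any(elements > nrow(nodes))) {
    stop("ELE references node index out of range 1..", nrow(nodes))
  }
  region <- as.integer(ele_rec[, 6])
  ph <- tet_phantom(nodes, elements, region)
  if (length(attr(ph, "degenerate"))) {
    warning("tet phantom contains ", length(attr(ph, "degenerate")),
            " degenerate element(s): indices ",
            paste(head(attr(ph, "degenerate"), 10), collapse = ", "))
  }
  ph
}

read_records <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty ELE/NODE file")
  toks <- strsplit(lines, "[ \t]+")
  list(header = as.numeric(toks[[1]]), records = toks[-1])
}

#' Write a tetrahedral phantom in TetGen ELE/NODE dialect
#'
#' Inverse of [read_tet_phantom()]; 1-based indices on disk, region id as
#' the single element attribute.
#'
#' @param phantom a [tet_phantom()].
#' @param ele_path,node_path output file paths.
#' @return invisibly `NULL`.
#' @export
write_tet_phantom <- function(phantom, ele_path, node_path) {
  stopifnot(inherits(phantom, "tet_phantom"))
  n <- nrow(phantom$nodes)
  writeLines(c(sprintf("%d 3 0 0", n),
               sprintf("%d %.17g %.17g %.17g", seq_len(n),
                       phantom$nodes[, 1], phantom$nodes[, 2],
                       phantom$nodes[, 3])),
             node_path)
  m <- nrow(phantom$elements)
  writeLines(c(sprintf("%d 4 1", m),
               sprintf("%d %d %d %d %d %d", seq_len(m),
                       phantom$elements[, 1], phantom$elements[, 2],
                       phantom$elements[, 3], phantom$elements[, 4],
                       phantom$region_id)),
             ele_path)
  invisible(NULL)
}

#' Read an ASCII voxel phantom
#'
#' Whitespace-separated integer organ ids.  The default raster order is x
#' fastest, then y, then z (one z slice after another, each slice row-major
#' in y); this ordering is a documented package convention, switchable via
#' `order`.
#'
#' @param path file path or connection.
#' @param dims integer length-3 `(nx, ny, nz)`.
#' @param pitch voxel pitch, mm (see [voxel_phantom()]).
#' @param catalog optional [region_catalog()]; ids absent from it are kept
#'   but reported as a warning.
#' @param order permutation of `c("x","y","z")`, fastest first.
#' @return a [voxel_phantom()].
#' @export
read_voxel_phantom <- function(path, dims, pitch = c(0.98, 0.98, 1.0),
                               catalog = NULL, order = c("x", "y", "z")) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L)
  vals <- scan(path, what = integer(), quiet = TRUE, comment.char = "#")
  if (length(vals) != prod(dims)) {
    stop("voxel stream has ", length(vals), " values but dims imply ",
         prod(dims))
  }
  ord <- match(order, c("x", "y", "z"))
  if (length(ord) != 3L || anyNA(ord) || anyDuplicated(ord)) {
    stop("order must be a permutation of c('x','y','z')")
  }
  arr <- array(vals, dim = dims[ord])
  arr <- aperm(arr, order(ord))                # back to x,y,z axis order
  if (!is.null(catalog)) {
    extra <- setdiff(unique(vals), c(0L, catalog$region_id))
    if (length(extra)) {
      warning("voxel ids not in catalog (kept): ",
              paste(extra, collapse = ", "))
    }
  }
  voxel_phantom(arr, pitch = pitch)
}

#' Write an ASCII voxel phantom
#'
#' @param phantom a [voxel_phantom()].
#' @param path output path.
#' @param order raster order, as in [read_voxel_phantom()].
#' @return invisibly `NULL`.
#' @export
write_voxel_phantom <- function(phantom, path, order = c("x", "y", "z")) {
  ord <- match(order, c("x", "y", "z"))
  arr <- aperm(phantom$organ_ids, ord)
  vals <- as.vector(arr)
  # one y-row (or first-axis run) per line keeps files diffable
  n_per_line <- dim(arr)[1]
  lines <- vapply(split(vals, ceiling(seq_along(vals) / n_per_line)),
                  paste, character(1), collapse = " ")
  writeLines(lines, path)
  invisible(NULL)
}
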
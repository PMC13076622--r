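#' Read a single delineated tree point cloud
#'
#' Reads one tree's 3D points from an XYZ text file, a PLY file (ascii or
#' binary little-endian), or a LAS/LAZ file. Only the x, y, z coordinates are
#' consumed; units are metres with the z axis vertical. Trees are assumed to be
#' pre-delineated, so no coordinate reference system handling is performed.
#'
#' XYZ dialect: one point per line, three numeric fields separated by
#' whitespace or commas; lines starting with `#` are ignored.
#'
#' LAS/LAZ support is optional at runtime: it delegates to the `lidR` package
#' when installed and raises an informative error otherwise.
#'
#' @param path Path to the point-cloud file.
#' @param format One of `"auto"`, `"xyz"`, `"ply"`, `"las"`. `"auto"` picks by
#'   file extension (default `"xyz"` for unknown extensions).
#' @param tree_id Identifier for the tree; defaults to the file name without
#'   extension.
#' @param species Optional species label to attach.
#' @return A tibble with columns `x`, `y`, `z` (points in file order) and
#'   attributes `tree_id` and `species`.
#' @examples
#' f <- tempfile(fileext = ".xyz")
#' writeLines(c("0 0 0", "1 0 0", "0 0 2"), f)
#' read_tree(f)
#' @export
read_tree <- function(path, format = c("auto", "xyz", "ply", "las"),
                      tree_id = NULL, species = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "crowncluster_io_error")
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, ply = "ply", las = "las", laz = "las", "xyz")
  }
  pts <- switch(format,
    xyz = read_xyz_points(path),
    ply = read_ply_points(path),
    las = read_las_points(path)
  )
  if (nrow(pts) == 0L) {
    abort(paste0("no points in ", path), class = "crowncluster_empty_input")
  }
  new_tree(pts, tree_id = tree_id %||% tools::file_path_sans_ext(basename(path)),
           species = species)
}

new_tree <- function(points, tree_id, species = NA_character_) {
  points <- as_tibble(points[, c("x", "y", "z")])
  assert_points(points, paste0("tree '", tree_id, "'"))
  attr(points, "tree_id") <- as.character(tree_id)
  attr(points, "species") <- as.character(species)
  class(points) <- c("tree_pointcloud", class(points))
  points
}

tree_id_of <- function(tree) attr(tree, "tree_id") %||% NA_character_

read_xyz_points <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(tibble(x = double(), y = double(), z = double()))
  }
  fields <- strsplit(trimws(lines[idx]), "[,[:space:]]+")
  bad <- which(vapply(fields, length, 1L) < 3L)
  if (length(bad) > 0L) {
    abort(sprintf("malformed point on line %d of %s", idx[bad[1L]], path),
          class = "crowncluster_parse_error")
  }
  vals <- suppressWarnings(
    vapply(fields, function(f) as.numeric(f[1:3]), numeric(3))
  )
  nas <- which(colSums(is.na(vals)) > 0L)
  if (length(nas) > 0L) {
    abort(sprintf("non-numeric point on line %d of %s", idx[nas[1L]], path),
          class = "crowncluster_parse_error")
  }
  tibble(x = vals[1L, ], y = vals[2L, ], z = vals[3L, ])
}

#' Write a tree point cloud to an XYZ text file
#'
#' @param tree A tibble with columns `x`, `y`, `z`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(tree, path) {
  m <- assert_points(tree)
  writeLines(sprintf("%.8f %.8f %.8f", m[, 1L], m[, 2L], m[, 3L]), path)
  invisible(path)
}

read_ply_points <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply")) {
    abort(paste0(path, " is not a PLY file"), class = "crowncluster_parse_error")
  }
  fmt <- NULL
  elements <- list()
  cur <- NULL
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) {
      abort("unterminated PLY header", class = "crowncluster_parse_error")
    }
    tok <- strsplit(trimws(line), "\\s+")[[1L]]
    if (identical(tok[1L], "end_header")) break
    if (identical(tok[1L], "format")) {
      fmt <- tok[2L]
    } else if (identical(tok[1L], "element")) {
      cur <- tok[2L]
      elements[[cur]] <- list(n = as.integer(tok[3L]), props = character(),
                              types = character())
    } else if (identical(tok[1L], "property") && !is.null(cur)) {
      if (identical(tok[2L], "list")) {
        elements[[cur]]$props <- c(elements[[cur]]$props, tok[5L])
        elements[[cur]]$types <- c(elements[[cur]]$types, "list")
      } else {
        elements[[cur]]$props <- c(elements[[cur]]$props, tok[3L])
        elements[[cur]]$types <- c(elements[[cur]]$types, tok[2L])
      }
    }
  }
  if (!fmt %in% c("ascii", "binary_little_endian")) {
    abort(paste0("unsupported PLY format: ", fmt),
          class = "crowncluster_parse_error")
  }
  if (!"vertex" %in% names(elements) || names(elements)[1L] != "vertex") {
    abort("PLY vertex element missing or not first",
          class = "crowncluster_parse_error")
  }
  el <- elements$vertex
  need <- match(c("x", "y", "z"), el$props)
  if (anyNA(need)) {
    abort("PLY vertex element lacks x/y/z properties",
          class = "crowncluster_parse_error")
  }
  if (fmt == "ascii") {
    lines <- readLines(con, n = el$n)
    vals <- vapply(strsplit(trimws(lines), "\\s+"),
                   function(f) as.numeric(f[need]), numeric(3))
  } else {
    sizes <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
               short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
               int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
               float = 4L, float32 = 4L, double = 8L, float64 = 8L)
    if (any(el$types == "list")) {
      abort("PLY list properties on vertices are unsupported",
            class = "crowncluster_parse_error")
    }
    w <- unname(sizes[el$types])
    if (anyNA(w)) {
      abort("unknown PLY property type", class = "crowncluster_parse_error")
    }
    raw <- readBin(con, "raw", n = sum(w) * el$n)
    offs <- cumsum(c(0L, w))
    vals <- vapply(seq_len(el$n), function(i) {
      base <- (i - 1L) * sum(w)
      vapply(need, function(j) {
        bytes <- raw[(base + offs[j] + 1L):(base + offs[j] + w[j])]
        tp <- el$types[j]
        if (tp %in% c("float", "float32", "double", "float64")) {
          readBin(bytes, "double", size = w[j], endian = "little")
        } else {
          as.double(readBin(bytes, "integer", size = w[j], endian = "little"))
        }
      }, numeric(1))
    }, numeric(3))
  }
  tibble(x = vals[1L, ], y = vals[2L, ], z = vals[3L, ])
}

#' Write a tree point cloud to a PLY file
#'
#' @param tree A tibble with columns `x`, `y`, `z`.
#' @param path Output path.
#' @param binary Write `binary_little_endian` (default) or ascii.
#' @return `path`, invisibly.
#' @export
write_ply <- function(tree, path, binary = FALSE) {
  m <- assert_points(tree)
  header <- c(
    "ply",
    if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
    paste("element vertex", nrow(m)),
    "property double x", "property double y", "property double z",
    "end_header"
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con)
  if (binary) {
    writeBin(as.vector(t(m)), con, size = 8L, endian = "little")
  } else {
    writeLines(sprintf("%.10g %.10g %.10g", m[, 1L], m[, 2L], m[, 3L]), con)
  }
  invisible(path)
}

read_las_points <- function(path) {
  if (!requireNamespace("lidR", quietly = TRUE)) {
    abort(paste0("LAS/LAZ input requires the 'lidR' package; ",
                 "convert to xyz or ply, or install lidR"),
          class = "crowncluster_missing_backend")
  }
  las <- lidR::readLAS(path, select = "xyz")
  tibble(x = las@data$X, y = las@data$Y, z = las@data$Z)
}

#' Load a forest of delineated trees from a directory
#'
#' Reads every point-cloud file in `dir` (one file per tree) into a forest
#' table, optionally attaching species labels from a CSV with header
#' `tree_id,species`. Trees are sorted by `tree_id` so iteration order is a
#' pure function of the identifiers.
#'
#' @param dir Directory holding one point-cloud file per tree.
#' @param labels Optional path to a `tree_id,species` CSV. Labels for unknown
#'   tree ids produce a warning, not an error.
#' @param pattern Regular expression selecting files (default: xyz/ply/las).
#' @return A forest tibble with columns `tree_id`, `species`, and a `points`
#'   list-column of x/y/z tibbles.
#' @export
read_forest <- function(dir, labels = NULL,
                        pattern = "\\.(xyz|ply|las|laz)$") {
  files <- list.files(dir, pattern = pattern, full.names = TRUE,
                      ignore.case = TRUE)
  if (length(files) == 0L) {
    abort(paste0("no point-cloud files in ", dir),
          class = "crowncluster_io_error")
  }
  trees <- purrr::map(files, read_tree)
  ids <- vapply(trees, tree_id_of, character(1))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate tree_id: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
          class = "crowncluster_duplicate_id")
  }
  forest <- tibble(
    tree_id = ids,
    species = NA_character_,
    points = purrr::map(trees, function(t) tibble(x = t$x, y = t$y, z = t$z))
  ) %>% dplyr::arrange(.data$tree_id)
  if (!is.null(labels)) {
    lab <- readr::read_csv(labels, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
    if (!all(c("tree_id", "species") %in% names(lab))) {
      abort("labels CSV must have columns tree_id,species",
            class = "crowncluster_parse_error")
    }
    unknown <- setdiff(lab$tree_id, forest$tree_id)
    if (length(unknown) > 0L) {
      warn(paste0("labels for unknown tree_id ignored: ",
                  paste(unknown, collapse = ", ")))
    }
    forest$species <- lab$species[match(forest$tree_id, lab$tree_id)]
  }
  forest
}

#' Write a forest to one XYZ file per tree plus a labels CSV
#'
#' @param forest A forest tibble (`tree_id`, `species`, `points`).
#' @param dir Output directory, created if needed.
#' @param format `"xyz"` or `"ply"`.
#' @return `dir`, invisibly. Writes `labels.csv` when any species is known.
#' @export
write_forest <- function(forest, dir, format = c("xyz", "ply")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  purrr::pwalk(forest[, c("tree_id", "points")], function(tree_id, points) {
    path <- file.path(dir, paste0(tree_id, ".", format))
    if (format == "xyz") write_xyz(points, path) else write_ply(points, path)
  })
  if (any(!is.na(forest$species))) {
    readr::write_csv(forest[, c("tree_id", "species")],
                     file.path(dir, "labels.csv"), progress = FALSE)
  }
  invisible(dir)
}
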
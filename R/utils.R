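#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

# Deterministic child seeds: one master seed fans out to per-unit streams so
# trees can be generated independently yet reproducibly. Kept below 2^31 - 1.
derive_seed <- function(master, index) {
  master <- as.double(master)
  s <- (master * 48271 + index * 30269 + 11) %% 2147483629
  as.integer(s)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

assert_points <- function(points, context = "point cloud") {
  if (!all(c("x", "y", "z") %in% names(points))) {
    abort(paste0(context, " must have columns x, y, z"),
          class = "crowncluster_invalid_points")
  }
  m <- as.matrix(points[, c("x", "y", "z")])
  if (nrow(m) < 1L) {
    abort(paste0(context, " has zero points"), class = "crowncluster_empty_input")
  }
  if (!all(is.finite(m))) {
    abort(paste0(context, " contains non-finite coordinates"),
          class = "crowncluster_invalid_points")
  }
  invisible(m)
}

# Competition ("1224") ranks, ascending: ties share the smallest applicable
# rank and the next distinct value jumps.
competition_rank <- function(x) {
  rank(x, ties.method = "min")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
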
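#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic operations in the package route through this so that a
# single integer seed makes a whole run reproducible.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed and an index, staying inside the
# 32-bit signed range R requires of set.seed().
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + as.double(index) * 104729) %% 2147483647)
}

stopifnot_matrix <- function(x, what = "image") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("%s must be a numeric matrix, got %s", what, class(x)[1]), call. = FALSE)
  }
  invisible(x)
}

clip255 <- function(x) {
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}

#' Write a grayscale matrix as a plain-text PGM (P2) raster
#'
#' Lossless raster export used for visual debugging of generated frames and
#' extracted B-mode rectangles. The plain PGM format is readable by any image
#' viewer and by `read_pgm()`.
#'
#' @param image Numeric matrix of gray levels in \[0, 255\] (rows x columns).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(image, path) {
  stopifnot_matrix(image)
  vals <- round(clip255(image))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(image), nrow(image)), "255"), con)
  # one image row per line
  writeLines(apply(vals, 1, paste, collapse = " "), con)
  invisible(path)
}

#' Read a plain-text PGM (P2) raster written by [write_pgm()]
#'
#' @param path File path.
#' @return Numeric matrix of gray levels.
#' @export
read_pgm <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (lines[1] != "P2") stop("not a plain PGM (P2) file: ", path)
  dims <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  vals <- as.numeric(unlist(strsplit(trimws(lines[-(1:3)]), "\\s+")))
  matrix(vals, nrow = dims[2], ncol = dims[1], byrow = TRUE)
}

# Trapezoidal integral with unit spacing.
trapz_unit <- function(y) {
  n <- length(y)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) / 2)
}
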
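# Internal helpers shared across modules.

#' Evaluate an expression under a local random seed
#'
#' Runs `expr` with the RNG seeded at `seed` and restores the caller's
#' RNG state afterwards, so seeded generators do not perturb the global
#' random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible child seed from a parent seed and a stream label.
# Kept below 2^31 so the result is always a valid R integer seed.
childSeed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629)
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# clamp numeric values into [lo, hi]
clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

# Mean RGB -> grayscale for an H x W x 3 array (or pass-through for matrices)
toGray <- function(img) {
  if (is.matrix(img)) return(img)
  stopifnot(length(dim(img)) == 3L)
  (img[, , 1] + img[, , 2] + img[, , 3]) / 3
}

# Normalised cross-correlation of two images over a logical mask.
ncc <- function(a, b, mask = NULL) {
  av <- if (is.null(mask)) as.numeric(a) else as.numeric(a)[mask]
  bv <- if (is.null(mask)) as.numeric(b) else as.numeric(b)[mask]
  keep <- is.finite(av) & is.finite(bv)
  av <- av[keep]; bv <- bv[keep]
  if (length(av) < 2L) return(0)
  sa <- stats::sd(av); sb <- stats::sd(bv)
  if (sa == 0 || sb == 0) return(0)
  mean((av - mean(av)) * (bv - mean(bv))) / (sa * sb) * length(av) / (length(av) - 1L)
}

# Background (mounting medium) intensity estimated from the image border.
borderBackground <- function(gray) {
  stats::median(c(gray[1, ], gray[nrow(gray), ], gray[, 1], gray[, ncol(gray)]))
}

# Tissue mask: pixels that deviate from the border background level.
tissueMask <- function(gray, tol = 0.05) {
  abs(gray - borderBackground(gray)) > tol
}

writeTsv <- function(df, file) {
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

readTsv <- function(file, ...) {
  utils::read.delim(file, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE, ...)
}
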
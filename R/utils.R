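#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif rbeta qbinom pbinom median setNames aggregate sd
#' @importFrom graphics boxplot abline
#' @importFrom utils read.csv write.csv
NULL

CLASSES <- c("normal", "benign", "malignant")
WEIGHT_COLS <- c("w_normal", "w_benign", "w_malignant")
SOURCES <- c("original", "sda", "pixel_mixup", "manifold_flag",
             "dreamon", "dreamoff")
STRATEGIES <- c("vanilla", "sda", "pixel_mixup", "manifold_mixup",
                "dreamon", "dreamon_sda", "dreamoff")

`%||%` <- function(a, b) if (is.null(a)) b else a

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, then restores the
#' previous RNG state, so seeded internals never disturb a caller's stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

#' Derive a reproducible child seed from a master seed
#'
#' Hashes the master seed together with any number of stage labels or indices
#' into an integer in `[1, 2^31 - 2]`. Used to give every stage (and every
#' image within a stage) its own independent, reproducible RNG stream.
#'
#' @param master integer master seed.
#' @param ... stage names and indices (coerced to character).
#' @return integer seed.
#' @export
#' @examples
#' derive_seed(1, "noise", "gaussian", 3, 17)
derive_seed <- function(master, ...) {
  parts <- paste(c(as.character(as.integer(master)),
                   vapply(list(...), as.character, "")), collapse = "\r")
  h <- 0
  m <- 2147483563
  for (cp in utf8ToInt(parts)) h <- (h * 69069 + cp) %% m
  as.integer(h %% (m - 2L) + 1L)
}

#' Largest-remainder apportionment of counts
#'
#' Distributes `n` units over categories proportionally to `proportions`,
#' giving each category `floor(n * p)` and assigning the remaining units in
#' order of decreasing fractional remainder (ties broken by category order).
#' This is the rounding rule under which 780 images at proportions
#' (0.17, 0.56, 0.27) yield class counts (133, 437, 210).
#'
#' @param n total count.
#' @param proportions non-negative weights, summing to 1.
#' @return integer vector of counts summing to `n`.
#' @export
#' @examples
#' largest_remainder(780, c(0.17, 0.56, 0.27))
largest_remainder <- function(n, proportions) {
  stopifnot(n >= 0, all(proportions >= 0),
            abs(sum(proportions) - 1) < 1e-9)
  quota <- n * proportions
  counts <- floor(quota)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- quota - counts
    ord <- order(-frac, seq_along(frac))
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  as.integer(counts)
}

is_simplex <- function(w, tol = 1e-6) {
  all(w >= -tol) && abs(sum(w) - 1) <= tol
}

check_class_weights <- function(w, tol = 1e-6) {
  if (length(w) != 3 || !is_simplex(w, tol))
    stop("class weights must be 3 non-negative values summing to 1",
         call. = FALSE)
  invisible(w)
}

#' Flatten an image matrix to a feature row (column-major)
#' @noRd
flat <- function(img) as.numeric(img)

unflat <- function(v, size) matrix(v, size, size)
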
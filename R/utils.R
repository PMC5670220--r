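#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

## complement of plus-strand bases; vectorized over character vectors of
## single bases or longer strings
.complement <- function(x) chartr("ACGT", "TGCA", x)

.revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(.complement(s), "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

.is_base <- function(x) x %in% DNA_BASES

## Run code with a temporary RNG state seeded at `seed`, restoring the
## caller's stream afterwards. seed = NULL leaves the RNG untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Cosine similarity between two non-negative vectors
#'
#' The score used to match de novo signatures against a reference catalog:
#' `sum(a*b) / (||a|| * ||b||)`, in `[0, 1]` for non-negative input.
#'
#' @param a,b Numeric vectors of equal length; neither may be all zero.
#' @return A single numeric similarity.
#' @examples
#' cosine_similarity(c(1, 0), c(1, 0))
#' cosine_similarity(c(1, 0), c(0, 1))
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    stop("cosine similarity is undefined for a zero vector")
  }
  sum(a * b) / (na * nb)
}
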
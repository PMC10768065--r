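#' @useDynLib weedseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pnorm dnorm rnorm runif var
NULL

#' Construct a feature map
#'
#' Feature maps are the currency of every block in the network: dense
#' rank-4 arrays laid out as `H x W x C x B` (rows, columns, channels,
#' batch), the natural column-major layout for R. A 2-d or 3-d array is
#' promoted by adding singleton channel/batch dimensions.
#'
#' @param x numeric array with 2, 3 or 4 dimensions.
#' @return a 4-d numeric array (`H x W x C x B`) with all entries finite.
#' @examples
#' fm <- feature_map(array(rnorm(3 * 16 * 16), c(16, 16, 3)))
#' dim(fm)
#' @export
feature_map <- function(x) {
  if (is.null(dim(x))) stop("feature_map: `x` must be an array")
  d <- dim(x)
  if (length(d) == 2) d <- c(d, 1L, 1L)
  if (length(d) == 3) d <- c(d, 1L)
  if (length(d) != 4) stop("feature_map: `x` must have 2-4 dimensions")
  if (any(d < 1)) stop("feature_map: all dimensions must be >= 1")
  x <- as.double(x)
  if (!all(is.finite(x))) stop("feature_map: all entries must be finite")
  dim(x) <- d
  x
}

check_fmap <- function(x, what = "x") {
  if (is.null(dim(x)) || length(dim(x)) != 4)
    stop(sprintf("`%s` must be a 4-d H x W x C x B feature map", what))
  invisible(x)
}

# number of pixels N = H * W
fm_pixels <- function(x) prod(dim(x)[1:2])

gelu <- function(x) x * pnorm(x)
gelu_grad <- function(x) pnorm(x) + x * dnorm(x)
# variant reusing the cached standard-normal CDF from the forward pass
gelu_grad_phi <- function(x, phi) phi + x * dnorm(x)
sigmoid <- function(x) 1 / (1 + exp(-x))

# Row-wise numerically stable softmax of a matrix.
softmax_rows <- function(m) {
  mx <- m[, 1]
  nc <- ncol(m)
  if (nc > 1) for (j in 2:nc) mx <- pmax(mx, m[, j])
  m <- exp(m - mx)
  m / rowSums(m)
}

# uniform fan-in initialisation (the ecosystem default for conv layers):
# U(-1/sqrt(fan_in), 1/sqrt(fan_in))
init_uniform <- function(n, fan_in) {
  b <- 1 / sqrt(fan_in)
  runif(n, -b, b)
}

# Run `expr` under a fixed seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
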
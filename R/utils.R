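#' @keywords internal
#' @useDynLib taxaformer, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

#' @importFrom stats cor ks.test kmeans rnorm runif rbinom rlnorm quantile sd
#'   median setNames predict binomial glm plogis qnorm
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `expr` under a temporary RNG state seeded with `seed`,
## restoring the caller's stream afterwards. All stochastic operations in the
## package funnel through this so that a single integer seed pins them down.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

## Derive a child seed from a base seed and a stream label; keeps independent
## randomness sources reproducible from one user-facing seed. Result < 2^31.
derive_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483587) + 1L
}

round_half_up <- function(x) floor(x + 0.5)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' MD5 fingerprint of an R object
#'
#' Serializes the object and returns the MD5 of the byte stream. Used to
#' assert that frozen parameters are bit-identical before and after training
#' and to bind model checkpoints to the vocabulary they were trained with.
#'
#' @param x any serializable R object
#' @return a length-1 character MD5 string
#' @export
object_digest <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  con <- file(f, "wb")
  serialize(x, con, version = 2, xdr = TRUE)
  close(con)
  unname(tools::md5sum(f))
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 1 && x == floor(x)

## sample k elements from a vector, immune to R's scalar-x sample() surprise
sample_vec <- function(x, k, replace = FALSE) {
  x[sample.int(length(x), k, replace = replace)]
}
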
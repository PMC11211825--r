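#' @importFrom stats rnorm runif rbinom cor sd quantile
#' @importFrom methods new validObject is slot show
#' @importFrom utils head read.table write.table read.csv write.csv
NULL

# Run code under a fixed RNG seed without disturbing the caller's stream.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# FNV-1a style string hash folded to a positive 31-bit integer. Used to derive
# per-atom / per-residue sub-seeds so identical local environments map to
# identical embedding rows. Collision quality is irrelevant; determinism is.
fnvHash <- function(x) {
  # modulus ~2^29 keeps h * 16777619 exactly representable in a double
  vapply(x, function(s) {
    h <- 216613
    for (code in utf8ToInt(s)) {
      h <- bitwXor(as.integer(h), code)
      h <- (h * 16777619) %% 536870909
    }
    h
  }, numeric(1), USE.NAMES = FALSE)
}

relu <- function(x) pmax(x, 0)

leakyRelu <- function(x, slope = 0.2) pmax(x, 0) + slope * pmin(x, 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

# Glorot-uniform weight init.
glorot <- function(fanIn, fanOut) {
  lim <- sqrt(6 / (fanIn + fanOut))
  matrix(runif(fanIn * fanOut, -lim, lim), fanIn, fanOut)
}

stopifnotScalarCount <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1)
    stop(sprintf("'%s' must be a single count >= 1", name), call. = FALSE)
}
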
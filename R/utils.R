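#' @useDynLib noveltank, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif median pf pt ptukey t.test lm anova
#' @importFrom utils read.csv write.csv head tail
NULL

#' FNV-1a hash of a character string
#'
#' Small stable digest used to stamp output files with the configuration they
#' were produced under, so reruns are verifiably identical.
#'
#' @param x a character scalar.
#' @return an 8-hex-digit character scalar.
#' @export
#' @examples
#' fnv1a_hash("max_jump_px=5000")
fnv1a_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- as.integer(charToRaw(x))
  h <- 2166136261
  for (b in bytes) {
    # XOR acts on the low byte only; keep h as a double below 2^32
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit multiply by the FNV prime 16777619, in 16-bit halves to stay
    # exactly representable in doubles
    lo <- h %% 2^16
    hi <- h %/% 2^16
    h <- (lo * 16777619 + ((hi * 16777619) %% 2^16) * 2^16) %% 2^32
  }
  sprintf("%04x%04x", h %/% 2^16, h %% 2^16)
}

# Serialize a named list of scalar settings into a canonical string and hash it.
config_hash <- function(cfg) {
  flat <- unlist(cfg)
  flat <- flat[order(names(flat))]
  fnv1a_hash(paste(names(flat), as.character(flat), sep = "=", collapse = ";"))
}

nt_version <- function() as.character(utils::packageVersion("noveltank"))

# Run code with a deterministic RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  code
}
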
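#' @keywords internal
"_PACKAGE"

#' @importFrom stats aov kruskal.test median p.adjust pchisq pt predict
#'   qlogis plogis rnorm runif sd setNames wilcox.test rbinom var
#'   model.matrix
#' @importFrom utils head
NULL

# logit/inverse-logit on the natural scale (the generator's combination scale)
.logit <- function(p) qlogis(p)
.invlogit <- function(x) plogis(x)

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Deterministic 31-bit hash of a character key (polynomial rolling hash mod
# a Mersenne prime), for deriving per-gene / per-sample seeds from a master
# seed independent of position. Multiplier and modulus keep every
# intermediate below 2^53 so the arithmetic is exact in doubles.
str_seed <- function(...) {
  key <- paste(..., sep = "\r")
  bytes <- utf8ToInt(key)
  h <- 17
  for (b in bytes) {
    h <- (h * 1159241 + b) %% 2147483647
  }
  as.integer(h)
}

# row variances without extra dependencies
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
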
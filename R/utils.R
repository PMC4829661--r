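#' @keywords internal
"_PACKAGE"

#' @useDynLib repliconsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rlnorm runif rnorm sd cor setNames
#' @importFrom utils read.table write.table read.csv write.csv head tail
NULL

# Chromatin class levels used throughout the package.  EU = euchromatin,
# FAC = facultative heterochromatin, CON = constitutive heterochromatin.
CHROMATIN_CLASSES <- c("EU", "FAC", "CON")

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so that seeded helpers do not perturb the session.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

chromatin_class_factor <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), CHROMATIN_CLASSES)
  if (length(bad) > 0) {
    stop("unknown chromatin class value(s): ", paste(bad, collapse = ", "))
  }
  factor(x, levels = CHROMATIN_CLASSES)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
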
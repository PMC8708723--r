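## Internal helpers shared across modules.

## Evaluate `expr` under a temporary RNG state seeded with `seed`,
## restoring the caller's stream afterwards. Used so generators are
## deterministic without clobbering user randomness.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
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
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

geomean <- function(x) exp(mean(log(x)))

## Population (n-denominator) standard deviation.
sdPop <- function(x) sqrt(mean((x - mean(x))^2))

stopifnot_scalar <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(what, " must be a single finite number", call. = FALSE)
  }
  invisible(x)
}

## cCRE class labels, in precedence order; "unclassified" always last.
ccreClassLevels <- function() {
  c("PLS", "pELS", "dELS", "DNase-H3K4me3", "DNase-only", "unclassified")
}

## Classes counting as promoter- or enhancer-like for network inference.
regulatoryClassLevels <- function() c("PLS", "pELS", "dELS")
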
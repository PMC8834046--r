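# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs \code{code} with the global random-number stream seeded at
#' \code{seed}, then restores the previous stream so callers' randomness is
#' unaffected. With \code{seed = NULL} the code runs on the current stream.
#'
#' @param seed Integer seed or \code{NULL}.
#' @param code Expression to evaluate.
#' @return The value of \code{code}.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Numeric sort key for chromosome labels: 1..22 first, then X, Y, MT,
# anything else after, stable within group.
chrom_sort_key <- function(chrom) {
  stripped <- sub("^chr", "", chrom, ignore.case = TRUE)
  num <- suppressWarnings(as.numeric(stripped))
  special <- match(toupper(stripped), c("X", "Y", "MT", "M"))
  key <- ifelse(!is.na(num), num,
    ifelse(!is.na(special), 100 + special,
      200 + as.integer(factor(stripped))
    )
  )
  key
}

stop_ginscore <- function(...) {
  stop(paste0(...), call. = FALSE)
}
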
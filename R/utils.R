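`%||%` <- function(a, b) if (is.null(a)) b else a

#' Numerically stable softmax
#'
#' Maps K unconstrained reals to a point on the K-simplex.  Used to
#' parameterise diet proportions inside the mixing model.
#'
#' @param f numeric vector.
#' @return numeric vector of the same length, positive, summing to 1.
#' @export
softmax <- function(f) {
  stopifnot(is.numeric(f), length(f) >= 1, all(is.finite(f)))
  e <- exp(f - max(f))
  e / sum(e)
}

# Deterministic substream seed for (unit i, chain j) under a master seed.
# Kept well below 2^31 so set.seed() never overflows.
derive_seed <- function(master, i, j = 0L) {
  as.integer((as.numeric(master) %% 100003) * 10007 +
               (i %% 1000) * 131 + (j %% 100) + 1) %% 2147483587L
}

stop_input <- function(...) stop(..., call. = FALSE)

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop_input(sprintf("%s is missing required column(s): %s",
                       what, paste(missing, collapse = ", ")))
  invisible(df)
}
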
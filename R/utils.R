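#' @keywords internal
"_PACKAGE"

# Scoped RNG: run `expr` under `seed` and restore the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive independent per-module random seeds from one global seed
#'
#' One global seed fans out to named streams (`phantoms`, `noise`, `training`,
#' `misc`) so each module can be re-seeded independently while a whole run
#' stays reproducible from a single integer.
#'
#' @param global_seed single integer.
#' @return named integer vector of derived seeds, all in `[1, 2^31 - 2]`.
#' @export
seed_streams <- function(global_seed) {
  streams <- c("phantoms", "noise", "training", "misc")
  with_seed(global_seed, {
    s <- sample.int(.Machine$integer.max - 1L, length(streams))
    names(s) <- streams
    s
  })
}

# Argument checks -------------------------------------------------------------

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  invisible(x)
}

assert_matrix <- function(x, name, dims = NULL) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("`%s` must be a numeric matrix", name), call. = FALSE)
  if (!is.null(dims) && !all(dim(x) == dims))
    stop(sprintf("`%s` must be %d x %d (got %d x %d)", name,
                 dims[1], dims[2], nrow(x), ncol(x)), call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
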
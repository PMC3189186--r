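# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards. seed = NULL means "use the current
# stream" (no isolation).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

.log_levels <- c(DEBUG = 10L, INFO = 20L, WARN = 30L, ERROR = 40L)

#' Set the logging threshold
#'
#' Messages below `level` are suppressed. Logging always goes to standard
#' error so that TSV/JSON written to standard output stays clean.
#'
#' @param level one of `"DEBUG"`, `"INFO"`, `"WARN"`, `"ERROR"`.
#' @return the previous level, invisibly.
#' @export
set_log_level <- function(level = c("INFO", "DEBUG", "WARN", "ERROR")) {
  level <- match.arg(level)
  old <- getOption("pishift.log_level", "INFO")
  options(pishift.log_level = level)
  invisible(old)
}

pishift_log <- function(level, ...) {
  threshold <- .log_levels[[getOption("pishift.log_level", "INFO")]]
  if (.log_levels[[level]] >= threshold) {
    message(sprintf("[%s] %s", level, paste0(...)))
  }
  invisible(NULL)
}

# All n! permutations of seq_len(n) as rows of a matrix; only ever called for
# small n (exhaustive permutation p-values).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    out[[k]] <- cbind(k, matrix(rest[sub], nrow = nrow(sub)))
  }
  do.call(rbind, out)
}
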
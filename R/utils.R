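#' @keywords internal
"_PACKAGE"

#' @importFrom stats quantile rnbinom rlnorm runif rgamma prcomp
#'   p.adjust lm coef sd median setNames
#' @importFrom utils write.table read.table head
#' @importFrom methods as is
NULL

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library functions never clobber user streams.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a per-stage seed from a global one; keeps results < 2^31 and gives
# independent streams for pipeline stages run standalone or composed.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offsets <- c(generate = 11L, state = 23L, preprocess = 37L, cluster = 53L,
               match = 67L, signatures = 79L, correct = 97L, benchmark = 113L)
  off <- if (stage %in% names(offsets)) offsets[[stage]] else
    sum(utf8ToInt(stage)) %% 1000L
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483647)
}

# Largest-remainder quota allocation: integer counts summing to n with
# proportions p; deterministic, ties broken by earlier index.
quota_allocate <- function(n, p) {
  stopifnot(abs(sum(p) - 1) < 1e-9, all(p >= 0))
  base <- floor(n * p)
  rem <- n * p - base
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(-rem, seq_along(p))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1L
  }
  as.integer(base)
}

# Percentile with linear interpolation between closest ranks (R type 7).
percentile_interp <- function(x, p) {
  stopifnot(p > 0, p <= 100)
  unname(quantile(x, probs = p / 100, type = 7, names = FALSE))
}

stop_validation <- function(...) {
  stop(structure(class = c("popmatch_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_integrity <- function(...) {
  stop(structure(class = c("popmatch_integrity_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Coerce numeric input to a column-compressed sparse matrix without relying
# on coercion methods from base "matrix" being attached.
as_csparse <- function(v) {
  if (!methods::is(v, "Matrix")) v <- Matrix::Matrix(as.matrix(v), sparse = TRUE)
  methods::as(methods::as(v, "generalMatrix"), "CsparseMatrix")
}
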
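# Internal helpers shared across modules.

.default_stages <- c("MII", "L1C", "L2C")
.known_assays <- c("IP", "input", "rna", "ribo", "protein")

#' @keywords internal
#' @noRd
abort_schema <- function(msg) {
  rlang::abort(msg, class = "mztm6a_schema_error")
}

#' @keywords internal
#' @noRd
abort_value <- function(msg) {
  rlang::abort(msg, class = "mztm6a_value_error")
}

#' @keywords internal
#' @noRd
abort_io <- function(msg) {
  rlang::abort(msg, class = "mztm6a_io_error")
}

# Geometric mean of strictly positive values.
#' @noRd
geomean <- function(x) exp(mean(log(x)))

# Deterministic sub-seed for a named component, so one global seed expands to
# independent substreams; kept below 2^31 - 1.
#' @keywords internal
#' @noRd
substream_seed <- function(seed, component) {
  offsets <- c(truth = 1L, counts = 2L, kd = 3L, detection = 4L, ct = 5L,
               resample = 6L)
  if (!component %in% names(offsets)) {
    abort_value(sprintf("unknown seed substream '%s'", component))
  }
  m <- 2147483647
  as.integer((as.double(seed %% m) * 48271 + offsets[[component]] * 10007) %% m)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' @keywords internal
#' @noRd
row_vars <- function(m) {
  n <- ncol(m)
  if (n < 2) return(rep(NA_real_, nrow(m)))
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}
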
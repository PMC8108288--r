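# Internal helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single value in [0, 1]", name), call. = FALSE)
}

# Geometric mean of positive values.
geo_mean <- function(x) exp(mean(log(x)))

assert_panel <- function(panel) {
  need <- c("donor_id", "condition_id", "analyte", "concentration_pg_ml")
  if (!is.data.frame(panel) || !all(need %in% names(panel)))
    stop("panel must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (any(panel$concentration_pg_ml < 0, na.rm = TRUE))
    stop("panel concentrations must be non-negative", call. = FALSE)
  key <- paste(panel$donor_id, panel$condition_id, panel$analyte)
  if (anyDuplicated(key))
    stop("each (donor, condition, analyte) may appear at most once in a panel",
         call. = FALSE)
  invisible(panel)
}
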
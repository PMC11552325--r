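# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero to the nearest integer
#'
#' Pixel rasterization uses round-half-up (0.5 -> 1, 1.5 -> 2) rather than
#' base R's round-half-to-even, so spot-to-pixel assignment has a single
#' documented convention.
#'
#' @param x numeric vector.
#' @return integer vector.
#' @keywords internal
round_half_up <- function(x) {
  as.integer(floor(x + 0.5))
}

# Deduplicate names: first occurrence unchanged, later occurrences get a
# "_k" suffix with k the occurrence index (second copy of "A" becomes "A_2").
dedup_suffix <- function(x) {
  counts <- table(x)
  dups <- names(counts)[counts > 1L]
  if (length(dups) == 0L) return(x)
  out <- x
  for (nm in dups) {
    idx <- which(x == nm)
    out[idx[-1L]] <- paste0(nm, "_", seq_along(idx)[-1L])
  }
  out
}

# Fixed 10-colour palette for mask overlays; cycles by mask_id.
stroi_palette <- function() {
  rbind(
    c(228L,  26L,  28L),
    c( 55L, 126L, 184L),
    c( 77L, 175L,  74L),
    c(152L,  78L, 163L),
    c(255L, 127L,   0L),
    c(255L, 255L,  51L),
    c(166L,  86L,  40L),
    c(247L, 129L, 191L),
    c(  0L, 206L, 209L),
    c(153L, 153L, 153L)
  )
}

# Run an expression with a locally-seeded RNG, restoring the caller's RNG
# state afterwards so package functions do not perturb user randomness.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
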
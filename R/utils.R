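# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed below 2^31 from a parent seed and an index.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729 + 13) %% 2147483629)
}

# Mean over non-overlapping f x f blocks; nrow and ncol must be multiples of f.
block_mean <- function(m, f) {
  if (f == 1L) return(m)
  H <- nrow(m)
  W <- ncol(m)
  stopifnot(H %% f == 0L, W %% f == 0L)
  m1 <- matrix(colMeans(matrix(m, nrow = f)), nrow = H %/% f, ncol = W)
  t(matrix(colMeans(matrix(t(m1), nrow = f)), nrow = W %/% f, ncol = H %/% f))
}

# Rec. 601 luma of an H x W x 3 array of 8-bit counts.
luminance <- function(arr) {
  0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
}

# Summed-area table with a zero border row/column, so that
# window_sum(I, y0, x0, h, w) = sum(m[y0 + 1:h, x0 + 1:w]) for 0-based offsets.
integral_image <- function(m) {
  integral_image_cpp(m)
}

window_sum <- function(I, y0, x0, h, w) {
  I[y0 + h + 1, x0 + w + 1] - I[y0 + 1, x0 + w + 1] -
    I[y0 + h + 1, x0 + 1] + I[y0 + 1, x0 + 1]
}

# Half-up rounding (5 rounds away from zero), the convention used for the
# printed three-decimal performance tables.
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Metric display: three decimals, with exact unity printed as "1.0".
format_metric <- function(x, digits = 3) {
  out <- ifelse(is.na(x), "NA",
    ifelse(x == 1, "1.0", sprintf(paste0("%.", digits, "f"), round_half_up(x, digits)))
  )
  out
}
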
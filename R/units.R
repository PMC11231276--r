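# Internal unit conventions: the 0D (Windkessel) layer and all user-facing
# reports use clinical units (mmHg, ml, s, mm); the flow solver works in SI
# (Pa, m, s).  Conversions happen only at these boundaries.

MMHG_PA <- 133.322   # Pa per mmHg
ML_M3   <- 1e-6      # m^3 per ml
MM_M    <- 1e-3      # m per mm

mmHg_to_Pa <- function(x) x * MMHG_PA
Pa_to_mmHg <- function(x) x / MMHG_PA

# resistance mmHg.s/ml -> Pa.s/m^3 ; compliance ml/mmHg -> m^3/Pa
res_to_si  <- function(R) R * MMHG_PA / ML_M3
cap_to_si  <- function(C) C * ML_M3 / MMHG_PA

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

# Moving-average smoother with shrinking windows at the ends (keeps endpoints
# and exactly preserves straight lines / constants).
smooth_ma <- function(x, k = 5L) {
  n <- length(x)
  if (k <= 1L || n < 3L) return(x)
  h <- (k - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    w <- min(i - lo, hi - i)      # symmetric shrink so lines stay lines
    mean(x[(i - w):(i + w)])
  }, numeric(1))
}

# Truncation toward zero used by the published error tables: 26.9% prints as
# 26, 3.45% as 3.4.  A tiny guard absorbs float noise like 2.2999999999.
trunc_guard <- function(x, digits = 0L) {
  s <- 10^digits
  trunc(x * s + sign(x) * 1e-9) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
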
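# internal helpers shared across modules

# Run expr with a local RNG state seeded by `seed`; NULL seed uses the
# current stream. Restores the caller's RNG state afterwards so generators
# are reproducible bit-for-bit without side effects.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# biexponential magnitude envelope at times t (ms)
biexpEnvelope <- function(t, mFast, mSlow, t2sFast, t2sSlow) {
  mFast * exp(-t / t2sFast) + mSlow * exp(-t / t2sSlow)
}

# signal-weighted biexponential decay factor D(TE) of the concentration
# correction: Ms exp(-TE/T2s*) + Mf exp(-TE/T2f*)
decayFactor <- function(mSlow, mFast, t2sSlow, t2sFast, te) {
  mSlow * exp(-te / t2sSlow) + mFast * exp(-te / t2sFast)
}

# one draw from a normal truncated to [lower, upper] by rejection;
# degenerate sd = 0 returns the (clamped) mean
rtruncnorm1 <- function(mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(min(max(mean, lower), upper))
  for (i in 1:10000) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lower && x <= upper) return(x)
  }
  stop("truncated normal rejection failed; bounds too far from the mean")
}

# complex circular Gaussian noise, sd per real/imaginary channel
complexNoise <- function(n, sd) {
  complex(real = stats::rnorm(n, 0, sd), imaginary = stats::rnorm(n, 0, sd))
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
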
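# Internal helpers shared across modules.

# Moore-Penrose pseudoinverse via SVD; tolerance relative to largest
# singular value, as in standard numerical practice.
pinv <- function(A, tol = .Machine$double.eps * max(dim(A))) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) {
    return(matrix(0, ncol(A), nrow(A)))
  }
  s$v[, keep, drop = FALSE] %*%
    ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

# Adler-style position-weighted checksum over a raw vector; used to
# fingerprint models so a lead field matrix refuses to load against a
# different conductor. Vectorised (no per-byte loop), collision-resistant
# enough for accidental-mismatch detection.
content_hash <- function(raw) {
  stopifnot(is.raw(raw))
  x <- as.double(raw) + 1
  n <- length(x)
  i <- seq_len(n)
  h1 <- sum(x) %% 2147483629
  h2 <- sum(x * (i %% 65521)) %% 2147483587
  h3 <- sum(x * ((i * 31 + 7) %% 32749)) %% 2147483563
  sprintf("%08x%08x%08x", as.integer(h1 %% 2^31), as.integer(h2 %% 2^31),
          as.integer(h3 %% 2^31))
}

model_hash <- function(model) {
  payload <- list(
    labels = as.integer(model$labels),
    dim = dim(model$labels),
    pitch_mm = model$pitch_mm,
    origin_mm = model$origin_mm,
    sigma = model$tissues$sigma_S_per_m,
    lab = model$tissues$label
  )
  content_hash(serialize(payload, NULL, version = 2))
}

# Uniform sample of unit vectors on the sphere.
runif_sphere <- function(n) {
  v <- matrix(rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

vec3 <- function(x, what = "value") {
  x <- as.numeric(x)
  if (length(x) != 3 || anyNA(x)) {
    abort(sprintf("`%s` must be a finite numeric 3-vector", what))
  }
  x
}
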
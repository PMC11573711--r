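# Internal numeric helpers shared across modules.

# logit/expit with clipping so VCF-like data containing exact 0/1 stay finite
.CLIP_EPS <- 1e-6

.clip01 <- function(x, eps = .CLIP_EPS) pmin(pmax(x, eps), 1 - eps)

.logit <- function(p, eps = .CLIP_EPS) {
  p <- .clip01(p, eps)
  log(p / (1 - p))
}

.expit <- function(x) stats::plogis(x)

# row products of a small-column matrix without apply() overhead
.rowProds <- function(m) {
  out <- m[, 1L]
  nc <- ncol(m)
  if (nc > 1L) for (j in 2:nc) out <- out * m[, j]
  out
}

# FNV-1a hash of a character scalar; used to stamp outputs with a config id
.fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
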
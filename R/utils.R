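#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# canonical chromosome ordering: 1..22, X, Y
chrom_order <- function(chrom) {
  chrom <- sub("^chr", "", as.character(chrom))
  num <- suppressWarnings(as.integer(chrom))
  num[chrom == "X"] <- 23L
  num[chrom == "Y"] <- 24L
  num
}

is_autosome <- function(chrom) {
  !is.na(suppressWarnings(as.integer(sub("^chr", "", as.character(chrom)))))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# deterministic seed stream: derive per-task seeds from one master seed
derive_seed <- function(seed, offset) {
  (as.integer(seed) * 7919L + as.integer(offset) * 104729L) %% 2147483562L
}
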
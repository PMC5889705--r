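# Internal helpers shared across modules.

# Derive a per-stage seed from a root seed. Keeps results < 2^31 so the
# value is a valid R integer seed.
stage_seed <- function(seed, stage) {
  offsets <- c(dem = 1L, covariates = 2L, cover = 3L, spectra = 4L,
               sample = 5L, train = 6L, assess = 7L, associate = 8L,
               misc = 9L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  as.integer((as.numeric(seed) * 127 + offsets[[stage]] * 9973) %%
               (.Machine$integer.max - 1))
}

inv_logit <- function(x) stats::plogis(x)

# Pad a matrix by replicating its border cells (one ring per `n`).
pad_replicate <- function(m, n = 1L) {
  for (k in seq_len(n)) {
    m <- rbind(m[1L, , drop = FALSE], m, m[nrow(m), , drop = FALSE])
    m <- cbind(m[, 1L, drop = FALSE], m, m[, ncol(m), drop = FALSE])
  }
  m
}

# Block means of a matrix, blocks of size f x f; partial blocks at the
# south/east edges are averaged over the cells they contain.
block_means <- function(m, f) {
  nr <- nrow(m); nc <- ncol(m)
  br <- ceiling(nr / f); bc <- ceiling(nc / f)
  ri <- rep(seq_len(br), each = f, length.out = nr)
  ci <- rep(seq_len(bc), each = f, length.out = nc)
  # mean over each (ri, ci) block, NA-aware
  sums <- rowsum(m, ri, na.rm = TRUE)
  cnts <- rowsum((!is.na(m)) * 1, ri)
  sums <- t(rowsum(t(sums), ci, na.rm = TRUE))
  cnts <- t(rowsum(t(cnts), ci))
  out <- sums / cnts
  out[cnts == 0] <- NA_real_
  dimnames(out) <- NULL
  out
}

# Expand a block matrix back to full resolution (nearest / replication).
expand_blocks <- function(bm, f, nr, nc) {
  ri <- rep(seq_len(nrow(bm)), each = f, length.out = nr)
  ci <- rep(seq_len(ncol(bm)), each = f, length.out = nc)
  bm[ri, ci, drop = FALSE]
}

check_grid <- function(x, arg = deparse(substitute(x))) {
  if (!inherits(x, "grid")) stop("`", arg, "` must be a grid object",
                                 call. = FALSE)
  invisible(x)
}
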
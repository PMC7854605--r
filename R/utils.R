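# Internal numeric helpers shared across modules.

#' Clip values to an interval
#' @noRd
clip01 <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

#' Evaluate an expression under a temporary RNG seed, restoring global state.
#' @noRd
withSeed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Box-filter mean with border shrink (kernel clipped at the matrix edge).
#'
#' Shifted-sum implementation: for the small kernels used here (3x3 by
#' default) summing kr x kc shifted copies beats a summed-area table.
#'
#' @param m numeric matrix
#' @param kr,kc odd kernel extents along rows / columns
#' @return list(mean = matrix of window means, count = matrix of window sizes)
#' @noRd
boxMean2d <- function(m, kr, kc) {
  nr <- nrow(m); nc <- ncol(m)
  hr <- (kr - 1L) %/% 2L; hc <- (kc - 1L) %/% 2L
  if (hr == 0L && hc == 0L)
    return(list(mean = m, count = matrix(1L, nr, nc)))
  acc <- matrix(0, nr, nc)
  for (dr in -hr:hr) {
    rs <- max(1L, 1L + dr):min(nr, nr + dr)   # source rows shifted by dr
    rt <- max(1L, 1L - dr):min(nr, nr - dr)
    for (dc in -hc:hc) {
      cs <- max(1L, 1L + dc):min(nc, nc + dc)
      ct <- max(1L, 1L - dc):min(nc, nc - dc)
      acc[rt, ct] <- acc[rt, ct] + m[rs, cs]
    }
  }
  r1 <- pmax(seq_len(nr) - hr, 1L); r2 <- pmin(seq_len(nr) + hr, nr)
  c1 <- pmax(seq_len(nc) - hc, 1L); c2 <- pmin(seq_len(nc) + hc, nc)
  cnt <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  list(mean = acc / cnt, count = cnt)
}

# Stable content hash for provenance metadata (no external digest dependency):
# md5 of the ASCII serialization written to a scratch file.
contentHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, ascii = TRUE, version = 2)
  close(con)
  unname(tools::md5sum(f))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

checkSameDim <- function(...) {
  args <- list(...)
  d <- lapply(args, dim)
  ref <- d[[1]]
  ok <- vapply(d, function(x) identical(as.integer(x), as.integer(ref)), logical(1))
  if (!all(ok))
    stopf("volumes are not co-registered: dimension mismatch (%s)",
          paste(vapply(d, function(x) paste(x, collapse = "x"), character(1)),
                collapse = " vs "))
  invisible(ref)
}
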
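#' Derive a stage-specific seed from a global seed
#'
#' Stages of the pipeline draw their own seeds deterministically from one
#' global seed plus a stage label, so any stage can be re-run standalone and
#' reproduce its output bit-identically.
#'
#' @param seed integer global seed.
#' @param label character stage label.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- as.double(seed %% 2147483647)
  for (code in utf8ToInt(label)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h) + 1L
}

#' Total-variation distance between two discrete distributions
#' @param p,q numeric probability vectors of equal length.
#' @return `0.5 * sum(|p - q|)`.
#' @export
tv_distance <- function(p, q) {
  stopifnot(length(p) == length(q))
  0.5 * sum(abs(p - q))
}

#' Match estimated topics to reference topics
#'
#' LDA is identified only up to topic relabelling. This matches rows of an
#' estimated term-topic matrix to rows of a reference matrix by minimising the
#' mean total-variation distance over permutations (exhaustive for K <= 8,
#' greedy otherwise).
#'
#' @param phi_hat,phi_ref matrices with one row per topic, rows summing to 1.
#' @return list with `perm` (index into `phi_ref` rows for each `phi_hat` row),
#'   `tv` (per matched pair) and `mean_tv`.
#' @export
match_topics <- function(phi_hat, phi_ref) {
  stopifnot(ncol(phi_hat) == ncol(phi_ref))
  K <- nrow(phi_hat)
  stopifnot(nrow(phi_ref) == K)
  d <- matrix(0, K, K)
  for (i in seq_len(K)) {
    for (j in seq_len(K)) d[i, j] <- tv_distance(phi_hat[i, ], phi_ref[j, ])
  }
  if (K <= 8L) {
    perms <- permutations_all(K)
    costs <- vapply(perms, function(p) sum(d[cbind(seq_len(K), p)]), numeric(1))
    perm <- perms[[which.min(costs)]]
  } else {
    perm <- integer(K)
    free <- rep(TRUE, K)
    for (i in order(apply(d, 1L, min))) {
      j <- which(free)[which.min(d[i, free])]
      perm[i] <- j
      free[j] <- FALSE
    }
  }
  tv <- d[cbind(seq_len(K), perm)]
  list(perm = perm, tv = tv, mean_tv = mean(tv))
}

permutations_all <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- permutations_all(n - 1L)
  out <- vector("list", n * length(sub))
  idx <- 1L
  for (p in sub) {
    for (pos in 0:(n - 1L)) {
      out[[idx]] <- append(p, n, after = pos)
      idx <- idx + 1L
    }
  }
  out
}

softmax_rows <- function(a) {
  m <- apply(a, 1L, max)
  e <- exp(a - m)
  e / rowSums(e)
}

# Dirichlet draws, one row per observation
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  x / rowSums(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
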
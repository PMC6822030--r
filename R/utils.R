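# Internal numerical and error helpers.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log-sum-exp down the columns of a matrix
col_logsumexp <- function(V) {
  m <- apply(V, 2, max)
  out <- m + log(colSums(exp(sweep(V, 2, m, "-"))))
  out[!is.finite(m)] <- m[!is.finite(m)]
  out
}

# central-difference Hessian; h scaled per coordinate
num_hessian <- function(f, x, h = NULL) {
  k <- length(x)
  if (is.null(h)) h <- 1e-4 * (abs(x) + 1)
  H <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) {
    for (j in i:k) {
      ei <- ej <- numeric(k)
      ei[i] <- h[i]; ej[j] <- h[j]
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "scrdens_error")))
}

abort_validation <- function(msg, subclass = NULL) {
  abort(msg, class = c(subclass, "scrdens_validation_error"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
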
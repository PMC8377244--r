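# Independent brute-force oracles used to cross-check the implementations.

# Score every window of a sequence under a PWM by explicit looping, both
# strands, no shared code with the scanner.
bf_scan <- function(seq, pwm, threshold_frac = 0.8, pc = 1e-3, bg = 0.25) {
  lo <- log2((pwm$prob + pc) / (bg + pc))
  L <- ncol(lo)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  score_at <- function(chars) {
    s <- 0
    for (l in seq_len(L)) {
      b <- match(chars[l], c("A", "C", "G", "T"))
      if (is.na(b)) return(NA_real_)
      s <- s + lo[b, l]
    }
    s
  }
  chars <- strsplit(seq, "")[[1]]
  thr <- threshold_frac * sum(apply(lo, 2, max))
  out <- list()
  for (i in seq_len(max(length(chars) - L + 1, 0))) {
    win <- chars[i:(i + L - 1)]
    s_f <- score_at(win)
    if (!is.na(s_f) && s_f >= thr) {
      out[[length(out) + 1]] <- data.frame(start = i - 1L, end = i - 1L + L,
                                           strand = "+", score = s_f)
    }
    s_r <- score_at(rev(unname(comp[win])))
    if (!is.na(s_r) && s_r >= thr) {
      out[[length(out) + 1]] <- data.frame(start = i - 1L, end = i - 1L + L,
                                           strand = "-", score = s_r)
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(), strand = character(),
                      score = numeric()))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$strand), , drop = FALSE]
}

# Exhaustive two-constant-segment least-squares split search.
bf_changepoint <- function(series, timepoints) {
  n <- length(series)
  best <- NULL; best_sse <- Inf
  for (j in 1:(n - 1)) {
    a <- series[1:j]; b <- series[(j + 1):n]
    sse <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (sse < best_sse - 1e-15) { best_sse <- sse; best <- j }
  }
  list(split = best, onset = timepoints[best + 1], sse = best_sse)
}

# Hypergeometric upper tail by direct mass summation.
bf_hyper_upper <- function(k, K, N, n) {
  sum(stats::dhyper(k:min(K, n), K, N - K, n))
}

# Hand Benjamini-Hochberg.
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# A sharply peaked PWM from a consensus string.
make_pwm <- function(consensus, id = "TEST", p_hi = 0.85) {
  chars <- strsplit(consensus, "")[[1]]
  prob <- matrix((1 - p_hi) / 3, 4, length(chars),
                 dimnames = list(c("A", "C", "G", "T"), NULL))
  prob[cbind(match(chars, c("A", "C", "G", "T")), seq_along(chars))] <- p_hi
  list(id = id, name = id, prob = prob, consensus = consensus)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
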
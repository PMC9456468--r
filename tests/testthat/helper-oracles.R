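# Independent brute-force oracles. These deliberately re-derive results
# with explicit loops and naive algorithms so they share no code path with
# the package implementation.

# Welch t-test + hand-rolled Benjamini-Hochberg + fold gate, per gene
oracle_de_transcripts <- function(high, low, fold_threshold = 2,
                                  alpha = 0.05) {
  genes <- rownames(high)
  p <- diff <- rep(NA_real_, length(genes))
  for (i in seq_along(genes)) {
    x <- high[genes[i], ]
    y <- low[genes[i], ]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < 2 || length(y) < 2) next
    diff[i] <- mean(x) - mean(y)
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      p[i] <- if (diff[i] == 0) 1 else 0
    } else {
      p[i] <- stats::t.test(x, y, var.equal = FALSE)$p.value
    }
  }
  ok <- !is.na(p)
  # BH by hand
  pv <- p[ok]
  n <- length(pv)
  o <- order(pv)
  adj <- rep(NA_real_, n)
  prev <- 1
  for (k in n:1) {
    prev <- min(prev, pv[o[k]] * n / k)
    adj[o[k]] <- prev
  }
  keep <- ok
  keep[ok] <- abs(diff[ok]) >= log2(fold_threshold) & adj <= alpha
  data.frame(entity = genes[keep], log2fc = diff[keep],
             direction = ifelse(diff[keep] > 0, "up", "down"),
             stringsAsFactors = FALSE)
}

# per-position log-odds score with explicit loops
oracle_score <- function(pwm, sequence, position, strand = "+") {
  bases <- strsplit(sequence, "")[[1]]
  L <- ncol(pwm$mat)
  win <- bases[position:(position + L - 1)]
  if (strand == "-") {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    win <- rev(unname(comp[win]))
  }
  s <- 0
  for (j in seq_len(L)) {
    b <- win[j]
    if (b %in% c("A", "C", "G", "T")) {
      bi <- match(b, c("A", "C", "G", "T"))
      s <- s + log2(pwm$mat[bi, j] / pwm$background[bi])
    }
  }
  unname(s)
}

# exhaustive enumeration of all 4^L sequences: exact score distributions
# and the minSUM cutoff
oracle_calibrate <- function(pwm) {
  L <- ncol(pwm$mat)
  stopifnot(L <= 6)
  combos <- expand.grid(rep(list(1:4), L))
  scores <- pm <- pb <- numeric(nrow(combos))
  for (r in seq_len(nrow(combos))) {
    s <- 0; qm <- 1; qb <- 1
    for (j in seq_len(L)) {
      b <- combos[r, j]
      s <- s + log2(pwm$mat[b, j] / pwm$background[b])
      qm <- qm * pwm$mat[b, j]
      qb <- qb * pwm$background[b]
    }
    scores[r] <- s; pm[r] <- qm; pb[r] <- qb
  }
  cuts <- sort(unique(scores))
  best_obj <- Inf; best_cut <- NA
  for (cut in cuts) {
    fn <- sum(pm[scores < cut - 1e-12])
    fp <- sum(pb[scores >= cut - 1e-12])
    obj <- fn + fp
    if (obj <= best_obj + 1e-12) {   # ties toward the higher cutoff
      best_obj <- min(best_obj, obj)
      best_cut <- cut
    }
  }
  list(cutoff = best_cut, objective = best_obj)
}

# breadth-first shortest distances with explicit queue
oracle_bfs <- function(edges, start, radius) {
  adj <- split(edges$to, edges$from)
  dist <- c(stats::setNames(0, start))
  queue <- start
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    if (dist[v] >= radius) next
    for (w in adj[[v]]) {
      if (!w %in% names(dist)) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  dist[names(dist) != start]
}

# small helpers used across test files ---------------------------------

random_pwm <- function(L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  counts <- matrix(stats::rexp(4 * L) * 20, 4, L)
  new_pwm(counts, id = sprintf("R%04.0f", stats::runif(1) * 9999))
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

consensus_of <- function(pwm) {
  paste(c("A", "C", "G", "T")[apply(pwm$mat, 2, which.max)], collapse = "")
}
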
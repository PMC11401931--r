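# Exhaustive hard-margin separator search in 2-D: every maximum-margin
# hyperplane is supported either by one point per class (midpoint rule) or
# by an edge of one class and a point of the other. Independent of libsvm.
brute_force_max_margin <- function(X, y) {
  classes <- sort(unique(y))
  A <- X[y == classes[1L], , drop = FALSE]
  B <- X[y == classes[2L], , drop = FALSE]
  best <- NULL
  cand <- list()
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      w <- A[i, ] - B[j, ]
      b <- -sum(w * (A[i, ] + B[j, ]) / 2)
      cand[[length(cand) + 1L]] <- list(w = w, b = b)
    }
  }
  edge_cands <- function(P, Q) {
    out <- list()
    if (nrow(P) < 2L) return(out)
    for (i in seq_len(nrow(P) - 1L)) {
      for (j in (i + 1L):nrow(P)) {
        e <- P[j, ] - P[i, ]
        for (q in seq_len(nrow(Q))) {
          w <- c(-e[2L], e[1L])  # normal to the edge
          d_edge <- sum(w * P[i, ])
          d_q <- sum(w * Q[q, ])
          if (abs(d_q - d_edge) < 1e-12) next
          s <- sign(d_edge - d_q)
          out[[length(out) + 1L]] <-
            list(w = w * s, b = -(d_edge + d_q) * s / 2)
        }
      }
    }
    out
  }
  cand <- c(cand, edge_cands(A, B), edge_cands(B, A))
  for (cn in cand) {
    sa <- as.vector(A %*% cn$w) + cn$b
    sb <- as.vector(B %*% cn$w) + cn$b
    if (all(sa > 0) && all(sb < 0)) {
      margin <- min(c(sa, -sb)) / sqrt(sum(cn$w^2))
      if (is.null(best) || margin > best$margin) {
        best <- list(w = cn$w, b = cn$b, margin = margin)
      }
    }
  }
  best
}
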
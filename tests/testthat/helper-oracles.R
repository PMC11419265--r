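# Independent oracles used to cross-check package computations.

# Definition-based dip oracle: minimum over unimodal CDFs U of the sup-norm
# distance to the empirical CDF, by LP feasibility (boot::simplex) over the
# values of U at the data points for each candidate mode position, with a
# binary search on the band half-width d.  A unimodal CDF is convex up to
# its mode and concave after it, and may jump only at the mode, so for
# fixed mode x_t and half-width d the existence of U is linear feasibility
# in v_j = U(x_j) plus the pre-jump value w = U(x_t^-).  Entirely
# independent of the package's modal-interval algorithm.
dip_oracle <- function(x, tol = 1e-8) {
  x <- sort(x)
  n <- length(x)
  x <- (x - x[1]) / (x[n] - x[1])  # dip is affine invariant; stabilizes LP
  feasible1 <- function(t, d) {
    nv <- n + 1L
    W <- nv
    lo <- pmax(0, (1:n) / n - d)
    hi <- pmin(1, (0:(n - 1)) / n + d)
    hi[t] <- min(1, t / n + d)
    lo[W] <- max(0, (t - 1) / n - d)
    hi[W] <- min(1, (t - 1) / n + d)
    if (any(lo > hi + 1e-12)) return(FALSE)
    A <- NULL
    add <- function(idx, coef) {
      r <- numeric(nv)
      for (k in seq_along(idx)) r[idx[k]] <- r[idx[k]] + coef[k]
      A <<- rbind(A, r)
    }
    for (j in seq_len(n - 1)) {           # monotone, w spliced at the mode
      if (j == t - 1) { add(c(j, W), c(1, -1)); add(c(W, t), c(1, -1)) }
      else add(c(j, j + 1), c(1, -1))
    }
    if (t == 1) add(c(W, 1), c(1, -1))
    ci <- c(seq_len(t - 1), W); cx <- x[seq_len(t)]   # convex side
    if (length(ci) >= 3) for (k in seq_len(length(ci) - 2)) {
      s1 <- 1 / (cx[k + 1] - cx[k]); s2 <- 1 / (cx[k + 2] - cx[k + 1])
      add(c(ci[k + 1], ci[k], ci[k + 1], ci[k + 2]), c(s1, -s1, s2, -s2))
    }
    di <- c(t, seq(t + 1, length.out = n - t)); dx <- x[seq(t, n)]  # concave
    if (length(di) >= 3) for (k in seq_len(length(di) - 2)) {
      s1 <- 1 / (dx[k + 1] - dx[k]); s2 <- 1 / (dx[k + 2] - dx[k + 1])
      add(c(di[k], di[k + 1], di[k + 2], di[k + 1]), c(s1, -s1, s2, -s2))
    }
    for (j in 1:nv) add(j, 1)             # upper box bounds as rows
    b <- c(rep(0, nrow(A) - nv), hi)
    keep <- lo > 0                        # x >= 0 implicit in simplex()
    A2 <- diag(nv)[keep, , drop = FALSE]; b2 <- lo[keep]
    if (nrow(A2) == 0L) { A2 <- NULL; b2 <- NULL }
    sc <- pmax(apply(abs(A), 1, max), 1e-12)
    s <- tryCatch(boot::simplex(a = rep(0, nv), A1 = A / sc, b1 = b / sc,
                                A2 = A2, b2 = b2, maxi = FALSE),
                  error = function(e) e)
    if (inherits(s, "error")) return(NA)  # degenerate pivot: caller nudges d
    s$solved >= 0
  }
  feasible <- function(t, d0) {
    for (eps in c(0, 1e-9, -1e-9, 5e-9)) {
      f <- feasible1(t, d0 + eps)
      if (!is.na(f)) return(f)
    }
    stop("LP oracle: persistent degeneracy")
  }
  best <- 0.25 + tol
  for (t in 1:n) {
    if (!feasible(t, best)) next
    lo. <- 0; hi. <- best
    while (hi. - lo. > tol) {
      mid <- (lo. + hi.) / 2
      if (feasible(t, mid)) hi. <- mid else lo. <- mid
    }
    best <- min(best, hi.)
  }
  best
}

# Hypergeometric upper tail P(X > k) for overlap of a size-nC subset of a
# size-nG universe with a marked set of size nZ.
hyper_tail <- function(k, nC, nZ, nG) {
  stats::phyper(k, nZ, nG - nZ, nC, lower.tail = FALSE)
}

# All-pairs interval overlap scan (0-based half-open).
overlap_bruteforce <- function(genes, svs) {
  hits <- setNames(vector("list", nrow(genes)), genes$gene_id)
  for (i in seq_len(nrow(genes))) {
    out <- character(0)
    for (j in seq_len(nrow(svs))) {
      if (genes$chrom[i] == svs$chrom[j] &&
          genes$start[i] < svs$end[j] && svs$start[j] < genes$end[i])
        out <- c(out, svs$name[j])
    }
    hits[[genes$gene_id[i]]] <- out
  }
  hits
}

# Per-subject brute-force concordance.
concordance_bruteforce <- function(calls) {
  ok <- 0L
  for (s in seq_len(ncol(calls))) {
    col <- calls[, s]
    if (all(col) || all(!col)) ok <- ok + 1L
  }
  ok / ncol(calls)
}
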
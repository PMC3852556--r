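# Independent brute-force oracles. Everything here is deliberately naive
# (explicit loops, no shared helpers with the package) so that agreement
# with the package is evidence, not tautology.

random_dna <- function(L, p_ambiguous = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  alphabet <- c("A", "C", "G", "T")
  s <- sample(alphabet, L, replace = TRUE)
  if (p_ambiguous > 0) {
    amb <- which(runif(L) < p_ambiguous)
    s[amb] <- sample(c("N", "R", "Y"), length(amb), replace = TRUE)
  }
  paste(s, collapse = "")
}

# lexicographic k-mers, built independently of the package
oracle_kmers <- function(k) {
  g <- do.call(expand.grid,
               rep(list(c("A", "C", "G", "T")), k))[, k:1, drop = FALSE]
  sort(apply(g, 1, paste, collapse = ""), method = "radix")
}

# sliding-window k-mer counter; windows with non-ACGT skipped
oracle_kmer_counts <- function(seq, k, phase = NULL) {
  counts <- setNames(integer(4^k), oracle_kmers(k))
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  if (L < k) return(counts)
  for (i in 1:(L - k + 1)) {
    if (!is.null(phase) && (i - 1) %% 3 != phase) next
    w <- ch[i:(i + k - 1)]
    if (all(w %in% c("A", "C", "G", "T"))) {
      km <- paste(w, collapse = "")
      counts[km] <- counts[km] + 1L
    }
  }
  counts
}

oracle_kmer_freq <- function(seq, k) {
  cts <- oracle_kmer_counts(seq, k)
  cts / sum(cts)
}

# direct, loop-based evaluation of the Z-curve catalogue in the documented
# order: scopes (all, p0, p1, p2) x k = 1..3 x prefixes x (x, y, z)
oracle_zcurve <- function(seq) {
  out <- numeric(0)
  for (scope in list(NULL, 0, 1, 2)) {
    for (k in 1:3) {
      cts <- oracle_kmer_counts(seq, k, phase = scope)
      prefixes <- if (k == 1) "" else oracle_kmers(k - 1)
      for (pre in prefixes) {
        f <- setNames(numeric(4), c("A", "C", "G", "T"))
        for (b in names(f)) f[b] <- cts[paste0(pre, b)]
        tot <- sum(f)
        if (tot > 0) f <- f / tot
        out <- c(out,
                 (f["A"] + f["G"]) - (f["C"] + f["T"]),
                 (f["A"] + f["C"]) - (f["G"] + f["T"]),
                 (f["A"] + f["T"]) - (f["G"] + f["C"]))
      }
    }
  }
  unname(out)
}

oracle_gc <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  sum(ch %in% c("G", "C")) / sum(ch %in% c("A", "C", "G", "T"))
}

oracle_gc3s <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch) %/% 3
  thirds <- ch[3 * seq_len(n)]
  thirds <- thirds[thirds %in% c("A", "C", "G", "T")]
  out <- setNames(numeric(4), c("A", "C", "G", "T"))
  for (b in thirds) out[b] <- out[b] + 1
  out / sum(out)
}

oracle_rho <- function(seq) {
  f1 <- oracle_kmer_freq(seq, 1)
  f2 <- oracle_kmer_freq(seq, 2)
  out <- setNames(numeric(16), oracle_kmers(2))
  for (dn in names(out)) {
    e <- f1[substr(dn, 1, 1)] * f1[substr(dn, 2, 2)]
    out[dn] <- if (e > 0) f2[dn] / e else 0
  }
  out
}

oracle_dinuc_profile <- function(seq, table) {
  ch <- strsplit(seq, "")[[1]]
  acc <- numeric(ncol(table))
  nwin <- 0
  for (i in 1:(length(ch) - 1)) {
    w <- ch[i:(i + 1)]
    if (all(w %in% c("A", "C", "G", "T"))) {
      acc <- acc + table[paste(w, collapse = ""), ]
      nwin <- nwin + 1
    }
  }
  unname(acc / nwin)
}

# textbook PLS1 (NIPALS with y-deflation); standardization via base scale()
oracle_pls1 <- function(X, y, A) {
  Xs <- scale(X)
  f <- y - mean(y)
  E <- Xs
  p <- ncol(X)
  W <- P <- matrix(0, p, A)
  q <- numeric(A)
  for (a in 1:A) {
    w <- drop(t(E) %*% f)
    w <- w / sqrt(sum(w^2))
    t_a <- drop(E %*% w)
    P[, a] <- drop(t(E) %*% t_a) / sum(t_a^2)
    q[a] <- sum(f * t_a) / sum(t_a^2)
    E <- E - t_a %*% t(P[, a])
    f <- f - t_a * q[a]
    W[, a] <- w
  }
  list(coefficients = drop(W %*% solve(t(P) %*% W) %*% q),
       intercept = mean(y))
}

# the penalized rank-one objective of the sparse-direction step
sparse_objective <- function(u, m, lambda1, omega) {
  sum((m - u)^2) + 2 * lambda1 * sum(omega * abs(u))
}

# two-class labelled toy data with y = sign of a sparse linear score
random_two_class <- function(n, p, seed) {
  set.seed(seed)
  repeat {
    X <- matrix(rnorm(n * p), n, p)
    y <- ifelse(X[, 1] + 0.5 * X[, 2] + rnorm(n, 0, 0.5) >= 0, 1, -1)
    if (length(unique(y)) == 2) return(list(X = X, y = y))
  }
}
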
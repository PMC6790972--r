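# Independent brute-force oracles, written as plain base-R loops so they
# share no code path with the package implementations.

# reciprocal-best-hit AAI by exhaustive enumeration
oracle_aai <- function(a_to_b, b_to_a, coverage = 0.70) {
  best <- function(h) {
    out <- list()
    for (q in unique(h$query)) {
      rows <- h[h$query == q & h$align_length >= coverage * h$query_length, ,
                drop = FALSE]
      if (!nrow(rows)) next
      rows <- rows[order(-rows$bitscore, -rows$identity, rows$subject), ,
                   drop = FALSE]
      out[[q]] <- rows[1, ]
    }
    out
  }
  fwd <- best(as.data.frame(a_to_b))
  rev <- best(as.data.frame(b_to_a))
  num <- 0; den <- 0; n <- 0
  for (q in names(fwd)) {
    s <- fwd[[q]]$subject
    if (!is.null(rev[[s]]) && rev[[s]]$subject == q) {
      num <- num + fwd[[q]]$identity * fwd[[q]]$query_length
      den <- den + fwd[[q]]$query_length
      n <- n + 1
    }
  }
  if (n == 0) return(list(aai = NA_real_, n = 0))
  list(aai = num / den, n = n)
}

# exclusive family sharing by per-family set comparison
oracle_exclusive <- function(m, focal) {
  hits <- character()
  for (f in rownames(m)) {
    present <- colnames(m)[m[f, ] >= 1]
    if (setequal(intersect(present, focal), focal) &&
        length(setdiff(present, focal)) == 0) {
      hits <- c(hits, f)
    }
  }
  hits
}

# per-protein NSAF by an explicit loop
oracle_nsaf <- function(spc, len) {
  saf <- numeric(length(spc))
  for (i in seq_along(spc)) saf[i] <- spc[i] / len[i]
  saf / sum(saf)
}

# OLS slope/intercept via the normal equations
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}

# closed-form pool-dilution forward state at time t (days)
oracle_forward <- function(p, cons, c0, ape0, t) {
  ct <- c0 + (p - cons) * t
  ape <- if (abs(p - cons) < 1e-12) {
    ape0 * exp(-p * t / c0)
  } else {
    ape0 * (ct / c0)^(-p / (p - cons))
  }
  list(c = ct, ape = ape)
}

# random directed hit tables with an embedded true pairing
random_hit_tables <- function(n_genes, seed) {
  set.seed(seed)
  lens <- sample(100:900, n_genes, replace = TRUE)
  ids_a <- sprintf("a%02d", seq_len(n_genes))
  ids_b <- sprintf("b%02d", seq_len(n_genes))
  perm <- sample(n_genes)
  mk <- function(q, s, qlen, slen) {
    true_cov <- stats::runif(n_genes, 0.5, 1)   # some pairs fail coverage
    true <- tibble::tibble(
      query = q, subject = s[perm],
      identity = stats::runif(n_genes, 40, 95),
      align_length = pmax(1L, as.integer(true_cov * qlen)),
      bitscore = stats::runif(n_genes, 200, 500),
      query_length = qlen, subject_length = slen[perm])
    n_noise <- n_genes
    qi <- sample(n_genes, n_noise, replace = TRUE)
    si <- sample(n_genes, n_noise, replace = TRUE)
    noise <- tibble::tibble(
      query = q[qi], subject = s[si],
      identity = stats::runif(n_noise, 20, 95),
      align_length = pmax(1L, as.integer(stats::runif(n_noise, 0.3, 1) * qlen[qi])),
      bitscore = stats::runif(n_noise, 10, 450),
      query_length = qlen[qi], subject_length = slen[si])
    rbind(true, noise)
  }
  lens_b <- sample(100:900, n_genes, replace = TRUE)
  list(ab = mk(ids_a, ids_b, lens, lens_b),
       ba = mk(ids_b, ids_a, lens_b, lens))
}

# random families-by-genomes count matrix
random_presence_matrix <- function(n_fam, genomes, seed) {
  set.seed(seed)
  m <- matrix(stats::rpois(n_fam * length(genomes), 0.6),
              nrow = n_fam,
              dimnames = list(sprintf("fam%03d", seq_len(n_fam)), genomes))
  m
}
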
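# Fixture builders and independent oracles used across the suite. Oracles
# are deliberately naive, straight-line re-statements of the definitions,
# kept free of any code path they are checking.

make_design <- function(reps = 3, genotypes = genotype_levels(),
                        spatios = spatio_levels()) {
  dd <- expand.grid(replicate = seq_len(reps), spatio = spatios,
                    genotype = genotypes, stringsAsFactors = FALSE)[, c(3, 2, 1)]
  dd$library_id <- sprintf("%s_%s_r%d", dd$genotype, dd$spatio, dd$replicate)
  sample_design(dd, genotypes = genotypes, spatios = spatios)
}

# Expression matrix with chosen per-cell means plus iid normal noise.
make_expr <- function(design, cell_fun, n_genes = 1, noise_sd = 0,
                      gene_ids = sprintf("Yg%03d", seq_len(n_genes))) {
  Y <- t(vapply(seq_len(n_genes), function(g) {
    mu <- mapply(cell_fun, as.character(design$genotype),
                 as.character(design$spatio), MoreArgs = list(gene = g))
    mu + stats::rnorm(nrow(design), 0, noise_sd)
  }, numeric(nrow(design))))
  dimnames(Y) <- list(gene_ids, design$library_id)
  Y
}

# --- TMM: literal step-by-step restatement of the trim-and-weight recipe ---
oracle_tmm <- function(x, trim_M = 0.30, trim_A = 0.05) {
  x <- as.matrix(x) + 0
  N <- colSums(x)
  f75 <- sapply(seq_len(ncol(x)), function(j) quantile(x[, j], 0.75) / N[j])
  ref <- which.min(abs(f75 - mean(f75)))
  fac <- sapply(seq_len(ncol(x)), function(j) {
    ok <- x[, j] > 0 & x[, ref] > 0
    o <- x[ok, j]; r <- x[ok, ref]
    M <- log2((o / N[j]) / (r / N[ref]))
    A <- 0.5 * log2((o / N[j]) * (r / N[ref]))
    w <- (N[j] - o) / (N[j] * o) + (N[ref] - r) / (N[ref] * r)
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * trim_M) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_A) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    f <- sum(M[keep] / w[keep]) / sum(1 / w[keep])
    2^f
  })
  fac / exp(mean(log(fac)))
}

# --- ANOVA: least-squares model-comparison oracle built on lm() ---
oracle_anova <- function(y, design) {
  df <- data.frame(y = y, g = design$genotype, s = design$spatio)
  m0 <- lm(y ~ 1, df); mg <- lm(y ~ g, df); ms <- lm(y ~ s, df)
  ma <- lm(y ~ g + s, df); mf <- lm(y ~ g * s, df)
  cmp <- function(small, big) {
    a <- anova(small, big)
    list(F = a$F[2], p = a$`Pr(>F)`[2])
  }
  list(genotype = cmp(ms, ma), spatio = cmp(mg, ma),
       interaction = cmp(ma, mf),
       add_null = cmp(m0, ma), int_null = cmp(m0, mf),
       add_r2 = summary(ma)$r.squared, int_r2 = summary(mf)$r.squared)
}

# --- Holm: the step-down definition applied literally ---
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, min(1, (m - i + 1) * p[o[i]]))
    adj[o[i]] <- running
  }
  adj
}

# --- complete-linkage agglomeration, naive O(n^3) ---
oracle_complete_linkage <- function(Z, k) {
  d <- as.matrix(dist(Z))
  clusters <- as.list(seq_len(nrow(Z)))
  while (length(clusters) > k) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      h <- max(d[clusters[[i]], clusters[[j]]])
      if (h < best[1]) best <- c(h, i, j)
    }
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  memb <- integer(nrow(Z))
  for (i in seq_along(clusters)) memb[clusters[[i]]] <- i
  memb
}

same_partition <- function(a, b) {
  tt <- table(a, b)
  all(rowSums(tt > 0) == 1) && all(colSums(tt > 0) == 1)
}

# --- exact r x c Fisher by exhaustive enumeration over fixed margins ---
oracle_fisher_rxc <- function(m) {
  rs <- rowSums(m); cs <- colSums(m); N <- sum(m)
  log_prob <- function(tab)
    sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(N) -
      sum(lfactorial(tab))
  tables <- list()
  fill <- function(tab, i, j, rrem, crem) {
    if (i > nrow(m)) { tables[[length(tables) + 1]] <<- tab; return() }
    if (j == ncol(m)) {
      v <- rrem[i]
      if (v >= 0 && v <= crem[j]) {
        tab[i, j] <- v
        fill(tab, i + 1, 1, {rr <- rrem; rr[i] <- 0; rr},
             {cc <- crem; cc[j] <- cc[j] - v; cc})
      }
      return()
    }
    for (v in 0:min(rrem[i], crem[j])) {
      tab[i, j] <- v
      fill(tab, i, j + 1, {rr <- rrem; rr[i] <- rr[i] - v; rr},
           {cc <- crem; cc[j] <- cc[j] - v; cc})
    }
  }
  fill(matrix(0, nrow(m), ncol(m)), 1, 1, rs, cs)
  lp <- vapply(tables, log_prob, 0)
  obs <- log_prob(m)
  sum(exp(lp[lp <= obs + 1e-7]))
}
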
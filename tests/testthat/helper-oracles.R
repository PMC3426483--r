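# Independent oracles used to cross-check the estimators.  These are kept
# deliberately different in construction from the package implementations.

# Weir-Cockerham theta via the hierarchical ANOVA decomposition on the raw
# per-allele data vector (alleles within individuals within populations):
# a = (MS_P - MS_I) / (2 n_c), b = (MS_I - MS_G) / 2, c = MS_G.
theta_anova_oracle <- function(genotype_table) {
  g <- as.matrix(genotype_table)
  y <- list(); pop <- list(); ind <- list()
  id <- 0L
  for (p in 1:2) {
    reps <- rep(c(0L, 1L, 2L), g[p, ])   # copies of allele "a" per individual
    for (kk in reps) {
      id <- id + 1L
      y[[id]] <- c(kk >= 1L, kk >= 2L) * 1   # the two allele values (0/1)
      pop[[id]] <- p
      ind[[id]] <- id
    }
  }
  y <- unlist(y)
  pop <- rep(unlist(pop), each = 2L)
  ind <- rep(unlist(ind), each = 2L)
  n_i <- as.vector(table(factor(pop, levels = 1:2))) / 2
  r <- 2
  ybar <- mean(y)
  ybar_p <- tapply(y, pop, mean)
  ybar_i <- tapply(y, ind, mean)
  SSP <- sum((ybar_p[as.character(pop)] - ybar)^2)
  SSI <- sum((ybar_i[as.character(ind)] - ybar_p[as.character(pop)])^2)
  SSG <- sum((y - ybar_i[as.character(ind)])^2)
  MSP <- SSP / (r - 1)
  MSI <- SSI / (sum(n_i) - r)
  MSG <- SSG / sum(n_i)
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  a <- (MSP - MSI) / (2 * nc)
  b <- (MSI - MSG) / 2
  cc <- MSG
  a / (a + b + cc)
}

# Haplotype diversity as the probability that two genomes drawn without
# replacement differ, by enumeration of every unordered pair.
diversity_pair_oracle <- function(counts) {
  genomes <- rep(seq_along(counts), counts)
  n <- length(genomes)
  pairs <- utils::combn(n, 2)
  mean(genomes[pairs[1, ]] != genomes[pairs[2, ]])
}

# Local polynomial regression with tricube weights, coded from scratch:
# for each evaluation point, weighted least squares on the floor(span * n)
# nearest records.
local_poly_oracle <- function(x, y, x0, span, degree) {
  n <- length(x)
  q <- floor(span * n)
  sapply(x0, function(xe) {
    d <- abs(x - xe)
    dq <- sort(d)[q]
    w <- pmax(0, 1 - (d / dq)^3)^3
    keep <- w > 0
    # center and scale the predictor so the normal equations stay
    # well-conditioned; the intercept (fit at xe) is unaffected
    xs <- (x[keep] - xe) / dq
    X <- outer(xs, 0:degree, `^`)
    beta <- solve(crossprod(X, w[keep] * X), crossprod(X, w[keep] * y[keep]))
    beta[1]
  })
}

# Random two-population diploid genotype table, polymorphic by construction.
random_genotype_table <- function(max_n = 30) {
  repeat {
    n1 <- sample(2:max_n, 1); n2 <- sample(2:max_n, 1)
    p1 <- runif(1, 0.05, 0.95); p2 <- runif(1, 0.05, 0.95)
    g1 <- table(factor(rbinom(n1, 2, p1), levels = 0:2))
    g2 <- table(factor(rbinom(n2, 2, p2), levels = 0:2))
    tab <- rbind(as.integer(g1), as.integer(g2))
    p <- (2 * tab[, 1] + tab[, 2])
    if (sum(p) > 0 && sum(p) < 2 * (n1 + n2)) return(tab)
  }
}

# Tiny helper: a read stack where every read is the same sequence.
uniform_stack <- function(seq_chars, depth, error_prob = 0,
                          site = "s1", ind = "i1", pop = "pop1") {
  L <- length(seq_chars)
  read_stack(site, ind, pop,
             matrix(rep(seq_chars, each = depth), nrow = depth),
             matrix(error_prob, depth, L))
}
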
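# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Closed-form ridge solution with known penalty, for validating the BRR
# Gibbs sampler with variances frozen at truth.
ridge_oracle <- function(Z, y, lambda) {
  m <- ncol(Z)
  drop(solve(crossprod(Z) + diag(lambda, m), crossprod(Z, y - mean(y))))
}

# Exact two-locus genotype distribution of selfed progeny: enumerates the
# diplotype Markov chain of repeated selfing from an F1 between inbred
# parents (haplotypes AB and ab), with recombination fraction c per meiosis.
# Returns the probability of each unordered haplotype pair after
# `n_meioses` selfing generations.
selfing_chain_oracle <- function(c_rec, n_meioses) {
  haps <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))  # ab, aB, Ab, AB
  pairs <- which(upper.tri(matrix(0, 4, 4), diag = TRUE), arr.ind = TRUE)
  n_states <- nrow(pairs)
  state_id <- function(i, j) which(pairs[, 1] == min(i, j) &
                                     pairs[, 2] == max(i, j))
  gamete_probs <- function(i, j) {
    p <- numeric(4)
    p[i] <- p[i] + (1 - c_rec) / 2
    p[j] <- p[j] + (1 - c_rec) / 2
    r1 <- which(haps[, 1] == haps[i, 1] & haps[, 2] == haps[j, 2])
    r2 <- which(haps[, 1] == haps[j, 1] & haps[, 2] == haps[i, 2])
    p[r1] <- p[r1] + c_rec / 2
    p[r2] <- p[r2] + c_rec / 2
    p
  }
  trans <- matrix(0, n_states, n_states)
  for (s in seq_len(n_states)) {
    gp <- gamete_probs(pairs[s, 1], pairs[s, 2])
    for (a in 1:4) for (b in a:4) {
      pr <- if (a == b) gp[a]^2 else 2 * gp[a] * gp[b]
      trans[s, state_id(a, b)] <- trans[s, state_id(a, b)] + pr
    }
  }
  p0 <- numeric(n_states)
  p0[state_id(1, 4)] <- 1  # F1 = ab / AB
  pt <- p0
  for (gen in seq_len(n_meioses)) pt <- drop(pt %*% trans)
  list(pairs = pairs, haps = haps, prob = pt,
       state_id = state_id)
}

# Probability that a selfed line is a recombinant homozygote (Ab/Ab or
# aB/aB) after n_meioses generations.
recombinant_homozygote_prob <- function(c_rec, n_meioses) {
  or <- selfing_chain_oracle(c_rec, n_meioses)
  or$prob[or$state_id(2, 2)] + or$prob[or$state_id(3, 3)]
}

# Textbook sums-of-squares ANOVA for a balanced env x rep x line design,
# computed from cell means only (no model fitting).
hand_anova_oracle <- function(d) {
  g <- length(unique(d$line)); e <- length(unique(d$env))
  r <- length(unique(d$rep))
  gm <- mean(d$value)
  m_e <- tapply(d$value, d$env, mean)
  m_g <- tapply(d$value, d$line, mean)
  m_er <- tapply(d$value, list(d$env, d$rep), mean)
  m_eg <- tapply(d$value, list(d$env, d$line), mean)
  ss_E <- r * g * sum((m_e - gm)^2)
  ss_R <- g * sum(sweep(m_er, 1, m_e[rownames(m_er)])^2)
  ss_G <- r * e * sum((m_g - gm)^2)
  ss_GE <- r * sum((sweep(sweep(m_eg, 1, m_e), 2, m_g) + gm)^2)
  ss_tot <- sum((d$value - gm)^2)
  ss_err <- ss_tot - ss_E - ss_R - ss_G - ss_GE
  list(ms_E = ss_E / (e - 1), ms_R = ss_R / (e * (r - 1)),
       ms_G = ss_G / (g - 1), ms_GE = ss_GE / ((e - 1) * (g - 1)),
       ms_err = ss_err / (e * (r - 1) * (g - 1)))
}

# Haldane map function (duplicated here on purpose: the tests should not
# lean on the package's internal helper).
haldane_oracle <- function(d_cM) 0.5 * (1 - exp(-2 * d_cM / 100))
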
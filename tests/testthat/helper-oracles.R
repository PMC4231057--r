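# Independent oracles used across the suite; none of these call package code.

# Textbook OLS slope/intercept from the normal equations
ols_oracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

# Fixed-step RK4 integration of the two-compartment exchange ODE
rk4_two_compartment <- function(ps, vd, vr, t_end, donor0, receiver0 = 0,
                                n_steps = 20000) {
  deriv <- function(state) {
    flux <- state[1] - state[2]
    c(-ps / vd * flux, ps / vr * flux)
  }
  h <- t_end / n_steps
  state <- c(donor0, receiver0)
  for (i in seq_len(n_steps)) {
    k1 <- deriv(state)
    k2 <- deriv(state + h / 2 * k1)
    k3 <- deriv(state + h / 2 * k2)
    k4 <- deriv(state + h * k3)
    state <- state + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  list(donor = state[1], receiver = state[2])
}

# Brute-force Otsu: evaluate between-class variance directly from the raw
# pixels for every candidate split, without histogram bookkeeping
otsu_oracle <- function(x) {
  v <- as.numeric(x)
  levels <- sort(unique(v))
  cands <- levels[-length(levels)]
  score <- vapply(cands, function(t) {
    lo <- v[v <= t]; hi <- v[v > t]
    (length(lo) / length(v)) * (length(hi) / length(v)) *
      (mean(lo) - mean(hi))^2
  }, numeric(1))
  cands[which.max(score)]
}

# Hand-computed two-way ANOVA sums of squares for a balanced design
balanced_two_way_ss <- function(y, a, b) {
  n <- length(y)
  grand <- mean(y)
  ma <- tapply(y, a, mean); mb <- tapply(y, b, mean)
  mab <- tapply(y, interaction(a, b), mean)
  na <- table(a); nb <- table(b); nab <- table(interaction(a, b))
  ss_a <- sum(na * (ma - grand)^2)
  ss_b <- sum(nb * (mb - grand)^2)
  ss_cells <- sum(nab * (mab - grand)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_tot <- sum((y - grand)^2)
  list(ss_a = ss_a, ss_b = ss_b, ss_ab = ss_ab,
       ss_resid = ss_tot - ss_cells)
}
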
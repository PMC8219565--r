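# Shared fixtures and independent oracles for the test suite.
# Oracles are written with plain loops, independent of the package's
# vectorized implementation paths.

# a small, fast study configuration
small_config <- function(n_total = 1200,
                         mode_split = c(PBA = 400, CBA = 250, WBA = 550),
                         seed = 1L, ...) {
  sim_config(n_total = n_total, mode_split = mode_split, seed = seed, ...)
}

# a compact item bank: n_dich Rasch items plus n_poly 4-category items
tiny_bank <- function(n_dich = 10L, n_poly = 5L, spread = 2) {
  delta <- c(as.list(seq(-spread, spread, length.out = n_dich)),
             lapply(seq(-1, 1, length.out = n_poly),
                    function(c) c + c(-0.8, 0, 0.8)))
  list(n_steps = c(rep(1L, n_dich), rep(3L, n_poly)),
       weight = c(rep(1, n_dich), rep(0.5, n_poly)),
       delta = delta,
       names = c(sprintf("d%02d", seq_len(n_dich)),
                 sprintf("p%02d", seq_len(n_poly))))
}

# draw responses from known parameters for one group of persons
draw_bank_responses <- function(theta, bank, shift = 0) {
  n <- length(theta)
  X <- matrix(NA_integer_, n, length(bank$n_steps))
  for (j in seq_along(bank$delta)) {
    P <- pcm_probs(bank$delta[[j]] + shift, theta)
    cum <- t(apply(P, 1, cumsum))
    X[, j] <- as.integer(rowSums(stats::runif(n) > cum))
  }
  colnames(X) <- bank$names
  X
}

# plain-loop category probabilities (oracle; mirrors the model definition)
oracle_probs <- function(delta, theta) {
  K <- length(delta)
  num <- numeric(K + 1)
  for (k in 0:K) num[k + 1] <- exp(k * theta - sum(delta[seq_len(k)]))
  num / sum(num)
}

# plain-loop expected weighted test score at one theta
oracle_ts <- function(bank, theta) {
  total <- 0
  for (j in seq_along(bank$delta)) {
    p <- oracle_probs(bank$delta[[j]], theta)
    total <- total + bank$weight[j] * sum((0:length(bank$delta[[j]])) * p)
  }
  total
}

# from-scratch trapezoid DTF oracle on a shared grid
oracle_dtf <- function(bank_ref, bank_comp, grid, mu = 0, sigma2 = 1) {
  ts_r <- vapply(grid, function(t) oracle_ts(bank_ref, t), 1.0)
  ts_c <- vapply(grid, function(t) oracle_ts(bank_comp, t), 1.0)
  f <- stats::dnorm(grid, mu, sqrt(sigma2))
  n <- length(grid)
  d <- diff(grid)
  tw <- c(d[1] / 2, (d[-(n - 1)] + d[-1]) / 2, d[n - 1] / 2)
  f <- f / sum(tw * f)
  list(sdtf = sum(tw * f * (ts_r - ts_c)),
       udtf = sum(tw * f * abs(ts_r - ts_c)))
}

# independent Warm-penalized likelihood maximization by optimize()
oracle_wle <- function(x, bank, bounds = c(-8, 8)) {
  pen <- function(theta) {
    ll <- 0
    info <- 0
    for (j in seq_along(bank$delta)) {
      if (is.na(x[j])) next
      p <- oracle_probs(bank$delta[[j]], theta)
      ll <- ll + log(p[x[j] + 1])
      k <- 0:length(bank$delta[[j]])
      e <- sum(k * p)
      info <- info + sum(k^2 * p) - e^2
    }
    ll + 0.5 * log(info)
  }
  stats::optimize(pen, bounds, maximum = TRUE, tol = 1e-7)$maximum
}

# item_params object built from known values (for DTF tests)
make_params <- function(bank, mu = 0, sigma2 = 1, vcov = NULL,
                        group = "G") {
  npar <- sum(bank$n_steps)
  if (is.null(vcov)) vcov <- matrix(0, npar, npar)
  structure(list(delta = bank$delta, n_steps = bank$n_steps,
                 weight = bank$weight, names = bank$names,
                 mu = mu, sigma2 = sigma2, vcov = vcov, group = group,
                 converged = TRUE, loglik = NA_real_, n_nodes = 61L,
                 n = 0L),
            class = "item_params")
}

# mode records with prescribed counts (deterministic bookkeeping fixture)
make_mode_records <- function(assigned, participated, switch_offered = 0,
                              switch_participated = 0) {
  n <- sum(assigned)
  mode <- rep(names(assigned), assigned)
  part <- unlist(lapply(names(assigned), function(m)
    c(rep(TRUE, participated[[m]]), rep(FALSE, assigned[[m]] - participated[[m]]))))
  rec <- data.frame(
    student_id = seq_len(n),
    assigned_mode = factor(mode, levels = c("PBA", "CBA", "WBA")),
    participated_first_stage = part,
    offered_switch = mode %in% c("PBA", "CBA") & !part,
    participated_switch = NA)
  off <- which(rec$offered_switch)
  rec$participated_switch[off] <- seq_along(off) <= switch_participated
  eff <- rep("none", n)
  eff[part] <- mode[part]
  eff[which(rec$participated_switch)] <- "WBA_switch"
  rec$effective_mode <- factor(eff, levels = c("PBA", "CBA", "WBA",
                                               "WBA_switch", "none"))
  rec
}
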
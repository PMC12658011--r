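# Independent oracles used across the suite. These re-derive expectations by
# brute force or closed form and never call the code paths they check.

# Direct scan of one 9-trial choice vector (TRUE = generous): indifference is
# the selfish amount at the first generous trial (75 if none), and the block
# is non-monotone iff any selfish choice follows the first generous one.
oracle_indifference <- function(gen) {
  amounts <- seq(155, 75, by = -10)
  if (!any(gen)) {
    return(list(ip = 75, violation = FALSE))
  }
  first <- which(gen)[1]
  list(ip = amounts[first], violation = any(!gen[first:9]))
}

# All 2^9 choice vectors as a logical matrix (rows = vectors).
all_choice_vectors <- function() {
  m <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), 9)))
  dimnames(m) <- NULL
  m
}

# Dense grid search over k (best V0 profiled out in closed form for the
# hyperbolic/exponential basis-function families, grid for linear).
oracle_grid_fit <- function(n, v, family = "hyperbolic",
                            k_grid = 10^seq(-6, 1, length.out = 600)) {
  best <- NULL
  for (k in k_grid) {
    basis <- switch(family,
                    hyperbolic = 1 / (1 + k * n),
                    exponential = exp(-k * n),
                    linear = NULL)
    if (family == "linear") {
      for (v0 in seq(0, 160, by = 1)) {
        rss <- sum((v - pmax(v0 - k * n, 0))^2)
        if (is.null(best) || rss < best$rss) best <- list(k = k, v0 = v0, rss = rss)
      }
    } else {
      v0 <- sum(v * basis) / sum(basis^2)
      v0 <- min(max(v0, 1e-6), 160)
      rss <- sum((v - v0 * basis)^2)
      if (is.null(best) || rss < best$rss) best <- list(k = k, v0 = v0, rss = rss)
    }
  }
  best
}

# Explicit normal-equations solve for OLS coefficients.
oracle_ols <- function(X, y) {
  X1 <- cbind(1, as.matrix(X))
  drop(solve(t(X1) %*% X1, t(X1) %*% y))
}

# Greedy 1:1 nearest-neighbour matching on a score, treated visited in the
# given order, each control used once, caliper on absolute distance.
oracle_greedy_match <- function(score_t, score_c, order_t, caliper) {
  avail <- rep(TRUE, length(score_c))
  pairs <- list()
  for (i in order_t) {
    d <- abs(score_c - score_t[i])
    d[!avail] <- Inf
    j <- as.integer(which.min(d))
    if (is.finite(d[j]) && d[j] <= caliper) {
      avail[j] <- FALSE
      pairs[[length(pairs) + 1]] <- c(treated = as.integer(i), control = j)
    }
  }
  do.call(rbind, pairs)
}

# Noise-free profile from a model family on the canonical distances.
noiseless_profile <- function(k, v0 = 80, family = "hyperbolic",
                              id = "P1") {
  n <- socialdisc::social_distances()
  tibble::tibble(
    participant_id = id,
    social_distance = n,
    v = socialdisc::model_value(family, v0, k, n)
  )
}
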
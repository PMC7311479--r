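# Independent oracles used across the suite. These deliberately avoid the
# package's fitting/scanning code paths: linear algebra and exhaustive
# enumeration only.

# Brute-force chi^2 grid search for the Boltzmann midpoint. For each
# (tm, slope) on the grid the two plateaus are profiled out exactly by
# linear least squares (the model is linear in them given the logistic
# term), so the scan is over the two nonlinear parameters only.
boltzmann_grid_oracle <- function(temperature, y, tm_grid, slope_grid) {
  best <- list(ss = Inf)
  for (s in slope_grid) {
    for (tm in tm_grid) {
      L <- 1 / (1 + exp((temperature - tm) / s))
      X <- cbind(pre = L, post = 1 - L)
      beta <- solve(crossprod(X), crossprod(X, y))
      r <- y - X %*% beta
      ss <- sum(r^2)
      if (ss < best$ss) best <- list(tm = tm, slope = s, ss = ss)
    }
  }
  best
}

# Brute-force 2-D grid search for the two-state model with flat baselines
# profiled out linearly.
two_state_grid_oracle <- function(D, y, dg_grid, m_grid, temperature = 293.15) {
  RT <- 1.987e-3 * temperature
  best <- list(ss = Inf)
  for (m in m_grid) {
    for (dg in dg_grid) {
      K <- exp(-(dg - m * D) / RT)
      fu <- K / (1 + K)
      X <- cbind(folded = 1 - fu, unfolded = fu)
      beta <- solve(crossprod(X), crossprod(X, y))
      r <- y - X %*% beta
      ss <- sum(r^2)
      if (ss < best$ss) best <- list(dg = dg, m = m, ss = ss)
    }
  }
  best
}

# Exhaustive run enumeration for CSP clusters: every pair of above-threshold
# residues defines a candidate run; a run is valid when consecutive
# above-threshold residues inside it are separated by at most max_gap
# below/missing residues; clusters are the maximal valid runs spanning at
# least min_length residues.
cluster_enumeration_oracle <- function(residues, csp, threshold,
                                       min_length = 3, max_gap = 1) {
  o <- order(residues)
  residues <- residues[o]; csp <- csp[o]
  above <- residues[csp > threshold]
  if (length(above) == 0)
    return(data.frame(start_residue = integer(), end_residue = integer()))
  valid <- function(i, j) {
    inside <- above[above >= i & above <= j]
    inside[1] == i && inside[length(inside)] == j &&
      all(diff(inside) <= max_gap + 1)
  }
  cand <- list()
  for (i in above) for (j in above[above >= i])
    if (valid(i, j)) cand[[length(cand) + 1L]] <- c(i, j)
  cand <- do.call(rbind, cand)
  maximal <- vapply(seq_len(nrow(cand)), function(k) {
    !any(cand[, 1] <= cand[k, 1] & cand[, 2] >= cand[k, 2] &
           (cand[, 1] != cand[k, 1] | cand[, 2] != cand[k, 2]))
  }, TRUE)
  runs <- cand[maximal, , drop = FALSE]
  runs <- runs[runs[, 2] - runs[, 1] + 1 >= min_length, , drop = FALSE]
  runs <- runs[order(runs[, 1]), , drop = FALSE]
  data.frame(start_residue = runs[, 1], end_residue = runs[, 2])
}

# All permutations of 1..n (n small), for the exhaustive assignment oracle.
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L))
    for (k in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  out
}

# Minimum-total-distance one-to-one assignment between equal-size peak sets
# in weighted shift space, by exhaustive permutation search.
assignment_oracle <- function(ref, mod, nitrogen_weight = 0.14) {
  n <- nrow(ref)
  d <- outer(seq_len(n), seq_len(n), function(i, j)
    sqrt((mod$h_ppm[j] - ref$h_ppm[i])^2 +
           (nitrogen_weight * (mod$n_ppm[j] - ref$n_ppm[i]))^2))
  best <- NULL; best_tot <- Inf
  for (p in all_perms(n)) {
    tot <- sum(d[cbind(seq_len(n), p)])
    if (tot < best_tot) { best_tot <- tot; best <- p }
  }
  list(perm = unlist(best), total = best_tot)
}

# Minimal three-residue PDB file (synthetic fixture), written fixed-width.
write_toy_pdb <- function(path, chain = "A", resnos = 1:3) {
  lines <- character()
  serial <- 1L
  for (i in seq_along(resnos)) {
    for (atom in c("N", "CA", "C")) {
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %1s",
        serial, atom, "ALA", chain, resnos[i],
        i * 1.5, i * 0.5, serial * 0.3, 1.00, 0.00, substr(atom, 1, 1)))
      serial <- serial + 1L
    }
  }
  writeLines(c(lines, "END"), path)
  path
}
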
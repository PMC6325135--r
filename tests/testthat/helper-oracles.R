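# Independent oracles used across tests.

# Brute-force maximal-intersection finder.  Probes every elementary region of
# the time axis for the set of records covering it; the NPMLE support
# intervals are the intersections of the maximal cover sets (maximal cliques
# of the interval graph).  Independent of the endpoint-scan algorithm in the
# package.
brute_turnbull <- function(records) {
  exact <- records$left == records$right
  vals <- sort(unique(c(records$left, records$right[is.finite(records$right)])))
  probes <- list()
  for (v in vals) probes[[length(probes) + 1]] <- c(v, v)
  if (length(vals) > 1) {
    for (k in seq_len(length(vals) - 1)) {
      probes[[length(probes) + 1]] <- c(vals[k], vals[k + 1])
    }
  }
  if (any(is.infinite(records$right))) {
    probes[[length(probes) + 1]] <- c(vals[length(vals)], Inf)
  }
  cover <- function(l, r) {
    if (l == r) {
      which((!exact & records$left < l & records$right >= l) |
              (exact & records$left == l))
    } else {
      which(!exact & records$left <= l & records$right >= r)
    }
  }
  sets <- unique(lapply(probes, function(pr) cover(pr[1], pr[2])))
  sets <- Filter(length, sets)
  maximal <- Filter(function(s) {
    !any(vapply(sets, function(o) {
      length(setdiff(s, o)) == 0 && length(setdiff(o, s)) > 0
    }, TRUE))
  }, sets)
  out <- do.call(rbind, lapply(maximal, function(s) {
    if (any(exact[s])) {
      t <- records$left[s][exact[s]][1]
      c(t, t)
    } else {
      c(max(records$left[s]), min(records$right[s]))
    }
  }))
  df <- unique(data.frame(left = out[, 1], right = out[, 2]))
  df[order(df$left, df$right), , drop = FALSE]
}

# Random small interval-censored record sets on an integer grid.
random_records <- function(n, max_t = 12, p_exact = 0.3, p_cens = 0.2) {
  left <- sample(0:(max_t - 1), n, replace = TRUE)
  width <- sample(1:3, n, replace = TRUE)
  right <- pmin(left + width, max_t)
  exact <- runif(n) < p_exact
  left[exact] <- right[exact]
  cens <- runif(n) < p_cens
  right[cens & !exact] <- Inf
  data.frame(left = left, right = right)
}

# Small, fast calibration used by population-model tests.
small_calibration <- function(N_F_eq = 500) {
  calibrate_equilibrium(life_history(N_F_eq = N_F_eq))
}
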
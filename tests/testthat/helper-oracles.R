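# Independent oracles, kept deliberately naive and separate from the
# implementation paths they check.

# exhaustive min-cost maximum-cardinality one-to-one matching between rows
# (references/trajectories) and columns (peaks) of a distance matrix,
# restricted to pairs with d <= gate; returns a data.frame(row, col).
# Exponential: use only for <= 7 rows.
oracle_matching <- function(d, gate) {
  n <- nrow(d); m <- ncol(d)
  best <- NULL; best_card <- -1L; best_cost <- Inf
  recurse <- function(i, used, pairs, cost) {
    if (i > n) {
      card <- nrow(pairs)
      if (card > best_card || (card == best_card && cost < best_cost)) {
        best <<- pairs; best_card <<- card; best_cost <<- cost
      }
      return(invisible())
    }
    # skip row i
    recurse(i + 1L, used, pairs, cost)
    for (j in seq_len(m)) {
      if (!used[j] && d[i, j] <= gate) {
        used[j] <- TRUE
        recurse(i + 1L, used, rbind(pairs, data.frame(row = i, col = j)),
                cost + d[i, j])
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, m), data.frame(row = integer(), col = integer()), 0)
  list(pairs = best[order(best$row), , drop = FALSE], cost = best_cost)
}

# Pearson correlation from the raw sum formula, independent of stats::cor
oracle_pearson <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# fraction bound by numeric root finding on the equilibrium condition,
# independent of the closed-form quadratic
oracle_fbound <- function(P, L, Kd) {
  if (L == 0) return(0)
  f <- function(cpx) (P - cpx) * (L - cpx) / cpx - Kd
  stats::uniroot(f, c(1e-12, min(P, L) - 1e-12), tol = 1e-14)$root / P
}

# a well-separated shift table on a grid: nearest scaled spacing `spacing`
grid_shift_table <- function(n, spacing = 0.4) {
  k <- ceiling(sqrt(n))
  g <- expand.grid(i = seq_len(k), j = seq_len(k))[seq_len(n), ]
  st <- data.frame(residue_number = seq_len(n),
                   residue_type = "A",
                   atom_group = "backbone-amide",
                   w_H = 7 + g$i * spacing,
                   w_N = 105 + g$j * spacing / 0.2,
                   stringsAsFactors = FALSE)
  class(st) <- c("shift_table", "data.frame")
  st
}

as_peaklist <- function(st, intensity = 1, assigned = TRUE) {
  df <- data.frame(w_N = st$w_N, w_H = st$w_H,
                   intensity = rep_len(intensity, nrow(st)))
  if (assigned) {
    df$residue_number <- st$residue_number
    df$residue_type <- st$residue_type
    df$atom_group <- st$atom_group
    df$label <- ifelse(st$atom_group == "trp-indole",
                       sprintf("%s%dNE1-HE1", st$residue_type, st$residue_number),
                       sprintf("%s%dN-H", st$residue_type, st$residue_number))
  }
  peaklist(df, spectrum_id = "test")
}
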
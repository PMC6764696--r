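# Independent brute-force oracles used to cross-check the package
# implementations on small instances.  These deliberately share no code
# with the package.

# Exhaustive randomization null: z-scores of per-class means over all
# distinct label assignments, via direct enumeration of index subsets
# (2-class case) or recursive permutation (general).
oracle_exact_null_z <- function(values, labels) {
  classes <- sort(unique(labels))
  n <- length(values)
  perms <- oracle_label_arrangements(labels)
  stats <- sapply(classes, function(k)
    apply(perms, 1, function(lab) mean(values[lab == k])))
  obs <- sapply(classes, function(k) mean(values[labels == k]))
  mu <- colMeans(stats)
  sdv <- sqrt(colMeans(sweep(stats, 2, mu)^2))
  z <- (obs - mu) / sdv
  z[sdv == 0 & obs == mu] <- 0
  names(z) <- classes
  z
}

oracle_label_arrangements <- function(labels) {
  n <- length(labels)
  if (n == 0) return(matrix(character(0), 0, 0))
  recurse <- function(pool) {
    if (length(pool) == 1) return(matrix(pool, 1, 1))
    res <- NULL
    for (u in unique(pool)) {
      rest <- pool[-which(pool == u)[1]]
      sub <- recurse(rest)
      res <- rbind(res, cbind(rep(u, nrow(sub)), sub))
    }
    res
  }
  unname(recurse(labels))
}

# Sort-based five-sector transition classifier, written independently:
# operates on an explicit per-gene table with repeated full sorts.
oracle_classify_transition <- function(fl, fh, n_invariant, n_specific,
                                       floor = 1e-4) {
  ids <- names(fl)
  tab <- data.frame(id = ids, fl = fl, fh = fh, stringsAsFactors = FALSE)
  tab$low <- tab$fl <= floor & tab$fh <= floor
  tab$r <- tab$fh / tab$fl
  tab$dist <- abs(log(tab$r))
  lab <- setNames(rep(NA_character_, nrow(tab)), ids)
  lab[tab$low] <- "low_activity"
  rk <- tab[!tab$low, ]
  rk <- rk[order(rk$dist, rk$id), ]
  inv <- rk$id[seq_len(n_invariant)]
  lab[inv] <- "invariant"
  rest <- rk[!(rk$id %in% inv), ]
  up <- rest[rest$r > 1, ]
  up <- up[order(-up$dist, up$id), ]
  act <- up$id[seq_len(min(n_specific, nrow(up)))]
  down <- rest[rest$r < 1, ]
  down <- down[order(-down$dist, down$id), ]
  rep_ <- down$id[seq_len(min(n_specific, nrow(down)))]
  lab[act] <- "activated"
  lab[rep_] <- "repressed"
  lab[setdiff(up$id, act)] <- "positive"
  lab[setdiff(down$id, rep_)] <- "negative"
  lab
}

# Longhand Pearson correlation from the defining sums.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# Dominant left singular vector by power iteration on M M^T.
oracle_power_iteration <- function(m, iters = 2000) {
  v <- rep(1, nrow(m)) / sqrt(nrow(m))
  for (i in seq_len(iters)) {
    v2 <- m %*% crossprod(m, v)
    v <- v2 / sqrt(sum(v2^2))
  }
  drop(v)
}

# Five-sector aggregation as an explicit rule table over count summaries.
oracle_aggregate <- function(n_nonspec, n_inv, n_pos, n_neg,
                             nonspecific_min = 9, invariant_min = 4) {
  if (n_nonspec >= nonspecific_min) {
    if (n_inv >= invariant_min) return("invariant")
    if (n_pos > n_neg) return("positive")
    if (n_neg > n_pos) return("negative")
    return(NA_character_)  # tie: handled by loading sign in the package
  }
  if (n_pos > n_neg) return("activated")
  if (n_neg > n_pos) return("repressed")
  NA_character_
}

# Two-sample KS statistic from explicit ECDF evaluation on a grid.
oracle_ks_D <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  ex <- sapply(grid, function(g) mean(x <= g))
  ey <- sapply(grid, function(g) mean(y <= g))
  max(abs(ex - ey))
}
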
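# Independent brute-force oracles, deliberately naive: every one recomputes
# its quantity with plain loops, sharing no code with the package internals.

naive_group_means <- function(table) {
  regions <- unique(table$region)
  groups <- unique(table$group)
  out <- matrix(NA_real_, length(regions), length(groups),
                dimnames = list(regions, groups))
  for (r in regions) {
    for (g in groups) {
      tot <- 0; cnt <- 0
      for (i in seq_len(nrow(table))) {
        if (table$region[i] == r && table$group[i] == g) {
          tot <- tot + table$value[i]
          cnt <- cnt + 1
        }
      }
      out[r, g] <- tot / cnt
    }
  }
  out
}

naive_phi <- function(rho) {
  R <- nrow(rho)
  out <- numeric(R)
  for (i in seq_len(R)) {
    s <- 0
    for (j in seq_len(R)) if (j != i) s <- s + rho[i, j]
    out[i] <- s
  }
  names(out) <- rownames(rho)
  out
}

naive_phi_con <- function(rho, edges, direction) {
  regions <- rownames(rho)
  out <- setNames(numeric(length(regions)), regions)
  for (k in seq_len(nrow(edges))) {
    src <- edges$source[k]; tgt <- edges$target[k]; w <- edges$weight[k]
    if (direction == "output") {
      out[src] <- out[src] + rho[src, tgt] * w
    } else {
      out[tgt] <- out[tgt] + rho[tgt, src] * w
    }
  }
  out
}

# Average-linkage (UPGMA) agglomeration from a full distance matrix:
# cluster distance = mean over all cross-cluster point pairs.
naive_average_linkage_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (b <= a) next
        tot <- 0; cnt <- 0
        for (i in clusters[[a]]) {
          for (j in clusters[[b]]) {
            tot <- tot + d[i, j]
            cnt <- cnt + 1
          }
        }
        if (tot / cnt < best_d) {
          best_d <- tot / cnt
          best <- c(a, b)
        }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

naive_chisq <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  stat <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      e <- sum(tab[i, ]) * sum(tab[, j]) / n
      stat <- stat + (tab[i, j] - e)^2 / e
    }
  }
  stat
}

# Random valid state-correlation structure: z-vectors of `n_cond` conditions
# per region, from which cor() yields a proper correlation matrix.
random_corr_matrix <- function(regions, n_cond = 4, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(length(regions) * n_cond), length(regions), n_cond,
              dimnames = list(regions, NULL))
  rho <- cor(t(m))
  attr(rho, "state") <- "synthetic"
  attr(rho, "undefined") <- matrix(FALSE, nrow(rho), ncol(rho),
                                   dimnames = dimnames(rho))
  rho
}

as_conn <- function(df) limbicnet:::as_connectome(df)

# Small long-form expression table with exactly reproducible values.
tiny_expression_table <- function(regions = c("A", "B"),
                                  groups = c("g1", "g2"),
                                  n = 2, seed = 1) {
  set.seed(seed)
  rec <- expand.grid(animal = paste0("a", seq_len(n)), region = regions,
                     group = groups, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  rec$animal <- paste(rec$group, rec$animal, sep = "_")
  rec$value <- round(runif(nrow(rec), 1, 100), 3)
  rec[, c("region", "group", "animal", "value")]
}
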
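# Network-analysis operations: group means, z-scores, correlations,
# phi / phi_con and their drug differences, normalization, ranking.

test_that("group means equal the arithmetic cell means", {
  tab <- data.frame(region = c("A", "A", "B", "B"),
                    group = "G", animal = c("a1", "a2", "a1", "a2"),
                    value = c(2, 4, 1, 7))
  prof <- group_mean_profile(tab)
  expect_equal(prof["A", "G"], 3)
  expect_equal(prof["B", "G"], 4)
  # single animal per cell: identity
  one <- tab[tab$animal == "a1", ]
  expect_equal(as.numeric(group_mean_profile(one)), one$value)
  # random table vs brute-force summation oracle
  big <- tiny_expression_table(regions = LETTERS[1:6],
                               groups = paste0("g", 1:5), n = 3, seed = 42)
  expect_equal(group_mean_profile(big), naive_group_means(big),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("an empty (region, group) cell is an error naming the cell", {
  tab <- tiny_expression_table()
  tab <- tab[!(tab$region == "B" & tab$group == "g2"), ]
  expect_error(group_mean_profile(tab), "region 'B', group 'g2'")
})

test_that("z-scoring uses the population SD and standardizes each row", {
  prof <- matrix(c(1, 2, 3), 1, 3, dimnames = list("A", paste0("g", 1:3)))
  z <- zscore_profile(prof)
  expect_equal(as.numeric(z), c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_equal(as.numeric(z), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  # every standardized row: mean 0, population SD 1
  set.seed(8)
  prof2 <- matrix(rnorm(40, 50, 10), 5, 8,
                  dimnames = list(paste0("r", 1:5), paste0("g", 1:8)))
  z2 <- zscore_profile(prof2)
  expect_true(all(abs(rowMeans(z2)) < 1e-9))
  expect_true(all(abs(apply(z2, 1, function(x)
    sqrt(mean((x - mean(x))^2))) - 1) < 1e-9))
  # constant row is an error naming the region
  prof3 <- rbind(prof2, flat = rep(1, 8))
  expect_error(zscore_profile(prof3), "flat")
})

test_that("groups outside the standardization scope share the row center and scale", {
  set.seed(2)
  prof <- matrix(rnorm(24, 10, 3), 3, 8,
                 dimnames = list(paste0("r", 1:3),
                                 c(paste0("g", 1:7), "homecage")))
  z <- zscore_profile(prof, groups = paste0("g", 1:7))
  ctr <- rowMeans(prof[, paste0("g", 1:7)])
  scl <- apply(prof[, paste0("g", 1:7)], 1,
               function(x) sqrt(mean((x - mean(x))^2)))
  expect_equal(z[, "homecage"], (prof[, "homecage"] - ctr) / scl)
  # crossed columns still standardized
  expect_true(all(abs(rowMeans(z[, paste0("g", 1:7)])) < 1e-9))
})

test_that("state vectors pick the four crossed groups in condition order", {
  conds <- c("none", "EPM", "shock", "shock_EPM")
  groups <- c(group_label("saline", conds), group_label("DZP", conds),
              "homecage")
  set.seed(1)
  prof <- matrix(rnorm(45), 5, 9, dimnames = list(paste0("r", 1:5), groups))
  z <- zscore_profile(prof, groups = setdiff(groups, "homecage"))
  v <- build_state_vectors(z, "saline", conds)
  expect_equal(ncol(v), 4)
  expect_equal(colnames(v), conds)
  expect_equal(unname(v[, "EPM"]), unname(z[, "saline_EPM"]))
  expect_error(build_state_vectors(z, "ketamine", conds), "missing group")
  # permuting the condition order permutes columns but leaves rho unchanged
  v2 <- build_state_vectors(z, "saline", conds[c(3, 1, 4, 2)])
  r1 <- state_correlation_matrix(v)
  r2 <- state_correlation_matrix(v2)
  expect_equal(unclass(r1), unclass(r2), ignore_attr = TRUE)
})

test_that("state correlations match Pearson on known vectors", {
  v <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1),
             d = c(0, 1, 0, 1), e = c(0, 0, 1, 1))
  rho <- state_correlation_matrix(v)
  expect_equal(rho["a", "b"], 1)
  expect_equal(rho["a", "c"], -1)
  expect_equal(rho["d", "e"], 0)
  expect_equal(diag(rho), setNames(rep(1, 5), rownames(v)))
  expect_equal(rho, t(rho))
})

test_that("zero-variance vectors are flagged and contribute zero", {
  v <- rbind(a = c(1, 2, 3, 4), b = c(5, 5, 5, 5), c = c(2, 1, 4, 3))
  expect_warning(rho <- state_correlation_matrix(v), "zero-variance")
  expect_equal(rho["a", "b"], 0)
  expect_true(attr(rho, "undefined")["a", "b"])
  expect_false(attr(rho, "undefined")["a", "c"])
  p <- phi(rho)
  expect_equal(unname(p["b"]), 0)
  expect_equal(unname(p["a"]), rho["a", "c"], ignore_attr = TRUE)
})

test_that("phi sums off-diagonal correlations and respects its bound", {
  rho <- matrix(c(1, 0.5, -0.2,
                  0.5, 1, 0.8,
                  -0.2, 0.8, 1), 3, 3,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_equal(unname(phi(rho)), c(0.3, 1.3, 0.6))
  expect_equal(unname(phi(diag(3))), c(0, 0, 0))
  for (s in 1:20) {
    rho <- random_corr_matrix(paste0("r", 1:15), seed = s)
    p <- phi(rho)
    expect_equal(p, naive_phi(rho), tolerance = 1e-12)
    expect_true(all(abs(p) <= 14 + 1e-12))
  }
})

test_that("delta phi is the drug-minus-saline difference over shared regions", {
  a <- c(A = 1, B = 0); b <- c(A = 0, B = 1)
  expect_equal(delta_phi(a, b), c(A = 1, B = -1))
  expect_equal(delta_phi(a, a), c(A = 0, B = 0))
  expect_error(delta_phi(a, c(A = 0, C = 1)), "region sets")
})

test_that("out-normalization scales outgoing weights to unit sum and is idempotent", {
  conn <- as_conn(data.frame(source = c("A", "A", "B"),
                             target = c("B", "C", "A"),
                             weight = c(2, 3, 5)))
  norm <- normalize_connectome(conn)
  expect_equal(norm$weight, c(0.4, 0.6, 1))
  expect_true(attr(norm, "normalized"))
  for (s in 1:10) {
    conn <- simulate_connectome(limbic_regions(), density = 0.4, seed = s)
    n1 <- normalize_connectome(conn)
    sums <- tapply(n1$weight, n1$source, sum)
    expect_true(all(abs(sums - 1) < 1e-9))
    n2 <- normalize_connectome(n1)
    expect_equal(n1$weight, n2$weight, tolerance = 1e-12)
  }
})

test_that("phi_con weights correlations by normalized edges in both directions", {
  rho <- matrix(c(1, 0.5, -0.2,
                  0.5, 1, 0.8,
                  -0.2, 0.8, 1), 3, 3,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  conn <- normalize_connectome(as_conn(data.frame(
    source = c("A", "A", "B", "C"), target = c("B", "C", "A", "A"),
    weight = c(0.7, 0.3, 1, 1))))
  out <- phi_con(rho, conn, "output")
  expect_equal(unname(out["A"]), 0.5 * 0.7 + (-0.2) * 0.3)
  # input variant reuses the out-normalized weights of incoming edges
  inn <- phi_con(rho, conn, "input")
  expect_equal(unname(inn["A"]), 0.5 * 1 + (-0.2) * 1)
  expect_equal(unname(inn["B"]), 0.5 * 0.7)
  # all neighbor correlations 1 attains the normalization bound
  rho1 <- matrix(1, 3, 3, dimnames = dimnames(rho))
  expect_equal(unname(phi_con(rho1, conn, "output")["A"]), 1)
  # unnormalized connectome is refused
  raw <- as_conn(data.frame(source = "A", target = "B", weight = 2))
  expect_error(phi_con(rho, raw, "output"), "normalized")
})

test_that("phi_con matches the brute-force edge-list oracle", {
  for (s in 1:20) {
    rho <- random_corr_matrix(limbic_regions(), seed = s)
    conn <- normalize_connectome(
      simulate_connectome(limbic_regions(), density = 0.5, seed = s + 100))
    for (dir in c("output", "input")) {
      expect_equal(as.numeric(phi_con(rho, conn, dir)),
                   as.numeric(naive_phi_con(rho, conn, dir)),
                   tolerance = 1e-12)
    }
  }
})

test_that("delta phi_con checks direction compatibility and is linear", {
  a <- structure(c(A = 1, B = -1), direction = "output")
  b <- structure(c(A = 0.5, B = 0.5), direction = "output")
  expect_equal(as.numeric(delta_phi_con(a, b)), c(0.5, -1.5))
  expect_equal(as.numeric(delta_phi_con(b, a)), -c(0.5, -1.5))
  expect_equal(as.numeric(delta_phi_con(a, a)), c(0, 0))
  bad <- structure(b, direction = "input")
  expect_error(delta_phi_con(a, bad), "direction mismatch")
})

test_that("region ranking is descending with lexicographic tie-break", {
  sc <- data.frame(region = c("CEA", "BLA", "LA"),
                   delta = c(-2.0, 1.5, -0.5))
  expect_equal(rank_regions(sc, "delta"), c("CEA", "BLA", "LA"))
  expect_equal(rank_regions(sc, "delta", by_absolute = FALSE),
               c("BLA", "LA", "CEA"))
  ties <- data.frame(region = c("PVT", "AI", "LSr"), delta = c(1, 1, 1))
  expect_equal(rank_regions(ties, "delta"), c("AI", "LSr", "PVT"))
  expect_error(rank_regions(sc, "nope"), "unknown score key")
})

test_that("the full pipeline ranks the planted region first under strong decoupling", {
  cfg <- cfos_sim_config(decoupling = 1, drug_effect = -1, noise_sd = 2,
                         seed = 21)
  sim <- simulate_cfos(cfg)
  conn <- simulate_connectome(limbic_regions(), density = 0.5, seed = 21)
  fit <- cfos_network_scores(sim$expression, conn)
  expect_equal(rank_regions(fit$scores, "delta_phicon_out")[1], "CEA")
  expect_equal(fit$scores$region[fit$scores$rank_delta_phicon_out == 1],
               "CEA")
})

test_that("permuting region labels permutes all scores identically", {
  cfg <- cfos_sim_config(seed = 33, decoupling = 0.7)
  sim <- simulate_cfos(cfg)
  conn <- simulate_connectome(limbic_regions(), density = 0.5, seed = 33)
  fit1 <- cfos_network_scores(sim$expression, conn)
  perm <- rev(limbic_regions())
  expr2 <- sim$expression[order(match(sim$expression$region, perm),
                                match(sim$expression$group,
                                      unique(sim$expression$group))), ]
  fit2 <- cfos_network_scores(expr2, conn)
  s1 <- fit1$scores[order(fit1$scores$region), ]
  s2 <- fit2$scores[order(fit2$scores$region), ]
  rownames(s1) <- rownames(s2) <- NULL
  expect_equal(s1, s2)
})
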
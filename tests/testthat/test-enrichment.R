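test_that("Fisher enrichment: forced cases and sample-OR conventions", {
  bg <- paste0("g", 1:100)
  # zero overlap -> OR 0, p 1
  r0 <- fisher_enrichment(bg[1:10], bg[11:20], bg)
  expect_equal(r0$odds_ratio, 0)
  expect_equal(r0$p, 1)
  # degenerate margins: query = target = background -> p = 1
  expect_equal(fisher_enrichment(bg, bg, bg)$p, 1)
  # full nesting with positive overlap and empty b or c -> Inf sentinel
  expect_equal(fisher_enrichment(bg[1:5], bg[1:10], bg)$odds_ratio, Inf)
  # Bonferroni arithmetic
  r <- fisher_enrichment(bg[1:20], bg[15:40], bg, family_size = 20)
  expect_equal(r$p_corrected, min(1, r$p * 20))
  expect_error(fisher_enrichment(c(bg[1], "zz"), bg[1:5], bg), "subset")
})

test_that("Fisher p equals brute-force hypergeometric enumeration", {
  # randomized configurations with background <= 50, vs the choose() oracle
  set.seed(121)
  for (i in 1:100) {
    N <- sample(5:50, 1)
    bg <- paste0("g", seq_len(N))
    nq <- sample.int(N, 1); nt <- sample.int(N, 1)
    q <- sample(bg, nq); t_ <- sample(bg, nt)
    got <- fisher_enrichment(q, t_, bg)
    a <- length(intersect(q, t_))
    expect_equal(got$p, oracle_hyper_upper(a, nt, N, nq), tolerance = 1e-12)
    # OR against the explicit 2x2 construction
    b <- nq - a; cc <- nt - a; d <- N - a - b - cc
    or <- if (a == 0) 0 else if (b * cc == 0) Inf else a * d / (b * cc)
    expect_equal(got$odds_ratio, or)
  }
})

test_that("category scores: singleton identity and planted recovery", {
  genes <- sprintf("g%02d", 1:30)
  r_obs <- setNames(seq(-0.9, 0.9, length.out = 30), genes)
  set.seed(122)
  ens <- matrix(abs(rnorm(30 * 50, sd = 0.2)), 30, 50,
                dimnames = list(genes, NULL))
  cats <- list(single = genes[30], strong = genes[c(1, 2, 29, 30)],
               weak = genes[14:17])
  res <- category_score_test(cats, r_obs, ens)
  expect_equal(res$score[res$category == "single"], unname(abs(r_obs[30])),
               tolerance = 1e-12)
  expect_equal(res$p_corrected, pmin(1, res$p_perm * nrow(res)))
  expect_lt(res$p_perm[res$category == "strong"],
            res$p_perm[res$category == "weak"])
  expect_warning(category_score_test(c(cats, list(empty = "zz")), r_obs, ens),
                 "skipped")
  expect_error(category_score_test(cats, r_obs, ens[, 1:5]), "at least 20")
})

test_that("category-score p-values are calibrated on exchangeable nulls", {
  set.seed(123)
  genes <- sprintf("g%02d", 1:40)
  E <- 199
  ps <- vapply(1:60, function(i) {
    absr <- setNames(abs(rnorm(40, sd = 0.2)), genes)
    ens <- matrix(abs(rnorm(40 * E, sd = 0.2)), 40, E,
                  dimnames = list(genes, NULL))
    category_score_test(list(c1 = genes[1:8]), absr, ens)$p_perm
  }, numeric(1))
  expect_lt(abs(mean(ps) - 0.5), 0.12)
  expect_lte(mean(ps < 0.05), 0.15)
})

test_that("pSI: forced extremes and brute-force rank oracle", {
  set.seed(124)
  G <- 20
  m <- matrix(exp(rnorm(G * 4, sd = 0.1)), G, 4,
              dimnames = list(sprintf("g%02d", 1:G), c("I", "II", "III", "IV")))
  m["g01", "II"] <- m["g01", "II"] * 50  # extreme stage-specific gene
  psi <- compute_psi(m, n_null = 400, seed = 5)
  # the planted gene attains the minimal pSI in its stage, below threshold
  expect_equal(which.min(psi[, "II"]), which(rownames(m) == "g01"),
               ignore_attr = TRUE)
  expect_lt(psi["g01", "II"], 0.01)
  expect_true(all(psi > 0 & psi <= 1))
  # brute-force SI oracle: mean rank of fold-change across comparisons
  s <- 2  # stage II
  oracle_si <- rowMeans(vapply(c(1, 3, 4), function(j)
    rank(-(m[, s] / m[, j])), numeric(G)))
  expect_equal(which.min(oracle_si), which(rownames(m) == "g01"),
               ignore_attr = TRUE)
  # internal SI ordering must match: smaller SI -> smaller pSI (same stage)
  expect_equal(order(psi[, s])[1], which.min(oracle_si), ignore_attr = TRUE)
  # exchangeable matrix: pSI roughly uniform
  m0 <- matrix(exp(rnorm(400, sd = 0.1)), 100, 4,
               dimnames = list(sprintf("h%03d", 1:100), c("I", "II", "III", "IV")))
  psi0 <- compute_psi(m0, n_null = 200, seed = 6)
  expect_lt(abs(mean(psi0) - 0.5), 0.1)
  expect_error(compute_psi(m[, 1, drop = FALSE]), "2 stages")
  expect_error(compute_psi(m[1:5, ]), "20 genes")
})

test_that("stage enrichment recovers planted stages and corrects as stated", {
  set.seed(125)
  G <- 60
  stages <- as.character(utils::as.roman(1:10))
  m <- matrix(exp(rnorm(G * 10, sd = 0.2)), G, 10,
              dimnames = list(sprintf("g%02d", 1:G), stages))
  planted <- sprintf("g%02d", 1:6)
  m[planted, "IX"] <- m[planted, "IX"] * 10
  psi <- compute_psi(m, n_null = 400, seed = 7)
  res <- stage_enrichment(planted, psi, threshold = 0.01, n_gene_sets = 2)
  expect_equal(res$stage[which.min(res$p_corrected)], "IX")
  # family size 2 x 10 -> corrected p = min(1, 20 p)
  expect_equal(res$p_corrected, pmin(1, res$p * 20))
  # disjoint query -> all p = 1
  res0 <- stage_enrichment(sprintf("g%02d", 55:60), psi, threshold = 1e-9)
  expect_true(all(res0$p == 1))
  expect_error(stage_enrichment("nope", psi), "universe")
})

test_that("cell-type enrichment: identity query, family arithmetic, labels", {
  bg <- sprintf("g%03d", 1:200)
  markers <- list(neurons = bg[1:30], astrocytes = bg[31:60],
                  oligodendrocytes = bg[61:90], microglia = bg[91:120],
                  macrophage = bg[121:150])
  res <- celltype_enrichment(markers$microglia, markers, bg, n_gene_sets = 2)
  expect_equal(res$cell_type[which.min(res$p)], "microglia")
  expect_equal(res$p_corrected, pmin(1, res$p * 10))
  expect_error(celltype_enrichment(bg[1:5], list(glia = bg[1:10]), bg),
               "unknown cell-type")
  # random queries on disjoint markers: p roughly uniform across types
  set.seed(126)
  ps <- unlist(lapply(1:25, function(i)
    celltype_enrichment(sample(bg, 20), markers, bg)$p))
  expect_gt(mean(ps), 0.35)
})
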
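test_that("intensity filter applies the >= 50% convention per probe", {
  pa <- rbind(p_low = c(rep(TRUE, 49), rep(FALSE, 51)),   # 49% -> dropped
              p_edge = c(rep(TRUE, 50), rep(FALSE, 50)),  # 50% -> retained
              p_high = rep(TRUE, 100))
  keep <- intensity_filter(pa)
  expect_identical(keep, c("p_edge", "p_high"))
  # random flags: retention equals the brute-force count per probe
  set.seed(101)
  pa2 <- matrix(runif(40 * 200) < 0.7, 40, 200,
                dimnames = list(sprintf("pr%02d", 1:40), NULL))
  keep2 <- intensity_filter(pa2, 0.5)
  oracle <- rownames(pa2)[vapply(seq_len(40), function(i)
    sum(pa2[i, ]) >= 100, logical(1))]
  expect_identical(keep2, oracle)
})

test_that("probe selection follows the strict r > threshold argmax rule", {
  set.seed(102)
  ns <- 40
  ref <- rnorm(ns)
  samples <- sprintf("S%02d", seq_len(ns))
  rnaseq <- matrix(ref, 1, ns, dimnames = list("g1", samples))
  mk <- function(x) matrix(x, 1, ns)
  # boundary: a single probe with r slightly above threshold is selected
  pr_boundary <- ref * 0.25 + rnorm(ns)  # r around 0.2-0.3
  r_b <- cor(pr_boundary, ref)
  probes <- rbind(pb = pr_boundary)
  colnames(probes) <- samples
  pi_ <- data.frame(probe_id = "pb", gene = "g1")
  if (r_b > 0.2) {
    sel <- select_probes(probes, pi_, rnaseq)
    expect_identical(unname(attr(sel, "selected_probe")), "pb")
  }
  # planted anti-correlated probe is never chosen; argmax wins among rest
  probes3 <- rbind(p1 = ref + rnorm(ns, sd = 0.2),
                   p2 = ref + rnorm(ns, sd = 1.5),
                   p3 = -ref + rnorm(ns, sd = 0.2))
  colnames(probes3) <- samples
  pi3 <- data.frame(probe_id = c("p1", "p2", "p3"), gene = "g1")
  sel3 <- select_probes(probes3, pi3, rnaseq)
  rr <- c(cor(probes3[1, ], ref), cor(probes3[2, ], ref))
  expect_identical(unname(attr(sel3, "selected_probe")),
                   c("p1", "p2")[which.max(rr)])
  expect_false(attr(sel3, "selected_probe") == "p3")
  # enumeration oracle on a toy 3-probe / 2-gene instance
  ref2 <- rnorm(ns)
  rnaseq2 <- rbind(rnaseq, g2 = ref2)
  probesT <- rbind(a1 = ref + rnorm(ns, sd = .5), a2 = ref + rnorm(ns, sd = .1),
                   b1 = ref2 + rnorm(ns, sd = .3))
  colnames(probesT) <- samples
  piT <- data.frame(probe_id = c("a1", "a2", "b1"), gene = c("g1", "g1", "g2"))
  selT <- select_probes(probesT, piT, rnaseq2)
  oracle <- c(g1 = c("a1", "a2")[which.max(c(cor(probesT["a1", ], ref),
                                             cor(probesT["a2", ], ref)))],
              g2 = "b1")
  expect_identical(attr(selT, "selected_probe"), oracle)
  # gene absent from the reference is dropped with a warning
  piX <- rbind(piT, data.frame(probe_id = "b1", gene = "g3"))
  expect_warning(select_probes(probesT, piX, rnaseq2), "absent")
})

test_that("sample assignment respects the 2 mm radius", {
  ctr <- matrix(c(0, 0, 0, 30, 0, 0), 2, 3, byrow = TRUE,
                dimnames = list(c("A", "B"), NULL))
  sc <- rbind(c(0, 0, 0),       # exactly at A
              c(30, 0, 2.01),   # 2.01 mm from B -> excluded
              c(30, 0, 1.99))   # inside B
  got <- assign_samples(sc, ctr)
  expect_identical(got, c("A", NA, "B"))
  # brute-force nearest-neighbour oracle on random data
  set.seed(103)
  sc2 <- matrix(runif(100 * 3, 0, 40), 100, 3)
  ctr2 <- matrix(runif(10 * 3, 0, 40), 10, 3,
                 dimnames = list(LETTERS[1:10], NULL))
  got2 <- assign_samples(sc2, ctr2, max_dist = 5)
  oracle <- vapply(1:100, function(i) {
    d <- sqrt(rowSums((ctr2 - matrix(sc2[i, ], 10, 3, byrow = TRUE))^2))
    if (min(d) <= 5) LETTERS[1:10][which.min(d)] else NA_character_
  }, character(1))
  expect_identical(got2, oracle)
})

test_that("scaled robust sigmoid: formula, monotonicity, bounds", {
  x <- c(1, 2, 3, 4, 100)
  out <- srs_normalize(matrix(x, 1, 5, dimnames = list("g", NULL)))
  # direct formula oracle
  s <- 1 / (1 + exp(-(x - median(x)) / (IQR(x) / 1.35)))
  oracle <- (s - min(s)) / (max(s) - min(s))
  expect_equal(as.vector(out), oracle, tolerance = 1e-12)
  # strictly increasing input -> strictly increasing output in [0, 1]
  expect_true(all(diff(as.vector(out)) > 0))
  expect_equal(range(out), c(0, 1))
  # value at the median maps to pre-rescale score 0.5
  expect_equal(s[3], 0.5)
  # IQR = 0 falls back to ranks with a warning
  expect_warning(srs_normalize(matrix(c(1, 1, 1, 1, 9), 1, 5,
                                      dimnames = list("g", NULL))), "IQR")
  # donor-wise application
  m <- matrix(rnorm(20), 2, 10, dimnames = list(c("g1", "g2"), NULL))
  d <- rep(c("a", "b"), each = 5)
  nm <- srs_normalize(m, d)
  expect_true(all(nm >= 0 & nm <= 1))
  expect_error(srs_normalize(m, rep(c("a", "b", "c", "d", "e"), 2)),
               "fewer than 3")
})

test_that("differential stability: boundary values and Spearman oracle", {
  prof <- matrix(rnorm(4 * 6), 4, 6,
                 dimnames = list(paste0("g", 1:4), paste0("r", 1:6)))
  # identical donors -> DS = 1
  ds1 <- differential_stability(list(d1 = prof, d2 = prof, d3 = prof))
  expect_equal(unname(ds1), rep(1, 4))
  # exactly reversed region ranks (order-inverting transform) -> DS = -1
  rev_prof <- -prof
  ds2 <- differential_stability(list(d1 = prof, d2 = rev_prof))
  expect_equal(unname(ds2), rep(-1, 4))
  # 3 donors, 5 regions: equals mean pairwise Spearman via rank oracle
  set.seed(104)
  mats <- lapply(1:3, function(i)
    matrix(rnorm(3 * 5), 3, 5, dimnames = list(paste0("g", 1:3),
                                               paste0("r", 1:5))))
  got <- differential_stability(mats)
  oracle <- vapply(1:3, function(g) {
    mean(c(cor(mats[[1]][g, ], mats[[2]][g, ], method = "spearman"),
           cor(mats[[1]][g, ], mats[[3]][g, ], method = "spearman"),
           cor(mats[[2]][g, ], mats[[3]][g, ], method = "spearman")))
  }, numeric(1))
  expect_equal(unname(got), oracle, tolerance = 1e-12)
  expect_error(differential_stability(list(d1 = prof)), "2 donors")
  # too few shared regions errors
  a <- prof[, 1:2]; b <- prof[, 1:2]
  expect_error(differential_stability(list(a = a, b = b)), "fewer than 3")
})

test_that("full preprocessing chain yields a bounded, DS-scored dataset", {
  fix <- make_synthetic_dataset(n_genes = 60, n_samples = 120, n_signal = 5,
                                seed = 7)
  expr <- fix$expr
  expect_s3_class(expr, "expression_dataset")
  expect_true(all(expr$expr >= 0 & expr$expr <= 1))
  expect_true(all(expr$ds >= -1 & expr$ds <= 1))
  expect_false(anyNA(expr$expr))
  # planted anti-probes never selected
  sel <- attr(expr$expr, "selected_probe")
  expect_false(any(grepl("_p3$", sel %||% "")))
  # idempotence of normalization bounds: renormalizing stays in [0, 1]
  renorm <- srs_normalize(expr$expr, expr$samples$donor)
  expect_true(all(renorm >= 0 & renorm <= 1))
})
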
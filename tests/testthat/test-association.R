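test_that("sphere sampling matches offset enumeration on a 3 mm grid", {
  dims <- c(9, 9, 9)
  arr <- array(seq_len(prod(dims)), dims)
  tm <- wrap_tmap(arr, voxel_size = 3)
  center <- matrix(c(4, 4, 4) * 3, 1, 3)  # a voxel center
  ph <- sample_phenotype(tm, center, radius = 6)
  # offsets with 3 * sqrt(i^2+j^2+k^2) <= 6, i.e. i^2+j^2+k^2 <= 4
  off <- expand.grid(i = -2:2, j = -2:2, k = -2:2)
  off <- off[off$i^2 + off$j^2 + off$k^2 <= 4, ]
  expect_equal(ph$n_voxels, nrow(off))
  expect_equal(ph$n_voxels, 33L)
  oracle <- mean(arr[cbind(5 + off$i, 5 + off$j, 5 + off$k)])
  expect_equal(ph$t, oracle)

  # constant map -> constant sampled values
  tmc <- wrap_tmap(array(7, dims), voxel_size = 3)
  sc <- gen_sample_coords(20, dims, 3, seed = 1)
  expect_true(all(sample_phenotype(tmc, sc)$t == 7))
  # radius below half the voxel size at a center -> exactly one voxel
  ph1 <- sample_phenotype(tm, center, radius = 1)
  expect_equal(ph1$n_voxels, 1L)
  expect_error(sample_phenotype(tm, center, radius = 0), "radius")
  # samples with no in-mask voxel in range are dropped with a warning
  mask <- array(TRUE, dims); mask[1:3, , ] <- FALSE
  tmm <- wrap_tmap(arr, voxel_size = 3, mask = mask)
  expect_warning(ph2 <- sample_phenotype(tmm, rbind(center, c(0, 0, 0)),
                                         radius = 4), "dropping")
  expect_equal(nrow(ph2), 1L)
})

test_that("gene-map association: forced cases and invariants", {
  set.seed(111)
  co <- gen_sample_coords(60, seed = 2)
  em <- gen_effect_map(c(16, 16, 12), 9, seed = 3)
  tm <- wrap_tmap(em)
  ph <- sample_phenotype(tm, co)
  tvec <- ph$t
  ng <- 30
  E <- matrix(rnorm(ng * 60), ng, 60,
              dimnames = list(sprintf("g%02d", 1:ng), sprintf("S%02d", 1:60)))
  E[1, ] <- tvec                 # exact copy of the phenotype
  E[2, ] <- 5                    # zero-variance gene
  expr <- expression_dataset(E, data.frame(sample_id = colnames(E),
                                           donor = "d1", x = co[, 1],
                                           y = co[, 2], z = co[, 3]))
  B <- 99
  expect_warning(
    a <- gene_map_association(expr, ph, B = B, seed = 4, ds_quantile = 0),
    "zero-variance")
  expect_equal(a$r[1], 1, tolerance = 1e-12)
  expect_equal(a$p_fwe[1], 1 / (B + 1))
  expect_equal(a$r[2], 0)
  expect_equal(a$p_fwe[2], 1)
  expect_true(all(a$p_fwe >= 1 / (B + 1) & a$p_fwe <= 1))
  # p_fwe monotone non-increasing in |r|
  o <- order(abs(a$r))
  expect_true(all(diff(a$p_fwe[o]) <= 1e-12))
  # affine rescaling of a gene's expression leaves its r/p unchanged
  E2 <- E; E2[5, ] <- 3 - 2 * E[5, ]
  expr2 <- expression_dataset(E2, expr$samples)
  expect_warning(
    a2 <- gene_map_association(expr2, ph, B = B, seed = 4, ds_quantile = 0),
    "zero-variance")
  expect_equal(abs(a2$r[5]), abs(a$r[5]), tolerance = 1e-12)
  expect_equal(a2$p_fwe[5], a$p_fwe[5])
  expect_equal(a2$sign[5], if (a$r[5] >= 0) "-" else "+")
  # zero-variance phenotype rejected
  phc <- ph; phc$t <- rep(1, nrow(ph))
  expect_error(gene_map_association(expr, phc, B = 9, ds_quantile = 0),
               "zero-variance phenotype")
})

test_that("DS filter gates significance at the stated quantile", {
  set.seed(112)
  co <- gen_sample_coords(40, seed = 5)
  ph <- sample_phenotype(wrap_tmap(gen_effect_map(c(16, 16, 12), 9, seed = 6)),
                         co)
  ng <- 20
  E <- matrix(rnorm(ng * 40), ng, 40, dimnames = list(sprintf("g%02d", 1:ng),
                                                      NULL))
  E[1, ] <- ph$t; E[2, ] <- ph$t   # two perfect genes
  colnames(E) <- sprintf("S%02d", 1:40)
  ds <- setNames(seq(0, 1, length.out = ng), rownames(E))
  ds[1] <- 0.01; ds[2] <- 0.99     # gene 1 fails the top-50% DS filter
  expr <- expression_dataset(E, data.frame(sample_id = colnames(E),
                                           donor = "d1", x = co[, 1],
                                           y = co[, 2], z = co[, 3]), ds = ds)
  a <- gene_map_association(expr, ph, B = 99, seed = 7, ds_quantile = 0.5)
  expect_false(a$significant[1])
  expect_true(a$significant[2])
  expect_equal(attr(a, "ds_threshold"),
               unname(quantile(ds, 0.5)), tolerance = 1e-12)
})

test_that("partition logic matches hand enumeration", {
  mk <- function(genes, sig, sign) {
    structure(data.frame(gene = genes, r = ifelse(sign == "+", .5, -.5),
                         p_fwe = ifelse(sig, .001, .5), sign = sign,
                         ds = 1, significant = sig,
                         stringsAsFactors = FALSE),
              class = c("gene_assoc", "data.frame"))
  }
  genes <- paste0("g", 1:6)
  #            g1: both+  g2: only1  g3: both opposite  g4: only2
  #            g5: both-  g6: none
  a1 <- mk(genes, c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE),
           c("+", "+", "+", "+", "-", "+"))
  a2 <- mk(genes, c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE),
           c("+", "+", "-", "+", "-", "+"))
  p <- partition_genes(a1, a2)
  expect_setequal(p$insensitive, c("g1", "g5"))
  expect_setequal(p$sensitive, c("g2", "g3"))  # opposite-sign g3 -> sensitive
  expect_length(intersect(p$sensitive, p$insensitive), 0)
  # identity: everything significant replicates
  p2 <- partition_genes(a1, a1)
  expect_length(p2$sensitive, 0)
  expect_setequal(p2$insensitive, genes[a1$significant])
  expect_error(partition_genes(a1, mk(paste0("h", 1:6), rep(TRUE, 6),
                                      rep("+", 6))), "share no genes")
})

test_that("cross-disorder overlap proportions equal set enumeration", {
  part <- structure(list(sensitive = paste0("g", 1:4),
                         insensitive = paste0("g", 5:10)),
                    class = "gene_partition")
  other <- data.frame(gene = paste0("g", 1:10),
                      significant = c(TRUE, FALSE, TRUE, FALSE, TRUE,
                                      TRUE, TRUE, FALSE, FALSE, FALSE))
  ov <- cross_disorder_overlap(part, other)
  expect_equal(ov$n_overlap, c(2L, 3L))
  expect_equal(ov$proportion, c(2 / 4, 3 / 6))
  # same-dataset sanity: overlap of sensitive with its own table is 100%
  own <- data.frame(gene = paste0("g", 1:10),
                    significant = c(rep(TRUE, 4), rep(FALSE, 6)))
  expect_equal(cross_disorder_overlap(part, own)$proportion[1], 1)
  # no significant genes -> 0%
  none <- data.frame(gene = paste0("g", 1:10), significant = FALSE)
  expect_equal(cross_disorder_overlap(part, none)$proportion, c(0, 0))
  # empty class -> NA
  part0 <- structure(list(sensitive = character(0),
                          insensitive = paste0("g", 5:10)),
                     class = "gene_partition")
  expect_true(is.na(cross_disorder_overlap(part0, other)$proportion[1]))
})
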
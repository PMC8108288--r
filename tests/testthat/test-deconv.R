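test_that("eigengene matches the leading-eigenvector oracle", {
  set.seed(23)
  for (rep in 1:5) {
    n_genes <- sample(5:50, 1)
    f <- rnorm(60)
    expr <- outer(rnorm(n_genes, 1, 0.2), f) +
      matrix(rnorm(n_genes * 60, 0, 0.5), n_genes)
    rownames(expr) <- paste0("g", seq_len(n_genes))
    colnames(expr) <- paste0("s", 1:60)
    e <- eigengene(expr, rownames(expr))
    expect_equal(unname(e), eigengene_eigen_oracle(expr, rownames(expr)),
                 tolerance = 1e-8)
    expect_equal(sum(e^2), 1, tolerance = 1e-10)
  }
})

test_that("eigengene conventions: identical genes, sign flips, degenerate input", {
  f <- rnorm(40)
  expr <- rbind(g1 = f, g2 = f, g3 = f)
  colnames(expr) <- paste0("s", 1:40)
  e <- eigengene(expr, rownames(expr))
  expect_equal(abs(cor(e, f)), 1, tolerance = 1e-12)
  expect_gt(cor(e, f) * 1, 0)             # oriented along the genes
  # flipping every gene leaves the oriented eigengene invariant up to sign
  # orientation: mean correlation with members is still non-negative
  e_flip <- eigengene(-expr, rownames(expr))
  expect_gte(mean(cor(e_flip, t(-expr))), 0)
  expect_error(eigengene(matrix(1, 3, 10,
                                dimnames = list(letters[1:3], NULL)),
                         letters[1:3]), "constant")
  expect_error(eigengene(expr, "g1"), "at least 2")
})

test_that("module detection recovers planted orthogonal modules", {
  set.seed(29)
  n_samp <- 80
  f1 <- rnorm(n_samp); f2 <- rnorm(n_samp)
  expr <- rbind(
    outer(rep(1, 50), f1) + matrix(rnorm(50 * n_samp, 0, 0.3), 50),
    outer(rep(1, 50), f2) + matrix(rnorm(50 * n_samp, 0, 0.3), 50),
    matrix(rnorm(100 * n_samp, 0, 1), 100))
  rownames(expr) <- c(sprintf("m1_%02d", 1:50), sprintf("m2_%02d", 1:50),
                      sprintf("bg_%03d", 1:100))
  colnames(expr) <- sprintf("s%02d", seq_len(n_samp))
  ms <- detect_modules(expr)
  expect_equal(sum(names(ms$sizes) != "unassigned"), 2)
  m1_lab <- ms$modules["m1_01"]
  expect_true(all(ms$modules[sprintf("m1_%02d", 1:50)] == m1_lab))
  expect_true(all(ms$modules[sprintf("bg_%03d", 1:100)] == "unassigned"))
  # module labels are invariant under sample permutation
  perm <- sample(n_samp)
  ms_perm <- detect_modules(expr[, perm])
  expect_identical(ms$modules, ms_perm$modules)
})

test_that("a single shared factor yields a single module", {
  set.seed(31)
  f <- rnorm(50)
  expr <- outer(runif(80, 0.8, 1.2), f) + matrix(rnorm(80 * 50, 0, 0.3), 80)
  rownames(expr) <- paste0("g", 1:80)
  colnames(expr) <- paste0("s", 1:50)
  ms <- detect_modules(expr)
  expect_equal(sum(names(ms$sizes) != "unassigned"), 1)
  expect_true(all(ms$modules == "M1"))
})

test_that("constant genes are dropped with a warning", {
  set.seed(37)
  f <- rnorm(30)
  expr <- rbind(outer(rep(1, 40), f) + matrix(rnorm(40 * 30, 0, 0.3), 40),
                flat = rep(1, 30))
  rownames(expr) <- c(paste0("g", 1:40), "flat")
  colnames(expr) <- paste0("s", 1:30)
  expect_warning(ms <- detect_modules(expr), "constant")
  expect_false("flat" %in% names(ms$modules))
})

test_that("module-trait correlations behave at the extremes", {
  tc <- simulate_tissue_cohort(tissue_cohort_spec(seed = 41))
  ms <- detect_modules(tc$expr)
  md <- tc$metadata
  md$self <- ms$eigengenes[, 1]
  md$flat <- 1
  mt <- module_trait_correlation(ms, md, traits = c("self", "flat", "diagnosis"))
  expect_equal(mt$r[mt$module == colnames(ms$eigengenes)[1] &
                    mt$trait == "self"], 1, tolerance = 1e-10)
  expect_true(all(is.na(mt$r[mt$trait == "flat"])))
  expect_true(all(mt$note[mt$trait == "flat"] == "constant trait"))
})

test_that("signature partitioning classifies by eigengene correlation", {
  set.seed(43)
  n <- 400
  e_i <- rnorm(n); e_l <- rnorm(n)
  expr <- rbind(
    pure_infl = e_i,
    pure_noise = rnorm(n),
    dual = 0.7 * e_i + 0.7 * e_l + rnorm(n, 0, 0.3))
  colnames(expr) <- paste0("s", 1:n)
  part <- partition_signature(rownames(expr), expr, e_i, e_l)
  expect_equal(part$class[part$gene == "pure_infl"], "inflammatory_only")
  expect_equal(part$class[part$gene == "pure_noise"], "unassigned")
  expect_equal(part$class[part$gene == "dual"], "both")
  # affine rescaling of expression leaves the partition unchanged
  part2 <- partition_signature(rownames(expr), 3 * expr + 7, e_i, e_l)
  expect_identical(part$class, part2$class)
  # absent genes are reported and skipped
  expect_message(
    part3 <- partition_signature(c("pure_infl", "ghost"), expr, e_i, e_l),
    "absent")
  expect_identical(attr(part3, "missing"), "ghost")
})

test_that("the planted tissue cohort round-trips through the deconvolution", {
  tc <- simulate_tissue_cohort(tissue_cohort_spec(seed = 47))
  ms <- detect_modules(tc$expr)
  expect_equal(sum(names(ms$sizes) != "unassigned"), 2)
  cor_i <- cor(ms$eigengenes, tc$factors$inflammatory)
  cor_l <- cor(ms$eigengenes, tc$factors$lymphoid)
  infl_m <- colnames(ms$eigengenes)[which.max(abs(cor_i))]
  lymph_m <- colnames(ms$eigengenes)[which.max(abs(cor_l))]
  expect_false(infl_m == lymph_m)
  expect_gte(max(abs(cor_i)), 0.9)
  part <- partition_signature(tc$signature$gene, tc$expr,
                              ms$eigengenes[, infl_m],
                              ms$eigengenes[, lymph_m])
  truth <- tc$signature$class[match(part$gene, tc$signature$gene)]
  expect_gte(sum(part$class == truth), 27)
})
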
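# Co-expression network: soft threshold, TOM, module detection, eigengenes
# and the hub screen.

block_data <- function(n_blocks = 2, block_size = 15, n = 60, r = 0.9,
                       noise_feats = 0, seed = 1) {
  feats <- sprintf("feat_%04d", seq_len(n_blocks * block_size + noise_feats))
  blocks <- split(feats[seq_len(n_blocks * block_size)],
                  rep(seq_len(n_blocks), each = block_size))
  names(blocks) <- paste0("b", seq_len(n_blocks))
  tr <- metabolome_truth(module_blocks = blocks, block_cor = r)
  sim <- generate_metabolome(n / 2, length(feats), tr, seed = seed)
  list(x = log(sim$abundance), blocks = blocks,
       trait = as.numeric(sim$metadata$group == "DD"))
}

test_that("variance filter keeps the requested fraction", {
  set.seed(1)
  x <- matrix(rnorm(40 * 10), 40, dimnames = list(paste0("f", 1:40), NULL))
  expect_equal(nrow(filter_top_variance(x, 0.5)), 20)
  expect_equal(nrow(filter_top_variance(x, 1)), 40)
  expect_error(filter_top_variance(x, 0), "frac")
})

test_that("soft threshold picks a candidate achieving scale-free fit", {
  d <- block_data(n_blocks = 5, block_size = 12, n = 100, r = 0.8, seed = 2)
  st <- pick_soft_threshold(d$x, candidates = 1:12, target_r2 = 0.6)
  expect_true(st$beta %in% 1:12)
  expect_gte(st$beta, 2)
  expect_gte(max(st$fit_table$fit, na.rm = TRUE), 0.6)
})

test_that("degenerate inputs take the warning path", {
  base <- rnorm(30)
  x <- matrix(rep(base, 25), 25, byrow = TRUE,
              dimnames = list(paste0("f", 1:25), NULL))
  x <- x + matrix(rnorm(25 * 30, 0, 1e-10), 25)
  expect_warning(pick_soft_threshold(x, candidates = 2:3), "degenerate|reach")
  expect_error(pick_soft_threshold(x[1:5, ]), "20 features")
})

test_that("TOM formula matches hand calculation and the brute-force oracle", {
  a <- matrix(0, 3, 3)
  a[1, 2] <- a[2, 1] <- 0.8
  a[1, 3] <- a[3, 1] <- 0.5
  tom <- tom_similarity(a)
  expect_equal(tom[1, 2], 0.8)    # 0.8 / (min(1.3, 0.8) + 1 - 0.8)

  expect_equal(tom_similarity(matrix(0, 4, 4)), diag(4))

  ones <- matrix(1, 5, 5); diag(ones) <- 0
  expect_true(all(tom_similarity(ones) == 1))

  set.seed(3)
  for (i in 1:5) {
    n <- sample(5:30, 1)
    a <- matrix(runif(n * n), n); a <- (a + t(a)) / 2; diag(a) <- 0
    tom <- tom_similarity(a)
    expect_equal(tom, brute_tom(a), tolerance = 1e-12)
    expect_true(isSymmetric(tom))
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  }
  bad <- matrix(runif(9), 3); bad[1, 2] <- 2
  expect_error(tom_similarity(matrix(1:9, 3)), "symmetric")
})

test_that("planted blocks are recovered as modules", {
  d <- block_data(n_blocks = 2, block_size = 15, n = 80, r = 0.9, seed = 4)
  adj <- momdep:::soft_adjacency(d$x, 6)
  tom <- tom_similarity(adj); dimnames(tom) <- dimnames(adj)
  labels <- detect_modules(1 - tom, d$x, min_size = 10)
  non_grey <- setdiff(unique(labels), "grey")
  expect_length(non_grey, 2)
  for (b in d$blocks)
    expect_length(unique(labels[b]), 1)   # each block lands in one module
})

test_that("module recovery reaches adjusted Rand >= 0.9 on planted blocks", {
  skip_if_not_installed("mclust")
  d <- block_data(n_blocks = 3, block_size = 15, n = 100, r = 0.8,
                  noise_feats = 15, seed = 5)
  # block-structured data need not be scale-free; the fallback warning is
  # expected here
  net <- suppressWarnings(
    coexpression_analysis(exp(d$x), d$trait, keep_frac = 1,
                          candidates = 1:10, min_size = 10))
  truth_lab <- rep("noise", nrow(d$x))
  names(truth_lab) <- rownames(d$x)
  for (b in names(d$blocks)) truth_lab[d$blocks[[b]]] <- b
  planted <- names(truth_lab)[truth_lab != "noise"]
  ari <- mclust::adjustedRandIndex(truth_lab[planted], net$labels[planted])
  expect_gte(ari, 0.9)
})

test_that("module size and merge rules are enforced", {
  d <- block_data(n_blocks = 1, block_size = 5, n = 40, r = 0.9,
                  noise_feats = 20, seed = 6)
  adj <- momdep:::soft_adjacency(d$x, 6)
  tom <- tom_similarity(adj); dimnames(tom) <- dimnames(adj)
  labels <- detect_modules(1 - tom, d$x, min_size = 10)
  expect_equal(unname(labels[d$blocks$b1]), rep("grey", 5))

  # merge_height = 0 leaves correlated modules separate
  d2 <- block_data(n_blocks = 2, block_size = 12, n = 60, r = 0.9, seed = 7)
  adj2 <- momdep:::soft_adjacency(d2$x, 6)
  tom2 <- tom_similarity(adj2); dimnames(tom2) <- dimnames(adj2)
  l0 <- detect_modules(1 - tom2, d2$x, min_size = 5, merge_height = 0)
  l1 <- detect_modules(1 - tom2, d2$x, min_size = 5, merge_height = 0.25)
  expect_gte(length(setdiff(unique(l0), "grey")),
             length(setdiff(unique(l1), "grey")))

  small <- matrix(runif(9), 3)
  expect_warning(detect_modules(small, min_size = 10), "min_size")
})

test_that("eigengenes summarize their module", {
  # identical features: eigengene equals the standardized common profile
  prof <- rnorm(30)
  x <- matrix(rep(prof, 4), 4, byrow = TRUE,
              dimnames = list(paste0("f", 1:4), paste0("s", 1:30)))
  labels <- setNames(rep("turquoise", 4), rownames(x))
  me <- module_eigengene(x, labels)
  expect_equal(unname(me[, 1]), as.numeric(scale(prof)), tolerance = 1e-6)
  expect_equal(stats::sd(me[, 1]), 1, tolerance = 1e-10)

  # planted one-factor block: eigengene tracks the factor
  set.seed(8)
  f <- rnorm(100)
  xb <- t(sapply(1:12, function(i) sqrt(0.8) * f + sqrt(0.2) * rnorm(100)))
  rownames(xb) <- paste0("g", 1:12); colnames(xb) <- paste0("s", 1:100)
  meb <- module_eigengene(xb, setNames(rep("blue", 12), rownames(xb)))
  expect_gt(abs(stats::cor(meb[, 1], f)), 0.9)

  # first PC explains more module variance than any single member
  z <- t(scale(t(xb)))
  var_expl <- function(v) sum(stats::cor(t(z), v)^2)
  expect_gte(var_expl(meb[, 1]) + 1e-8,
             max(sapply(seq_len(nrow(z)), function(i) var_expl(z[i, ]))))
})

test_that("MM/GS screen applies every criterion", {
  set.seed(9)
  n <- 49
  trait <- rep(0:1, length.out = n)
  f_hub <- trait + rnorm(n, 0, 0.4)
  x <- rbind(hub = f_hub,
             t(sapply(1:11, function(i) f_hub + rnorm(n, 0, 0.5))),
             noise = rnorm(n))
  rownames(x) <- c("hub", paste0("g", 1:11), "noise")
  colnames(x) <- paste0("s", 1:n)
  labels <- setNames(c(rep("turquoise", 12), "grey"), rownames(x))
  me <- module_eigengene(x, labels)
  scr <- mm_gs_screen(x, me, labels, trait)
  expect_true(scr$hub[scr$feature == "hub"])
  expect_false(scr$hub[scr$feature == "noise"])       # grey never hub
  expect_true(all(abs(scr$MM) <= 1, na.rm = TRUE))
  expect_true(all(scr$GS >= 0 & scr$GS <= 1, na.rm = TRUE))

  # feature identical to the trait: GS = 1, p ~ 0
  x2 <- rbind(x, tr_copy = trait)
  labels2 <- c(labels, tr_copy = "turquoise")
  scr2 <- mm_gs_screen(x2, me, labels2, trait)
  r <- scr2[scr2$feature == "tr_copy", ]
  expect_equal(r$GS, 1, tolerance = 1e-12)
  expect_lt(r$p_GS, 1e-12)

  expect_error(mm_gs_screen(x[, 1:3], me[1:3, , drop = FALSE],
                            labels, trait[1:3]), "samples")
})

test_that("correlation p transform matches the closed form", {
  # r = 0.7 at n = 49 gives t = 6.72 and p well below 1e-6
  p <- momdep:::cor_pval(0.7, 49)
  expect_lt(p, 1e-6)
  expect_equal(p, 2 * stats::pt(-0.7 * sqrt(47 / (1 - 0.49)), 47),
               tolerance = 1e-12)
})

test_that("hub screen is monotone in its thresholds", {
  set.seed(10)
  d <- block_data(n_blocks = 2, block_size = 12, n = 60, r = 0.8, seed = 10)
  adj <- momdep:::soft_adjacency(d$x, 5)
  tom <- tom_similarity(adj); dimnames(tom) <- dimnames(adj)
  labels <- detect_modules(1 - tom, d$x, min_size = 8)
  me <- module_eigengene(d$x, labels)
  loose <- mm_gs_screen(d$x, me, labels, d$trait, mm_min = 0.5, gs_min = 0.1)
  tight <- mm_gs_screen(d$x, me, labels, d$trait, mm_min = 0.8, gs_min = 0.3)
  expect_true(all(tight$hub <= loose$hub))
  # strict inequality at the boundary: MM exactly at the threshold fails
  expect_false(any(tight$hub & tight$MM <= 0.8))
})
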
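test_that("config validation enforces time ordering and probabilities", {
  expect_error(sim_config(t_wgd = 100, t_spec = 170), "t_wgd > t_spec")
  expect_error(sim_config(outgroup_times = c(Gar = 200, Shark = 465)),
               "predate")
  expect_error(sim_config(p_loss = 1.2), "probabilities")
})

test_that("block categories follow the rediploidization-time rule", {
  ## point mass just below the WGD: everything PreSpec (shared scenario)
  cfg_pre <- sim_config(prespec_fraction = 1, n_blocks = 20)
  t1 <- simulate_blocks(cfg_pre, seed = 1)
  expect_true(all(t1$families$category == "PreSpec"))
  expect_true(all(t1$blocks$r_shared > cfg_pre$t_spec, na.rm = TRUE))
  ## point mass near zero: everything PostSpec (independent-looking)
  cfg_post <- sim_config(prespec_fraction = 0, n_blocks = 20)
  t2 <- simulate_blocks(cfg_post, seed = 1)
  expect_true(all(t2$families$category == "PostSpec"))
  expect_true(all(t2$blocks$r_s < cfg_post$t_spec, na.rm = TRUE))
  ## uniform default: fraction near (t_wgd - t_spec) / t_wgd
  cfg_u <- sim_config(n_blocks = 500)
  t3 <- simulate_blocks(cfg_u, seed = 2)
  f_expect <- (cfg_u$t_wgd - cfg_u$t_spec) / cfg_u$t_wgd
  f_obs <- mean(t3$blocks$category == "PreSpec")
  se <- sqrt(f_expect * (1 - f_expect) / 500)
  expect_lt(abs(f_obs - f_expect), 3 * se)
})

test_that("simulated gene trees encode the true divergence times", {
  cfg <- sim_config(p_nni = 0)
  tr_fam <- data.frame(family_id = "famX", category = "PreSpec",
                       r_shared = 210, r_s = NA, r_p = NA,
                       s1 = "famX_S1", s2 = "famX_S2",
                       p1 = "famX_P1", p2 = "famX_P2")
  set.seed(1)
  g <- simulate_gene_tree(tr_fam, cfg)
  expect_false(g$flipped)
  qs <- quartet_subtree(g$tree, cfg$ingroup)
  expect_equal(classify_rooted_quartet(qs$subtree), "PreSpec")
  ## internal branch = ancestral rate x (r - t_spec)
  internal <- qs$subtree$edge.length[qs$subtree$edge[, 2] > 4]
  expect_equal(sort(internal), rep(cfg$rate_ancestral * (210 - 170), 2),
               tolerance = 1e-6)
  ## r near t_spec: internal branch near zero
  tr_fam$r_shared <- 170.001
  set.seed(1)
  g2 <- simulate_gene_tree(tr_fam, cfg)
  qs2 <- quartet_subtree(g2$tree, cfg$ingroup)
  expect_lt(max(qs2$subtree$edge.length[qs2$subtree$edge[, 2] > 4]), 1e-5)
})

test_that("without topology noise the classifier recovers all categories", {
  sim <- small_sim$data
  cfg <- small_sim$cfg
  cl <- classify_families(sim$trees, sim_species_tree(cfg), cfg$ingroup)
  expect_equal(cl$rooted_category, sim$truth$families$category)
  expect_false(any(sim$flipped))
})

test_that("topology noise concentrates near the speciation boundary", {
  cfg <- sim_config(p_nni = 0.3, n_blocks = 120)
  sim <- simulate_dataset(cfg, seed = 21)
  fam <- sim$truth$families
  near <- abs(ifelse(fam$category == "PreSpec", fam$r_shared,
                     pmax(fam$r_s, fam$r_p)) - cfg$t_spec) < 15
  expect_gt(mean(sim$flipped[near]), mean(sim$flipped[!near]))
  ## flipped trees classify as 'Other'
  cl <- classify_families(sim$trees[sim$flipped],
                          sim_species_tree(cfg), cfg$ingroup)
  expect_true(all(cl$rooted_category %in%
                    c("PreSpecLike", "PostSpecLike")))
})

test_that("sequence simulation responds to branch lengths as expected", {
  m <- subst_model()
  zero <- ape::read.tree(text = "((a:0,b:0):0,(c:0,d:0):0);")
  aln0 <- simulate_sequences(zero, 50, type = "aa", model = m, seed = 3)
  expect_true(all(aln0[1, ] == aln0[2, ]) && all(aln0[1, ] == aln0[4, ]))
  ## pairwise distance grows with path length
  set.seed(4)
  pdist <- function(t) {
    tr <- ape::read.tree(text = sprintf("(a:%f,b:%f);", t, t))
    a <- simulate_sequences(tr, 1000, type = "aa", model = m, alpha = Inf)
    mean(a[1, ] != a[2, ])
  }
  d <- vapply(c(0.01, 0.05, 0.2, 0.6), pdist, numeric(1))
  expect_true(all(diff(d) > 0))
  expect_error(simulate_sequences(zero, 0), "positive")
})

test_that("codon-mode distances track the synonymous branch scale", {
  cm <- codon_model()
  set.seed(9)
  tr <- ape::read.tree(text = "(a:0.06,b:0.06);")  # pair Ks expectation .12
  ks <- replicate(60, {
    s <- simulate_sequences(tr, 300, type = "codon", model = cm,
                            alpha = Inf)
    ks_ng86(s[["a"]], s[["b"]])$Ks
  })
  expect_equal(median(ks), 0.12, tolerance = 0.15 * 0.12)
})

test_that("observables implement loss and collapse as designed", {
  cfg0 <- sim_config(p_loss = 0, p_collapse = 0, n_blocks = 15)
  sim0 <- simulate_dataset(cfg0, seed = 31)
  expect_true(all(sim0$observables$status == "quartet"))
  expect_equal(bimodality_check(
    sim0$observables$depth$depth)$n_modes, 1L)
  cfg1 <- sim_config(p_loss = 0.2, p_collapse = 0.6, n_blocks = 60,
                     prespec_fraction = 0.3)
  sim1 <- simulate_dataset(cfg1, seed = 32)
  st <- sim1$observables$status
  expect_true(all(c("lost", "collapsed", "quartet") %in% st))
  d <- sim1$observables$depth
  ## collapsed genes sit near twice the depth of the others
  coll_genes <- d$depth[d$gene_id %in% paste0(
    names(st)[st == "collapsed"], "_P1")]
  expect_equal(mean(coll_genes) / cfg1$depth_mean, 2, tolerance = 0.1)
  ## lost families keep one paddlefish gene at single depth
  lost_ids <- names(st)[st == "lost"]
  lost_rows <- d[d$gene_id %in% c(paste0(lost_ids, "_P1"),
                                  paste0(lost_ids, "_P2")), ]
  expect_equal(nrow(lost_rows), length(lost_ids))
  expect_equal(mean(lost_rows$depth) / cfg1$depth_mean, 1,
               tolerance = 0.1)
  ## collapse only hits PostSpec families
  fam <- sim1$truth$families
  expect_true(all(fam$category[match(names(st)[st == "collapsed"],
                                     fam$family_id)] == "PostSpec"))
})

test_that("the generator is deterministic given config and seed", {
  cfg <- sim_config(n_blocks = 8)
  a <- simulate_dataset(cfg, seed = 99, codon_families = TRUE)
  b <- simulate_dataset(cfg, seed = 99, codon_families = TRUE)
  expect_identical(a$truth, b$truth)
  expect_identical(lapply(a$trees, ape::write.tree),
                   lapply(b$trees, ape::write.tree))
  expect_identical(a$cds, b$cds)
  expect_identical(a$observables, b$observables)
})
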
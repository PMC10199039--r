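toy_quartets <- function() {
  data.frame(family_id = c("f1", "f2"),
             rooted_category = c("PreSpec", "PostSpec"),
             s1 = c("f1_S1", "f2_S1"), s2 = c("f1_S2", "f2_S2"),
             p1 = c("f1_P1", "f2_P1"), p2 = c("f1_P2", "f2_P2"))
}

toy_coords <- function() {
  g <- c(t(outer(c("f1", "f2"), c("_S1", "_S2", "_P1", "_P2"), paste0)))
  data.frame(gene_id = g,
             species = rep(rep(c("Sturgeon", "Paddlefish"), each = 2), 2),
             chrom = rep(c("chr01", "chr02"), 4),
             start = rep(c(0, 0, 0, 0, 5e4, 5e4, 5e4, 5e4)),
             end = rep(c(1e4, 1e4, 1e4, 1e4, 6e4, 6e4, 6e4, 6e4)))
}

test_that("link multiplicities follow the mode rules", {
  q <- toy_quartets(); co <- toy_coords()
  intra <- build_links(q, co, mode = "intra")
  expect_equal(nrow(intra), 4L)          # one per species per family
  inter <- build_links(q, co, mode = "inter")
  expect_equal(nrow(inter), 2L)          # PreSpec family only, 2 links
  expect_true(all(inter$family_id == "f1"))
  comb <- build_links(q, co, mode = "combined")
  expect_equal(nrow(comb), 4L)           # 2 intra (PostSpec) + 2 inter
  expect_equal(sum(comb$scope == "inter"), 2L)
  expect_equal(sum(comb$scope == "intra" & comb$category == "PostSpec"), 2L)
  ## anchors are midpoints
  expect_equal(intra$pos_a[1], 5e3)
})

test_that("total links are conserved across a simulated classification", {
  sim <- small_sim$data
  cfg <- small_sim$cfg
  cl <- classify_families(sim$trees, sim_species_tree(cfg), cfg$ingroup)
  roles <- t(vapply(names(sim$trees), function(f)
    quartet_gene_roles(sim$trees[[f]], cfg$ingroup), character(4)))
  q <- data.frame(family_id = names(sim$trees),
                  rooted_category = cl$rooted_category,
                  s1 = roles[, "s1"], s2 = roles[, "s2"],
                  p1 = roles[, "p1"], p2 = roles[, "p2"])
  links <- build_links(q, sim$truth$coords, mode = "intra")
  n_classified <- sum(!is.na(cl$rooted_category) &
                        cl$rooted_category != "unresolved")
  expect_equal(nrow(links), 2L * n_classified)
  n_pre <- sum(cl$rooted_category == "PreSpec", na.rm = TRUE)
  comb <- build_links(q, sim$truth$coords, mode = "combined")
  expect_equal(nrow(comb), 2L * (n_classified - n_pre) + 2L * n_pre)
})

test_that("block detection recovers simulated category runs exactly", {
  sim <- small_sim$data
  cfg <- small_sim$cfg
  cl <- classify_families(sim$trees, sim_species_tree(cfg), cfg$ingroup)
  roles <- t(vapply(names(sim$trees), function(f)
    quartet_gene_roles(sim$trees[[f]], cfg$ingroup), character(4)))
  q <- data.frame(family_id = names(sim$trees),
                  rooted_category = cl$rooted_category,
                  s1 = roles[, "s1"], s2 = roles[, "s2"],
                  p1 = roles[, "p1"], p2 = roles[, "p2"])
  links <- build_links(q, sim$truth$coords, mode = "intra")
  got <- detect_blocks(links, min_genes = 1, max_gap = 0)
  got_s <- got[got$species_a == cfg$ingroup[1], ]
  ## ground truth: category runs of consecutive families per chromosome pair
  fam <- sim$truth$families
  fam$pair <- sim$truth$blocks$chrom_pair[match(fam$block_id,
                                                sim$truth$blocks$block_id)]
  truth_runs <- do.call(rbind, lapply(split(fam, fam$pair), function(g) {
    r <- rle(g$category)
    data.frame(category = r$values, n = r$lengths)
  }))
  expect_equal(nrow(got_s), nrow(truth_runs))
  expect_equal(sort(got_s$n_genes), sort(truth_runs$n))
  expect_equal(table(got_s$category)[sort(unique(got_s$category))],
               table(truth_runs$category)[sort(unique(truth_runs$category))])
})

test_that("block calling tolerates gaps as configured and sorts internally", {
  pos <- seq(0, 9e5, by = 1e5)
  links <- data.frame(
    family_id = paste0("f", 1:10),
    category = rep(c("PreSpec", "PostSpec"), 5),
    scope = "intra", species_a = "S", chrom_a = "chr01",
    pos_a = pos, gene_a = paste0("g", 1:10),
    species_b = "S", chrom_b = "chr02", pos_b = pos,
    gene_b = paste0("h", 1:10))
  ## alternating categories, no gap tolerance: no block of >= 2
  b0 <- detect_blocks(links, min_genes = 2, max_gap = 0)
  expect_equal(nrow(b0), 0L)
  ## with max_gap 1 each category forms one run of 5
  b1 <- detect_blocks(links, min_genes = 2, max_gap = 1)
  expect_equal(sort(b1$n_genes), c(5L, 5L))
  ## single run of 10 same-category links: one block of 10
  links$category <- "PreSpec"
  b2 <- detect_blocks(links, min_genes = 3, max_gap = 1)
  expect_equal(b2$n_genes, 10L)
  ## order invariance
  shuf <- links[sample(nrow(links)), ]
  expect_equal(detect_blocks(shuf, min_genes = 3, max_gap = 1), b2)
})

test_that("clustering permutation test is calibrated and catches sorting", {
  sorted <- rep(c("PreSpec", "PostSpec"), each = 20)
  r <- clustering_permutation_test(sorted, n_perm = 1000, seed = 2)
  expect_lte(r$p_value, 0.01)
  expect_equal(clustering_permutation_test("PreSpec")$p_value, 1)
  expect_equal(clustering_permutation_test(rep("A", 10))$p_value, 1)
  ## uniform null: p approximately uniform (mean near .5, few extremes)
  set.seed(33)
  ps <- replicate(60, clustering_permutation_test(
    sample(c("A", "B"), 24, replace = TRUE), n_perm = 199)$p_value)
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps < 0.05), 0.15)
  ## reproducible under a fixed seed
  x <- sample(c("A", "B"), 30, replace = TRUE)
  expect_identical(clustering_permutation_test(x, 500, seed = 9),
                   clustering_permutation_test(x, 500, seed = 9))
})

test_that("circos writers emit well-formed link and karyotype lines", {
  q <- toy_quartets(); co <- toy_coords()
  links <- build_links(q, co, mode = "intra")
  lf <- tempfile(); kf <- tempfile()
  write_circos(links, lf, kf)
  ll <- readLines(lf)
  expect_length(ll, nrow(links))
  expect_true(all(grepl("^\\S+ \\d+ \\d+ \\S+ \\d+ \\d+ color=", ll)))
  kl <- readLines(kf)
  expect_true(all(grepl("^chr - ", kl)))
  unlink(c(lf, kf))
})
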
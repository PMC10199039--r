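sp13 <- default_species_tree()
rank13 <- species_ranking(sp13)

test_that("species ranking puts chondrichthyans farthest from the focal pair", {
  expect_true(all(rank13[c("GhostShark", "WhaleShark")] <
                    rank13[c("Human", "Frog")]))
  expect_true(all(rank13[c("Human", "Frog")] < rank13["Bichir"]))
  expect_true(all(rank13["Bichir"] < rank13[c("Zebrafish", "SpottedGar")]))
  expect_true(all(is.infinite(rank13[c("Sturgeon", "Paddlefish")])))
})

test_that("rooting picks the most distant leaf, ties broken by gene id", {
  tr <- qt(paste0("(Human|h,(GhostShark|g2,(GhostShark|g1,",
                  "((Sturgeon|a,Paddlefish|a),(Sturgeon|b,Paddlefish|b)))));"))
  r <- root_by_most_distant_outgroup(tr, rank13)
  root_children <- r$edge[r$edge[, 1] == length(r$tip.label) + 1L, 2]
  basal <- r$tip.label[root_children[root_children <= length(r$tip.label)]]
  expect_equal(basal, "GhostShark|g1")
  ## swapped ids flip the choice
  tr2 <- tr
  tr2$tip.label[tr2$tip.label == "GhostShark|g1"] <- "GhostShark|tmp"
  tr2$tip.label[tr2$tip.label == "GhostShark|g2"] <- "GhostShark|g1"
  tr2$tip.label[tr2$tip.label == "GhostShark|tmp"] <- "GhostShark|g2"
  r2 <- root_by_most_distant_outgroup(tr2, rank13)
  rc <- r2$edge[r2$edge[, 1] == length(r2$tip.label) + 1L, 2]
  expect_equal(r2$tip.label[rc[rc <= length(r2$tip.label)]], "GhostShark|g1")
  ## idempotence
  expect_identical(ape::write.tree(root_by_most_distant_outgroup(r, rank13)),
                   ape::write.tree(r))
  ## no outgroup
  expect_error(root_by_most_distant_outgroup(
    qt("((Sturgeon|a,Paddlefish|a),(Sturgeon|b,Paddlefish|b));"), rank13),
    "no outgroup")
})

test_that("is_clan agrees with a brute-force bipartition oracle", {
  brute_is_clan <- function(tree, leaves) {
    u <- ape::unroot(tree)
    target <- sort(leaves)
    parts <- ape::prop.part(u)
    all_tips <- u$tip.label
    for (p in parts) {
      s <- sort(all_tips[p])
      if (identical(s, target) ||
          identical(sort(setdiff(all_tips, s)), target)) return(TRUE)
    }
    length(leaves) %in% c(1L, length(all_tips) - 1L)
  }
  set.seed(17)
  labs <- paste0("sp", 1:8, "|g")
  for (i in 1:20) {
    tr <- random_tree(labs)
    k <- sample(1:7, 1)
    leaves <- sample(labs, k)
    expect_equal(is_clan(tr, leaves), brute_is_clan(tr, leaves),
                 info = ape::write.tree(tr))
  }
  tr <- random_tree(labs)
  expect_true(is_clan(tr, labs[1]))
  expect_error(is_clan(tr, character(0)), "subset")
  expect_error(is_clan(tr, labs), "subset")
})

test_that("strict reconciliation labels the expected duplication nodes", {
  ## shared duplication: root of the quartet is a duplication
  pre <- qt("((Sturgeon|a,Paddlefish|a),(Sturgeon|b,Paddlefish|b));")
  rc <- reconcile(pre, sp13)
  ev <- rc$event[!is.na(rc$event)]
  expect_equal(sum(ev == "duplication"), 1L)
  ntip <- 4L
  expect_equal(rc$event[ntip + 1L], "duplication")  # quartet root
  ## independent duplications: two, one per terminal lineage
  post <- qt("((Sturgeon|a,Sturgeon|b),(Paddlefish|a,Paddlefish|b));")
  rc2 <- reconcile(post, sp13)
  expect_equal(sum(rc2$event == "duplication", na.rm = TRUE), 2L)
  expect_equal(rc2$event[ntip + 1L], "speciation")
  ## a species tree as its own gene tree: all speciations
  sp_as_gene <- sp13
  sp_as_gene$tip.label <- make_leaf_label(sp13$tip.label, "g")
  rc3 <- reconcile(sp_as_gene, sp13)
  expect_false(any(rc3$event == "duplication", na.rm = TRUE))
  expect_error(reconcile(qt("((Martian|x,Sturgeon|a),Paddlefish|b);"), sp13),
               "missing")
})

test_that("reconciliation recovers simulated event labels without noise", {
  sim <- small_sim$data
  sptr <- sim_species_tree(small_sim$cfg)
  fam <- sim$truth$families
  for (i in seq_len(8)) {
    tr <- sim$trees[[fam$family_id[i]]]
    rc <- reconcile(tr, sptr)
    n_dup <- sum(rc$event == "duplication", na.rm = TRUE)
    expect_equal(n_dup, if (fam$category[i] == "PreSpec") 1L else 2L,
                 info = fam$family_id[i])
  }
})

test_that("PHOG extraction walks to the highest clean ancestor", {
  ## 2+2 only: whole tree
  tr <- qt(paste0("(((Sturgeon|a,Paddlefish|a),(Sturgeon|b,Paddlefish|b)),",
                  "(Gar|g,Shark|s));"))
  expect_equal(extract_phog_quartet(tr),
               list(sort(tr$tip.label)))
  ## extra sturgeon paralog outside: stop below its join point
  tr2 <- qt(paste0("(((((Sturgeon|a,Paddlefish|a),(Sturgeon|b,Paddlefish|b)),",
                   "Gar|g),Sturgeon|x),Shark|s);"))
  got <- extract_phog_quartet(tr2)
  expect_length(got, 1)
  expect_setdiff <- setdiff(got[[1]], c("Sturgeon|a", "Sturgeon|b",
                                        "Paddlefish|a", "Paddlefish|b",
                                        "Gar|g"))
  expect_length(expect_setdiff, 0)
  expect_false("Sturgeon|x" %in% got[[1]])
  expect_true("Gar|g" %in% got[[1]])
  ## deeper duplication retaining 2+2 in both copies: two disjoint sets
  tr3 <- qt(paste0("((((Sturgeon|a1,Paddlefish|a1),(Sturgeon|b1,Paddlefish|b1)),",
                   "Gar|g1),(((Sturgeon|a2,Paddlefish|a2),",
                   "(Sturgeon|b2,Paddlefish|b2)),Gar|g2));"))
  got3 <- extract_phog_quartet(tr3)
  expect_length(got3, 2)
  expect_length(intersect(got3[[1]], got3[[2]]), 0)
})

test_that("family filters assign independent reason codes", {
  coords <- data.frame(
    gene_id = c("s1", "s2", "p1", "p2"),
    species = c("Sturgeon", "Sturgeon", "Paddlefish", "Paddlefish"),
    chrom = c("chr05", "chr05", "chr01", "chr02"),
    start = 0, end = 100)
  placed <- list(Sturgeon = paste0("chr0", 1:6),
                 Paddlefish = paste0("chr0", 1:6))
  tr <- qt(paste0("(((Sturgeon|s1,Paddlefish|p1),(Sturgeon|s2,Paddlefish|p2)),",
                  "Gar|g);"))
  f <- apply_family_filters("famX", tr, coords, placed)
  expect_false(f$pass)
  expect_equal(f$reasons, "same_chromosome")
  coords2 <- coords; coords2$chrom <- c("chr01", "chr02", "chr03", "chr04")
  expect_true(apply_family_filters("famX", tr, coords2, placed)$pass)
  coords3 <- coords2; coords3$chrom[3] <- "scaffold_991"
  expect_equal(apply_family_filters("famX", tr, coords3, placed)$reasons,
               "unplaced_scaffold")
  ## no outgroup + non-clan quartet
  tr_no_og <- qt("((Sturgeon|s1,Paddlefish|p1),(Sturgeon|s2,Paddlefish|p2));")
  expect_true("no_outgroup" %in%
                apply_family_filters("f", tr_no_og, coords2, placed)$reasons)
  tr_nc <- qt(paste0("(((Sturgeon|s1,Paddlefish|p1),Gar|g1),",
                     "((Sturgeon|s2,Paddlefish|p2),Gar|g2));"))
  expect_true("not_clan" %in%
                apply_family_filters("f", tr_nc, coords2, placed)$reasons)
  expect_error(apply_family_filters("f", tr,
                                    coords[1:3, ], placed), "missing")
})

test_that("support filtering is a min rule and monotone in the cutoff", {
  expect_true(support_filter(c(100, 100), 100))
  expect_false(support_filter(c(94, 100), 95))
  expect_error(support_filter(c(NA, 100), 50, na_action = "error"),
               "missing")
  expect_false(support_filter(c(NA, 100), 50))  # NA treated as zero
  ## monotone retained sets on a simulated batch
  sim <- simulate_dataset(sim_config(n_blocks = 12), seed = 5)
  cl <- classify_families(sim$trees, sim_species_tree(sim_config()),
                          c("Sturgeon", "Paddlefish"))
  prev <- rep(TRUE, nrow(cl))
  for (co in seq(0, 100, by = 5)) {
    now <- cl$support_min >= co
    expect_true(all(now <= prev))   # nested: retained set shrinks
    prev <- now
  }
})

test_that("fold deviations match the printed-count arithmetic", {
  expect_equal(unname(fold_deviation(c(PostSpec = 1, PreSpec = 2,
                                       Other = 12))), c(1, 1, 1))
  fd <- fold_deviation(c(PostSpec = 2074, PreSpec = 1448, Other = 1917))
  expect_equal(round(unname(fd), 3), c(5.719, 1.997, 0.441),
               tolerance = 1e-3)
  expect_error(fold_deviation(c(PostSpec = 0, PreSpec = 0, Other = 0)),
               "positive")
})

test_that("clade recovery distinguishes true, false, and not-evaluable", {
  tr <- qt(paste0("((GhostShark|g,WhaleShark|w),((Human|h,(Chicken|c,Frog|f)),",
                  "((Sturgeon|a,Paddlefish|a),(Fugu|u,Zebrafish|z))));"))
  expect_true(clade_recovery(tr, c("Human", "Chicken", "Frog")))
  expect_true(clade_recovery(tr, c("Fugu", "Zebrafish")))
  expect_true(is.na(clade_recovery(tr, c("Human", "Chicken", "Coelacanth"))))
  tr_bad <- qt(paste0("((Fugu|u,GhostShark|g),((Zebrafish|z,WhaleShark|w),",
                      "(Sturgeon|a,Paddlefish|a)));"))
  expect_false(clade_recovery(tr_bad, c("Fugu", "Zebrafish")))
})

test_that("paired branch-length comparison filters and tests correctly", {
  expect_equal(compare_paired_branch_lengths(rep(0.05, 10),
                                             rep(0.05, 10))$p_value, 1)
  set.seed(3)
  s <- runif(50, 0.02, 0.1)
  r <- compare_paired_branch_lengths(s, s + 0.02)
  expect_lt(r$p_value, 0.001)
  expect_gt(r$medians[["paddlefish"]], r$medians[["sturgeon"]])
  ## outlier pair removed before testing
  r2 <- compare_paired_branch_lengths(c(0.2, s), c(0.01, s + 0.02))
  expect_equal(r2$n_used, 50L)
  expect_error(compare_paired_branch_lengths(0.2, 0.3), "removed")
})
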
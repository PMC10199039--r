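aaq <- function() {
  set.seed(31)
  tr <- ape::read.tree(text = paste0(
    "((Sturgeon|a:0.08,Paddlefish|a:0.1):0.03,",
    "(Sturgeon|b:0.08,Paddlefish|b:0.1):0.03);"))
  simulate_sequences(tr, 300, type = "aa", alpha = 1)
}

test_that("pruning equals exhaustive state summation on short alignments", {
  m <- subst_model()
  labs <- c("Sturgeon|a", "Sturgeon|b", "Paddlefish|a", "Paddlefish|b")
  set.seed(19)
  for (rep in 1:3) {
    L <- sample(1:3, 1)
    aln <- matrix(sample(m$states, 4 * L, replace = TRUE), 4, L,
                  dimnames = list(labs, NULL))
    tp <- quartet_topologies(labs)[[sample(3, 1)]]
    b <- runif(5, 0.01, 0.4)
    alpha <- runif(1, 0.3, 2)
    mine <- site_log_likelihoods(aln, tp, m, alpha = alpha,
                                 optimize_branches = FALSE,
                                 branch_lengths = b)
    rates <- gamma_rates(alpha, 4)
    oracle <- vapply(seq_len(L), function(s) {
      st <- match(aln[c(tp$pair1, tp$pair2), s], m$states)
      tot <- 0
      for (r in rates) {
        P <- lapply(b, function(bb) transition_matrix(m, bb * r))
        acc <- 0
        for (x in 1:20) for (y in 1:20)
          acc <- acc + m$freqs[x] * P[[1]][x, st[1]] * P[[2]][x, st[2]] *
            P[[5]][x, y] * P[[3]][y, st[3]] * P[[4]][y, st[4]]
        tot <- tot + acc / 4
      }
      log(tot)
    }, numeric(1))
    expect_equal(as.numeric(mine), oracle, tolerance = 1e-8)
  }
})

test_that("total likelihood matches an independent implementation", {
  aln <- aaq()
  m <- subst_model()
  tp <- quartet_topologies(rownames(aln))[[2]]
  b <- c(0.05, 0.07, 0.06, 0.09, 0.02)
  mine <- site_log_likelihoods(aln, tp, m, alpha = 0.8,
                               optimize_branches = FALSE,
                               branch_lengths = b)
  nwk <- sprintf("((%s:%f,%s:%f):%f,(%s:%f,%s:%f):0);",
                 tp$pair1[1], b[1], tp$pair1[2], b[2], b[5],
                 tp$pair2[1], b[3], tp$pair2[2], b[4])
  fit <- phangorn::pml(ape::read.tree(text = nwk),
                       phangorn::phyDat(aln, type = "AA"),
                       model = "JTT", k = 4, shape = 0.8)
  expect_equal(attr(mine, "logLik"), as.numeric(stats::logLik(fit)),
               tolerance = 1e-8)
})

test_that("identical sequences give equal likelihoods across topologies", {
  labs <- c("Sturgeon|a", "Sturgeon|b", "Paddlefish|a", "Paddlefish|b")
  aln <- matrix("A", 4, 50, dimnames = list(labs, NULL))
  sll <- quartet_site_likelihoods(aln)
  tot <- attr(sll, "logLik")
  expect_equal(max(tot) - min(tot), 0, tolerance = 1e-4)
})

test_that("the generating topology attains the highest likelihood", {
  aln <- aaq()
  sll <- quartet_site_likelihoods(aln)
  tot <- attr(sll, "logLik")
  expect_equal(names(which.max(tot)), "PreSpecType1")
})

test_that("AU p-values behave at the degenerate corners", {
  ## one topology uniformly best at every site
  L <- 60
  sll <- cbind(T1 = rep(-1, L), T2 = rep(-2, L), T3 = rep(-3, L))
  res <- au_test(sll, B = 200, seed = 4)
  expect_equal(res$p_au[res$topology == "T1"], 1)
  expect_equal(res$p_au[res$topology == "T2"], 0)
  expect_true(all(res$p_au >= 0 & res$p_au <= 1))
  ## all-equal site likelihoods: nothing distinguishable
  res2 <- au_test(cbind(A = rep(-1, L), B = rep(-1, L)), B = 100, seed = 1)
  expect_equal(res2$p_au, c(1, 1))
  ## identical vectors get identical p even with a third distinct one
  set.seed(12)
  v <- rnorm(L, -2, 1)
  res3 <- au_test(cbind(A = v, B = v, C = v + rnorm(L, 0.02, 0.3)),
                  B = 300, seed = 5)
  expect_equal(res3$p_au[1], res3$p_au[2])
  expect_error(au_test(sll[1:5, ]), "10 sites")
})

test_that("more replicates shrink the Monte-Carlo spread of p", {
  aln <- aaq()
  sll <- quartet_site_likelihoods(aln)
  spread <- function(B) {
    p <- vapply(1:6, function(s)
      au_test(sll, B = B, seed = s)$p_au[1], numeric(1))
    stats::sd(p)
  }
  expect_lt(spread(1000), spread(100) + 0.02)
})

test_that("rejection summaries equal direct counting", {
  res <- data.frame(
    rooted_category = c("PreSpec", "PreSpec", "PostSpec", "PreSpecLike"),
    p_prespec_type = c(0.9, 0.8, 0.01, 0.5),
    p_postspec_type = c(0.01, 0.2, 0.95, 0.04))
  sm <- summarize_rejections(res, alpha = 0.05)
  pre <- sm[sm$rooted_category == "PreSpec", ]
  expect_equal(pre$reject_alternative, 0.5)   # one of two p_post < .05
  expect_equal(pre$reject_matching, 0)
  post <- sm[sm$rooted_category == "PostSpec", ]
  expect_equal(post$reject_alternative, 1)
  like <- sm[sm$rooted_category == "PreSpecLike", ]
  expect_equal(like$reject_alternative, 1)
  ## all p = 1: no rejections anywhere
  res1 <- res; res1$p_prespec_type <- 1; res1$p_postspec_type <- 1
  sm1 <- summarize_rejections(res1)
  expect_true(all(sm1$reject_alternative == 0 & sm1$reject_matching == 0))
})
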
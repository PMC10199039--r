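## Shared fixtures: tiny labelled quartets and small simulated datasets.

q_labels <- c("Sturgeon|a", "Sturgeon|b", "Paddlefish|a", "Paddlefish|b")

qt <- function(nwk) ape::read.tree(text = nwk)

## a small noise-free simulated dataset reused across tests
small_sim <- local({
  cfg <- sim_config(p_nni = 0, p_loss = 0, p_collapse = 0,
                    n_blocks = 10, genes_per_block = c(4, 6))
  list(cfg = cfg, data = simulate_dataset(cfg, seed = 71))
})

## random rooted gene-tree-ish topology over given labels (for clan tests)
random_tree <- function(labels) {
  ape::rtree(length(labels), tip.label = sample(labels))
}
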
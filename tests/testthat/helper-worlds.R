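# Small worlds shared across test files.

# A world whose network is a single signed edge g001 -> g002.
single_edge_world <- function(weight = 1, noise_sd = 0.1, seed = 1L) {
  net <- directed_edge_set(
    data.frame(regulator = "g001", target = "g002",
               sign = if (weight >= 0) "+" else "-"),
    regulators = "g001", universe = c("g001", "g002"))
  net$edges$weight <- weight
  synthetic_world(net, noise_sd = noise_sd, seed = seed)
}

# A chain a -> b -> c with unit weights.
chain_world <- function(noise_sd = 0.3, seed = 1L) {
  net <- directed_edge_set(
    data.frame(regulator = c("g001", "g002"), target = c("g002", "g003"),
               sign = "+"),
    regulators = c("g001", "g002"), universe = c("g001", "g002", "g003"))
  net$edges$weight <- c(1, 1)
  synthetic_world(net, noise_sd = noise_sd, seed = seed)
}

# A collider a -> c <- b with a and b marginally independent.
collider_world <- function(noise_sd = 0.3, seed = 1L) {
  net <- directed_edge_set(
    data.frame(regulator = c("g001", "g002"), target = c("g003", "g003"),
               sign = "+"),
    regulators = c("g001", "g002"), universe = c("g001", "g002", "g003"))
  net$edges$weight <- c(1, 1)
  synthetic_world(net, noise_sd = noise_sd, seed = seed)
}

# A world with no edges at all.
edgeless_world <- function(n_genes = 10, noise_sd = 0.5, seed = 1L) {
  synthetic_world(generate_true_network(n_genes, 2, 0, seed = seed),
                  noise_sd = noise_sd, seed = seed)
}
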
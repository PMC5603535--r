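# Shared fixtures, built in code. Generated networks and fitted pipelines
# are cached per seed so the slower protocol tests can share them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# desk-scale pipeline configuration used for the 50x40 synthetic benchmark
desk_cfg <- function(seed = 0L, ...) {
  pipeline_config(dim_drug = 20L, dim_protein = 20L, k = 10L, lambda = 1,
                  iters = 60L, seed = seed, ...)
}

synth_fixture <- function(seed = 0L) {
  cached(paste0("synth", seed), generate_network(synth_config(seed = seed)))
}

# a tiny hand-built heterogeneous network: 3 drugs, 2 proteins,
# 2 diseases, 2 side-effects
toy_network <- function() {
  hetero_network(
    drugs = c("D1", "D2", "D3"),
    proteins = c("P1", "P2"),
    diseases = c("Z1", "Z2"),
    side_effects = c("S1", "S2"),
    relations = list(
      drug_protein = matrix(c(1, 0, 0,
                              0, 1, 1), 3, 2),
      drug_drug = matrix(c(0, 1, 0,
                           1, 0, 1,
                           0, 1, 0), 3, 3),
      protein_protein = matrix(c(0, 1,
                                 1, 0), 2, 2),
      drug_disease = matrix(c(1, 0, 1,
                              0, 1, 0), 3, 2),
      drug_side_effect = matrix(c(1, 1, 0,
                                  0, 0, 1), 3, 2),
      protein_disease = matrix(c(1, 0,
                                 0, 1), 2, 2)))
}

# write a network directory by hand (independent of write_network) for
# reader tests
write_toy_dir <- function(dir, extra_edges = character(0),
                          drop_drug3 = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(f, lines) writeLines(lines, file.path(dir, f))
  w("drug.tsv", c("id", "D1", "D2", "D3"))
  w("protein.tsv", c("id", "P1", "P2"))
  w("disease.tsv", c("id", "Z1", "Z2"))
  w("side_effect.tsv", c("id", "S1", "S2"))
  w("drug_protein.tsv", c("D1\tP1", "D2\tP2"))
  dd <- c("D1\tD2")
  if (!drop_drug3) dd <- c(dd, "D2\tD3")
  w("drug_drug.tsv", c(dd, extra_edges))
  w("protein_protein.tsv", "P1\tP2")
  w("drug_disease.tsv", c("D1\tZ1", "D2\tZ2"))
  w("drug_side_effect.tsv", c("D1\tS1", "D2\tS2"))
  w("protein_disease.tsv", c("P1\tZ1", "P2\tZ2"))
  dir
}

# dense random row-stochastic-ready nonnegative matrix
rand_net <- function(n, seed, density = 0.5) {
  set.seed(seed)
  A <- matrix(stats::runif(n * n), n, n) * (matrix(stats::runif(n * n),
                                                   n, n) < density)
  diag(A) <- 0
  A
}

rwr_closed_form <- function(W, p) {
  p * solve(diag(nrow(W)) - (1 - p) * W)
}
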
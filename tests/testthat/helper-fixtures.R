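# Shared fixture builders; everything generated in code at test time.

# random open polyline with n vertices
random_polyline <- function(n, seed) {
  set.seed(seed)
  cbind(cumsum(runif(n, 0.2, 1)), rnorm(n))
}

# ultrametric caterpillar (maximally imbalanced) clock tree with n tips,
# every tip at depth n - 1
ladder_tree <- function(n) {
  nwk <- "(t1:1,t2:1)"
  for (i in 3:n) {
    nwk <- sprintf("(%s:1,t%d:%d)", nwk, i, i - 1)
  }
  parse_newick(paste0(nwk, ";"))
}

# balanced ultrametric tree with unit branches
balanced_tree <- function(n) {
  tr <- ape::stree(n, "balanced")
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

star_tree <- function(n, depth = 1) {
  tr <- ape::stree(n, "star")
  tr$edge.length <- rep(depth, n)
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

random_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rphylo(n, birth = 1, death = 0)
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

# resampled profile curves for an interclavicular-angle-only sweep
angle_sweep_curves <- function(angles, n_points = 100) {
  lapply(seq_along(angles), function(i) {
    cv <- make_furcula_outline(
      furcula_params(angles[i], 0.4, 0.05, 0, 0.4), "profile",
      specimen_id = sprintf("s%02d", i))
    resample_equal_arclength(orient_standard(cv), n_points)
  })
}

write_tps_fixture <- function(text) {
  path <- tempfile(fileext = ".tps")
  writeLines(text, path)
  path
}
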
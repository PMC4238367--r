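test_that("pruning removes exactly the no-neuron incident links", {
  links <- data.frame(a = c(1, 1, 2, 3), b = c(2, 3, 3, 4), C_P = 1)
  # all nodes have neurons: unchanged
  out <- prune_no_neuron_nodes(links, rep(1L, 4))
  expect_equal(nrow(out$links), 4)
  expect_equal(out$removed_links, 0)
  # star graph whose hub (node 1) has no neuron
  star <- data.frame(a = c(1, 1, 1), b = c(2, 3, 4), C_P = 1)
  out2 <- prune_no_neuron_nodes(star, c(0L, 1L, 1L, 1L))
  expect_equal(nrow(out2$links), 0)
  expect_equal(out2$removed_links, 3)
  expect_equal(out2$removed_nodes, 1)
})

test_that("pruned link count equals the incident-edge oracle", {
  set.seed(30)
  for (rep in 1:10) {
    n <- 12
    pr <- utils::combn(n, 2)
    keep <- sample(ncol(pr), 25)
    links <- data.frame(a = pr[1, keep], b = pr[2, keep])
    nmap <- rbinom(n, 1, 0.7)
    out <- prune_no_neuron_nodes(links, nmap)
    oracle <- sum(nmap[links$a] == 0 | nmap[links$b] == 0)
    expect_equal(out$removed_links, oracle)
    expect_equal(nrow(out$links), 25 - oracle)
  }
})

test_that("pruning demands a total neuron map", {
  links <- data.frame(a = 1, b = 9)
  expect_error(prune_no_neuron_nodes(links, rep(1L, 4)), "cover")
  expect_error(prune_no_neuron_nodes(links, c(1L, rep(NA, 8L))), "missing")
})

test_that("reweighting follows the power law in the structural distance", {
  expect_equal(reweight(1, 0.7), 1)
  expect_equal(reweight(0.5, 1), 0.25)
  expect_equal(reweight(0.8, 0.5), 0.8^1.5)
  expect_equal(reweight(0.8, 0), 0.8)
  expect_error(reweight(1.2, 0.5), "cp_tilde")
  expect_error(reweight(0.5, -0.1), "d_norm")
})

test_that("reweighting penalises weak links more strongly with distance", {
  cp <- seq(0.05, 0.95, by = 0.05)
  for (d in c(0.2, 0.5, 1)) {
    w <- reweight(cp, rep(d, length(cp)))
    expect_true(all(w <= cp + 1e-12))
    # relative penalty W / C_P increases with C_P at fixed d > 0
    expect_true(all(diff(w / cp) > 0))
    # contrast: a negative-exponential weighting has constant relative
    # penalty, so it penalises high correlations comparatively more
    w_exp <- cp * exp(-d)
    expect_equal(diff((w_exp / cp)), rep(0, length(cp) - 1))
  }
  # equality cases: W = C_P iff d = 0 or C_P in {0, 1}
  expect_equal(reweight(c(0, 1), c(0.6, 0.6)), c(0, 1))
  expect_lt(reweight(0.5, 1e-6), 0.5)
})

test_that("reweighting is monotone in both arguments", {
  d <- seq(0, 1, by = 0.1)
  for (cp in c(0.2, 0.6, 0.9)) {
    expect_true(all(diff(reweight(rep(cp, 11), d)) < 0))
  }
  cp <- seq(0.1, 1, by = 0.1)
  for (dd in c(0, 0.4, 1)) {
    expect_true(all(diff(reweight(cp, rep(dd, 10))) > 0))
  }
})

test_that("accounting reproduces the derived percentages from raw counts", {
  r1 <- accounting(fc_initial = 4085, fc_above_cs = 1294,
                   fc_pruned = 3187, fc_pruned_above_cs = 1041,
                   fc_final = 553)
  expect_equal(r1$discarded_at_cs, 2791)
  expect_equal(r1$pct_discarded_at_cs, 68.3)
  expect_equal(r1$pruning_reduction_pct, 22)
  expect_equal(r1$discarded_final, 3532)
  expect_equal(r1$pct_discarded_final, 86.5)
  # printed discarded counts supplied directly (summary tables print the
  # discarded column, which need not tally with the retained column)
  r2 <- accounting(fc_initial = 16290, fc_above_cs = 9788,
                   fc_pruned = 10296, fc_pruned_above_cs = 6258,
                   fc_final = 2654, discarded_at_cs = 6052,
                   discarded_final = 13636)
  # 6052 / 16290 = 37.15%: one-decimal rounding gives 37.2
  expect_equal(r2$pct_discarded_at_cs, 37.2)
  expect_equal(r2$pruning_reduction_pct, 37)
  expect_equal(r2$pct_discarded_final, 83.7)
  # derived counts when only the retained column is given
  expect_equal(accounting(16290, fc_above_cs = 9788)$discarded_at_cs, 6502)
  # zero discarded
  r3 <- accounting(fc_initial = 10, fc_final = 10)
  expect_equal(r3$pct_discarded_final, 0.0)
  # internal consistency contract
  expect_error(accounting(fc_initial = 5, fc_above_cs = 6))
})

test_that("refinement thresholds and labels behave on a synthetic network", {
  set.seed(31)
  g <- electrode_grid(8, 8, pixels_per_um = 12 / 42)
  net <- generate_network(30, g, seed = 7)
  img <- render_image(net, noise_level = 0)
  spk <- simulate_spikes(net, T_s = 120, n_noise_electrodes = 5, seed = 7)
  sp <- structural_prior(img, rendered_grid(net), net$neuron_map)
  fg <- functional_graph(spk, reps = 30, n_pairs = 60, seed = 7)
  rg <- refine_functional(fg, sp)
  l <- rg$links
  # normalisation and bounds
  expect_equal(max(l$C_tilde), 1)
  expect_true(all(l$W <= l$C_tilde + 1e-12))
  expect_true(all(l$W >= 0 & l$W <= 1))
  expect_true(all(l$d_norm >= 0 & l$d_norm <= 1))
  # pruning removed every noise-electrode link
  pruned_nodes <- unique(c(l$a, l$b))
  expect_true(all(net$neuron_map[pruned_nodes] > 0))
  expect_equal(rg$counts$fc_pruned + rg$pruning$removed_links,
               rg$counts$fc_initial)
  # monotone refinement: final set no larger than the C_s set on the
  # same pruned universe
  expect_lte(rg$counts$fc_final, rg$counts$fc_pruned)
  expect_identical(l$retained, l$W >= rg$W_s)
  # determinism: same inputs give identical labels and thresholds
  rg2 <- refine_functional(fg, sp)
  expect_identical(rg$W_s, rg2$W_s)
  expect_identical(rg$links, rg2$links)
  # accounting mirrors the stage counts
  rep <- accounting_from_refined(rg)
  expect_equal(rep$fc_initial - rep$discarded_final, rg$counts$fc_final)
})

test_that("unreachable pairs carry maximal distance and a flag", {
  # structural graph with two components
  g <- electrode_grid(1, 4, pitch = 42)
  map <- matrix(0, 4, 4)
  map[1, 2] <- map[2, 1] <- 1
  map[3, 4] <- map[4, 3] <- 1
  sg <- structural_distances(manual_sc(map, 1:4), g, sc_threshold = 0.5)
  expect_true(sg$unreachable["1", "3"])
  expect_equal(sg$d_norm["1", "3"], 1)
  expect_false(sg$unreachable["1", "2"])
})
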